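direct_link <- function(rr, unit = 1) {
  list(rr = rr, unit = unit, pathway = "direct", mediator_slope = NA_real_)
}

test_that("population impact fraction matches enumeration on discrete spaces", {
  b <- discrete_distribution(c(0, 1), c(0.5, 0.5))
  cf <- discrete_distribution(c(0, 1), c(1, 0))

  # null counterfactual and unit RR both give exactly zero
  expect_identical(pif(b, b, direct_link(2), x_ref = 0), 0)
  expect_identical(pif(b, cf, direct_link(1), x_ref = 0), 0)

  # two-point space: (1.5 - 1)/1.5 = 1/3, exactly
  expect_equal(pif(b, cf, direct_link(2), x_ref = 0), 1 / 3)

  # brute-force enumeration oracle across random discrete distributions
  set.seed(7)
  for (rep in 1:20) {
    x <- sort(runif(5, 0, 10))
    pb <- runif(5); pb <- pb / sum(pb)
    pc <- runif(5); pc <- pc / sum(pc)
    rr <- exp(runif(1, -0.5, 0.7))
    got <- pif(discrete_distribution(x, pb), discrete_distribution(x, pc),
               direct_link(rr, unit = 2), x_ref = 3)
    want <- pif_enumerate(x, pb, pc, rr, x_ref = 3, unit = 2)
    expect_equal(got, want)
  }

  expect_error(pif(b, discrete_distribution(c(0, 2), c(1, 0)),
                   direct_link(2)), "common grid")
  bad <- b; bad$p <- bad$p * 2
  expect_error(pif(bad, cf, direct_link(2)), "non-normalised")
})

test_that("PIF is invariant to the reference exposure", {
  base <- intake_distribution(30, 12)
  cf <- intake_distribution(27, 12, grid = base$x)
  lk <- direct_link(0.91, unit = 7)
  p1 <- pif(base, cf, lk, x_ref = 0)
  p2 <- pif(base, cf, lk, x_ref = 30)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("discretised truncated normal is normalised and refinement-stable", {
  d <- intake_distribution(100, 40)
  expect_equal(sum(d$p), 1, tolerance = 1e-6)
  expect_true(all(d$x >= 0))

  # 1,000-point grid agrees with a 10,000-point reference
  base_lo <- intake_distribution(31, 13, grid_points = 1000)
  cf_lo <- intake_distribution(29, 13, grid = base_lo$x)
  base_hi <- intake_distribution(31, 13, grid_points = 10000)
  cf_hi <- intake_distribution(29, 13, grid = base_hi$x)
  lk <- direct_link(1.3)
  expect_equal(pif(base_lo, cf_lo, lk), pif(base_hi, cf_hi, lk),
               tolerance = 1e-3)
})

test_that("mediated links chain exposure through the mediator", {
  lk <- list(rr = 1.035, unit = 1, pathway = "via_sbp", mediator_slope = 0.001)
  expect_equal(mediated_shift(0, lk), 0)
  expect_equal(mediated_shift(-1000, lk), -1)

  # a salt reduction lowers blood pressure and protects against stroke
  base <- intake_distribution(2300, 900)
  cf <- intake_distribution(2300 - 1000, 900, grid = base$x)
  expect_gt(pif(base, cf, lk), 0)

  # linear chain equals the composition of the single-step slopes
  l1 <- list(rr = NA, unit = 1, pathway = "via_sbp", mediator_slope = 0.002)
  l2 <- list(rr = NA, unit = 1, pathway = "via_sbp", mediator_slope = 0.5)
  l12 <- list(rr = NA, unit = 1, pathway = "via_sbp",
              mediator_slope = 0.002 * 0.5)
  d <- -750
  expect_equal(mediated_shift(mediated_shift(d, l1), l2),
               mediated_shift(d, l12))

  # and the PIF through a mediated link equals the PIF computed directly
  # on the mediator scale (step-by-step oracle)
  med_base <- intake_distribution(2300 * 0.001, 900 * 0.001)
  med_cf <- intake_distribution(1300 * 0.001, 900 * 0.001, grid = med_base$x)
  expect_equal(pif(base, cf, lk),
               pif(med_base, med_cf, direct_link(1.035)), tolerance = 1e-9)

  expect_error(mediated_shift(1, direct_link(2)), "mediated links only")
  bad <- lk; bad$mediator_slope <- NA_real_
  expect_error(mediated_shift(1, bad), "mediator_slope")
  b2 <- discrete_distribution(c(0, 1), c(.5, .5))
  expect_error(pif(b2, b2, bad), "mediator_slope")
})

test_that("deaths averted scale with mortality and combine across links", {
  cfg <- study_config()
  inp <- gen_sales_and_mortality(cfg)
  zero <- setNames(rep(0, 10), nutrient_names())

  # zero delta: exactly zero in every cell
  r0 <- deaths_averted(zero, cfg$intake_total, cfg$intake_sd, cfg$links,
                       inp$population, inp$mortality)
  expect_identical(r0$total, 0)
  expect_true(all(r0$cells$averted == 0))
  expect_true(all(unlist(r0$by_factor) == 0))

  # single link, single stratum: deaths x PIF
  mort1 <- data.frame(sex = "male", age_band = "60-64", cause = "chd",
                      deaths = 1000L)
  links1 <- cfg$links[cfg$links$exposure == "fibre_g" &
                        cfg$links$cause == "chd", ]
  d <- zero; d["fibre_g"] <- 2
  r1 <- deaths_averted(d, cfg$intake_total, cfg$intake_sd, links1,
                       inp$population, mort1)
  p <- r1$link_pifs[[1]]
  expect_equal(r1$total, 1000 * p)

  # two links on one cause combine as 1 - (1-p1)(1-p2); with PIFs 0.1 and
  # 0.2 that is 0.28, i.e. 280 of 1000 deaths (joint-exposure oracle under
  # independence: survival fractions multiply)
  p12 <- 1 - (1 - 0.1) * (1 - 0.2)
  expect_equal(p12, 0.28)
  combined <- 1 - prod(1 - c(p, p))
  links2 <- rbind(links1, links1)
  r2 <- deaths_averted(d, cfg$intake_total, cfg$intake_sd, links2,
                       inp$population, mort1)
  expect_equal(r2$total, 1000 * combined)
  # sub-additivity of the combination
  expect_lte(r2$total, 2 * r1$total)

  # doubling population and mortality doubles the result exactly
  mort2 <- inp$mortality; mort2$deaths <- mort2$deaths * 2L
  ra <- deaths_averted(d, cfg$intake_total, cfg$intake_sd, cfg$links,
                       inp$population, inp$mortality)
  rb <- deaths_averted(d, cfg$intake_total, cfg$intake_sd, cfg$links,
                       inp$population, mort2)
  expect_equal(rb$total, 2 * ra$total)
  expect_equal(unclass(rb$by_sex), 2 * unclass(ra$by_sex))

  expect_error(deaths_averted(d, cfg$intake_total, cfg$intake_sd, cfg$links,
                              inp$population,
                              mort1[mort1$cause == "none", ]),
               "cause mismatch.*chd")
})

test_that("uniform dietary improvement averts deaths in every cell", {
  cfg <- study_config()
  inp <- gen_sales_and_mortality(cfg)
  d <- setNames(rep(0, 10), nutrient_names())
  d["satfat_g"] <- -2; d["sodium_mg"] <- -300; d["energy_kcal"] <- -80
  d["total_fat_g"] <- -3; d["fibre_g"] <- 1.5; d["fruit_g"] <- 30
  d["veg_g"] <- 20
  r <- deaths_averted(d, cfg$intake_total, cfg$intake_sd, cfg$links,
                      inp$population, inp$mortality)
  expect_true(all(r$link_pifs >= 0))
  expect_true(all(r$cells$averted >= 0))
  expect_true(all(unlist(r$by_factor) >= 0))
  expect_gte(r$with_energy_total, r$total)
  by_cg <- deaths_by_cause_group(r, cfg$mortality_params)
  expect_true(all(by_cg >= 0))
  expect_equal(sum(by_cg), r$total)
  # combined PIF never exceeds the sum of individual PIFs
  for (cs in unique(cfg$links$cause)) {
    ps <- r$link_pifs[cfg$links$cause == cs & cfg$links$factor_group != "energy"]
    expect_lte(1 - prod(1 - ps), sum(ps) + 1e-12)
  }
})
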