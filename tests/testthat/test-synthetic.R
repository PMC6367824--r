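test_that("claim flags reproduce the target prevalence structure", {
  cfg <- default_config()
  prods <- gen_product_survey(cfg, n_products = 4000, seed = 1, q = 0.26)
  overall <- mean(prods$has_hrc)
  expect_gte(overall, 0.24)
  expect_lte(overall, 0.28)

  # per-group realised prevalence within 3 binomial SEs of the target
  prev <- estimate_prevalence(prods)
  se <- sqrt(0.26 * 0.74 / prev$n)
  expect_true(all(abs(prev$q - 0.26) <= 3 * se))

  none <- gen_product_survey(cfg, n_products = 500, seed = 2, q = 0)
  expect_equal(sum(none$has_hrc), 0)

  expect_error(gen_product_survey(cfg, n_products = 100, seed = 1, q = 1.3),
               "prevalence")
})

test_that("claim-dependent mean shifts are realised in the survey", {
  # an absolute -43.7 kcal/100 g shift on one group, recovered at n = 1e5
  cfg <- default_config()
  g <- "fat_sugar"
  cfg$nqr$baseline[g, "energy_kcal"] <-
    (cfg$composition$mean_nonclaim[g, "energy_kcal"] - 43.7) /
    cfg$composition$mean_nonclaim[g, "energy_kcal"]
  prods <- gen_product_survey(cfg, n_products = 1e5, seed = 7)
  pg <- prods[prods$group == g, ]
  m1 <- mean(pg$energy_kcal[pg$has_hrc]); n1 <- sum(pg$has_hrc)
  m0 <- mean(pg$energy_kcal[!pg$has_hrc]); n0 <- sum(!pg$has_hrc)
  # expected difference of the doubly-truncated generating distributions
  cv <- cfg$composition$cv[["energy_kcal"]]
  mu0 <- cfg$composition$mean_nonclaim[g, "energy_kcal"]
  mu1 <- mu0 - 43.7
  exp_diff <- tnorm0_mean(mu1, cv * mu1, upper = 900) -
    tnorm0_mean(mu0, cv * mu0, upper = 900)
  se_diff <- sqrt(var(pg$energy_kcal[pg$has_hrc]) / n1 +
                    var(pg$energy_kcal[!pg$has_hrc]) / n0)
  expect_lt(abs((m1 - m0) - exp_diff), 3 * se_diff)
  expect_lt(abs(exp_diff + 43.7), 2)  # truncation bias negligible at defaults

  expect_error(rtnorm0(10, 5, -1), "negative SD")
})

test_that("prevalence estimator matches direct counts and the Wilson interval", {
  sv <- tiny_survey()
  g100 <- data.frame(id = 0, group = "dairy",
                     has_hrc = rep(c(TRUE, FALSE), c(26, 74)),
                     stringsAsFactors = FALSE)
  for (n in nutrient_names()) g100[[n]] <- 1
  g100$fvnl_percent <- 0
  prev <- estimate_prevalence(rbind(sv[sv$group != "dairy", ], g100))
  expect_equal(prev$q[prev$group == "dairy"], 0.26)

  # all flagged: q = 1 with CI upper at 1
  allf <- sv; allf$has_hrc <- TRUE
  pa <- estimate_prevalence(allf)
  expect_true(all(pa$q == 1))
  expect_true(all(pa$q_hi == 1))

  # 0 of 50: q = 0 but Wilson upper is positive, z^2/(n+z^2)
  ci <- wilson_ci(0, 50)
  expect_equal(ci$estimate, 0)
  z2 <- qnorm(0.975)^2
  expect_equal(ci$hi, z2 / (50 + z2))
  expect_gt(ci$hi, 0)

  # empty group flagged rather than dropped
  pe <- estimate_prevalence(sv[sv$group != "composite", ])
  expect_equal(pe$n[pe$group == "composite"], 0)
  expect_true(is.na(pe$q[pe$group == "composite"]))
})

test_that("NQR estimator computes stream-mean ratios with delta-method SEs", {
  sv <- tiny_survey()
  sv$energy_kcal[sv$group == "dairy"] <- c(200, 250)  # claim, non-claim
  est <- estimate_nqr(sv)
  expect_equal(est$nqr["dairy", "energy_kcal"], 0.8)
  # single observation per stream: NQR defined, SE missing
  expect_true(is.na(est$se["dairy", "energy_kcal"]))

  # identical streams give NQR 1 everywhere
  fresh <- tiny_survey()
  est1 <- estimate_nqr(rbind(fresh, fresh, fresh))
  expect_true(all(est1$nqr == 1))

  # two-product toy group: 100 vs 150 kcal -> 2/3
  sv2 <- sv
  sv2$energy_kcal[sv2$group == "starchy"] <- c(100, 150)
  expect_equal(estimate_nqr(sv2)$nqr["starchy", "energy_kcal"], 2 / 3)

  # zero non-claim mean: NQR reported missing
  sv3 <- sv
  sv3$fibre_g[sv3$group == "starchy" & !sv3$has_hrc] <- 0
  expect_true(is.na(estimate_nqr(sv3)$nqr["starchy", "fibre_g"]))

  # delta-method SE against the closed form on a 4-product group
  sv4 <- tiny_survey()
  extra <- sv4[sv4$group == "dairy", ]
  extra$id <- c(100, 101)
  extra$energy_kcal <- c(120, 160)
  sv4$energy_kcal[sv4$group == "dairy"] <- c(100, 200)
  sv4 <- rbind(sv4, extra)
  est4 <- estimate_nqr(sv4)
  a <- c(100, 120); b <- c(200, 160)
  r <- mean(a) / mean(b)
  se <- r * sqrt(var(a) / 2 / mean(a)^2 + var(b) / 2 / mean(b)^2)
  expect_equal(est4$se["dairy", "energy_kcal"], se)
})

test_that("generated sales reproduce the configured diet exactly", {
  cfg <- default_config()
  inp <- gen_sales_and_mortality(cfg)
  expect_equal(sum(inp$sales$energy_kcal), 1906.8)
  expect_equal(sum(inp$sales$fibre_g), 12.6)
  expect_equal(colSums(as.matrix(inp$sales[, nutrient_names()])),
               cfg$intake_total)
  expect_true(all(inp$mortality$deaths >= 0))
  expect_true(all(inp$mortality$deaths == round(inp$mortality$deaths)))

  # zero population gives an empty mortality table
  cfg0 <- cfg
  cfg0$population$count <- 0
  expect_equal(nrow(gen_sales_and_mortality(cfg0)$mortality), 0)
})

test_that("generation is reproducible for identical (config, seed)", {
  cfg <- default_config()
  a <- gen_product_survey(cfg, 2000, seed = 42)
  b <- gen_product_survey(cfg, 2000, seed = 42)
  expect_identical(a, b)
  c <- gen_product_survey(cfg, 2000, seed = 43)
  expect_false(identical(a, c))
  expect_identical(gen_sales_and_mortality(cfg), gen_sales_and_mortality(cfg))
})

test_that("synthetic input files are written and regenerable", {
  cfg <- default_config()
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(cfg, dir, n_products = 200, seed = 5)
  expect_true(all(file.exists(paths)))
  prods <- read.csv(paths[1])
  expect_equal(nrow(prods), 200)
  expect_true(all(nutrient_names() %in% names(prods)))
})
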