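test_that("null restriction and null reformulation reproduce baseline exactly", {
  cfg <- study_config()
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)

  q_base <- setNames(cfg$hrc_params$q_baseline, cfg$hrc_params$group)
  null_r <- build_restricted(base, q_base, cfg$nqr$baseline, cfg$hrc_params)
  expect_equal(null_r$intake_hrc, base$intake_hrc)
  expect_equal(null_r$intake_non, base$intake_non)
  expect_true(all(diet_delta(null_r, base) == 0))

  null_f <- build_reformulated(base, cfg$nqr$baseline)
  expect_true(all(diet_delta(null_f, base) == 0))
})

test_that("restriction to zero prevalence moves all intake to non-claim composition", {
  cfg <- study_config()
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)
  r0 <- build_restricted(base, setNames(rep(0, 8), base$groups$group),
                         cfg$nqr$pass_fsanz, cfg$hrc_params)
  expect_true(all(r0$intake_hrc == 0))
  expect_equal(unname(r0$groups$sales_non_g), unname(base$groups$sales_g))
  # group sales totals never change across scenarios
  expect_equal(r0$groups$sales_g, base$groups$sales_g)
})

test_that("restricted counterfactual matches the hand-solved toy group", {
  cfg <- study_config()
  sales <- toy_sales_table(cfg, "dairy", sales_g = 500, energy = 800)
  params <- cfg$hrc_params
  params[params$group == "dairy", c("q_baseline", "or")] <- c(0.5, 1)
  nqr <- cfg$nqr$baseline
  nqr["dairy", ] <- 1
  nqr["dairy", "energy_kcal"] <- 0.5
  base <- baseline_disaggregate(sales, params, nqr)
  # baseline: s = 0.5, conc_non = 213.33 kcal/100 g (hand solution)
  expect_equal(base$conc_non["dairy", "energy_kcal"], 640 / 3)

  # restrict to q_pass = 0.25 with nqr_pass = 0.4:
  # s' = 0.25; energy = 5 * (0.25 * 0.4 + 0.75) * 213.33 = 906.67 kcal
  nqr_pass <- nqr
  nqr_pass["dairy", "energy_kcal"] <- 0.4
  q_pass <- setNames(params$q_baseline, params$group)
  q_pass["dairy"] <- 0.25
  restr <- build_restricted(base, q_pass, nqr_pass, params)
  e_dairy <- restr$intake_hrc["dairy", "energy_kcal"] +
    restr$intake_non["dairy", "energy_kcal"]
  expect_equal(e_dairy, 5 * (0.25 * 0.4 + 0.75) * 640 / 3)  # 906.666...

  # reformulation toy: nqr 0.8 -> 0.5 at fixed split
  nqr3 <- nqr; nqr3["dairy", "energy_kcal"] <- 0.8
  base3 <- baseline_disaggregate(sales, params, nqr3)
  nqr3p <- nqr; nqr3p["dairy", "energy_kcal"] <- 0.5
  ref <- build_reformulated(base3, nqr3p)
  e3 <- ref$intake_hrc["dairy", "energy_kcal"] +
    ref$intake_non["dairy", "energy_kcal"]
  expect_equal(e3, 2000 / 3)  # 666.666... kcal, hand solution
})

test_that("pass-prevalence above baseline is rejected unless overridden", {
  cfg <- default_config()  # baseline-first reading has such groups
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)
  q_eu <- setNames(cfg$hrc_params$q_pass_eu, cfg$hrc_params$group)
  expect_error(build_restricted(base, q_eu, cfg$nqr$pass_eu, cfg$hrc_params),
               "exceeds q_baseline")
  ok <- build_restricted(base, q_eu, cfg$nqr$pass_eu, cfg$hrc_params,
                         allow_prevalence_increase = TRUE)
  expect_s3_class(ok, "diet_state")
  q_missing <- q_eu[-1]
  expect_error(build_restricted(base, q_missing[base$groups$group],
                                cfg$nqr$pass_eu, cfg$hrc_params,
                                allow_prevalence_increase = TRUE),
               "missing q_pass")
})

test_that("reformulation with a lower energy NQR strictly reduces energy", {
  cfg <- study_config()
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)
  lower <- cfg$nqr$baseline
  lower[, "energy_kcal"] <- lower[, "energy_kcal"] * 0.9
  ref <- build_reformulated(base, lower)
  d <- diet_delta(ref, base)
  expect_lt(d[["energy_kcal"]], 0)
  # reformulation dominance: for equal prevalence, the reformulated diet
  # has no more energy than the restricted one when pass NQR <= 1
  q_base <- setNames(cfg$hrc_params$q_baseline, cfg$hrc_params$group)
  restr <- build_restricted(base, q_base, lower, cfg$hrc_params)
  expect_lte(total_intake(ref)[["energy_kcal"]],
             total_intake(restr)[["energy_kcal"]] + 1e-9)
})

test_that("uniform boost variant reproduces the implied sales uplift", {
  cfg <- study_config()
  params <- cfg$hrc_params
  expect_equal(uniform_boost_params(params, 0)$or, rep(1, 8))

  sales <- gen_sales_and_mortality(cfg)$sales
  p16 <- uniform_boost_params(params, 0.16)
  no_boost <- uniform_boost_params(params, 0)
  st16 <- baseline_disaggregate(sales, p16, cfg$nqr$baseline)
  st0 <- baseline_disaggregate(sales, no_boost, cfg$nqr$baseline)
  expect_equal(st16$groups$sales_hrc_g, st0$groups$sales_hrc_g * 1.16)

  # larger boosts favour claim foods monotonically
  st75 <- baseline_disaggregate(sales, uniform_boost_params(params, 0.75),
                                cfg$nqr$baseline)
  expect_true(all(st75$groups$sales_hrc_g > st16$groups$sales_hrc_g))
  expect_error(or_from_boost(0.5, -1.2), "boost")
  expect_error(or_from_boost(0.9, 0.2), "boost too large")
})

test_that("diet deltas subtract by nutrient with strict group matching", {
  cfg <- study_config()
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)
  expect_true(all(diet_delta(base, base) == 0))

  # a single-nutrient perturbation propagates to exactly one component
  pert <- cfg$nqr$baseline
  pert[, "sugars_g"] <- pert[, "sugars_g"] * 0.8
  ref <- build_reformulated(base, pert)
  d <- diet_delta(ref, base)
  expect_lt(d[["sugars_g"]], 0)
  expect_true(all(d[setdiff(names(d), "sugars_g")] == 0))

  swapped <- base
  swapped$groups$group <- rev(swapped$groups$group)
  expect_error(diet_delta(swapped, base), "different food groups")
})

test_that("restriction of healthier claim foods raises energy intake", {
  # the central counterintuitive mechanism: claim foods are less energy
  # dense (NQR < 1); cutting their prevalence shifts purchases to denser
  # non-claim foods and energy intake rises
  cfg <- study_config()
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, cfg$hrc_params, cfg$nqr$baseline)
  q_red <- setNames(pmax(cfg$hrc_params$q_baseline - 0.10, 0),
                    cfg$hrc_params$group)
  restr <- build_restricted(base, q_red, cfg$nqr$baseline, cfg$hrc_params)
  expect_gt(diet_delta(restr, base)[["energy_kcal"]], 0)
})
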