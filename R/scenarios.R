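# Counterfactual diet construction.  Models "a" (claims restricted):
# claim-carrying foods failing the nutrient profile model lose their claim,
# their sales boost, and take on non-claim composition.  Models "b"
# (restricted + reformulation): prevalence is maintained, failing foods
# reformulate to pass, so only the claim stream's composition changes.
# Group sales totals are fixed in every scenario (substitution stays within
# food category); total nutrient intake is the quantity being measured.

#' Build the claims-restricted counterfactual (Models 1a/2a)
#'
#' Re-splits each group at the pass prevalence `q_pass` with the
#' pass-variant NQRs, keeping the baseline choice ORs and, crucially, the
#' baseline non-claim concentrations: foods that lose their claim are
#' assumed to take on the average composition of non-claim foods.
#'
#' @param baseline A baseline `diet_state`.
#' @param q_pass Named (or group-ordered) per-group pass prevalence.
#' @param nqr_pass Pass-variant NQR matrix, group x nutrient.
#' @param params `cfg$hrc_params`.
#' @param allow_prevalence_increase Permit `q_pass > q_baseline` (the source
#'   parameter table is ambiguous enough that some readings require this).
#' @return A `diet_state`.
#' @export
build_restricted <- function(baseline, q_pass, nqr_pass, params,
                             allow_prevalence_increase = FALSE) {
  grp <- baseline$groups$group
  nut <- nutrient_names()
  q_pass <- if (!is.null(names(q_pass))) q_pass[grp] else rep_len(q_pass, length(grp))
  if (any(is.na(q_pass)))
    stop("config error: missing q_pass for group ",
         paste(grp[is.na(q_pass)], collapse = ", "))
  j <- match(grp, params$group)
  if (!allow_prevalence_increase && any(q_pass > params$q_baseline[j] + 1e-12))
    stop("q_pass exceeds q_baseline for group ",
         paste(grp[q_pass > params$q_baseline[j] + 1e-12], collapse = ", "),
         " (set allow_prevalence_increase = TRUE to override)")
  s_new <- hrc_sales_share(q_pass, params$or[j])
  conc_non <- baseline$conc_non
  conc_hrc <- nqr_pass[grp, nut, drop = FALSE] * conc_non
  new_diet_state(grp, s_new, baseline$groups$sales_g, conc_hrc, conc_non)
}

#' Build the reformulation counterfactual (Models 1b/2b)
#'
#' Claim prevalence and the sales split stay at baseline; failing claim
#' foods reformulate, so the claim stream's concentration becomes the
#' pass-variant NQR times the baseline non-claim concentration.
#'
#' @param baseline A baseline `diet_state`.
#' @param nqr_pass Pass-variant NQR matrix, group x nutrient.
#' @return A `diet_state`.
#' @export
build_reformulated <- function(baseline, nqr_pass) {
  grp <- baseline$groups$group
  nut <- nutrient_names()
  conc_non <- baseline$conc_non
  conc_hrc <- nqr_pass[grp, nut, drop = FALSE] * conc_non
  new_diet_state(grp, baseline$groups$s_hrc, baseline$groups$sales_g,
                 conc_hrc, conc_non)
}

#' Uniform-boost sensitivity variant of the choice parameters
#'
#' Replaces every group's choice odds ratio by the OR implied by a uniform
#' relative sales increase of `boost` for claim-carrying foods (e.g. 0.16
#' for the natural-experiment estimate of a 16% sales uplift); the rest of
#' the pipeline is unchanged.
#'
#' @param params `cfg$hrc_params`.
#' @param boost Relative sales increase for claim foods, `> -1`.
#' @return `params` with `or` (and its CI, collapsed to the point) replaced.
#' @export
uniform_boost_params <- function(params, boost) {
  or <- or_from_boost(params$q_baseline, boost)
  params$or <- or
  params$or_lo <- or
  params$or_hi <- or
  params
}

#' Difference in population nutrient intake between two diet states
#'
#' Scenario minus baseline, per nutrient, per person per day; negative
#' values are reductions.
#'
#' @param scenario,baseline `diet_state`s over the same groups.
#' @return Named numeric vector of class `diet_delta`.
#' @export
diet_delta <- function(scenario, baseline) {
  if (!identical(scenario$groups$group, baseline$groups$group))
    stop("diet states cover different food groups")
  d <- total_intake(scenario) - total_intake(baseline)
  class(d) <- c("diet_delta", class(d))
  d
}

#' @export
print.diet_delta <- function(x, ...) {
  cat("<diet_delta> change in intake per person/day (scenario - baseline)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Run a regulation scenario end to end on the configured diet
#'
#' Convenience wrapper: builds the baseline diet state from the
#' configuration, constructs the requested counterfactual and returns both
#' states and the intake delta.  Scenario parameters (pass prevalences and
#' pass NQRs) come from the configuration by default, or from
#' `derived` as returned by [derive_scenario_params()] when the pipeline is
#' driven by a scored product survey.
#'
#' @param cfg An `hrc_config`.
#' @param model `"1a"`/`"2a"` (claims restricted under FSANZ / EU model),
#'   `"1b"`/`"2b"` (restricted + reformulation), or `"boost16"` (baseline
#'   recomputed under a uniform 16% sales boost; its natural comparator is
#'   the no-boost baseline).
#' @param derived Optional list with `q_pass_fsanz`, `q_pass_eu`,
#'   `nqr_pass_fsanz`, `nqr_pass_eu`, `nqr_baseline`, `q_baseline`
#'   overriding the configured tables (any subset).
#' @param allow_prevalence_increase Passed to [build_restricted()];
#'   defaults to the config option.
#' @return List: `baseline` and `scenario` diet states, `delta`.
#' @export
run_scenario <- function(cfg, model = c("1a", "2a", "1b", "2b", "boost16"),
                         derived = NULL,
                         allow_prevalence_increase =
                           cfg$options$allow_prevalence_increase) {
  model <- match.arg(model)
  params <- cfg$hrc_params
  nqr_base <- cfg$nqr$baseline
  if (!is.null(derived$q_baseline)) {
    params$q_baseline[match(names(derived$q_baseline), params$group)] <-
      derived$q_baseline
  }
  if (!is.null(derived$nqr_baseline)) nqr_base <- derived$nqr_baseline
  sales <- gen_sales_and_mortality(cfg)$sales
  base <- baseline_disaggregate(sales, params, nqr_base)

  pick <- function(nm, fallback) if (!is.null(derived[[nm]])) derived[[nm]] else fallback
  q_named <- function(col) stats::setNames(params[[col]], params$group)
  scen <- switch(model,
    "1a" = build_restricted(base, pick("q_pass_fsanz", q_named("q_pass_fsanz")),
                            pick("nqr_pass_fsanz", cfg$nqr$pass_fsanz), params,
                            allow_prevalence_increase),
    "2a" = build_restricted(base, pick("q_pass_eu", q_named("q_pass_eu")),
                            pick("nqr_pass_eu", cfg$nqr$pass_eu), params,
                            allow_prevalence_increase),
    "1b" = build_reformulated(base, pick("nqr_pass_fsanz", cfg$nqr$pass_fsanz)),
    "2b" = build_reformulated(base, pick("nqr_pass_eu", cfg$nqr$pass_eu)),
    "boost16" = baseline_disaggregate(sales, uniform_boost_params(params, 0.16),
                                      nqr_base))
  list(baseline = base, scenario = scen, delta = diet_delta(scen, base))
}

#' Derive scenario parameters from a scored product survey
#'
#' Runs both nutrient profile models over a product survey and returns the
#' realised baseline prevalence, pass prevalences and the baseline and
#' pass-variant NQR estimates -- the fully synthetic, end-to-end route into
#' [run_scenario()].  Missing NQR entries (empty stream or zero non-claim
#' mean, and the fruit/veg quantity columns) fall back to the configured
#' tables.
#'
#' @param products A `product_survey`.
#' @param cfg An `hrc_config`.
#' @param min_stream Minimum number of products a (claim or pass) stream
#'   must contain for its estimated NQRs to be used; smaller streams fall
#'   back to the configured tables, since a ratio of means over a handful
#'   of products is statistically meaningless.
#' @return List: `q_baseline`, `q_pass_fsanz`, `q_pass_eu` (named vectors),
#'   `nqr_baseline`, `nqr_pass_fsanz`, `nqr_pass_eu` (matrices), plus the
#'   underlying `prevalence` and NQR standard errors.
#' @export
derive_scenario_params <- function(products, cfg = default_config(),
                                   min_stream = 10) {
  fill <- function(est, fallback) {
    m <- fallback
    ok <- !is.na(est$nqr) & est$nqr > 0
    ok <- ok & (est$n_claim >= min_stream & est$n_nonclaim >= min_stream)
    m[rownames(est$nqr), colnames(est$nqr)][ok] <- est$nqr[ok]
    m
  }
  prev <- pass_prevalence(products, "fsanz", cfg)
  prev_eu <- pass_prevalence(products, "eu", cfg)
  pass_f <- score_products(products, "fsanz", cfg)$passes
  pass_e <- score_products(products, "eu", cfg)$passes
  est_base <- estimate_nqr(products)
  est_f <- estimate_nqr(products, pass_f)
  est_e <- estimate_nqr(products, pass_e)
  list(q_baseline = stats::setNames(prev$q_baseline, prev$group),
       q_pass_fsanz = stats::setNames(prev$q_pass, prev$group),
       q_pass_eu = stats::setNames(prev_eu$q_pass, prev_eu$group),
       nqr_baseline = fill(est_base, cfg$nqr$baseline),
       nqr_pass_fsanz = fill(est_f, cfg$nqr$pass_fsanz),
       nqr_pass_eu = fill(est_e, cfg$nqr$pass_eu),
       prevalence = prev,
       nqr_se = list(baseline = est_base$se, pass_fsanz = est_f$se,
                     pass_eu = est_e$se))
}
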