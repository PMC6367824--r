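# Monte Carlo propagation of parameter uncertainty to 95% uncertainty
# intervals (UIs), and one-at-a-time (tornado) variance decomposition.
# Sampled parameter groups: claim prevalences (logit-normal matched to
# their CIs), stream nutrient means behind the NQRs (normal with survey
# SEs), choice odds ratios and epidemiological relative risks (lognormal
# with sigma = log(upper/lower) / (2 * 1.96)).  Draws are shared between
# baseline and counterfactual within an iteration (common random numbers),
# otherwise the deltas would be noise-dominated.

#' Monte Carlo specification
#'
#' @param n_iter Number of iterations (`>= 1`; analyses in the source
#'   setting use 10000).
#' @param seed Integer base seed; iteration `i` uses a sub-seed derived
#'   from `(seed, i)` so single iterations are reproducible in isolation.
#' @param groups Parameter groups to sample; any subset of
#'   `"prevalence"`, `"nutrient_means"`, `"choice_ORs"`, `"epi_RRs"`.
#' @return An `mc_spec` list.
#' @export
mc_spec <- function(n_iter = 10000, seed = 1,
                    groups = c("prevalence", "nutrient_means",
                               "choice_ORs", "epi_RRs")) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  bad <- setdiff(groups, c("prevalence", "nutrient_means", "choice_ORs", "epi_RRs"))
  if (length(bad) > 0) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 groups = groups), class = "mc_spec")
}

# deterministic sub-seed per (seed, iteration), kept within 32-bit range
mc_iter_seed <- function(seed, iteration) {
  as.integer((as.double(seed) * 48271 + iteration * 104729) %% 2147483647)
}

#' Lognormal parameters from a point estimate and 95% CI
#'
#' Median at the point estimate, `sdlog = log(upper/lower) / (2 * 1.96)`.
#'
#' @param point,lo,hi Point estimate and 95% CI bounds (`0 < lo <= point <=
#'   hi`).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_from_ci <- function(point, lo, hi) {
  if (any(hi < lo)) stop("validation error: CI upper < lower")
  if (any(lo <= 0)) stop("lognormal CI requires positive bounds")
  list(meanlog = log(point), sdlog = log(hi / lo) / (2 * stats::qnorm(0.975)))
}

#' Sample a ratio parameter (OR or RR) lognormally from its 95% CI
#'
#' Degenerate CIs (`lo == hi`) give constant draws at the point estimate.
#'
#' @param n Number of draws. @inheritParams lognormal_from_ci
#' @return Numeric vector of draws.
#' @export
#' @examples
#' set.seed(1); quantile(sample_ratio(1e5, 1.75, 1.60, 1.91), c(.025, .975))
sample_ratio <- function(n, point, lo, hi) {
  par <- lognormal_from_ci(point, lo, hi)
  if (par$sdlog == 0) rep(point, n) else stats::rlnorm(n, par$meanlog, par$sdlog)
}

#' Sample a proportion logit-normally from its 95% CI
#'
#' Centre at `logit(point)`, `sd = (logit(hi) - logit(lo)) / (2 * 1.96)`;
#' degenerate CIs, and points at 0 or 1, give constant draws.
#'
#' @param n Number of draws. @param point,lo,hi Proportion and 95% CI.
#' @return Draws in (0, 1).
#' @export
sample_proportion <- function(n, point, lo, hi) {
  if (any(hi < lo)) stop("validation error: CI upper < lower")
  if (point <= 0 || point >= 1 || lo <= 0 || hi >= 1 || lo == hi)
    return(rep(point, n))
  sd <- (stats::qlogis(hi) - stats::qlogis(lo)) / (2 * stats::qnorm(0.975))
  stats::plogis(stats::rnorm(n, stats::qlogis(point), sd))
}

#' Draw one sampled parameter bundle
#'
#' Returns a copy of the configuration with the spec's parameter groups
#' perturbed: prevalences (baseline and pass, per group), the NQR tables
#' (via normal draws of the claim and non-claim stream means with their
#' survey standard errors), choice ORs and link RRs.  Draws are
#' reproducible per `(spec$seed, iteration)`.
#'
#' @param cfg An `hrc_config`. @param spec An [mc_spec()].
#' @param iteration Iteration index (`>= 1`).
#' @return A perturbed `hrc_config` (not revalidated: sampled prevalences
#'   remain in (0, 1) and NQRs positive by construction).
#' @export
sample_parameters <- function(cfg, spec, iteration = 1) {
  set.seed(mc_iter_seed(spec$seed, iteration))
  out <- cfg
  hp <- out$hrc_params
  if ("prevalence" %in% spec$groups) {
    for (stem in c("q_baseline", "q_pass_fsanz", "q_pass_eu")) {
      hp[[stem]] <- vapply(seq_len(nrow(hp)), function(i)
        sample_proportion(1, hp[[stem]][i], hp[[paste0(stem, "_lo")]][i],
                          hp[[paste0(stem, "_hi")]][i]), numeric(1))
    }
  }
  if ("choice_ORs" %in% spec$groups) {
    hp$or <- vapply(seq_len(nrow(hp)), function(i)
      sample_ratio(1, hp$or[i], hp$or_lo[i], hp$or_hi[i]), numeric(1))
  }
  out$hrc_params <- hp
  if ("nutrient_means" %in% spec$groups) {
    # claim-stream mean m_c = nqr * m_n; sample both stream means with the
    # survey SEs and recompute the ratio.  SE of the non-claim mean is
    # se(nqr) scaled to the mean; both truncated at a small positive floor.
    base_non <- cfg$composition$mean_nonclaim
    for (v in names(out$nqr)) {
      nqr <- cfg$nqr[[v]]
      se <- cfg$nqr_se[[v]]
      rel <- ifelse(nqr > 0, se / nqr, 0)        # relative SE of the ratio
      rel_each <- rel / sqrt(2)                  # split evenly across streams
      m_n <- base_non * (1 + rel_each * matrix(stats::rnorm(length(nqr)),
                                               nrow(nqr), ncol(nqr)))
      m_c <- nqr * base_non * (1 + rel_each * matrix(stats::rnorm(length(nqr)),
                                                     nrow(nqr), ncol(nqr)))
      m_n <- pmax(m_n, 1e-6 + 0 * m_n)
      m_c <- pmax(m_c, 0)
      drawn <- ifelse(base_non > 0, m_c / m_n, nqr)
      drawn <- pmax(drawn, 1e-6)
      drawn[, c("fruit_g", "veg_g")] <- 1
      out$nqr[[v]] <- drawn
    }
  }
  if ("epi_RRs" %in% spec$groups) {
    out$links$rr <- vapply(seq_len(nrow(out$links)), function(i)
      sample_ratio(1, out$links$rr[i], out$links$rr_lo[i], out$links$rr_hi[i]),
      numeric(1))
  }
  out
}

# one deterministic pipeline evaluation: scenario deltas + mortality impact
evaluate_pipeline <- function(cfg, model, derived = NULL,
                              allow_prevalence_increase = TRUE) {
  run <- run_scenario(cfg, model, derived = derived,
                      allow_prevalence_increase = allow_prevalence_increase)
  inp <- gen_sales_and_mortality(cfg)
  res <- deaths_averted(run$delta, cfg$intake_total, cfg$intake_sd,
                        cfg$links, inp$population, inp$mortality,
                        include_energy = TRUE,
                        grid_points = cfg$options$grid_points,
                        span = cfg$options$grid_span)
  by_cg <- deaths_by_cause_group(res, cfg$mortality_params)
  c(unclass(run$delta),
    stats::setNames(res$total, "deaths_total"),
    stats::setNames(res$with_energy_total, "deaths_total_with_energy"),
    stats::setNames(as.vector(res$by_sex), paste0("deaths_", names(res$by_sex))),
    stats::setNames(as.vector(by_cg), paste0("deaths_", names(by_cg))),
    stats::setNames(as.vector(res$by_factor),
                    paste0("deaths_factor_", names(res$by_factor))))
}

#' Monte Carlo uncertainty intervals for a regulation scenario
#'
#' Runs the full pipeline once at the central parameters (the point
#' estimate) and `spec$n_iter` times with sampled parameters, and returns
#' the 2.5th/97.5th percentile uncertainty interval for every output cell
#' (each nutrient's intake delta, and deaths averted in total, by sex, by
#' cause group, by risk factor, and including the energy pathway).
#'
#' @param cfg An `hrc_config`. @param model Scenario id, see
#'   [run_scenario()]. @param spec An [mc_spec()].
#' @param derived Optional derived scenario parameters (held fixed across
#'   iterations).
#' @param progress_every Print progress every this many iterations
#'   (0 = silent).
#' @return An `mc_result` data.frame: `cell`, `point`, `lo`, `hi`, plus
#'   attribute `"draws"` (iteration x cell matrix).
#' @export
monte_carlo <- function(cfg, model, spec = mc_spec(), derived = NULL,
                        progress_every = 0) {
  point <- evaluate_pipeline(cfg, model, derived)
  draws <- matrix(NA_real_, spec$n_iter, length(point),
                  dimnames = list(NULL, names(point)))
  for (i in seq_len(spec$n_iter)) {
    cfg_i <- sample_parameters(cfg, spec, i)
    res_i <- tryCatch(evaluate_pipeline(cfg_i, model, derived),
                      error = function(e)
                        stop("Monte Carlo iteration ", i, " failed: ",
                             conditionMessage(e)))
    draws[i, ] <- res_i
    if (progress_every > 0 && i %% progress_every == 0)
      message("  iteration ", i, "/", spec$n_iter)
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(cell = names(point), point = unname(point),
                    lo = qs[1, ], hi = qs[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "draws") <- draws
  class(out) <- c("mc_result", "data.frame")
  out
}

#' Tornado (one-at-a-time) uncertainty decomposition
#'
#' For each sampled parameter group, reruns the Monte Carlo varying only
#' that group (all others fixed at central values) and reports the width of
#' the 95% uncertainty interval of a chosen output cell, sorted descending.
#'
#' @param cfg An `hrc_config`. @param model Scenario id.
#' @param spec An [mc_spec()] (its `groups` are decomposed one at a time).
#' @param cell Output cell whose UI width is reported (default total deaths
#'   averted).
#' @param derived Optional derived scenario parameters.
#' @return Data frame `group`, `lo`, `hi`, `width`, sorted by width.
#' @export
tornado <- function(cfg, model, spec = mc_spec(), cell = "deaths_total",
                    derived = NULL) {
  if (length(spec$groups) < 2)
    stop("tornado analysis needs at least 2 parameter groups")
  rows <- lapply(spec$groups, function(g) {
    sp <- mc_spec(spec$n_iter, spec$seed, groups = g)
    mc <- monte_carlo(cfg, model, sp, derived)
    r <- mc[mc$cell == cell, ]
    data.frame(group = g, lo = r$lo, hi = r$hi, width = r$hi - r$lo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}
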