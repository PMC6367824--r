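# Synthetic study inputs: a product-label survey with group-specific claim
# prevalence and claim-dependent composition, purchase/intake tables that
# reproduce the configured population diet exactly, intake dispersions, and
# stratified population/mortality tables.

#' Truncated-at-zero normal draws
#'
#' Resamples (rejection) rather than clips, so realised means stay close to
#' the analytic truncated-normal mean rather than accumulating a point mass
#' at zero.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal; `sd` must be `>= 0`.
#'   Vectors are recycled to length `n`.
#' @param upper Optional upper truncation bound (a physical cap such as
#'   900 kcal/100 g for energy density), also enforced by resampling.
#' @return Numeric vector of draws in `[0, upper]`.
#' @export
rtnorm0 <- function(n, mean, sd, upper = Inf) {
  if (any(sd < 0)) stop("validation error: negative SD")
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > upper)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0 | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection sampling failed to converge")
  }
  out
}

#' Mean of a truncated normal distribution
#'
#' Closed form for a normal truncated below at zero and (optionally) above
#' at `upper`: the generating parameter that [gen_product_survey()] draws
#' actually realise, and the reference for parameter-recovery checks.
#'
#' @param mean,sd Parent-normal parameters.
#' @param upper Optional upper truncation bound.
#' @return The truncated mean (equals `mean` when `sd = 0`).
#' @export
tnorm0_mean <- function(mean, sd, upper = Inf) {
  out <- mean
  pos <- sd > 0
  a <- (0 - mean[pos]) / sd[pos]
  b <- (upper - mean[pos]) / sd[pos]
  z <- stats::pnorm(b) - stats::pnorm(a)
  out[pos] <- mean[pos] + sd[pos] * (stats::dnorm(a) - stats::dnorm(b)) / z
  out
}

#' Generate a synthetic pre-packaged food survey
#'
#' Emulates a product-label survey: products are allocated to food groups by
#' the configured mix, carry a health-related claim with the group's
#' baseline prevalence (Bernoulli), and draw each nutrient independently
#' from a truncated-at-zero normal whose mean depends on claim status
#' (claim mean = baseline NQR x non-claim mean; SD = CV x stream mean).
#' A percent fruit/vegetable/nut/legume content (`fvnl_percent`) is drawn
#' per product for nutrient-profile scoring.
#'
#' @param cfg An `hrc_config`.
#' @param n_products Number of products (`>= 1`).
#' @param seed Integer seed; identical `(cfg, n_products, seed)` give
#'   identical surveys.
#' @param q Optional named override of per-group claim prevalence (defaults
#'   to `cfg$hrc_params$q_baseline`).
#' @return A `product_survey` data.frame: `id`, `group`, `has_hrc`, one
#'   column per nutrient (per 100 g) and `fvnl_percent`.
#' @export
#' @examples
#' prods <- gen_product_survey(default_config(), n_products = 500, seed = 1)
#' table(prods$group, prods$has_hrc)
gen_product_survey <- function(cfg, n_products = cfg$survey$n_products,
                               seed = 1, q = NULL) {
  stopifnot(inherits(cfg, "hrc_config"))
  if (n_products < 1) stop("n_products must be >= 1")
  grp <- food_groups()
  nut <- nutrient_names()
  if (is.null(q)) {
    q <- stats::setNames(cfg$hrc_params$q_baseline, cfg$hrc_params$group)[grp]
  } else {
    q <- rep_len(q, length(grp))
    if (is.null(names(q))) names(q) <- grp
  }
  if (any(q < 0 | q > 1)) stop("validation error: prevalence outside [0, 1]")
  if (any(cfg$composition$mean_nonclaim < 0)) stop("validation error: negative mean")

  set.seed(seed)
  group <- sample(grp, n_products, replace = TRUE,
                  prob = cfg$survey$product_mix[grp])
  has_hrc <- stats::rbinom(n_products, 1L, q[group]) == 1L

  mean_non <- cfg$composition$mean_nonclaim
  mean_claim <- cfg$nqr$baseline[grp, nut, drop = FALSE] * mean_non[grp, nut, drop = FALSE]
  X <- matrix(0, n_products, length(nut), dimnames = list(NULL, nut))
  for (n in setdiff(nut, c("fruit_g", "veg_g"))) {
    m <- ifelse(has_hrc, mean_claim[group, n], mean_non[group, n])
    s <- cfg$composition$cv[[n]] * m
    up <- if (n == "energy_kcal") 900 else Inf
    X[, n] <- rtnorm0(n_products, m, s, upper = up)
  }
  fvnl_par <- cfg$composition$fvnl[match(group, cfg$composition$fvnl$group), ]
  fvnl <- rtnorm0(n_products, fvnl_par$mean, fvnl_par$sd, upper = 100)

  out <- data.frame(id = seq_len(n_products), group = group,
                    has_hrc = has_hrc, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  out$fvnl_percent <- fvnl
  check_nutrients(out, concentration = TRUE, what = "product survey")
  class(out) <- c("product_survey", "data.frame")
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes. @param n Trials. @param conf Confidence level.
#' @return List with `estimate`, `lo`, `hi`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lo = pmax(0, centre - half), hi = pmin(1, centre + half))
}

#' Estimate per-group claim prevalence from a product survey
#'
#' `q = claim count / group count`, with a Wilson score 95% CI.  Groups with
#' no products are flagged (`n = 0`, `q = NA`).
#'
#' @param products A `product_survey` (or data.frame with `group`, `has_hrc`).
#' @return Data frame with one row per food group: `group`, `n`, `n_hrc`,
#'   `q`, `q_lo`, `q_hi`; the overall prevalence and its CI are attached as
#'   attribute `"overall"`.
#' @export
estimate_prevalence <- function(products) {
  grp <- food_groups()
  n <- as.vector(table(factor(products$group, levels = grp)))
  k <- as.vector(tapply(products$has_hrc,
                        factor(products$group, levels = grp), sum))
  k[is.na(k)] <- 0
  out <- data.frame(group = grp, n = n, n_hrc = k,
                    q = NA_real_, q_lo = NA_real_, q_hi = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- n > 0
  ci <- wilson_ci(k[ok], n[ok])
  out$q[ok] <- ci$estimate; out$q_lo[ok] <- ci$lo; out$q_hi[ok] <- ci$hi
  tot <- wilson_ci(sum(k), sum(n))
  attr(out, "overall") <- c(q = tot$estimate, lo = tot$lo, hi = tot$hi)
  out
}

#' Estimate nutrient quality ratios from a product survey
#'
#' The NQR for a nutrient is the mean content per 100 g in claim-carrying
#' foods divided by the mean in non-claim foods, per group.  With an
#' `np_filter`, the numerator set is restricted to claim-carrying foods that
#' also pass the filter (the scenario-variant NQR).  Standard errors come
#' from the delta method on the ratio of two independent stream means; an
#' SE is reported missing when either stream has fewer than two products,
#' and the NQR itself is missing when the non-claim mean is zero or a
#' stream is empty.
#'
#' @param products A `product_survey`.
#' @param np_filter Optional logical vector (length `nrow(products)`) or a
#'   predicate `function(products) -> logical`, TRUE where a product passes
#'   the nutrient profile model.
#' @return List with matrices `nqr` and `se` (group x nutrient) plus
#'   `n_claim`, `n_nonclaim` per group.
#' @export
estimate_nqr <- function(products, np_filter = NULL) {
  grp <- food_groups()
  nut <- setdiff(nutrient_names(), c("fruit_g", "veg_g"))
  if (is.function(np_filter)) np_filter <- np_filter(products)
  pass <- if (is.null(np_filter)) rep(TRUE, nrow(products)) else np_filter
  num_set <- products$has_hrc & pass
  den_set <- !products$has_hrc

  nqr <- se <- matrix(NA_real_, length(grp), length(nut),
                      dimnames = list(grp, nut))
  n_claim <- n_non <- stats::setNames(integer(length(grp)), grp)
  for (g in grp) {
    ing <- products$group == g
    a <- products[ing & num_set, nut, drop = FALSE]
    b <- products[ing & den_set, nut, drop = FALSE]
    n_claim[g] <- nrow(a); n_non[g] <- nrow(b)
    if (nrow(a) == 0 || nrow(b) == 0) next
    ma <- colMeans(a); mb <- colMeans(b)
    r <- ifelse(mb > 0, ma / mb, NA_real_)
    nqr[g, ] <- r
    if (nrow(a) >= 2 && nrow(b) >= 2) {
      va <- apply(a, 2, stats::var) / nrow(a)
      vb <- apply(b, 2, stats::var) / nrow(b)
      se[g, ] <- ifelse(mb > 0 & ma > 0,
                        abs(r) * sqrt(va / ma^2 + vb / mb^2), NA_real_)
    }
  }
  list(nqr = nqr, se = se, n_claim = n_claim, n_nonclaim = n_non)
}

#' Generate baseline diet, population and mortality tables
#'
#' Builds the study's population-level inputs from the configuration: a
#' per-group sales/intake table whose nutrient totals equal the configured
#' population diet exactly (group intakes are fixed shares of each total),
#' the age/sex population table, a deaths-by-stratum-and-cause mortality
#' table from the configured age-rate model (counts rounded to integers),
#' and the intake standard deviations.  The construction is deterministic
#' given the configuration; `seed` is accepted for interface uniformity.
#'
#' @param cfg An `hrc_config`.
#' @param seed Unused beyond reproducibility bookkeeping.
#' @return List with `sales` (group, sales_g, one intake column per
#'   nutrient), `population`, `mortality` (sex, age_band, cause, deaths),
#'   `intake_sd`.
#' @export
#' @examples
#' inp <- gen_sales_and_mortality(default_config())
#' sum(inp$sales$energy_kcal) # printed baseline energy total
gen_sales_and_mortality <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "hrc_config"))
  grp <- food_groups()
  nut <- nutrient_names()
  if (any(cfg$intake_total < 0)) stop("validation error: negative intake total")

  intake <- sweep(cfg$intake_shares[grp, nut, drop = FALSE], 2,
                  cfg$intake_total[nut], "*")
  sales <- data.frame(group = grp,
                      sales_g = cfg$sales$sales_g[match(grp, cfg$sales$group)],
                      stringsAsFactors = FALSE)
  sales <- cbind(sales, as.data.frame(intake))

  pop <- cfg$population
  mp <- cfg$mortality_params
  agemid <- band_midpoint(pop$age_band)
  rows <- expand.grid(i = seq_len(nrow(pop)), j = seq_len(nrow(mp)))
  rate <- mp$rate60[rows$j] * exp(mp$slope[rows$j] * (agemid[rows$i] - 62.5)) *
    ifelse(pop$sex[rows$i] == "female", mp$female_mult[rows$j], 1)
  mortality <- data.frame(sex = pop$sex[rows$i],
                          age_band = pop$age_band[rows$i],
                          cause = mp$cause[rows$j],
                          deaths = as.integer(round(pop$count[rows$i] * rate)),
                          stringsAsFactors = FALSE)
  if (sum(pop$count) == 0) mortality <- mortality[0, ]
  list(sales = sales, population = pop, mortality = mortality,
       intake_sd = cfg$intake_sd)
}

# midpoint of an "a-b" or "a+" age band (open band assumed 7.5 years wide)
band_midpoint <- function(band) {
  lo <- as.numeric(sub("[-+].*$", "", band))
  open <- grepl("\\+", band)
  hi <- lo + 7.5
  hi[!open] <- as.numeric(sub("^.*-", "", band[!open])) + 1
  (lo + hi) / 2 - 0.5
}

#' Write the synthetic study inputs to CSV files
#'
#' @param cfg An `hrc_config`.
#' @param dir Output directory (created if needed).
#' @param n_products,seed Passed to [gen_product_survey()].
#' @return Invisibly, the paths written (`products.csv`, `sales.csv`,
#'   `population.csv`, `mortality.csv`).
#' @export
write_synthetic_inputs <- function(cfg, dir, n_products = cfg$survey$n_products,
                                   seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prods <- gen_product_survey(cfg, n_products, seed)
  inp <- gen_sales_and_mortality(cfg, seed)
  paths <- file.path(dir, c("products.csv", "sales.csv", "population.csv",
                            "mortality.csv"))
  utils::write.csv(prods, paths[1], row.names = FALSE)
  utils::write.csv(inp$sales, paths[2], row.names = FALSE)
  utils::write.csv(inp$population, paths[3], row.names = FALSE)
  utils::write.csv(inp$mortality, paths[4], row.names = FALSE)
  invisible(paths)
}
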