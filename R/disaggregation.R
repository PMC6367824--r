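# Split per-group sales and nutrient intake into claim (HRC) and non-claim
# streams so that stream sums reconstruct the observed totals exactly.

#' Claim-food share of purchases implied by prevalence and choice odds ratio
#'
#' The purchase odds ratio is read as an odds-scale boost: the odds that a
#' purchased item carries a claim equal OR times the odds that an available
#' item does, so `s = q OR / (q OR + (1 - q))`.  This is the only reading
#' consistent with a "likelihood of choosing a product when a claim is
#' present relative to when it is not" together with conservation of total
#' sales; an alternative reading needs only this function swapped.
#'
#' @param q Claim prevalence among available products, in \[0, 1\].
#' @param or_choice Choice odds ratio, `> 0`.  Both arguments vectorised.
#' @return Purchase share `s` in \[0, 1\], strictly increasing in both
#'   arguments (for `0 < q < 1`).
#' @export
#' @examples
#' hrc_sales_share(0.31, 1.92) # fruit & veg baseline
hrc_sales_share <- function(q, or_choice) {
  if (any(q < 0 | q > 1)) stop("prevalence outside [0, 1]")
  if (any(or_choice <= 0)) stop("odds ratio must be > 0")
  q * or_choice / (q * or_choice + (1 - q))
}

#' Odds ratio implied by a uniform relative sales boost
#'
#' Solves for the choice OR under which claim-food purchases exceed the
#' no-boost (OR = 1) counterfactual by a factor `1 + boost`:
#' `OR = (1 + boost) (1 - q) / (1 - q (1 + boost))`.
#'
#' @param q Claim prevalence. @param boost Relative sales increase,
#'   `> -1` and with `q (1 + boost) < 1`.
#' @return Odds ratio(s).
#' @export
or_from_boost <- function(q, boost) {
  if (any(boost <= -1)) stop("boost must be > -1")
  if (any(q * (1 + boost) >= 1))
    stop("boost too large: boosted share would reach 1")
  (1 + boost) * (1 - q) / (1 - q * (1 + boost))
}

#' Split one food group's sales and intake into claim/non-claim streams
#'
#' Given group totals, claim prevalence, choice OR and per-nutrient NQRs,
#' solves the stream concentrations in closed form so the streams
#' reconstruct the totals exactly: `sales_hrc = s * total`,
#' `conc_non(n) = total_intake(n) / ((sales_hrc * nqr(n) + sales_non)/100)`,
#' `conc_hrc = nqr * conc_non`.
#'
#' @param total_sales Group sales, g/person/day (`>= 0`).
#' @param total_intake Named nutrient vector, per person/day.
#' @param q,or_choice Claim prevalence and choice odds ratio.
#' @param nqr Named per-nutrient quality ratios (`> 0`).
#' @return List: `s_hrc`, `sales_hrc_g`, `sales_non_g`, `conc_hrc`,
#'   `conc_non` (per 100 g), `intake_hrc`, `intake_non` (per person/day).
#' @export
split_group <- function(total_sales, total_intake, q, or_choice, nqr) {
  if (total_sales < 0 || any(total_intake < 0)) stop("totals must be >= 0")
  if (any(nqr <= 0)) stop("nqr must be > 0")
  if (total_sales == 0) {
    if (any(total_intake > 0))
      stop("inconsistency error: zero sales with positive intake")
    z <- total_intake * 0
    return(list(s_hrc = 0, sales_hrc_g = 0, sales_non_g = 0,
                conc_hrc = z, conc_non = z, intake_hrc = z, intake_non = z))
  }
  s <- hrc_sales_share(q, or_choice)
  s_h <- s * total_sales
  s_n <- (1 - s) * total_sales
  conc_non <- total_intake / ((s_h * nqr + s_n) / 100)
  conc_non[total_intake == 0] <- 0
  conc_hrc <- nqr * conc_non
  list(s_hrc = s, sales_hrc_g = s_h, sales_non_g = s_n,
       conc_hrc = conc_hrc, conc_non = conc_non,
       intake_hrc = s_h * conc_hrc / 100, intake_non = s_n * conc_non / 100)
}

# assemble a diet_state from per-group split results
new_diet_state <- function(groups, s, sales_total, conc_hrc, conc_non) {
  intake_hrc <- conc_hrc * (s * sales_total) / 100
  intake_non <- conc_non * ((1 - s) * sales_total) / 100
  st <- list(groups = data.frame(group = groups, sales_g = sales_total,
                                 s_hrc = s,
                                 sales_hrc_g = s * sales_total,
                                 sales_non_g = (1 - s) * sales_total,
                                 stringsAsFactors = FALSE),
             conc_hrc = conc_hrc, conc_non = conc_non,
             intake_hrc = intake_hrc, intake_non = intake_non)
  class(st) <- "diet_state"
  st
}

#' Disaggregate the baseline diet into claim and non-claim streams
#'
#' Applies [split_group()] to every food group of a sales/intake table,
#' using the configured prevalences, choice ORs and baseline NQRs.  Stream
#' sums reconstruct the input totals exactly (closed form).
#'
#' @param sales Sales/intake table from [gen_sales_and_mortality()] (one
#'   row per group: `sales_g` plus a column per nutrient).
#' @param params `cfg$hrc_params` (or compatible data.frame).
#' @param nqr Baseline NQR matrix, group x nutrient.
#' @return A `diet_state`.
#' @export
#' @examples
#' cfg <- default_config()
#' st <- baseline_disaggregate(gen_sales_and_mortality(cfg)$sales,
#'                             cfg$hrc_params, cfg$nqr$baseline)
#' hrc_share(st, "energy_kcal")
baseline_disaggregate <- function(sales, params, nqr) {
  grp <- food_groups()
  nut <- nutrient_names()
  missing <- setdiff(grp, intersect(sales$group, params$group))
  if (length(missing) > 0)
    stop("missing food group(s): ", paste(missing, collapse = ", "))
  i <- match(grp, sales$group)
  j <- match(grp, params$group)
  conc_h <- conc_n <- matrix(0, length(grp), length(nut),
                             dimnames = list(grp, nut))
  s <- numeric(length(grp))
  for (k in seq_along(grp)) {
    sp <- split_group(sales$sales_g[i[k]],
                      unlist(sales[i[k], nut]),
                      params$q_baseline[j[k]], params$or[j[k]],
                      nqr[grp[k], nut])
    s[k] <- sp$s_hrc
    conc_h[k, ] <- sp$conc_hrc
    conc_n[k, ] <- sp$conc_non
  }
  new_diet_state(grp, s, sales$sales_g[i], conc_h, conc_n)
}

#' Total nutrient intake of a diet state
#' @param state A `diet_state`.
#' @return Named nutrient vector, per person per day.
#' @export
total_intake <- function(state) {
  colSums(state$intake_hrc) + colSums(state$intake_non)
}

#' Claim-food share of purchases or of a nutrient's intake
#'
#' @param state A `diet_state`.
#' @param what `"grams"` for the purchase-weight share, or a nutrient name
#'   for that nutrient's intake share.
#' @return A proportion in \[0, 1\].
#' @export
hrc_share <- function(state, what = "grams") {
  if (identical(what, "grams")) {
    sum(state$groups$sales_hrc_g) / sum(state$groups$sales_g)
  } else {
    stopifnot(what %in% nutrient_names())
    sum(state$intake_hrc[, what]) / (sum(state$intake_hrc[, what]) +
                                       sum(state$intake_non[, what]))
  }
}

#' @export
print.diet_state <- function(x, ...) {
  cat("<diet_state> ", nrow(x$groups), " food groups\n", sep = "")
  cat("  total purchases :", round(sum(x$groups$sales_g), 1), "g/person/day",
      sprintf("(HRC share %.1f%%)\n", 100 * hrc_share(x, "grams")))
  ti <- total_intake(x)
  cat("  total energy    :", round(ti[["energy_kcal"]], 1), "kcal/person/day",
      sprintf("(HRC share %.1f%%)\n", 100 * hrc_share(x, "energy_kcal")))
  invisible(x)
}

#' Export a diet state as a long data frame
#'
#' One row per group x stream, with sales and nutrient intakes; the shape
#' written by the command-line `baseline` subcommand.
#'
#' @param x A `diet_state`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.diet_state <- function(x, ...) {
  g <- x$groups
  rbind(
    data.frame(group = g$group, stream = "hrc", sales_g = g$sales_hrc_g,
               as.data.frame(x$intake_hrc), row.names = NULL),
    data.frame(group = g$group, stream = "non_hrc", sales_g = g$sales_non_g,
               as.data.frame(x$intake_non), row.names = NULL))
}
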