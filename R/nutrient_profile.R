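# Nutrient profile models gating claim eligibility: the FSANZ Nutrient
# Profiling Scoring Criterion (points-based) and a configurable EU-style
# per-group threshold model.

# Published NPSC points schedule, packaged as data.  Baseline points accrue
# for energy (335 kJ bands), saturated fat (1 g), total sugars (4.5 g) and
# sodium (90 mg); modifying points for fruit/veg/nut/legume content,
# protein (1.6 g) and fibre.  Strict ">" comparisons throughout.
npsc_schedule <- function() {
  list(energy_kj = 335 * (1:10),
       satfat_g  = 1 * (1:10),
       sugars_g  = 4.5 * (1:10),
       sodium_mg = 90 * (1:10),
       fibre_g   = c(0.9, 1.9, 2.8, 3.7, 4.7),
       protein_g = 1.6 * (1:5),
       fvnl_cuts = c(40, 60, 80),      # > cut -> points below
       fvnl_pts  = c(1, 2, 5),
       pass_below = c(`1` = 1, `2` = 4, `3` = 28),
       protein_gate_baseline = 13,     # baseline >= 13 withholds protein...
       protein_gate_fvnl = 5)          # ...unless FVNL points >= 5
}

band_points <- function(x, cuts) {
  # number of thresholds strictly exceeded, capped at length(cuts)
  rowSums(outer(x, cuts, ">"))
}

#' Score foods against the FSANZ Nutrient Profiling Scoring Criterion
#'
#' Computes baseline points (energy, saturated fat, total sugars, sodium),
#' modifying points (fruit/veg/nut/legume content, protein, fibre) and the
#' final score (baseline minus modifying) per the published points bands.
#' Energy is supplied in kcal and converted to kJ (x 4.184) before banding.
#' Protein points are withheld when baseline points reach 13 unless the
#' FVNL points are at least 5.  A food passes when its score is strictly
#' below the category threshold: category 1 (beverages) < 1, category 2
#' (foods) < 4, category 3 (fats and oils) < 28.
#'
#' @param nutrients Named nutrient vector per 100 g (see [nutrient_names()];
#'   `fruit_g`/`veg_g` ignored), or a matrix/data.frame of such rows.
#' @param category Scoring category, 1, 2 or 3 (recycled over rows).
#' @param fvnl_percent Percent fruit/vegetable/nut/legume content, 0-100.
#' @return A data.frame (`npsc_result`): `baseline_points`,
#'   `modifying_points`, `final_score`, `category`, `passes`.
#' @export
#' @examples
#' v <- c(energy_kcal = 2000 / 4.184, satfat_g = 5, sugars_g = 20,
#'        sodium_mg = 400, fibre_g = 2, protein_g = 5)
#' fsanz_score(v, category = 2, fvnl_percent = 0)
fsanz_score <- function(nutrients, category = 2, fvnl_percent = 0) {
  sch <- npsc_schedule()
  nm <- c("energy_kcal", "satfat_g", "sugars_g", "sodium_mg",
          "fibre_g", "protein_g")
  if (is.data.frame(nutrients)) nutrients <- as.matrix(
    nutrients[, intersect(colnames(nutrients), nutrient_names()), drop = FALSE])
  if (!is.matrix(nutrients)) {
    nutrients <- as_nutrient_vector(nutrients[intersect(names(nutrients),
                                                        nutrient_names())])
    nutrients <- matrix(nutrients, nrow = 1,
                        dimnames = list(NULL, names(nutrients)))
  } else {
    miss <- setdiff(nm, colnames(nutrients))
    if (length(miss) > 0)
      stop("missing nutrient component(s): ", paste(miss, collapse = ", "))
  }
  if (any(nutrients[, nm] < 0)) stop("validation error: negative nutrient")
  n <- nrow(nutrients)
  category <- rep_len(as.integer(category), n)
  if (any(!category %in% 1:3)) stop("invalid NPSC category")
  fvnl_percent <- rep_len(fvnl_percent, n)
  if (any(fvnl_percent < 0 | fvnl_percent > 100))
    stop("fvnl_percent must be within [0, 100]")

  baseline <- band_points(nutrients[, "energy_kcal"] * KJ_PER_KCAL, sch$energy_kj) +
    band_points(nutrients[, "satfat_g"], sch$satfat_g) +
    band_points(nutrients[, "sugars_g"], sch$sugars_g) +
    band_points(nutrients[, "sodium_mg"], sch$sodium_mg)
  fvnl_pts <- vapply(fvnl_percent, function(p) {
    i <- sum(p > sch$fvnl_cuts)
    if (i == 0) 0 else sch$fvnl_pts[i]
  }, numeric(1))
  fibre_pts <- band_points(nutrients[, "fibre_g"], sch$fibre_g)
  protein_pts <- band_points(nutrients[, "protein_g"], sch$protein_g)
  protein_pts[baseline >= sch$protein_gate_baseline &
                fvnl_pts < sch$protein_gate_fvnl] <- 0
  modifying <- fvnl_pts + fibre_pts + protein_pts
  score <- baseline - modifying
  out <- data.frame(baseline_points = as.integer(baseline),
                    modifying_points = as.integer(modifying),
                    final_score = as.integer(score),
                    category = category,
                    passes = score < sch$pass_below[as.character(category)])
  rownames(out) <- NULL
  class(out) <- c("npsc_result", "data.frame")
  out
}

#' EU-style threshold model pass decision
#'
#' A food passes when every thresholded nutrient (energy, saturated fat,
#' sugars, sodium per 100 g) is at or below its per-group cap.  The draft
#' EU model's actual structure is unpublished; this is a configurable
#' abstraction with illustrative packaged caps.
#'
#' @param nutrients Named nutrient vector per 100 g, or matrix/data.frame.
#' @param group Food group code(s), recycled over rows.
#' @param thresholds Per-group cap table (`cfg$eu_thresholds`).
#' @return Logical vector, TRUE where the food passes.
#' @export
eu_model_pass <- function(nutrients, group, thresholds) {
  capn <- c("energy_kcal", "satfat_g", "sugars_g", "sodium_mg")
  if (is.data.frame(nutrients)) nutrients <- as.matrix(nutrients[, capn, drop = FALSE])
  if (!is.matrix(nutrients))
    nutrients <- matrix(nutrients[capn], nrow = 1, dimnames = list(NULL, capn))
  idx <- match(group, thresholds$group)
  if (any(is.na(idx)))
    stop("config error: missing EU threshold entry for group ",
         paste(unique(group[is.na(idx)]), collapse = ", "))
  idx <- rep_len(idx, nrow(nutrients))
  caps <- as.matrix(thresholds[idx, capn, drop = FALSE])
  rowSums(nutrients[, capn, drop = FALSE] > caps) == 0
}

#' Score a product survey with a nutrient profile model
#'
#' Adds `final_score` (FSANZ only) and `passes` columns.
#'
#' @param products A `product_survey`.
#' @param model `"fsanz"` or `"eu"`.
#' @param cfg An `hrc_config` (category map and EU caps).
#' @return `products` with scoring columns appended.
#' @export
score_products <- function(products, model = c("fsanz", "eu"),
                           cfg = default_config()) {
  model <- match.arg(model)
  if (model == "fsanz") {
    res <- fsanz_score(products, category = cfg$npsc_category[products$group],
                       fvnl_percent = products$fvnl_percent)
    products$final_score <- res$final_score
    products$passes <- res$passes
  } else {
    products$passes <- eu_model_pass(products, products$group,
                                     cfg$eu_thresholds)
  }
  products
}

#' Per-group prevalence of claim-carrying foods that pass a profile model
#'
#' `q_pass = #(claim AND pass) / #(group)`, which can never exceed the
#' group's realised claim prevalence.
#'
#' @param products A `product_survey`.
#' @param model `"fsanz"` or `"eu"`, or a predicate
#'   `function(products) -> logical` for a custom scorer.
#' @param cfg An `hrc_config`.
#' @return Data frame per group: `n`, `n_hrc`, `n_pass`, `q_baseline`
#'   (realised), `q_pass`.
#' @export
pass_prevalence <- function(products, model = "fsanz", cfg = default_config()) {
  pass <- if (is.function(model)) model(products) else
    score_products(products, model, cfg)$passes
  grp <- food_groups()
  f <- factor(products$group, levels = grp)
  n <- as.vector(table(f))
  n_hrc <- as.vector(tapply(products$has_hrc, f, sum)); n_hrc[is.na(n_hrc)] <- 0
  n_pass <- as.vector(tapply(products$has_hrc & pass, f, sum)); n_pass[is.na(n_pass)] <- 0
  data.frame(group = grp, n = n, n_hrc = n_hrc, n_pass = n_pass,
             q_baseline = ifelse(n > 0, n_hrc / n, NA_real_),
             q_pass = ifelse(n > 0, n_pass / n, NA_real_),
             stringsAsFactors = FALSE)
}
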