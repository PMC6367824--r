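# Parameter bundle: claim-choice odds ratios and prevalences per Eatwell
# group, nutrient quality ratios (NQRs) per scenario variant, baseline
# intake totals and dispersions, demography/mortality inputs and the
# epidemiological risk-factor links.

# ---------------------------------------------------------------------------
# printed parameter table: one row per food group; three prevalence columns
# whose scenario semantics are ambiguous in the source table and therefore a
# config choice (see `prevalence_mapping`).  The starchy-carbohydrates OR CI
# and the oils-and-spreads row are documented fallbacks (see vignette).
hrc_printed_table <- function() {
  tab <- read.csv(text = "
group,or,or_lo,or_hi,p1,p1_lo,p1_hi,p2,p2_lo,p2_hi,p3,p3_lo,p3_hi
starchy,1.17,1.07,1.28,0.19,0.14,0.25,0.19,0.14,0.25,0.29,0.23,0.36
composite,1.06,0.91,1.24,0.12,0.08,0.17,0.14,0.10,0.20,0.16,0.12,0.22
fat_sugar,1.35,1.09,1.66,0.11,0.09,0.13,0.11,0.09,0.14,0.23,0.20,0.26
fruit_veg,1.92,1.56,2.35,0.31,0.25,0.39,0.30,0.23,0.37,0.33,0.26,0.41
protein_foods,2.42,1.87,3.12,0.09,0.06,0.13,0.12,0.08,0.16,0.18,0.14,0.22
dairy,1.25,1.22,1.27,0.37,0.30,0.45,0.40,0.32,0.47,0.46,0.39,0.54
miscellaneous,1.00,1.00,1.00,0.18,0.14,0.23,0.25,0.21,0.31,0.31,0.26,0.37
oils_spreads,1.75,1.60,1.91,0.26,0.24,0.28,0.26,0.24,0.28,0.26,0.24,0.28
", stringsAsFactors = FALSE)
  tab[match(food_groups(), tab$group), , drop = FALSE]
}

# survey-aggregate reference composition (per 100 g) and the mean
# claim-vs-non-claim shifts used to derive the default NQR tables
nqr_reference_shifts <- function() {
  nut <- c("energy_kcal", "protein_g", "total_fat_g", "satfat_g",
           "carbohydrate_g", "sugars_g", "fibre_g", "sodium_mg")
  ref <- c(250, 8, 11, 5.5, 28, 15, 2.2, 1150)
  shift <- rbind(
    baseline   = c(-43.7, -1.0, -3.0, -2.9, -4.0, -3.2, 0.7, -354.0),
    pass_fsanz = c(-56.0, -1.6, -3.5, -2.9, -6.0, -7.3, 1.0, -977.6),
    pass_eu    = c(-29.0, -1.0, -2.5, -2.0, -3.0, -3.0, 0.8, -842.0))
  colnames(shift) <- nut
  list(nutrients = nut, reference = stats::setNames(ref, nut), shift = shift)
}

# ---------------------------------------------------------------------------

#' Default model configuration
#'
#' Returns the packaged parameter bundle: per-food-group claim-choice odds
#' ratios and claim prevalences, nutrient quality ratio (NQR) tables for the
#' baseline and the two nutrient-profile pass variants, baseline nutrient
#' intake totals and their population standard deviations, a UK-like
#' population table, mortality-rate parameters, the epidemiological
#' risk-factor links (illustrative defaults; the published
#' comparative-risk-assessment RR catalogue is user-supplied config), the
#' synthetic product-survey composition model, the EU-style threshold table
#' and numerical options.
#'
#' @param prevalence_mapping How the three printed prevalence columns map to
#'   scenario roles.  `"baseline_first"` (default) reads them as (baseline,
#'   FSANZ-pass, EU-pass); `"pass_last"` reads them as (FSANZ-pass, EU-pass,
#'   baseline).  The source table's layout does not determine the mapping;
#'   only `"pass_last"` keeps every pass-prevalence at or below baseline.
#'   See the methods vignette.
#' @return An object of class `hrc_config` (a named list).
#' @export
#' @examples
#' cfg <- default_config()
#' subset(cfg$hrc_params, group == "fruit_veg")
default_config <- function(prevalence_mapping = c("baseline_first", "pass_last")) {
  prevalence_mapping <- match.arg(prevalence_mapping)
  grp <- food_groups()
  nut <- nutrient_names()

  tab <- hrc_printed_table()
  role <- switch(prevalence_mapping,
                 baseline_first = c(base = "p1", fsanz = "p2", eu = "p3"),
                 pass_last      = c(fsanz = "p1", eu = "p2", base = "p3"))
  pick <- function(r, suff = "") tab[[paste0(role[[r]], suff)]]
  hrc_params <- data.frame(
    group = tab$group,
    or = tab$or, or_lo = tab$or_lo, or_hi = tab$or_hi,
    q_baseline = pick("base"), q_baseline_lo = pick("base", "_lo"),
    q_baseline_hi = pick("base", "_hi"),
    q_pass_fsanz = pick("fsanz"), q_pass_fsanz_lo = pick("fsanz", "_lo"),
    q_pass_fsanz_hi = pick("fsanz", "_hi"),
    q_pass_eu = pick("eu"), q_pass_eu_lo = pick("eu", "_lo"),
    q_pass_eu_hi = pick("eu", "_hi"),
    stringsAsFactors = FALSE)

  # --- NQR tables: survey-aggregate claim/non-claim shifts applied as
  #     ratios, uniform across groups; fruit/veg quantities have NQR 1
  rs <- nqr_reference_shifts()
  ratio <- sweep(sweep(rs$shift, 2, rs$reference, "+"), 2, rs$reference, "/")
  nqr <- lapply(c(baseline = "baseline", pass_fsanz = "pass_fsanz",
                  pass_eu = "pass_eu"), function(v) {
    m <- matrix(1, length(grp), length(nut), dimnames = list(grp, nut))
    m[, rs$nutrients] <- rep(ratio[v, rs$nutrients], each = length(grp))
    m
  })

  # --- synthetic product-survey composition model (non-claim stream means
  #     per 100 g; claim means are NQR * non-claim mean)
  comp_mean <- rbind(
    starchy       = c(250, 8.0,  3.0, 0.80, 50, 3.0, 3.5, 420, 0, 0),
    fat_sugar     = c(450, 5.0, 22.0, 10.0, 55, 35,  1.5, 350, 0, 0),
    oils_spreads  = c(550, 0.3, 60.0, 22.0,  1, 0.5, 0.0, 650, 0, 0),
    dairy         = c(120, 5.0,  6.0, 3.50,  8, 8.0, 0.0, 150, 0, 0),
    protein_foods = c(200, 18., 12.0, 4.00,  3, 1.5, 0.5, 500, 0, 0),
    fruit_veg     = c( 55, 1.5,  0.6, 0.12, 11, 9.0, 2.5,  30, 0, 0),
    composite     = c(180, 7.0,  8.0, 3.00, 20, 4.0, 1.8, 450, 0, 0),
    miscellaneous = c(150, 2.0,  3.0, 1.00, 25, 15,  0.8, 300, 0, 0))
  colnames(comp_mean) <- nut
  comp_mean <- comp_mean[grp, , drop = FALSE]
  cv <- stats::setNames(
    c(0.30, 0.40, 0.45, 0.45, 0.35, 0.45, 0.45, 0.45, 0, 0), nut)
  fvnl <- data.frame(
    group = grp,
    mean = c(5, 5, 0, 0, 10, 85, 25, 10)[match(grp, food_groups())],
    sd   = c(5, 5, 2, 2, 10, 10, 15, 10)[match(grp, food_groups())],
    stringsAsFactors = FALSE)
  # se_inflation is a design-effect multiplier on the NQR standard errors:
  # the label survey's stream means carry heterogeneity (countries, product
  # sub-categories, skewed label values) well beyond simple random product
  # sampling, and that underpowered food-composition data is the model's
  # dominant uncertainty source
  survey <- list(
    n_products = 2000,
    product_mix = stats::setNames(
      c(0.16, 0.22, 0.03, 0.15, 0.16, 0.12, 0.08, 0.08), grp),
    se_inflation = 2.5)

  # --- baseline diet: per-group purchases (g/person/day) and the share of
  #     each nutrient total supplied by each group (columns sum to 1);
  #     totals reproduce the printed population diet exactly by construction
  sales <- data.frame(
    group = grp,
    sales_g = c(300, 170, 15, 255, 180, 282.3, 125, 190),
    stringsAsFactors = FALSE)
  intake_total <- stats::setNames(
    c(1906.8, 66.1, 79.7, 31.0, 233.8, 105.9, 12.6, 2300, 151.2, 131.1), nut)
  shares <- cbind(
    energy_kcal    = c(0.24, 0.20, 0.05, 0.10, 0.14, 0.065, 0.115, 0.09),
    protein_g      = c(0.18, 0.05, 0.00, 0.20, 0.44, 0.05, 0.06, 0.02),
    total_fat_g    = c(0.06, 0.30, 0.14, 0.17, 0.23, 0.01, 0.07, 0.02),
    satfat_g       = c(0.05, 0.32, 0.13, 0.22, 0.19, 0.01, 0.06, 0.02),
    carbohydrate_g = c(0.42, 0.24, 0.00, 0.05, 0.01, 0.09, 0.06, 0.13),
    sugars_g       = c(0.04, 0.42, 0.00, 0.10, 0.01, 0.17, 0.03, 0.23),
    fibre_g        = c(0.42, 0.08, 0.00, 0.01, 0.04, 0.30, 0.08, 0.07),
    sodium_mg      = c(0.24, 0.14, 0.02, 0.10, 0.26, 0.02, 0.14, 0.08),
    fruit_g        = c(0, 0, 0, 0, 0, 1, 0, 0),
    veg_g          = c(0, 0, 0, 0, 0, 1, 0, 0))
  rownames(shares) <- grp
  intake_sd <- stats::setNames(
    c(530, 22, 32, 13, 75, 48, 5.2, 900, 140, 110), nut)

  # --- demography (counts in persons, UK-like 2013 shape, ages 15+)
  bands <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49",
             "50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80-84",
             "85+")
  male <- 1000 * c(2050, 2200, 2180, 2150, 2000, 2200, 2330, 2210, 1950,
                   1800, 1700, 1300, 1000, 700, 450)
  female <- 1000 * c(1950, 2100, 2130, 2130, 2000, 2250, 2400, 2270, 2000,
                     1870, 1780, 1420, 1200, 950, 900)
  population <- data.frame(
    sex = rep(c("male", "female"), each = length(bands)),
    age_band = rep(bands, 2),
    count = c(male, female),
    stringsAsFactors = FALSE)

  # annual mortality-rate model per cause: rate(age, sex) =
  # rate60 * exp(slope * (agemid - 62.5)) * (female_mult if female)
  mortality_params <- data.frame(
    cause = c("chd", "stroke", "colorectal_cancer", "stomach_cancer"),
    cause_group = c("cvd", "cvd", "cancer", "cancer"),
    rate60 = c(1.69e-3, 6.4e-4, 4.15e-4, 1.25e-4),
    slope = c(0.095, 0.105, 0.075, 0.080),
    female_mult = c(0.45, 0.85, 0.72, 0.50),
    stringsAsFactors = FALSE)

  # --- exposure-outcome links (synthetic defaults, labelled illustrative:
  #     the published CRA model's RR catalogue is out of scope).  `unit` is
  #     the exposure change per application of `rr` for direct pathways, and
  #     the mediator change for mediated ones; `mediator_slope` is mediator
  #     units per exposure unit.
  links <- read.csv(text = "
exposure,cause,pathway,rr,rr_lo,rr_hi,unit,mediator_slope,factor_group
fruit_g,chd,direct,0.93,0.89,0.97,80,NA,fruit_veg
fruit_g,stroke,direct,0.90,0.85,0.95,80,NA,fruit_veg
fruit_g,stomach_cancer,direct,0.93,0.88,0.98,100,NA,fruit_veg
veg_g,chd,direct,0.94,0.90,0.98,80,NA,fruit_veg
veg_g,stroke,direct,0.92,0.87,0.97,80,NA,fruit_veg
fibre_g,chd,direct,0.91,0.86,0.96,7,NA,fibre
fibre_g,colorectal_cancer,direct,0.90,0.85,0.95,10,NA,fibre
satfat_g,chd,via_cholesterol,1.30,1.20,1.40,1,0.022,fats
total_fat_g,chd,via_bmi,1.06,1.02,1.10,1,0.008,fats
sodium_mg,chd,via_sbp,1.02,1.01,1.03,1,0.0010,salt
sodium_mg,stroke,via_sbp,1.035,1.02,1.05,1,0.0010,salt
energy_kcal,chd,via_bmi,1.06,1.02,1.10,1,0.0040,energy
energy_kcal,stroke,via_bmi,1.04,1.01,1.07,1,0.0040,energy
energy_kcal,colorectal_cancer,via_bmi,1.03,1.00,1.06,1,0.0040,energy
", stringsAsFactors = FALSE)

  # --- EU-style threshold model: per-group caps per 100 g (illustrative,
  #     non-authoritative stand-in for the unpublished draft model)
  eu_thresholds <- data.frame(
    group = grp,
    energy_kcal = c(350, 400, 650, 160, 260, 110, 230, 210),
    satfat_g    = c(2.5, 6.0, 32.0, 3.0, 4.5, 1.5, 3.5, 2.5),
    sugars_g    = c(12, 30, 5, 13, 5, 16, 9, 16),
    sodium_mg   = c(500, 450, 750, 250, 550, 150, 500, 400),
    stringsAsFactors = FALSE)

  npsc_category <- stats::setNames(
    ifelse(grp == "oils_spreads", 3L, 2L), grp)

  cfg <- list(
    prevalence_mapping = prevalence_mapping,
    hrc_params = hrc_params,
    nqr = nqr,
    composition = list(mean_nonclaim = comp_mean, cv = cv, fvnl = fvnl),
    survey = survey,
    sales = sales,
    intake_total = intake_total,
    intake_shares = shares,
    intake_sd = intake_sd,
    population = population,
    mortality_params = mortality_params,
    links = links,
    eu_thresholds = eu_thresholds,
    npsc_category = npsc_category,
    options = list(salt_per_sodium_g = 2.5,
                   grid_points = 1000L,
                   grid_span = 6,
                   allow_prevalence_increase = FALSE))
  cfg$nqr_se <- nqr_se_from_survey(cfg)
  order <- c("prevalence_mapping", "hrc_params", "nqr", "nqr_se",
             "composition", "survey", "sales", "intake_total",
             "intake_shares", "intake_sd", "population", "mortality_params",
             "links", "eu_thresholds", "npsc_category", "options")
  cfg <- cfg[order]
  class(cfg) <- "hrc_config"
  validate_config(cfg)
  cfg
}

# standard errors of the NQR entries implied by the survey design
# (delta method on the ratio of two stream means, per group and nutrient);
# these carry the "underpowered food-label survey" uncertainty into the
# Monte Carlo analysis
nqr_se_from_survey <- function(cfg) {
  grp <- food_groups()
  nut <- nutrient_names()
  n_grp <- cfg$survey$n_products * cfg$survey$product_mix[grp]
  q <- cfg$hrc_params$q_baseline[match(grp, cfg$hrc_params$group)]
  n_claim <- pmax(q * n_grp, 2)
  n_non <- pmax((1 - q) * n_grp, 2)
  infl <- if (is.null(cfg$survey$se_inflation)) 1 else cfg$survey$se_inflation
  rel <- infl * sqrt(outer(1 / n_claim + 1 / n_non, cfg$composition$cv[nut]^2))
  lapply(cfg$nqr, function(m) m * rel)
}

#' The calibrated study configuration
#'
#' [default_config()] under the `"pass_last"` prevalence reading, which is
#' the only reading of the printed parameter table under which every
#' nutrient-profile pass-prevalence stays at or below its baseline and the
#' published baseline claim-food purchase shares (about 37% of purchase
#' grams and 29% of energy, i.e. roughly 559 of 1906.8 kcal/person/day) are
#' reproducible.  Used by the packaged acceptance analyses; see the methods
#' vignette for the calibration.
#'
#' @return An `hrc_config`.
#' @export
#' @examples
#' st <- baseline_disaggregate(gen_sales_and_mortality(study_config())$sales,
#'                             study_config()$hrc_params,
#'                             study_config()$nqr$baseline)
#' round(hrc_share(st, "energy_kcal"), 3)
study_config <- function() default_config(prevalence_mapping = "pass_last")

#' Validate a configuration bundle
#'
#' Checks the structural invariants of an `hrc_config`: all eight food
#' groups present everywhere, prevalences in \[0, 1\] with ordered CIs that
#' contain the point estimate, positive odds ratios (miscellaneous group
#' fixed at 1), positive finite NQRs, intake shares summing to one,
#' non-negative population counts, and risk-factor links whose causes exist
#' in the mortality model and whose mediated pathways define a slope.
#'
#' @param cfg An `hrc_config`.
#' @return `cfg`, invisibly classed, if valid; otherwise an error naming the
#'   offending group/field.
#' @export
validate_config <- function(cfg) {
  grp <- food_groups()
  nut <- nutrient_names()
  hp <- cfg$hrc_params
  missing <- setdiff(grp, hp$group)
  if (length(missing) > 0)
    stop("config schema error: missing food group(s) in hrc_params: ",
         paste(missing, collapse = ", "))
  for (stem in c("q_baseline", "q_pass_fsanz", "q_pass_eu")) {
    for (suff in c("", "_lo", "_hi")) {
      v <- hp[[paste0(stem, suff)]]
      bad <- which(!is.finite(v) | v < 0 | v > 1)
      if (length(bad) > 0)
        stop("config validation error: ", stem, suff, " outside [0, 1] for group ",
             paste(hp$group[bad], collapse = ", "))
    }
    lo <- hp[[paste0(stem, "_lo")]]; hi <- hp[[paste0(stem, "_hi")]]
    p <- hp[[stem]]
    bad <- which(lo > p | p > hi)
    if (length(bad) > 0)
      stop("config validation error: ", stem, " CI does not contain point for group ",
           paste(hp$group[bad], collapse = ", "))
  }
  if (any(hp$or <= 0))
    stop("config validation error: non-positive odds ratio")
  bad <- which(hp$or_lo > hp$or | hp$or > hp$or_hi)
  if (length(bad) > 0)
    stop("config validation error: or CI does not contain point for group ",
         paste(hp$group[bad], collapse = ", "))
  if (abs(hp$or[hp$group == "miscellaneous"] - 1) > 1e-12)
    stop("config validation error: miscellaneous group must have or = 1")

  for (v in names(cfg$nqr)) {
    m <- cfg$nqr[[v]]
    if (!all(grp %in% rownames(m)) || !all(nut %in% colnames(m)))
      stop("config schema error: nqr$", v, " must cover all groups and nutrients")
    if (any(!is.finite(m)) || any(m <= 0))
      stop("config validation error: nqr$", v, " entries must be finite and > 0")
  }

  if (any(cfg$sales$sales_g < 0))
    stop("config validation error: negative sales")
  if (!all(grp %in% cfg$sales$group))
    stop("config schema error: missing food group(s) in sales")
  cs <- colSums(cfg$intake_shares[grp, nut, drop = FALSE])
  if (any(abs(cs - 1) > 1e-9))
    stop("config validation error: intake_shares columns must each sum to 1 (",
         paste(names(cs)[abs(cs - 1) > 1e-9], collapse = ", "), ")")
  check_nutrients(cfg$intake_total, what = "intake_total")
  if (any(cfg$intake_sd[setdiff(nut, c("fruit_g", "veg_g"))] <= 0))
    stop("config validation error: intake SDs must be positive")

  if (any(cfg$population$count < 0))
    stop("config validation error: negative population count")
  if (any(!cfg$population$sex %in% c("male", "female")))
    stop("config validation error: sex must be male/female")

  lk <- cfg$links
  unknown <- setdiff(lk$cause, cfg$mortality_params$cause)
  if (length(unknown) > 0)
    stop("config validation error: link cause(s) missing from mortality model: ",
         paste(unique(unknown), collapse = ", "))
  if (any(lk$rr <= 0) || any(lk$rr_lo > lk$rr) || any(lk$rr > lk$rr_hi))
    stop("config validation error: link RRs must be positive with CI containing the point")
  med <- lk$pathway != "direct"
  if (any(med & !is.finite(lk$mediator_slope)))
    stop("config error: mediated link without a mediator_slope")
  if (!all(grp %in% cfg$eu_thresholds$group))
    stop("config schema error: missing food group(s) in eu_thresholds")
  invisible(cfg)
}

#' @export
print.hrc_config <- function(x, ...) {
  cat("<hrc_config>\n")
  cat("  prevalence mapping :", x$prevalence_mapping, "\n")
  cat("  food groups        :", nrow(x$hrc_params), "\n")
  cat("  baseline energy    :", x$intake_total[["energy_kcal"]], "kcal/person/day\n")
  cat("  causes of death    :", paste(x$mortality_params$cause, collapse = ", "), "\n")
  cat("  risk-factor links  :", nrow(x$links), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialisation

mat_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}
list_to_mat <- function(l) {
  rows <- names(l)
  cols <- names(l[[1]])
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in rows) m[r, ] <- unlist(l[[r]])[cols]
  m
}
df_to_list <- function(d) lapply(d, function(col) as.vector(col))
list_to_df <- function(l) {
  l <- lapply(l, function(col) if (is.list(col)) unlist(col) else col)
  as.data.frame(l, stringsAsFactors = FALSE)
}

config_to_plain <- function(cfg) {
  list(prevalence_mapping = cfg$prevalence_mapping,
       hrc_params = df_to_list(cfg$hrc_params),
       nqr = lapply(cfg$nqr, mat_to_list),
       nqr_se = lapply(cfg$nqr_se, mat_to_list),
       composition = list(mean_nonclaim = mat_to_list(cfg$composition$mean_nonclaim),
                          cv = as.list(cfg$composition$cv),
                          fvnl = df_to_list(cfg$composition$fvnl)),
       survey = list(n_products = cfg$survey$n_products,
                     product_mix = as.list(cfg$survey$product_mix),
                     se_inflation = cfg$survey$se_inflation),
       sales = df_to_list(cfg$sales),
       intake_total = as.list(cfg$intake_total),
       intake_shares = mat_to_list(cfg$intake_shares),
       intake_sd = as.list(cfg$intake_sd),
       population = df_to_list(cfg$population),
       mortality_params = df_to_list(cfg$mortality_params),
       links = df_to_list(cfg$links),
       eu_thresholds = df_to_list(cfg$eu_thresholds),
       npsc_category = as.list(cfg$npsc_category),
       options = cfg$options)
}

plain_to_config <- function(pl) {
  named_vec <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  cfg <- list(
    prevalence_mapping = pl$prevalence_mapping,
    hrc_params = list_to_df(pl$hrc_params),
    nqr = lapply(pl$nqr, list_to_mat),
    nqr_se = lapply(pl$nqr_se, list_to_mat),
    composition = list(mean_nonclaim = list_to_mat(pl$composition$mean_nonclaim),
                       cv = named_vec(pl$composition$cv),
                       fvnl = list_to_df(pl$composition$fvnl)),
    survey = list(n_products = pl$survey$n_products,
                  product_mix = named_vec(pl$survey$product_mix),
                  se_inflation = pl$survey$se_inflation),
    sales = list_to_df(pl$sales),
    intake_total = named_vec(pl$intake_total),
    intake_shares = list_to_mat(pl$intake_shares),
    intake_sd = named_vec(pl$intake_sd),
    population = list_to_df(pl$population),
    mortality_params = list_to_df(pl$mortality_params),
    links = list_to_df(pl$links),
    eu_thresholds = list_to_df(pl$eu_thresholds),
    npsc_category = {
      v <- unlist(pl$npsc_category)
      storage.mode(v) <- "integer"
      v
    },
    options = pl$options)
  cfg$links$mediator_slope <- as.numeric(cfg$links$mediator_slope)
  cfg$options$grid_points <- as.integer(cfg$options$grid_points)
  class(cfg) <- "hrc_config"
  cfg
}

#' Write a configuration to YAML (or JSON)
#'
#' @param cfg An `hrc_config`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`, the latter requiring jsonlite).
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hrc_config"))
  pl <- config_to_plain(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write JSON configs")
    writeLines(jsonlite::toJSON(pl, auto_unbox = TRUE, digits = NA, null = "null"),
               path)
  } else {
    writeLines(yaml::as.yaml(pl, precision = 15), path)
  }
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON parameter bundle written by [write_config()] (the
#' packaged default lives at
#' `system.file("extdata", "default_config.yaml", package = "hrcimpact")`)
#' and validates it.  Missing groups raise a schema error naming the group;
#' out-of-range proportions raise a validation error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated `hrc_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "default_config.yaml",
#'                                package = "hrcimpact"))
#' subset(cfg$hrc_params, group == "dairy")$q_baseline
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  pl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON configs")
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- plain_to_config(pl)
  validate_config(cfg)
  cfg
}
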