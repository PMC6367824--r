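# Independent oracles and small fixture builders used across the suite.

# Brute-force NPSC oracle: literal published band tables, findInterval with
# open left limits (count of cuts strictly below x), scalar logic -- an
# implementation path disjoint from the package's banding code.
npsc_oracle <- function(energy_kcal, satfat_g, sugars_g, sodium_mg,
                        fibre_g, protein_g, fvnl_percent, category = 2) {
  below <- function(x, cuts) findInterval(x, cuts, left.open = TRUE)
  kj <- energy_kcal * 4.184
  base <- below(kj, c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)) +
    below(satfat_g, 1:10) +
    below(sugars_g, c(4.5, 9, 13.5, 18, 22.5, 27, 31.5, 36, 40.5, 45)) +
    below(sodium_mg, c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900))
  vp <- if (fvnl_percent > 80) 5 else if (fvnl_percent > 60) 2 else
    if (fvnl_percent > 40) 1 else 0
  fp <- below(fibre_g, c(0.9, 1.9, 2.8, 3.7, 4.7))
  pp <- below(protein_g, c(1.6, 3.2, 4.8, 6.4, 8.0))
  if (base >= 13 && vp < 5) pp <- 0
  score <- base - (vp + fp + pp)
  passes <- score < c(1, 4, 28)[category]
  list(baseline = base, modifying = vp + fp + pp, score = score,
       passes = passes)
}

# Discrete-choice simulation: a shelf of products, purchase probability
# proportional to the choice weight (OR for claim items), realised claim
# share of purchases.  Returns the simulated share, the analytic share
# implied by the realised shelf prevalence, and its Monte Carlo SE.
simulate_choice_share <- function(q, or, n_shelf = 4000, n_draws = 2e5) {
  claim <- stats::rbinom(n_shelf, 1, q) == 1
  w <- ifelse(claim, or, 1)
  picks <- sample.int(n_shelf, n_draws, replace = TRUE, prob = w)
  s_hat <- mean(claim[picks])
  q_hat <- mean(claim)
  s_exp <- q_hat * or / (q_hat * or + (1 - q_hat))
  list(s_hat = s_hat, s_exp = s_exp, se = sqrt(s_exp * (1 - s_exp) / n_draws))
}

# Brute-force PIF by explicit enumeration of a discrete outcome space.
pif_enumerate <- function(x, p_base, p_cf, rr_per_unit, x_ref = 0, unit = 1) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    rr <- rr_per_unit^((x[i] - x_ref) / unit)
    den <- den + p_base[i] * rr
    num <- num + (p_base[i] - p_cf[i]) * rr
  }
  num / den
}

# A minimal single-group sales table for direct split checks.
toy_sales_table <- function(cfg, group = "dairy", sales_g = 500,
                            energy = 800) {
  sl <- gen_sales_and_mortality(cfg)$sales
  sl[sl$group == group, "sales_g"] <- sales_g
  sl[sl$group == group, "energy_kcal"] <- energy
  sl
}

# A tiny hand-built product survey covering all groups (so group-structure
# preconditions hold); two products per group, one claim-carrying, all
# nutrients at 1 except energy at 100.  Tests modify rows as needed.
tiny_survey <- function() {
  base <- do.call(rbind, lapply(food_groups(), function(g)
    data.frame(group = g, has_hrc = c(TRUE, FALSE), stringsAsFactors = FALSE)))
  base <- cbind(id = seq_len(nrow(base)), base)
  for (n in nutrient_names()) base[[n]] <- 1
  base$energy_kcal <- 100
  base$fvnl_percent <- 0
  base
}

central_config <- function() study_config()
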