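# Synthetic study generator.
#
# Stands in for the unavailable survey, footprint, emission-factor,
# expenditure and mortality inputs. Food-group attributes are drawn within
# published plausibility for the Indian setting; pattern-level totals are
# rejection-sampled into the magnitudes of the baseline study population
# (energy 2300-3400 kcal/day, blue water 550-900 L/day, GHG 1.8-3.5
# kgCO2e/day). A tiny three-food fixture with a closed-form optimum serves
# as an analytic oracle for the optimiser.

#' Specification of a synthetic study
#'
#' @param n_food_groups number of food groups (>= 3; >= 12 covers all
#'   category tags), default 36.
#' @param n_patterns number of dietary patterns (>= 1), default 5.
#' @param seed integer seed.
#' @param energy_range,bwf_range,ghg_range per-pattern acceptance ranges for
#'   dietary energy (kcal/day), blue water (L/day) and GHG (kgCO2e/day).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_food_groups = 36L, n_patterns = 5L, seed = 1L,
                           energy_range = c(2300, 3400),
                           bwf_range = c(550, 900),
                           ghg_range = c(1.8, 3.5)) {
  n_food_groups <- as.integer(n_food_groups)
  n_patterns <- as.integer(n_patterns)
  if (n_food_groups < 3L) stop_validation("synthetic spec: n_food_groups must be >= 3")
  if (n_patterns < 1L) stop_validation("synthetic spec: n_patterns must be >= 1")
  for (r in list(energy_range, bwf_range, ghg_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop_validation("synthetic spec: ranges must be positive with low <= high")
    }
  }
  structure(list(n_food_groups = n_food_groups, n_patterns = n_patterns,
                 seed = as.integer(seed),
                 energy_range = as.numeric(energy_range),
                 bwf_range = as.numeric(bwf_range),
                 ghg_range = as.numeric(ghg_range)),
            class = "synthetic_spec")
}

# Per-category attribute ranges (per gram of food as consumed) and typical
# daily intakes. bwf ranges span almost two orders of magnitude between
# vegetables and irrigated cereals so water-driven substitution is possible.
food_category_table <- function() {
  cat_row <- function(tag, carb, fat, protein, fsug_frac, sodium, bwf, ghg, intake) {
    data.frame(tag = tag,
               carb_lo = carb[1], carb_hi = carb[2],
               fat_lo = fat[1], fat_hi = fat[2],
               prot_lo = protein[1], prot_hi = protein[2],
               fsug_lo = fsug_frac[1], fsug_hi = fsug_frac[2],
               sod_lo = sodium[1], sod_hi = sodium[2],
               bwf_lo = bwf[1], bwf_hi = bwf[2],
               ghg_lo = ghg[1], ghg_hi = ghg[2],
               intake = intake, stringsAsFactors = FALSE)
  }
  rbind(
    cat_row("cereal",    c(.70, .80), c(.010, .030), c(.07, .12), c(0, 0),     c(.01, .10), c(0.45, 1.00), c(8e-4, 3.0e-3), 450),
    cat_row("legume",    c(.55, .65), c(.020, .060), c(.20, .26), c(0, 0),     c(.05, .30), c(0.60, 1.40), c(8e-4, 1.5e-3),  80),
    cat_row("vegetable", c(.04, .08), c(.002, .010), c(.01, .03), c(0, 0),     c(.10, .50), c(0.02, 0.12), c(3e-4, 8e-4),   300),
    cat_row("fruit",     c(.10, .20), c(.002, .010), c(.005, .015), c(.4, .7), c(.01, .05), c(0.05, 0.60), c(4e-4, 1.0e-3), 150),
    cat_row("red_meat",  c(0, .010),  c(.08, .20),  c(.18, .25), c(0, 0),     c(.50, .90), c(0.30, 0.60), c(1.2e-2, 2.5e-2), 10),
    cat_row("poultry",   c(0, .010),  c(.06, .14),  c(.20, .27), c(0, 0),     c(.50, .90), c(0.70, 1.20), c(4e-3, 8e-3),    15),
    cat_row("dairy",     c(.04, .06), c(.03, .09),  c(.03, .05), c(0, 0),     c(.40, .60), c(0.20, 0.45), c(2e-3, 4e-3),   350),
    cat_row("fish",      c(0, .010),  c(.02, .10),  c(.18, .24), c(0, 0),     c(.60, 1.0), c(0.03, 0.15), c(3e-3, 6e-3),    15),
    cat_row("egg",       c(.01, .02), c(.09, .11),  c(.12, .14), c(0, 0),     c(1.2, 1.5), c(0.50, 1.00), c(4e-3, 5e-3),    15),
    cat_row("oil",       c(0, 0),     c(.96, 1.0),  c(0, 0),     c(0, 0),     c(0, .01),   c(0.40, 1.50), c(2e-3, 3e-3),    35),
    cat_row("sugar",     c(.98, 1.0), c(0, 0),      c(0, 0),     c(.90, .97), c(.01, .05), c(0.30, 0.90), c(1e-3, 2e-3),    40),
    cat_row("other",     c(.30, .50), c(.10, .20),  c(.05, .10), c(.1, .3),   c(1.0, 3.0), c(0.20, 0.60), c(2e-3, 4e-3),    30)
  )
}

# Assign categories to n food groups: one of each in priority order first,
# remainder cycled over the staple-heavy categories.
assign_categories <- function(n) {
  cats <- food_category_table()$tag
  fill <- c("cereal", "vegetable", "fruit", "legume", "dairy", "oil")
  out <- cats[seq_len(min(n, length(cats)))]
  if (n > length(cats)) {
    out <- c(out, rep(fill, length.out = n - length(cats)))
  }
  out
}

#' Generate a synthetic food-group table
#'
#' Draws per-gram attributes uniformly within category-specific plausibility
#' ranges; energy is set exactly to the Atwater value of the drawn
#' macronutrients (4/9/4 kcal per g). Blue-water spatial SDs default to 20%
#' of the mean. Expenditure shares are normalised to sum to 0.95 with SEs of
#' 10% of the share; elasticities are uniform in [-1.5, -0.3].
#'
#' @param spec a `synthetic_spec`.
#' @return a validated `food_table` with `spec$n_food_groups` rows.
#' @export
generate_food_table <- function(spec) {
  ct <- food_category_table()
  cats <- assign_categories(spec$n_food_groups)
  with_seed(spec$seed, {
    rows <- lapply(seq_along(cats), function(i) {
      r <- ct[ct$tag == cats[i], ]
      carb <- stats::runif(1, r$carb_lo, r$carb_hi)
      fat <- stats::runif(1, r$fat_lo, r$fat_hi)
      protein <- stats::runif(1, r$prot_lo, r$prot_hi)
      fsug <- carb * stats::runif(1, r$fsug_lo, r$fsug_hi)
      # The first cereal plays the part of irrigated rice: always present and
      # always near the top of the cereal water range.
      bwf <- if (cats[i] == "cereal" && i == match("cereal", cats)) {
        stats::runif(1, 0.85 * r$bwf_hi, r$bwf_hi)
      } else {
        stats::runif(1, r$bwf_lo, r$bwf_hi)
      }
      data.frame(
        id = sprintf("fg%02d", i),
        name = sprintf("%s group %d", cats[i], i),
        energy_kcal_per_g = ATWATER[["carb"]] * carb + ATWATER[["fat"]] * fat +
          ATWATER[["protein"]] * protein,
        carb_g_per_g = carb, fat_g_per_g = fat, protein_g_per_g = protein,
        free_sugar_g_per_g = fsug,
        sodium_mg_per_g = stats::runif(1, r$sod_lo, r$sod_hi),
        bwf_l_per_g = bwf, bwf_sd_l_per_g = 0.2 * bwf,
        ghg_kgco2e_per_g = stats::runif(1, r$ghg_lo, r$ghg_hi),
        exp_share = NA_real_, exp_share_se = NA_real_,
        elasticity = -stats::runif(1, 0.3, 1.5),
        tags = cats[i], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    raw_share <- stats::rgamma(nrow(df), shape = 2)
    df$exp_share <- 0.95 * raw_share / sum(raw_share)
    df$exp_share_se <- 0.10 * df$exp_share
    food_table(df)
  })
}

# Archetype category multipliers and energy targets for the five pattern
# templates (cycled if n_patterns != 5).
pattern_archetypes <- function() {
  base <- rep(1, 12)
  names(base) <- food_category_table()$tag
  mk <- function(name, energy, cereal_bias, ...) {
    mult <- base
    tweaks <- list(...)
    mult[names(tweaks)] <- unlist(tweaks)
    list(name = name, energy = energy, mult = mult, cereal_bias = cereal_bias)
  }
  # cereal_bias concentrates cereal intake on the most water-intensive
  # cereal foods (rice-dominated diets), raising the diet's blue water per
  # kcal the way irrigated rice does.
  list(
    mk("rice and low diversity", c(2350, 2550), 1.0, cereal = 1.10,
       fruit = 0.40, vegetable = 0.60, dairy = 0.50, legume = 0.55,
       oil = 0.65, poultry = 0.5, red_meat = 0.5, fish = 0.5, egg = 0.5,
       other = 0.5),
    mk("rice and fruit", c(2650, 2900), 0.6, fruit = 2.2, cereal = 1.00,
       dairy = 0.80, legume = 0.80),
    mk("wheat and pulses", c(2900, 3150), 0.3, legume = 1.8, vegetable = 1.5,
       fruit = 0.5, dairy = 1.2, cereal = 1.10, red_meat = 0.4,
       poultry = 0.4, fish = 0.3),
    mk("wheat, rice, and oils", c(3200, 3400), 0.3, oil = 1.6, cereal = 1.25,
       dairy = 1.10, sugar = 1.2),
    mk("rice and meat", c(2550, 2850), 0.6, red_meat = 2.5, poultry = 2.5,
       fish = 2.5, egg = 1.8, dairy = 0.90, fruit = 0.8)
  )
}

#' Generate synthetic dietary patterns calibrated to study magnitudes
#'
#' For each pattern, food-level consumption is drawn log-normally around
#' category archetypes, scaled exactly to a drawn energy target, and
#' accepted only if pattern-level blue water and GHG fall within the spec
#' ranges (at most 1000 attempts, otherwise an informative error).
#' Between-person SDs are set to 25% of the mean with a 1 g/day floor.
#' Population shares are normalised random draws.
#'
#' @param foods a `food_table` from [generate_food_table()].
#' @param spec the same `synthetic_spec`.
#' @return list of `dietary_pattern`, validated against `foods`.
#' @export
generate_patterns <- function(foods, spec) {
  arch <- pattern_archetypes()
  ct <- food_category_table()
  intake <- stats::setNames(ct$intake, ct$tag)
  cats <- vapply(foods$tags, function(s) food_tags(s)[1], character(1),
                 USE.NAMES = FALSE)
  n_in_cat <- table(cats)
  base_food <- intake[cats] / as.numeric(n_in_cat[cats])
  with_seed(spec$seed + 1L, {
    shares <- stats::runif(spec$n_patterns, 0.1, 0.3)
    shares <- shares / sum(shares)
    patterns <- lapply(seq_len(spec$n_patterns), function(p) {
      a <- arch[[(p - 1L) %% length(arch) + 1L]]
      e_lo <- max(a$energy[1], spec$energy_range[1])
      e_hi <- min(a$energy[2], spec$energy_range[2])
      cereal_sel <- cats == "cereal"
      for (attempt in seq_len(1000L)) {
        cons <- base_food * a$mult[cats] *
          exp(stats::rnorm(nrow(foods), 0, 0.25)) *
          exp(stats::rnorm(1, 0, 0.10))
        if (a$cereal_bias > 0 && sum(cereal_sel) > 1) {
          wb <- foods$bwf_l_per_g[cereal_sel]^(4 * a$cereal_bias *
                                                 stats::runif(1, 0.5, 1.5))
          cons[cereal_sel] <- sum(cons[cereal_sel]) *
            cons[cereal_sel] * wb / sum(cons[cereal_sel] * wb)
        }
        target_e <- stats::runif(1, e_lo, e_hi)
        e <- sum(cons * foods$energy_kcal_per_g)
        cons <- cons * target_e / e
        bwf <- sum(cons * foods$bwf_l_per_g)
        ghg <- sum(cons * foods$ghg_kgco2e_per_g)
        if (bwf >= spec$bwf_range[1] && bwf <= spec$bwf_range[2] &&
            ghg >= spec$ghg_range[1] && ghg <= spec$ghg_range[2]) {
          nm <- if (spec$n_patterns <= length(arch)) a$name
                else sprintf("%s #%d", a$name, p)
          return(dietary_pattern(nm, stats::setNames(cons, foods$id),
                                 stats::setNames(pmax(0.25 * cons, 1), foods$id),
                                 shares[p]))
        }
      }
      stop_validation(paste0(
        "generate_patterns: could not reach the target ranges for pattern %d ",
        "in 1000 attempts (last draw: energy %.0f kcal, bwf %.0f L, ghg %.2f kg)"),
        p, target_e, bwf, ghg)
    })
    validate_patterns(patterns, foods)
  })
}

#' Generate synthetic historical life tables
#'
#' Three calendar years (1990, 2000, 2010) of single-year life tables, ages
#' 0--100, with a Gompertz-like adult hazard (monotone increasing above age
#' 30), an infant-mortality component, a gently declining secular trend, and
#' cause-specific fractions for each modelled outcome within [0.005, 0.15]
#' of the all-cause rate.
#'
#' @param spec a `synthetic_spec`.
#' @return list of three `life_table`s.
#' @export
generate_life_tables <- function(spec) {
  years <- c(1990, 2000, 2010)
  trend <- c(1.25, 1.11, 1.00)
  ages <- 0:100
  with_seed(spec$seed + 2L, {
    base_rate <- 0.03 * exp(-0.6 * ages) + 0.00025 * exp(0.075 * ages)
    population <- 1e5 * exp(-0.028 * ages)
    frac_noise <- exp(stats::rnorm(length(OUTCOMES), 0, 0.1))
    names(frac_noise) <- OUTCOMES
    cause_frac <- function(outcome, trend_k) {
      f <- switch(outcome,
        CHD = 0.010 + 0.0018 * ages,
        stroke = 0.005 + 0.0010 * ages,
        T2D = 0.005 + 0.0004 * ages,
        0.004 + 0.0003 * ages)  # cancers
      f <- f * frac_noise[[outcome]] * trend_k
      pmin(pmax(f, 0.005), 0.15)
    }
    lapply(seq_along(years), function(k) {
      all_cause <- base_rate * trend[k]
      # Cause fractions drift mildly across years (cardiometabolic up,
      # others flat) so the polynomial projection has a trend to follow.
      cr <- vapply(OUTCOMES, function(o) {
        drift <- if (o %in% c("CHD", "stroke", "T2D")) 1 + 0.03 * (k - 3) else 1
        cause_frac(o, drift) * all_cause
      }, numeric(length(ages)))
      life_table(years[k], ages, population, all_cause, cr)
    })
  })
}

#' Default exposure-response catalogue
#'
#' Configuration placeholders on the published-evidence scale: protective
#' log-linear effects of fruit (RR 0.95 per 100 g/day for CHD and stroke,
#' 0.96 for the five cancers) and vegetables (0.96 for CHD and stroke);
#' harmful effects of red meat (1.10 per 100 g/day for type 2 diabetes,
#' 1.12 for colorectal cancer). CIs are +/- 0.03 on the RR scale.
#'
#' @return list of `exposure_response`.
#' @export
default_exposure_responses <- function() {
  mk <- function(exposure, outcome, rr) {
    exposure_response(exposure, outcome, rr, ci_low = rr - 0.03,
                      ci_high = rr + 0.03, unit_size = 100)
  }
  cancers <- grep("^cancer", OUTCOMES, value = TRUE)
  c(list(mk("fruit", "CHD", 0.95), mk("fruit", "stroke", 0.95)),
    lapply(cancers, function(o) mk("fruit", o, 0.96)),
    list(mk("vegetable", "CHD", 0.96), mk("vegetable", "stroke", 0.96),
         mk("red_meat", "T2D", 1.10), mk("red_meat", "cancer_colorectum", 1.12)))
}

#' Generate a complete synthetic study
#'
#' Bundles foods, patterns, life tables, exposure-response catalogue, lag
#' curves and nutrient rules generated from one spec.
#'
#' @param spec a `synthetic_spec`.
#' @return list with elements `foods`, `patterns`, `life_tables`,
#'   `exposure_responses`, `lags`, `rules`, `spec`.
#' @export
generate_study <- function(spec = synthetic_spec()) {
  foods <- generate_food_table(spec)
  list(foods = foods,
       patterns = generate_patterns(foods, spec),
       life_tables = generate_life_tables(spec),
       exposure_responses = default_exposure_responses(),
       lags = default_lag_curves(),
       rules = nutrient_rules(),
       spec = spec)
}

# ---------------------------------------------------------------------------
# Analytic fixture with closed-form optimum

#' Three-food analytic fixture with a closed-form optimum
#'
#' A deliberately tiny problem in which only two constraints can be active:
#' blue water pinned to `L` and energy pinned to the baseline energy. All
#' objective weights are 1 (equal expenditure shares, unit elasticities) and
#' the nutrient rules are wide open, so the optimum solves the
#' two-constraint equality-constrained minimisation of the sum of squared
#' percentage changes -- a linear (KKT) system with an exact solution, see
#' [analytic_fixture_optimum()].
#'
#' @return list with `foods` (3 rows), `pattern`, `scenario` (15% water
#'   reduction), `rules` (non-binding), and `L`.
#' @export
make_analytic_fixture <- function() {
  df <- data.frame(
    id = c("staple", "veg", "oil"),
    name = c("staple", "veg", "oil"),
    energy_kcal_per_g = c(3.5, 0.6, 9.0),
    carb_g_per_g = c(0.80, 0.10, 0),
    fat_g_per_g = c(0.02, 0.01, 1.0),
    protein_g_per_g = c(0.03, 0.02, 0),
    free_sugar_g_per_g = c(0, 0, 0),
    sodium_mg_per_g = c(0.05, 0.2, 0),
    bwf_l_per_g = c(1.2, 0.1, 0.5),
    bwf_sd_l_per_g = c(0.24, 0.02, 0.1),
    ghg_kgco2e_per_g = c(0.002, 0.0005, 0.0025),
    exp_share = c(0.2, 0.2, 0.2),
    exp_share_se = c(0.02, 0.02, 0.02),
    elasticity = c(-1, -1, -1),
    tags = c("cereal", "vegetable", "oil"),
    stringsAsFactors = FALSE)
  foods <- food_table(df)
  cm <- stats::setNames(c(300, 200, 100), foods$id)
  pattern <- dietary_pattern("analytic", cm, pmax(0.25 * cm, 1), 1)
  sc <- scenario("fixture", 0.15, 40L)
  rules <- nutrient_rules(carb_energy_bounds = c(0, 1),
                          fat_energy_bounds = c(0, 1),
                          protein_energy_bounds = c(0, 1),
                          free_sugar_energy_max = 1,
                          sodium_max = 1e9, fruit_veg_min = 0,
                          energy_tolerance = 1e-9)
  W0 <- sum(cm * foods$bwf_l_per_g)
  list(foods = foods, pattern = pattern, scenario = sc, rules = rules,
       L = (1 - sc$reduction) * W0)
}

#' Closed-form optimum of the analytic fixture
#'
#' Solves the stationarity system of minimising
#' `sum_i (100 (c_i - b_i) / b_i)^2` subject to `a' c = L` and `e' c = E0`
#' by Lagrange multipliers: `c = b - (lambda a + mu e) .* b^2 / (2 * 100^2)`
#' with `(lambda, mu)` from the 2x2 linear system the two equalities impose.
#'
#' @param fixture the list returned by [make_analytic_fixture()].
#' @return list with `consumption` (optimal g/day), `objective`,
#'   `lambda`, `mu`.
#' @export
analytic_fixture_optimum <- function(fixture) {
  b <- unname(fixture$pattern$consumption_mean)
  a <- fixture$foods$bwf_l_per_g
  e <- fixture$foods$energy_kcal_per_g
  L <- fixture$L
  E0 <- sum(b * e)
  W0 <- sum(b * a)
  k <- b^2 / (2 * 1e4)  # c_i = b_i - k_i (lambda a_i + mu e_i)
  S <- matrix(c(sum(k * a * a), sum(k * a * e),
                sum(k * a * e), sum(k * e * e)), 2, 2)
  rhs <- c(W0 - L, E0 - E0)
  lm2 <- solve(S, rhs)
  cons <- b - k * (lm2[1] * a + lm2[2] * e)
  list(consumption = stats::setNames(cons, fixture$foods$id),
       objective = sum((100 * (cons - b) / b)^2),
       lambda = lm2[1], mu = lm2[2])
}

# ---------------------------------------------------------------------------
# Monte Carlo input sampling

#' Draw one perturbed copy of the central inputs
#'
#' Sampling distributions: consumption ~ Normal(mean, sd) truncated at 0;
#' blue water footprints ~ Normal(mean, spatial sd) truncated at 0;
#' expenditure shares ~ Normal(share, se) truncated to [0, 1]; log relative
#' risks ~ Normal with SD = (log ci_high - log ci_low) / (2 * 1.96);
#' nutrient composition, GHG factors and price elasticities ~ Uniform within
#' +/- `uniform_halfwidth` of the central value (sign preserved for
#' elasticities; food energy is recomputed from the perturbed macronutrients
#' so Atwater consistency is kept; free sugars are capped at carbohydrate).
#'
#' @param central list with `foods`, `patterns`, `exposure_responses` (as in
#'   [generate_study()]).
#' @param seed integer seed for this draw.
#' @param uniform_halfwidth relative halfwidth of the uniform perturbations
#'   (default 0.10; 0 gives a degenerate copy).
#' @return perturbed copy of `central` (same structure, validated).
#' @export
sample_inputs <- function(central, seed, uniform_halfwidth = 0.10) {
  with_seed(seed, {
    foods <- as.data.frame(central$foods)
    n <- nrow(foods)
    runif_pm <- function(x) {
      if (uniform_halfwidth == 0) x
      else x * stats::runif(length(x), 1 - uniform_halfwidth, 1 + uniform_halfwidth)
    }
    foods$carb_g_per_g <- runif_pm(foods$carb_g_per_g)
    foods$fat_g_per_g <- runif_pm(foods$fat_g_per_g)
    foods$protein_g_per_g <- runif_pm(foods$protein_g_per_g)
    # Keep the physical bound carb + fat + protein <= 1 g per g after the
    # independent perturbations (binding only for near-pure foods like oils).
    macro_sum <- foods$carb_g_per_g + foods$fat_g_per_g + foods$protein_g_per_g
    over <- macro_sum > 1
    if (any(over)) {
      fac <- 1 / macro_sum[over]
      foods$carb_g_per_g[over] <- foods$carb_g_per_g[over] * fac
      foods$fat_g_per_g[over] <- foods$fat_g_per_g[over] * fac
      foods$protein_g_per_g[over] <- foods$protein_g_per_g[over] * fac
    }
    foods$free_sugar_g_per_g <- pmin(runif_pm(foods$free_sugar_g_per_g),
                                     foods$carb_g_per_g)
    foods$sodium_mg_per_g <- runif_pm(foods$sodium_mg_per_g)
    if (uniform_halfwidth > 0) {
      foods$energy_kcal_per_g <- ATWATER[["carb"]] * foods$carb_g_per_g +
        ATWATER[["fat"]] * foods$fat_g_per_g +
        ATWATER[["protein"]] * foods$protein_g_per_g
    }
    foods$ghg_kgco2e_per_g <- runif_pm(foods$ghg_kgco2e_per_g)
    foods$elasticity <- runif_pm(foods$elasticity)
    foods$bwf_l_per_g <- rnorm_trunc0(n, foods$bwf_l_per_g, foods$bwf_sd_l_per_g)
    share <- stats::rnorm(n, foods$exp_share, foods$exp_share_se)
    foods$exp_share <- pmin(pmax(share, 0), 1)
    foods <- food_table(foods)

    patterns <- lapply(central$patterns, function(p) {
      cm <- rnorm_trunc0(length(p$consumption_mean), p$consumption_mean,
                         p$consumption_sd)
      dietary_pattern(p$name, stats::setNames(cm, names(p$consumption_mean)),
                      p$consumption_sd, p$pop_share)
    })

    ers <- lapply(central$exposure_responses, function(er) {
      sd_log <- (log(er$ci_high) - log(er$ci_low)) / (2 * stats::qnorm(0.975))
      rr <- exp(stats::rnorm(1, log(er$rr_per_unit), sd_log))
      exposure_response(er$exposure, er$outcome, rr,
                        ci_low = min(er$ci_low, rr),
                        ci_high = max(er$ci_high, rr),
                        unit_size = er$unit_size)
    })

    out <- central
    out$foods <- foods
    out$patterns <- patterns
    out$exposure_responses <- ers
    out
  })
}

#' Write a full synthetic study to an output directory
#'
#' Produces foods.csv, patterns.csv, patterns_meta.csv, lifetable.csv and
#' config.yaml (2050 scenario defaults).
#'
#' @param dir output directory (created if needed).
#' @param spec a `synthetic_spec`.
#' @param scenario_obj scenario stored in the config (default the 2050 one).
#' @return invisible character vector of the written file paths.
#' @export
write_synthetic_study <- function(dir, spec = synthetic_spec(),
                                  scenario_obj = default_scenarios()[["2050"]]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(spec)
  paths <- file.path(dir, c("foods.csv", "patterns.csv", "patterns_meta.csv",
                            "lifetable.csv", "config.yaml"))
  write_food_table(study$foods, paths[1])
  write_patterns(study$patterns, paths[2], paths[3])
  write_life_tables(study$life_tables, paths[4])
  write_config(list(scenario = scenario_obj, nutrient_rules = study$rules,
                    exposure_response = study$exposure_responses,
                    lags = study$lags,
                    monte_carlo = list(n_reps = 1000L, n_restarts = 20L,
                                       seed = spec$seed)),
               paths[5])
  invisible(paths)
}
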