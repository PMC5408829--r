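# Domain types, validation and plain-text IO shared by every stage.
#
# The central objects are deliberately light: a food table is a validated
# data.frame (one row per food group, per-gram attributes), a dietary pattern
# is a consumption vector with between-person SDs and a population share, and
# a life table is an age-structured population with all-cause and
# cause-specific hazards for one calendar year.

#' Recognised food-category tags
#' @export
TAG_LEVELS <- c("fruit", "vegetable", "red_meat", "poultry", "dairy",
                "legume", "cereal", "fish", "egg", "oil", "sugar", "other")

#' Mortality outcomes with diet exposure-response evidence
#'
#' Coronary heart disease, stroke, type 2 diabetes, and five cancers.
#' @export
OUTCOMES <- c("CHD", "stroke", "T2D", "cancer_mouth_pharynx_larynx",
              "cancer_oesophagus", "cancer_lung", "cancer_stomach",
              "cancer_colorectum")

#' Dietary exposures entering the health model
#' @export
EXPOSURE_TAGS <- c("red_meat", "fruit", "vegetable")

# Fixed column layout of foods.csv.
FOOD_COLUMNS <- c("id", "name", "energy_kcal_per_g", "carb_g_per_g",
                  "fat_g_per_g", "protein_g_per_g", "free_sugar_g_per_g",
                  "sodium_mg_per_g", "bwf_l_per_g", "bwf_sd_l_per_g",
                  "ghg_kgco2e_per_g", "exp_share", "exp_share_se",
                  "elasticity", "tags")

NONNEG_FOOD_FIELDS <- c("energy_kcal_per_g", "carb_g_per_g", "fat_g_per_g",
                        "protein_g_per_g", "free_sugar_g_per_g",
                        "sodium_mg_per_g", "bwf_l_per_g", "bwf_sd_l_per_g",
                        "ghg_kgco2e_per_g")

#' Validate and classify a food-group table
#'
#' A food table holds one row per food group with per-gram nutritional
#' (energy, macronutrients, free sugars, sodium), environmental (blue water
#' footprint mean and spatial SD, greenhouse gas factor) and economic
#' (expenditure share and SE, own-price elasticity) attributes, plus
#' semicolon-separated category tags.
#'
#' @param df data.frame with the columns of `FOOD_COLUMNS`.
#' @return the validated data.frame with class `food_table`.
#' @export
food_table <- function(df) {
  missing_cols <- setdiff(FOOD_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop_validation("food table: missing column(s) %s",
                    paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, FOOD_COLUMNS]
  df$id <- as.character(df$id)
  df$name <- as.character(df$name)
  df$tags <- as.character(df$tags)
  if (anyDuplicated(df$id)) {
    stop_validation("food table: duplicate id '%s'",
                    df$id[duplicated(df$id)][1])
  }
  for (i in seq_len(nrow(df))) {
    for (field in NONNEG_FOOD_FIELDS) {
      v <- df[[field]][i]
      if (!is.finite(v) || v < 0) {
        stop_validation("food table row %d ('%s'): field '%s' must be a non-negative number (got %s)",
                        i, df$id[i], field, format(v))
      }
    }
    if (df$free_sugar_g_per_g[i] > df$carb_g_per_g[i] + 1e-12) {
      stop_validation("food table row %d ('%s'): field 'free_sugar_g_per_g' exceeds 'carb_g_per_g'",
                      i, df$id[i])
    }
    macro_sum <- df$carb_g_per_g[i] + df$fat_g_per_g[i] + df$protein_g_per_g[i]
    if (macro_sum > 1 + 1e-9) {
      stop_validation("food table row %d ('%s'): carbohydrate + fat + protein exceed 1 g per g",
                      i, df$id[i])
    }
    if (!is.finite(df$exp_share[i]) || df$exp_share[i] < 0 || df$exp_share[i] > 1) {
      stop_validation("food table row %d ('%s'): field 'exp_share' must lie in [0,1]",
                      i, df$id[i])
    }
    if (!is.finite(df$exp_share_se[i]) || df$exp_share_se[i] < 0) {
      stop_validation("food table row %d ('%s'): field 'exp_share_se' must be non-negative",
                      i, df$id[i])
    }
    if (!is.finite(df$elasticity[i]) || df$elasticity[i] == 0) {
      stop_validation("food table row %d ('%s'): field 'elasticity' must be non-zero",
                      i, df$id[i])
    }
    tags_i <- food_tags(df$tags[i])
    bad <- setdiff(tags_i, TAG_LEVELS)
    if (length(bad) > 0) {
      stop_validation("food table row %d ('%s'): unknown tag '%s'",
                      i, df$id[i], bad[1])
    }
  }
  class(df) <- c("food_table", "data.frame")
  df
}

# Split a semicolon-separated tag string.
food_tags <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

#' Which foods in a table carry a given tag?
#' @param foods a `food_table`.
#' @param tag one of `TAG_LEVELS`.
#' @return logical vector along the rows of `foods`.
#' @export
has_tag <- function(foods, tag) {
  vapply(foods$tags, function(s) tag %in% food_tags(s), logical(1),
         USE.NAMES = FALSE)
}

#' Construct a dietary pattern
#'
#' A pattern is a subgroup's mean daily consumption (g/day) over the food
#' groups, the between-person SD of consumption, and the fraction of the
#' population following the pattern.
#'
#' @param name pattern label.
#' @param consumption_mean named numeric vector, g/day by food id.
#' @param consumption_sd named numeric vector, g/day, same ids.
#' @param pop_share population share in `[0, 1]`.
#' @return object of class `dietary_pattern`.
#' @export
dietary_pattern <- function(name, consumption_mean, consumption_sd, pop_share) {
  if (is.null(names(consumption_mean)) ||
      !identical(names(consumption_mean), names(consumption_sd))) {
    stop_validation("pattern '%s': consumption_mean and consumption_sd must share food-id names", name)
  }
  if (any(!is.finite(consumption_mean)) || any(consumption_mean < 0)) {
    stop_validation("pattern '%s': negative or non-finite consumption_mean", name)
  }
  if (any(!is.finite(consumption_sd)) || any(consumption_sd < 0)) {
    stop_validation("pattern '%s': negative or non-finite consumption_sd", name)
  }
  if (!is.finite(pop_share) || pop_share < 0 || pop_share > 1) {
    stop_validation("pattern '%s': pop_share must lie in [0,1]", name)
  }
  structure(list(name = as.character(name),
                 consumption_mean = consumption_mean,
                 consumption_sd = consumption_sd,
                 pop_share = as.numeric(pop_share)),
            class = "dietary_pattern")
}

#' Validate a list of patterns against a food table
#'
#' Checks that every pattern covers exactly the food ids of `foods` and that
#' population shares sum to 1 (tolerance 1e-9).
#' @param patterns list of `dietary_pattern`.
#' @param foods a `food_table`.
#' @return the patterns, invisibly reordered to the food-table id order.
#' @export
validate_patterns <- function(patterns, foods) {
  ids <- foods$id
  for (p in patterns) {
    unknown <- setdiff(names(p$consumption_mean), ids)
    if (length(unknown) > 0) {
      stop_validation("pattern '%s': unknown food id '%s'", p$name, unknown[1])
    }
    missing <- setdiff(ids, names(p$consumption_mean))
    if (length(missing) > 0) {
      stop_validation("pattern '%s': missing food id '%s'", p$name, missing[1])
    }
  }
  shares <- vapply(patterns, function(p) p$pop_share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-9) {
    stop_validation("pattern population shares sum to %.10g, not 1", sum(shares))
  }
  lapply(patterns, function(p) {
    p$consumption_mean <- p$consumption_mean[ids]
    p$consumption_sd <- p$consumption_sd[ids]
    p
  })
}

#' Construct a water-reduction scenario
#'
#' @param name scenario label (e.g. "2025", "2050").
#' @param reduction fraction of the per-person blue water footprint to
#'   remove, in `[0, 1)`.
#' @param horizon_years follow-up horizon for the health model (years).
#' @return object of class `scenario`.
#' @export
scenario <- function(name, reduction, horizon_years = 40L) {
  if (!is.finite(reduction) || reduction < 0 || reduction >= 1) {
    stop_validation("scenario '%s': reduction must lie in [0,1)", name)
  }
  horizon_years <- as.integer(horizon_years)
  if (horizon_years < 1L) {
    stop_validation("scenario '%s': horizon_years must be >= 1", name)
  }
  structure(list(name = as.character(name), reduction = as.numeric(reduction),
                 horizon_years = horizon_years),
            class = "scenario")
}

#' The two printed scenarios: 18.0% by 2025 and 30.3% by 2050
#'
#' Per-person blue-water reductions implied by holding national irrigation
#' volume constant while the population grows.
#' @return named list of `scenario` objects.
#' @export
default_scenarios <- function() {
  list(`2025` = scenario("2025", 0.180, 40L),
       `2050` = scenario("2050", 0.303, 40L))
}

#' WHO-style nutrient rule set
#'
#' Defaults follow the WHO population nutrient intake goals: carbohydrate
#' 55--75% of energy, fat 15--30%, protein 10--15%, free sugars below 10% of
#' energy, sodium below 2000 mg/day, and fruits plus vegetables at least
#' 400 g/day.
#'
#' @param carb_energy_bounds,fat_energy_bounds,protein_energy_bounds
#'   length-2 fraction-of-energy intervals.
#' @param free_sugar_energy_max maximum fraction of energy from free sugars.
#' @param sodium_max mg/day.
#' @param fruit_veg_min g/day of fruit plus vegetables.
#' @param energy_tolerance relative tolerance of the fixed-energy equality.
#' @return object of class `nutrient_rules`.
#' @export
nutrient_rules <- function(carb_energy_bounds = c(0.55, 0.75),
                           fat_energy_bounds = c(0.15, 0.30),
                           protein_energy_bounds = c(0.10, 0.15),
                           free_sugar_energy_max = 0.10,
                           sodium_max = 2000,
                           fruit_veg_min = 400,
                           energy_tolerance = 1e-6) {
  for (b in list(carb_energy_bounds, fat_energy_bounds, protein_energy_bounds)) {
    if (length(b) != 2 || any(b < 0) || any(b > 1) || b[1] > b[2]) {
      stop_validation("nutrient rules: energy-fraction bounds must be ordered intervals within [0,1]")
    }
  }
  if (free_sugar_energy_max < 0 || free_sugar_energy_max > 1) {
    stop_validation("nutrient rules: free_sugar_energy_max must lie in [0,1]")
  }
  if (energy_tolerance <= 0) {
    stop_validation("nutrient rules: energy_tolerance must be positive")
  }
  structure(list(carb_energy_bounds = as.numeric(carb_energy_bounds),
                 fat_energy_bounds = as.numeric(fat_energy_bounds),
                 protein_energy_bounds = as.numeric(protein_energy_bounds),
                 free_sugar_energy_max = as.numeric(free_sugar_energy_max),
                 sodium_max = as.numeric(sodium_max),
                 fruit_veg_min = as.numeric(fruit_veg_min),
                 energy_tolerance = as.numeric(energy_tolerance)),
            class = "nutrient_rules")
}

#' Construct a log-linear exposure-response function
#'
#' `rr_per_unit` is the relative risk of `outcome` per `unit_size` g/day
#' change in the tagged exposure; the response is log-linear, so a change of
#' `d` g/day multiplies risk by `rr_per_unit^(d / unit_size)`.
#'
#' @param exposure one of `EXPOSURE_TAGS`.
#' @param outcome one of `OUTCOMES`.
#' @param rr_per_unit relative risk per `unit_size` change.
#' @param ci_low,ci_high 95% CI bounds of `rr_per_unit`.
#' @param unit_size g/day corresponding to `rr_per_unit`.
#' @return object of class `exposure_response`.
#' @export
exposure_response <- function(exposure, outcome, rr_per_unit,
                              ci_low = rr_per_unit, ci_high = rr_per_unit,
                              unit_size = 100) {
  exposure <- match.arg(exposure, EXPOSURE_TAGS)
  outcome <- match.arg(outcome, OUTCOMES)
  if (!is.finite(rr_per_unit) || rr_per_unit <= 0) {
    stop_validation("exposure response %s/%s: rr_per_unit must be positive",
                    exposure, outcome)
  }
  if (unit_size <= 0) {
    stop_validation("exposure response %s/%s: unit_size must be positive",
                    exposure, outcome)
  }
  if (ci_low > rr_per_unit || ci_high < rr_per_unit) {
    stop_validation("exposure response %s/%s: need ci_low <= rr_per_unit <= ci_high",
                    exposure, outcome)
  }
  structure(list(exposure = exposure, outcome = outcome,
                 rr_per_unit = as.numeric(rr_per_unit),
                 ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                 unit_size = as.numeric(unit_size)),
            class = "exposure_response")
}

#' Construct a normal-CDF effect lag curve
#'
#' The fraction of a dietary risk change realised `t` years after adoption is
#' `pnorm((t - mu) / sigma)`; with `normalize_at_zero` the curve is shifted
#' and rescaled so it starts at exactly 0 at `t = 0`.
#'
#' @param mu years to half of the full effect.
#' @param sigma spread in years (> 0).
#' @param normalize_at_zero logical.
#' @return object of class `lag_curve`.
#' @export
lag_curve <- function(mu, sigma, normalize_at_zero = TRUE) {
  if (!is.finite(mu) || mu < 0) stop_validation("lag curve: mu must be >= 0")
  if (!is.finite(sigma) || sigma <= 0) stop_validation("lag curve: sigma must be > 0")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 normalize_at_zero = isTRUE(normalize_at_zero)),
            class = "lag_curve")
}

#' Construct a single-year life table for one calendar year
#'
#' Single-sex (sex-combined) with ages 0--100; age 100 is the open-ended
#' class. Cause-specific hazards must never sum beyond the all-cause hazard.
#'
#' @param year calendar year label.
#' @param ages integer ages (default 0:100).
#' @param population persons alive at each age.
#' @param all_cause_rate deaths per person-year at each age.
#' @param cause_rates matrix (ages x outcomes) of cause-specific rates; may
#'   have zero columns.
#' @return object of class `life_table`.
#' @export
life_table <- function(year, ages = 0:100, population, all_cause_rate,
                       cause_rates = NULL) {
  n <- length(ages)
  if (length(population) != n || length(all_cause_rate) != n) {
    stop_validation("life table %s: population and all_cause_rate must match ages", year)
  }
  if (any(!is.finite(population)) || any(population < 0)) {
    stop_validation("life table %s: population must be non-negative", year)
  }
  if (any(!is.finite(all_cause_rate)) || any(all_cause_rate < 0)) {
    stop_validation("life table %s: all_cause_rate must be non-negative", year)
  }
  if (is.null(cause_rates)) {
    cause_rates <- matrix(0, n, 0)
  }
  cause_rates <- as.matrix(cause_rates)
  if (nrow(cause_rates) != n) {
    stop_validation("life table %s: cause_rates must have one row per age", year)
  }
  if (ncol(cause_rates) > 0) {
    if (any(cause_rates < 0)) {
      stop_validation("life table %s: cause rates must be non-negative", year)
    }
    tot <- rowSums(cause_rates)
    bad <- which(tot > all_cause_rate + 1e-12)
    if (length(bad) > 0) {
      stop_validation("life table %s: cause-specific rates exceed the all-cause rate at age %d",
                      year, ages[bad[1]])
    }
  }
  structure(list(year = as.numeric(year), ages = as.integer(ages),
                 population = as.numeric(population),
                 all_cause_rate = as.numeric(all_cause_rate),
                 cause_rates = cause_rates),
            class = "life_table")
}

# ---------------------------------------------------------------------------
# CSV / YAML readers and writers

#' Read / write a food-group table
#'
#' `foods.csv` has the fixed columns of `FOOD_COLUMNS`; numeric values are
#' written with 17 significant digits so a write/read round-trip is lossless.
#' @param path CSV file path.
#' @return `read_food_table`: a validated `food_table`.
#' @export
read_food_table <- function(path) {
  if (!file.exists(path)) stop_validation("food table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character", name = "character",
                                       tags = "character"))
  food_table(df)
}

#' @rdname read_food_table
#' @param foods a `food_table`.
#' @export
write_food_table <- function(foods, path) {
  write_csv_exact(as.data.frame(foods), path)
  invisible(path)
}

#' Read / write dietary patterns
#'
#' Long format `patterns.csv` (pattern, food_id, mean_g_day, sd_g_day) plus
#' `patterns_meta.csv` (pattern, pop_share).
#' @param path,meta_path CSV file paths.
#' @param foods `food_table` the patterns must reference.
#' @return `read_patterns`: list of validated `dietary_pattern`s.
#' @export
read_patterns <- function(path, meta_path, foods) {
  if (!file.exists(path)) stop_validation("patterns file not found: %s", path)
  if (!file.exists(meta_path)) stop_validation("patterns meta file not found: %s", meta_path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- setdiff(c("pattern", "food_id", "mean_g_day", "sd_g_day"), names(long))
  if (length(need) > 0) {
    stop_validation("patterns file: missing column(s) %s", paste(need, collapse = ", "))
  }
  if (!all(c("pattern", "pop_share") %in% names(meta))) {
    stop_validation("patterns meta file: needs columns pattern, pop_share")
  }
  patterns <- lapply(meta$pattern, function(pn) {
    rows <- long[long$pattern == pn, ]
    if (nrow(rows) == 0) stop_validation("patterns file: no rows for pattern '%s'", pn)
    cm <- stats::setNames(rows$mean_g_day, rows$food_id)
    cs <- stats::setNames(rows$sd_g_day, rows$food_id)
    dietary_pattern(pn, cm, cs, meta$pop_share[meta$pattern == pn])
  })
  validate_patterns(patterns, foods)
}

#' @rdname read_patterns
#' @param patterns list of `dietary_pattern`.
#' @export
write_patterns <- function(patterns, path, meta_path) {
  long <- do.call(rbind, lapply(patterns, function(p) {
    data.frame(pattern = p$name, food_id = names(p$consumption_mean),
               mean_g_day = unname(p$consumption_mean),
               sd_g_day = unname(p$consumption_sd),
               stringsAsFactors = FALSE)
  }))
  meta <- data.frame(pattern = vapply(patterns, `[[`, character(1), "name"),
                     pop_share = vapply(patterns, `[[`, numeric(1), "pop_share"),
                     stringsAsFactors = FALSE)
  write_csv_exact(long, path)
  write_csv_exact(meta, meta_path)
  invisible(path)
}

#' Read / write life tables
#'
#' Long format `lifetable.csv`: year, age, population, all_cause_rate,
#' outcome, cause_rate. Rows with an empty outcome carry the all-cause data
#' only; cause-specific rows repeat population and all-cause values.
#' @param path CSV file path.
#' @return `read_life_tables`: list of `life_table`, one per year.
#' @export
read_life_tables <- function(path) {
  if (!file.exists(path)) stop_validation("life table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("year", "age", "population", "all_cause_rate",
                    "outcome", "cause_rate"), names(df))
  if (length(need) > 0) {
    stop_validation("life table file: missing column(s) %s",
                    paste(need, collapse = ", "))
  }
  df$outcome[is.na(df$outcome)] <- ""
  lapply(sort(unique(df$year)), function(y) {
    d <- df[df$year == y, ]
    base <- d[d$outcome == "", ]
    base <- base[order(base$age), ]
    ages <- base$age
    outs <- setdiff(unique(d$outcome), "")
    cr <- matrix(0, length(ages), length(outs), dimnames = list(NULL, outs))
    for (o in outs) {
      rows <- d[d$outcome == o, ]
      rows <- rows[order(rows$age), ]
      if (!identical(rows$age, ages)) {
        stop_validation("life table year %s: outcome '%s' does not cover every age", y, o)
      }
      cr[, o] <- rows$cause_rate
    }
    life_table(y, ages, base$population, base$all_cause_rate, cr)
  })
}

#' @rdname read_life_tables
#' @param life_tables list of `life_table`.
#' @export
write_life_tables <- function(life_tables, path) {
  rows <- do.call(rbind, lapply(life_tables, function(lt) {
    base <- data.frame(year = lt$year, age = lt$ages,
                       population = lt$population,
                       all_cause_rate = lt$all_cause_rate,
                       outcome = "", cause_rate = 0,
                       stringsAsFactors = FALSE)
    if (ncol(lt$cause_rates) == 0) return(base)
    causes <- do.call(rbind, lapply(colnames(lt$cause_rates), function(o) {
      data.frame(year = lt$year, age = lt$ages, population = lt$population,
                 all_cause_rate = lt$all_cause_rate, outcome = o,
                 cause_rate = lt$cause_rates[, o], stringsAsFactors = FALSE)
    }))
    rbind(base, causes)
  }))
  write_csv_exact(rows, path)
  invisible(path)
}

#' Read / write the analysis configuration
#'
#' YAML with top-level keys `scenario`, `nutrient_rules`,
#' `exposure_response`, `lags`, and `monte_carlo`. A missing key raises a
#' validation error naming it.
#' @param path YAML file path.
#' @return `read_config`: list with elements `scenario` (a [scenario()]),
#'   `nutrient_rules`, `exposure_response` (list of [exposure_response()]),
#'   `lags` (named list of [lag_curve()]) and `monte_carlo` (list with
#'   n_reps, n_restarts, seed).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  for (key in c("scenario", "nutrient_rules", "exposure_response", "lags",
                "monte_carlo")) {
    if (is.null(raw[[key]])) stop_validation("config: missing key '%s'", key)
  }
  for (key in c("name", "reduction", "horizon_years")) {
    if (is.null(raw$scenario[[key]])) {
      stop_validation("config: missing key 'scenario.%s'", key)
    }
  }
  sc <- scenario(raw$scenario$name, raw$scenario$reduction,
                 raw$scenario$horizon_years)
  nr <- do.call(nutrient_rules, lapply(raw$nutrient_rules, unlist))
  ers <- lapply(raw$exposure_response, function(e) {
    exposure_response(e$exposure, e$outcome, e$rr_per_unit,
                      ci_low = e$ci_low %||% e$rr_per_unit,
                      ci_high = e$ci_high %||% e$rr_per_unit,
                      unit_size = e$unit_size %||% 100)
  })
  lags <- lapply(raw$lags, function(l) {
    lag_curve(l$mu, l$sigma, l$normalize_at_zero %||% TRUE)
  })
  mc <- raw$monte_carlo
  for (key in c("n_reps", "n_restarts", "seed")) {
    if (is.null(mc[[key]])) stop_validation("config: missing key 'monte_carlo.%s'", key)
  }
  list(scenario = sc, nutrient_rules = nr, exposure_response = ers,
       lags = lags,
       monte_carlo = list(n_reps = as.integer(mc$n_reps),
                          n_restarts = as.integer(mc$n_restarts),
                          seed = as.integer(mc$seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config a configuration list shaped like the return of `read_config`.
#' @export
write_config <- function(config, path) {
  raw <- list(
    scenario = unclass(config$scenario),
    nutrient_rules = unclass(config$nutrient_rules),
    exposure_response = lapply(config$exposure_response, unclass),
    lags = lapply(config$lags, unclass),
    monte_carlo = config$monte_carlo
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.dietary_pattern <- function(x, ...) {
  cat(sprintf("<dietary_pattern> %s: %d food groups, pop share %.3f, total %.0f g/day\n",
              x$name, length(x$consumption_mean), x$pop_share,
              sum(x$consumption_mean)))
  invisible(x)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> year %g: ages %d-%d, population %.0f, %d cause-specific outcomes\n",
              x$year, min(x$ages), max(x$ages), sum(x$population),
              ncol(x$cause_rates)))
  invisible(x)
}
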