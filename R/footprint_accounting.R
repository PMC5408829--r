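# Linear accounting of diet-level blue water, GHG and nutrient totals.

# Atwater energy factors, kcal per g.
ATWATER <- c(carb = 4, fat = 9, protein = 4, free_sugar = 4)

#' Compute diet-level metrics for a consumption vector
#'
#' All metrics are linear weighted sums over food groups: blue water (L/day),
#' greenhouse gases (kgCO2e/day), energy (kcal/day), sodium (mg/day), fruit
#' plus vegetable mass (g/day), and fractions of total energy from
#' carbohydrate, fat, protein and free sugars using Atwater factors 4/9/4
#' kcal per g (4 for free sugars, counted as a subset of carbohydrate).
#'
#' @param consumption non-negative g/day vector, named by food id or aligned
#'   with the rows of `foods`.
#' @param foods a `food_table`.
#' @return object of class `diet_metrics`: list with elements `bwf`, `ghg`,
#'   `energy`, `carb_energy_frac`, `fat_energy_frac`, `protein_energy_frac`,
#'   `free_sugar_energy_frac`, `sodium`, `fruit_veg`.
#' @export
compute_metrics <- function(consumption, foods) {
  if (length(consumption) != nrow(foods)) {
    stop_validation("compute_metrics: consumption has %d entries for %d food groups",
                    length(consumption), nrow(foods))
  }
  if (!is.null(names(consumption))) {
    if (!setequal(names(consumption), foods$id)) {
      stop_validation("compute_metrics: consumption names do not match food ids")
    }
    consumption <- consumption[foods$id]
  }
  if (any(consumption < 0)) {
    stop_validation("compute_metrics: negative consumption")
  }
  energy <- sum(consumption * foods$energy_kcal_per_g)
  carb_e <- ATWATER[["carb"]] * sum(consumption * foods$carb_g_per_g)
  fat_e <- ATWATER[["fat"]] * sum(consumption * foods$fat_g_per_g)
  protein_e <- ATWATER[["protein"]] * sum(consumption * foods$protein_g_per_g)
  fs_e <- ATWATER[["free_sugar"]] * sum(consumption * foods$free_sugar_g_per_g)
  fv <- has_tag(foods, "fruit") | has_tag(foods, "vegetable")
  structure(list(
    bwf = sum(consumption * foods$bwf_l_per_g),
    ghg = sum(consumption * foods$ghg_kgco2e_per_g),
    energy = energy,
    carb_energy_frac = if (energy > 0) carb_e / energy else 0,
    fat_energy_frac = if (energy > 0) fat_e / energy else 0,
    protein_energy_frac = if (energy > 0) protein_e / energy else 0,
    free_sugar_energy_frac = if (energy > 0) fs_e / energy else 0,
    sodium = sum(consumption * foods$sodium_mg_per_g),
    fruit_veg = sum(consumption[fv])
  ), class = "diet_metrics")
}

#' Percentage change of a metric
#'
#' @param baseline positive baseline value.
#' @param new new value.
#' @return `100 * (new - baseline) / baseline`.
#' @export
percent_change <- function(baseline, new) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop_validation("percent_change: baseline must be positive")
  }
  100 * (new - baseline) / baseline
}

#' Per-pattern table of energy, blue water and GHG
#'
#' @param patterns list of `dietary_pattern`.
#' @param foods a `food_table`.
#' @return data.frame with columns pattern, pop_share, energy_kcal_day,
#'   bwf_l_day, ghg_kgco2e_day.
#' @export
metrics_table <- function(patterns, foods) {
  do.call(rbind, lapply(patterns, function(p) {
    m <- compute_metrics(p$consumption_mean, foods)
    data.frame(pattern = p$name, pop_share = p$pop_share,
               energy_kcal_day = m$energy, bwf_l_day = m$bwf,
               ghg_kgco2e_day = m$ghg, stringsAsFactors = FALSE)
  }))
}

#' @export
print.diet_metrics <- function(x, ...) {
  cat(sprintf(paste0("<diet_metrics> energy %.0f kcal/day, blue water %.1f L/day, ",
                     "GHG %.2f kgCO2e/day\n  energy fractions: carb %.1f%%, fat %.1f%%, ",
                     "protein %.1f%%, free sugars %.1f%%\n  sodium %.0f mg/day, ",
                     "fruit+veg %.0f g/day\n"),
              x$energy, x$bwf, x$ghg, 100 * x$carb_energy_frac,
              100 * x$fat_energy_frac, 100 * x$protein_energy_frac,
              100 * x$free_sugar_energy_frac, x$sodium, x$fruit_veg))
  invisible(x)
}
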