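# Shared fixtures, built in code and cached per test run.

.study_cache <- new.env(parent = emptyenv())

# Default synthetic study (36 foods, 5 patterns, seed 1), generated once.
test_study <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(synthetic_spec(seed = seed))
  }
  .study_cache[[key]]
}

# A small hand-built food table whose attributes are easy to reason about.
toy_foods <- function() {
  food_table(data.frame(
    id = c("grain", "greens", "ghee"),
    name = c("grain", "greens", "ghee"),
    energy_kcal_per_g = c(3.5, 0.4, 9.0),
    carb_g_per_g = c(0.75, 0.06, 0),
    fat_g_per_g = c(0.02, 0.005, 1.0),
    protein_g_per_g = c(0.10, 0.02, 0),
    free_sugar_g_per_g = c(0, 0, 0),
    sodium_mg_per_g = c(0.05, 0.3, 0),
    bwf_l_per_g = c(1.0, 0.05, 0.8),
    bwf_sd_l_per_g = c(0.2, 0.01, 0.16),
    ghg_kgco2e_per_g = c(0.002, 0.0005, 0.003),
    exp_share = c(0.4, 0.2, 0.1),
    exp_share_se = c(0.04, 0.02, 0.01),
    elasticity = c(-0.4, -0.8, -1.2),
    tags = c("cereal", "vegetable", "oil"),
    stringsAsFactors = FALSE))
}

# Four-food table plus a baseline diet that satisfies the default WHO rules
# (verified by evaluate_constraints in the tests that rely on it).
feasible_toy <- function() {
  foods <- food_table(data.frame(
    id = c("grain", "dal", "greens", "ghee"),
    name = c("grain", "dal", "greens", "ghee"),
    energy_kcal_per_g = c(3.5, 3.51, 0.4, 9.0),
    carb_g_per_g = c(0.75, 0.57, 0.06, 0),
    fat_g_per_g = c(0.02, 0.03, 0.005, 1.0),
    protein_g_per_g = c(0.10, 0.24, 0.02, 0),
    free_sugar_g_per_g = c(0, 0, 0, 0),
    sodium_mg_per_g = c(0.05, 0.1, 0.3, 0),
    bwf_l_per_g = c(1.0, 1.2, 0.05, 0.8),
    bwf_sd_l_per_g = c(0.2, 0.24, 0.01, 0.16),
    ghg_kgco2e_per_g = c(0.002, 0.001, 0.0005, 0.003),
    exp_share = c(0.35, 0.15, 0.2, 0.1),
    exp_share_se = c(0.03, 0.02, 0.02, 0.01),
    elasticity = c(-0.4, -0.6, -0.8, -1.2),
    tags = c("cereal", "legume", "vegetable", "oil"),
    stringsAsFactors = FALSE))
  baseline <- stats::setNames(c(420, 120, 450, 55), foods$id)
  pattern <- dietary_pattern("toy", baseline, 0.25 * baseline, 1)
  list(foods = foods, pattern = pattern, baseline = baseline)
}

# Degenerate-variance copy of a study: every sampling distribution collapses
# to its central value.
zero_variance_study <- function(study) {
  foods <- as.data.frame(study$foods)
  foods$bwf_sd_l_per_g <- 0
  foods$exp_share_se <- 0
  study$foods <- food_table(foods)
  study$patterns <- lapply(study$patterns, function(p) {
    p$consumption_sd[] <- 0
    p
  })
  study$exposure_responses <- lapply(study$exposure_responses, function(er) {
    exposure_response(er$exposure, er$outcome, er$rr_per_unit,
                      ci_low = er$rr_per_unit, ci_high = er$rr_per_unit,
                      unit_size = er$unit_size)
  })
  study
}
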