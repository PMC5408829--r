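# End-to-end orchestration: synthetic inputs (or user files) -> optimisation
# -> footprint accounting -> health impact -> Monte Carlo, with CSV outputs,
# summary figures and a run manifest.

#' Run the full analysis pipeline
#'
#' Stages: generate (or load) the study inputs; optimise every pattern for
#' the scenario; write the per-pattern metrics table, optimised diets and
#' constraint report; run the health-impact model; run the Monte Carlo
#' analysis; and write a key-changes summary table (per-pattern
#' fruit/vegetable/red-meat/poultry g/day changes with intervals, blue-water
#' and GHG percentage changes), box-plot figures of per-outcome life-years,
#' and a JSON run manifest.
#'
#' @param outdir output directory (created if needed).
#' @param config a config list as from [read_config()], a path to a YAML
#'   config, or NULL for defaults (2050 scenario).
#' @param seed master seed for every stage.
#' @param input_dir optional directory with foods.csv, patterns.csv,
#'   patterns_meta.csv and lifetable.csv; when NULL, synthetic inputs are
#'   generated from `spec` and written into `outdir/inputs`.
#' @param spec `synthetic_spec` used when generating inputs.
#' @param n_reps,n_restarts override the Monte Carlo settings of the config.
#' @return invisible run-manifest list (config hash, seed, version,
#'   timestamps, per-stage output files).
#' @export
run_pipeline <- function(outdir, config = NULL, seed = 1L, input_dir = NULL,
                         spec = NULL, n_reps = NULL, n_restarts = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  if (is.null(spec)) spec <- synthetic_spec(seed = seed)

  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- read_config(config)
  }
  if (is.null(config)) {
    config <- list(scenario = default_scenarios()[["2050"]],
                   nutrient_rules = nutrient_rules(),
                   exposure_response = default_exposure_responses(),
                   lags = default_lag_curves(),
                   monte_carlo = list(n_reps = 1000L, n_restarts = 20L,
                                      seed = seed))
  }
  n_reps <- as.integer(n_reps %||% config$monte_carlo$n_reps)
  n_restarts <- as.integer(n_restarts %||% config$monte_carlo$n_restarts)

  # Stage: inputs
  if (is.null(input_dir)) {
    input_dir <- file.path(outdir, "inputs")
    write_synthetic_study(input_dir, spec, config$scenario)
  }
  foods <- read_food_table(file.path(input_dir, "foods.csv"))
  patterns <- read_patterns(file.path(input_dir, "patterns.csv"),
                            file.path(input_dir, "patterns_meta.csv"), foods)
  life_tables <- read_life_tables(file.path(input_dir, "lifetable.csv"))
  study <- list(foods = foods, patterns = patterns, life_tables = life_tables,
                exposure_responses = config$exposure_response,
                lags = config$lags, rules = config$nutrient_rules)
  files <- character(0)

  # Stage: baseline metrics
  mt <- metrics_table(patterns, foods)
  f <- file.path(outdir, "metrics.csv")
  write_csv_exact(mt, f)
  files <- c(files, f)

  # Stage: optimisation
  results <- optimise_all(patterns, foods, config$scenario,
                          config$nutrient_rules, n_restarts = n_restarts,
                          seed = seed)
  diets <- do.call(rbind, lapply(seq_along(results), function(i) {
    base <- patterns[[i]]$consumption_mean
    opt <- results[[i]]$consumption_opt
    data.frame(pattern = patterns[[i]]$name, food_id = foods$id,
               baseline_g_day = unname(base), optimised_g_day = unname(opt),
               pct_change = ifelse(base > 0, 100 * (opt - base) / base, 0),
               stringsAsFactors = FALSE)
  }))
  f <- file.path(outdir, "optimised_diets.csv")
  write_csv_exact(diets, f)
  files <- c(files, f)
  creport <- do.call(rbind, lapply(results, function(r) {
    cbind(pattern = r$pattern_name, feasible = r$feasible, r$constraint_report)
  }))
  f <- file.path(outdir, "constraint_report.csv")
  write_csv_exact(creport, f)
  files <- c(files, f)

  # Stage: health impact (central run)
  surfaces <- project_mortality(life_tables, config$scenario$horizon_years)
  health <- do.call(rbind, lapply(seq_along(results), function(i) {
    hi <- life_years_difference(
      surfaces,
      delta_exposures(patterns[[i]]$consumption_mean,
                      results[[i]]$consumption_opt, foods),
      config$exposure_response, lags = config$lags,
      horizon = config$scenario$horizon_years,
      pattern_name = patterns[[i]]$name,
      scenario_name = config$scenario$name)
    rbind(data.frame(pattern = hi$pattern_name,
                     outcome = names(hi$life_years_by_outcome),
                     life_years_per_100k = unname(hi$life_years_by_outcome),
                     stringsAsFactors = FALSE),
          data.frame(pattern = hi$pattern_name, outcome = "all (joint)",
                     life_years_per_100k = hi$life_years_joint,
                     stringsAsFactors = FALSE))
  }))
  f <- file.path(outdir, "health_impact.csv")
  write_csv_exact(health, f)
  files <- c(files, f)

  # Stage: Monte Carlo
  mc <- run_mc(study, config$scenario, n_reps = n_reps,
               n_restarts = n_restarts, seed = seed, keep_draws = TRUE)
  f <- file.path(outdir, "mc_summary.csv")
  write_csv_exact(cbind(mc$summary, n_failed = mc$n_failed), f)
  files <- c(files, f)

  # Stage: key-changes summary (fruit / vegetable / red meat / poultry g/day
  # changes in the central run, with MC intervals for the footprint changes)
  key <- do.call(rbind, lapply(seq_along(results), function(i) {
    d <- function(tag) {
      sel <- has_tag(foods, tag)
      sum(results[[i]]$consumption_opt[sel]) -
        sum(patterns[[i]]$consumption_mean[sel])
    }
    m <- mc$summary
    pick <- function(metric) m[m$metric == metric, c("mean", "p2_5", "p97_5")]
    bwf <- pick(paste0("bwf_pct_change.", patterns[[i]]$name))
    ghg <- pick(paste0("ghg_pct_change.", patterns[[i]]$name))
    data.frame(pattern = patterns[[i]]$name,
               fruit_g_day = d("fruit"), vegetable_g_day = d("vegetable"),
               red_meat_g_day = d("red_meat"), poultry_g_day = d("poultry"),
               bwf_pct_mean = bwf$mean, bwf_pct_lo = bwf$p2_5,
               bwf_pct_hi = bwf$p97_5,
               ghg_pct_mean = ghg$mean, ghg_pct_lo = ghg$p2_5,
               ghg_pct_hi = ghg$p97_5, stringsAsFactors = FALSE)
  }))
  f <- file.path(outdir, "key_changes.csv")
  write_csv_exact(key, f)
  files <- c(files, f)

  # Stage: figures (per-outcome life-year distributions; deviation curve)
  fig <- file.path(outdir, "life_years_boxplot.pdf")
  grDevices::pdf(fig, width = 8, height = 5)
  ly_cols <- grep("^life_years_per_100k\\.", colnames(mc$draws), value = TRUE)
  graphics::boxplot(as.data.frame(mc$draws[, ly_cols, drop = FALSE]),
                    las = 2, cex.axis = 0.6,
                    ylab = "life-years per 100 000",
                    main = sprintf("Scenario %s: life-years over %d years",
                                   config$scenario$name,
                                   config$scenario$horizon_years))
  graphics::abline(h = 0, lty = 2)
  grDevices::dev.off()
  files <- c(files, fig)

  manifest <- list(
    package_version = as.character(utils::packageVersion("waterdiet")),
    seed = seed,
    config_hash = if (!is.null(config_path)) unname(tools::md5sum(config_path))
                  else NA_character_,
    scenario = config$scenario$name,
    n_reps = n_reps, n_restarts = n_restarts,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files)
  stopifnot(all(file.exists(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
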