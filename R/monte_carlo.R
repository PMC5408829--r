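# Monte Carlo propagation of input uncertainty through the full chain:
# sampling -> common-level optimisation with restarts -> footprint
# accounting -> life-table health impact.

#' Summarise per-repetition draws of one metric
#'
#' @param draws numeric vector of successful-repetition values (>= 1).
#' @return named list: mean, median, p2_5, p97_5 (empirical percentiles with
#'   linear interpolation between order statistics) and n.
#' @export
summarize_draws <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop_validation("summarize_draws: no successful draws")
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  list(mean = mean(draws), median = qs[2], p2_5 = qs[1], p97_5 = qs[3],
       n = length(draws))
}

#' Run the Monte Carlo uncertainty analysis
#'
#' For each repetition (child seed derived deterministically from `seed`):
#' draw a perturbed copy of the inputs with [sample_inputs()]; recompute the
#' baseline footprints and the common level L on the sampled inputs;
#' optimise every pattern best-of-`n_restarts`; and record per-pattern and
#' population-weighted blue-water and GHG percentage changes plus
#' life-years per 100 000 (joint-run estimate). Repetitions in which any
#' pattern is infeasible are counted in `n_failed` and excluded from the
#' summaries. Reductions are computed against each repetition's own sampled
#' baseline, keeping every repetition internally consistent.
#'
#' @param study list with `foods`, `patterns`, `life_tables`,
#'   `exposure_responses`, `lags`, `rules` (see [generate_study()]).
#' @param scenario a [scenario()].
#' @param n_reps repetitions (default 1000).
#' @param n_restarts optimiser starts per pattern per repetition (default 20).
#' @param seed master seed.
#' @param uniform_halfwidth passed to [sample_inputs()].
#' @param keep_draws keep the per-repetition draw matrix in the result.
#' @return object of class `mc_summary`: data.frame `summary` (metric, mean,
#'   median, p2_5, p97_5), plus `n_reps`, `n_failed`, and optionally `draws`.
#' @export
run_mc <- function(study, scenario, n_reps = 1000L, n_restarts = 20L,
                   seed = 1L, uniform_halfwidth = 0.10, keep_draws = FALSE) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop_validation("run_mc: n_reps must be >= 1")
  patterns <- validate_patterns(study$patterns, study$foods)
  pnames <- vapply(patterns, `[[`, character(1), "name")
  shares <- vapply(patterns, `[[`, numeric(1), "pop_share")
  surfaces <- project_mortality(study$life_tables, scenario$horizon_years)

  metric_names <- c(paste0("bwf_pct_change.", pnames),
                    paste0("ghg_pct_change.", pnames),
                    paste0("life_years_per_100k.", pnames),
                    "bwf_pct_change.weighted", "ghg_pct_change.weighted",
                    "life_years_per_100k.weighted")
  seeds <- with_seed(seed, child_seeds(2L * n_reps))
  draws <- matrix(NA_real_, n_reps, length(metric_names),
                  dimnames = list(NULL, metric_names))
  n_failed <- 0L
  failures <- character(0)

  for (r in seq_len(n_reps)) {
    rep_inputs <- sample_inputs(study, seeds[2L * r - 1L], uniform_halfwidth)
    foods_r <- rep_inputs$foods
    patterns_r <- rep_inputs$patterns
    results <- optimise_all(patterns_r, foods_r, scenario, study$rules,
                            n_restarts = n_restarts, seed = seeds[2L * r])
    if (!all(vapply(results, `[[`, logical(1), "feasible"))) {
      n_failed <- n_failed + 1L
      bad <- pnames[!vapply(results, `[[`, logical(1), "feasible")]
      failures <- c(failures, sprintf("rep %d: infeasible pattern(s) %s",
                                      r, paste(bad, collapse = ", ")))
      next
    }
    row <- numeric(0)
    bwf_b <- bwf_o <- ghg_b <- ghg_o <- ly <- numeric(length(patterns_r))
    for (i in seq_along(patterns_r)) {
      base <- patterns_r[[i]]$consumption_mean
      opt <- results[[i]]$consumption_opt
      bwf_b[i] <- sum(base * foods_r$bwf_l_per_g)
      bwf_o[i] <- sum(opt * foods_r$bwf_l_per_g)
      ghg_b[i] <- sum(base * foods_r$ghg_kgco2e_per_g)
      ghg_o[i] <- sum(opt * foods_r$ghg_kgco2e_per_g)
      hi <- life_years_difference(surfaces,
                                  delta_exposures(base, opt, foods_r),
                                  rep_inputs$exposure_responses,
                                  lags = study$lags,
                                  horizon = scenario$horizon_years,
                                  pattern_name = pnames[i],
                                  scenario_name = scenario$name)
      ly[i] <- hi$life_years_joint
    }
    draws[r, ] <- c(percent_change(bwf_b, bwf_o), percent_change(ghg_b, ghg_o),
                    ly,
                    percent_change(sum(shares * bwf_b), sum(shares * bwf_o)),
                    percent_change(sum(shares * ghg_b), sum(shares * ghg_o)),
                    sum(shares * ly))
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) {
    stop_validation("run_mc: all %d repetitions failed:\n%s", n_reps,
                    paste(utils::head(failures, 5), collapse = "\n"))
  }
  summ <- do.call(rbind, lapply(metric_names, function(m) {
    s <- summarize_draws(draws[ok, m])
    data.frame(metric = m, mean = s$mean, median = s$median,
               p2_5 = s$p2_5, p97_5 = s$p97_5, stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, n_reps = n_reps, n_failed = n_failed,
                 failures = failures,
                 draws = if (keep_draws) draws[ok, , drop = FALSE] else NULL,
                 scenario = scenario$name),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> scenario %s: %d repetitions, %d failed\n",
              x$scenario, x$n_reps, x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
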