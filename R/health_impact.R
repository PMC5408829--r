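# IOMLIFET-style life-table estimation of life-years gained or lost from
# diet-driven relative-risk changes. Cohorts advance annually under
# hazard-derived survival probabilities; mortality rates are projected
# forward with second-order polynomials fitted to historical years; risk
# changes phase in along normal-CDF lag curves.

#' Project a historical series with a second-order polynomial
#'
#' Least-squares degree-2 fit in calendar time (exact through three points),
#' evaluated annually from the first historical year to `to_year`, floored
#' at 0.
#'
#' @param years >= 3 historical time points.
#' @param values non-negative rates or counts at those points.
#' @param to_year last year to evaluate.
#' @return named numeric vector over `min(years):to_year`.
#' @export
project_series <- function(years, values, to_year) {
  if (length(years) < 3) {
    stop_validation("project_series: need at least 3 historical points")
  }
  if (length(values) != length(years)) {
    stop_validation("project_series: years and values must have equal length")
  }
  if (any(values < 0)) stop_validation("project_series: negative values")
  x <- years - years[1]
  co <- stats::lm.fit(cbind(1, x, x^2), values)$coefficients
  co[is.na(co)] <- 0
  out_years <- seq(min(years), to_year)
  xx <- out_years - years[1]
  stats::setNames(pmax(co[1] + co[2] * xx + co[3] * xx^2, 0),
                  as.character(out_years))
}

# Vectorised polynomial projection of an (ages x years) rate matrix to the
# target years. Returns ages x length(target_years).
project_rate_matrix <- function(years, rate_matrix, target_years) {
  x <- years - years[1]
  X <- cbind(1, x, x^2)
  co <- stats::lm.fit(X, t(rate_matrix))$coefficients  # 3 x ages
  co[is.na(co)] <- 0
  xx <- target_years - years[1]
  out <- t(cbind(1, xx, xx^2) %*% co)                  # ages x years
  pmax(out, 0)
}

#' Annual survival probability from a mortality hazard
#'
#' The IOMLIFET mid-interval actuarial transform `s = (2 - M) / (2 + M)`,
#' floored at 0.
#'
#' @param M deaths per person-year (>= 0); vectorised.
#' @return survival probability in `[0, 1]`.
#' @export
survival_probability <- function(M) {
  if (any(M < 0)) stop_validation("survival_probability: negative rate")
  pmax((2 - M) / (2 + M), 0)
}

#' Combined relative risk of an outcome from dietary exposure changes
#'
#' Log-linear responses multiplied across exposures:
#' `RR = prod(rr_per_unit ^ (delta / unit_size))` over the responses that
#' affect `outcome`.
#'
#' @param delta_exposure named g/day changes by exposure tag.
#' @param exposure_responses list of `exposure_response`.
#' @param outcome one of `OUTCOMES`.
#' @return relative risk (> 0); 1 when nothing affects the outcome.
#' @export
rr_total <- function(delta_exposure, exposure_responses, outcome) {
  rr <- 1
  for (er in exposure_responses) {
    if (er$outcome != outcome) next
    d <- delta_exposure[[er$exposure]]
    if (is.null(d) || is.na(d)) d <- 0
    rr <- rr * er$rr_per_unit^(d / er$unit_size)
  }
  rr
}

#' Fraction of the full risk change realised t years after adoption
#'
#' `pnorm((t - mu) / sigma)`; with `normalize_at_zero` the curve is anchored
#' to 0 at `t = 0` and rescaled to still reach 1.
#'
#' @param t years since dietary change (>= 0); vectorised.
#' @param curve a `lag_curve`.
#' @return fraction in `[0, 1]`, non-decreasing in `t`.
#' @export
lag_factor <- function(t, curve) {
  if (any(t < 0)) stop_validation("lag_factor: t must be >= 0")
  f <- stats::pnorm((t - curve$mu) / curve$sigma)
  if (curve$normalize_at_zero) {
    f0 <- stats::pnorm(-curve$mu / curve$sigma)
    f <- (f - f0) / (1 - f0)
  }
  pmin(pmax(f, 0), 1)
}

#' All-cause mortality modified by a lagged relative risk on one cause
#'
#' `M' = all_cause + cause * (RR_t - 1)`, floored at 0.
#'
#' @param all_cause,cause rates with `cause <= all_cause` elementwise.
#' @param rr_t lagged relative risk (> 0).
#' @return modified all-cause rate.
#' @export
impacted_mortality <- function(all_cause, cause, rr_t) {
  if (any(cause > all_cause + 1e-12)) {
    stop_validation("impacted_mortality: cause-specific rate exceeds all-cause rate")
  }
  if (any(rr_t <= 0)) stop_validation("impacted_mortality: rr_t must be positive")
  pmax(all_cause + cause * (rr_t - 1), 0)
}

#' Life-years lived by a closed cohort population under a mortality surface
#'
#' Each age cohort advances annually: survivors at age a+1 next year are
#' survivors at age a this year times `survival_probability(M[a, year])`.
#' The open age class (last row) retains its own hazard and accumulates
#' entrants. No births. Life-years are the sum over years of mid-year
#' population (average of each year's start and end populations).
#'
#' @param population persons per age at baseline.
#' @param M mortality surface, matrix ages x horizon years.
#' @param horizon years to run (default `ncol(M)`).
#' @return total life-years over the horizon.
#' @export
cohort_life_years <- function(population, M, horizon = ncol(M)) {
  M <- as.matrix(M)
  n <- length(population)
  if (nrow(M) != n) stop_validation("cohort_life_years: M must have one row per age")
  if (horizon > ncol(M)) stop_validation("cohort_life_years: horizon exceeds surface")
  start <- as.numeric(population)
  total <- 0
  for (k in seq_len(horizon)) {
    s <- survival_probability(M[, k])
    surv <- start * s
    end <- numeric(n)
    if (n > 1) end[2:n] <- surv[1:(n - 1)]
    end[n] <- end[n] + surv[n]  # open-ended class retains its survivors
    total <- total + (sum(start) + sum(end)) / 2
    start <- end
  }
  total
}

#' Dietary exposure changes between baseline and optimised diets
#'
#' Sums consumption over the foods tagged with each health-relevant exposure
#' (red meat, fruit, vegetable) and differences optimised minus baseline.
#'
#' @param baseline,optimised g/day vectors aligned with `foods`.
#' @param foods a `food_table`.
#' @return named numeric vector over `EXPOSURE_TAGS`, g/day.
#' @export
delta_exposures <- function(baseline, optimised, foods) {
  vapply(EXPOSURE_TAGS, function(tag) {
    sel <- has_tag(foods, tag)
    sum(optimised[sel]) - sum(baseline[sel])
  }, numeric(1))
}

# Build projected all-cause and cause-specific mortality surfaces
# (ages x horizon) from >= 3 historical life tables. After projection,
# cause-specific rates are scaled down proportionally wherever their sum
# would exceed the all-cause rate. Baseline population is taken from the
# most recent year. Exported because the Monte Carlo loop reuses one set of
# surfaces across repetitions.

#' Project mortality surfaces from historical life tables
#'
#' @param life_tables list of `life_table` for >= 3 years (same ages and
#'   outcomes).
#' @param horizon years beyond the most recent table to project.
#' @return list with `population` (baseline, most recent year), `all_cause`
#'   (ages x horizon matrix), `causes` (named list of ages x horizon
#'   matrices) and `base_year`.
#' @export
project_mortality <- function(life_tables, horizon) {
  if (length(life_tables) < 3) {
    stop_validation("project_mortality: need at least 3 historical life tables")
  }
  years <- vapply(life_tables, `[[`, numeric(1), "year")
  o <- order(years)
  life_tables <- life_tables[o]
  years <- years[o]
  latest <- life_tables[[length(life_tables)]]
  target_years <- max(years) + seq_len(horizon)
  all_hist <- do.call(cbind, lapply(life_tables, `[[`, "all_cause_rate"))
  all_proj <- project_rate_matrix(years, all_hist, target_years)
  outs <- colnames(latest$cause_rates)
  causes <- lapply(outs, function(oname) {
    hist_o <- do.call(cbind, lapply(life_tables, function(lt) lt$cause_rates[, oname]))
    project_rate_matrix(years, hist_o, target_years)
  })
  names(causes) <- outs
  if (length(causes) > 0) {
    tot <- Reduce(`+`, causes)
    over <- tot > all_proj & tot > 0
    if (any(over)) {
      fac <- matrix(1, nrow(all_proj), ncol(all_proj))
      fac[over] <- all_proj[over] / tot[over]
      causes <- lapply(causes, function(m) m * fac)
    }
  }
  list(population = latest$population, all_cause = all_proj,
       causes = causes, base_year = max(years))
}

#' Life-years difference from adopting an optimised diet
#'
#' Runs the cohort life table twice -- under the projected baseline
#' mortality surface and under the surface impacted by the lagged relative
#' risks implied by the dietary change -- and scales the difference to a
#' baseline population of `per`. Positive values are life-years gained. The
#' per-outcome decomposition applies one outcome's relative risk at a time;
#' `life_years_total` is their sum, and `life_years_joint` is the joint run
#' with all outcomes applied together (the headline estimate).
#'
#' Risk changes phase in as `RR_t = 1 + (RR - 1) * lag_factor(t)` evaluated
#' at mid-year (`t = k - 0.5` in simulation year `k`); `lags = NULL` applies
#' the full risk immediately.
#'
#' @param surfaces result of [project_mortality()].
#' @param delta_exposure named g/day changes from [delta_exposures()].
#' @param exposure_responses list of `exposure_response`.
#' @param lags named list of `lag_curve` by outcome, or NULL for no lag.
#' @param horizon follow-up years (default 40).
#' @param per reference population (default 100 000).
#' @param pattern_name,scenario_name labels carried into the result.
#' @return object of class `health_impact_result` with
#'   `life_years_by_outcome`, `life_years_total` (sum of single-outcome
#'   runs), `life_years_joint` (all outcomes at once) and `rr_by_outcome`.
#' @export
life_years_difference <- function(surfaces, delta_exposure, exposure_responses,
                                  lags = default_lag_curves(), horizon = 40L,
                                  per = 1e5, pattern_name = "pattern",
                                  scenario_name = "scenario") {
  if (horizon > ncol(surfaces$all_cause)) {
    stop_validation("life_years_difference: horizon exceeds projected surface")
  }
  outs <- names(surfaces$causes)
  rrs <- vapply(outs, function(o) rr_total(delta_exposure, exposure_responses, o),
                numeric(1))
  t_mid <- seq_len(horizon) - 0.5
  lagf <- vapply(outs, function(o) {
    if (is.null(lags) || is.null(lags[[o]])) rep(1, horizon)
    else lag_factor(t_mid, lags[[o]])
  }, numeric(horizon))
  if (horizon == 1L) lagf <- matrix(lagf, nrow = 1, dimnames = list(NULL, outs))

  base_M <- surfaces$all_cause[, seq_len(horizon), drop = FALSE]
  pop <- surfaces$population
  scale <- per / sum(pop)
  ly_base <- cohort_life_years(pop, base_M, horizon)

  surface_with <- function(which_outcomes) {
    M <- base_M
    for (o in which_outcomes) {
      rr_t <- 1 + (rrs[[o]] - 1) * lagf[, o]
      M <- M + surfaces$causes[[o]][, seq_len(horizon), drop = FALSE] *
        matrix(rr_t - 1, nrow(M), horizon, byrow = TRUE)
    }
    pmax(M, 0)
  }

  by_outcome <- vapply(outs, function(o) {
    (cohort_life_years(pop, surface_with(o), horizon) - ly_base) * scale
  }, numeric(1))
  joint <- (cohort_life_years(pop, surface_with(outs), horizon) - ly_base) * scale

  structure(list(pattern_name = pattern_name, scenario_name = scenario_name,
                 life_years_by_outcome = by_outcome,
                 life_years_total = sum(by_outcome),
                 life_years_joint = joint,
                 rr_by_outcome = rrs,
                 horizon_years = as.integer(horizon), per = per),
            class = "health_impact_result")
}

#' Default effect-lag curves by outcome
#'
#' Cardiovascular and metabolic outcomes: half effect at 5 years (sigma
#' 2.5); cancers: half effect at 15 years (sigma 5). Configuration
#' placeholders, anchored at zero effect on adoption.
#' @return named list of `lag_curve` over `OUTCOMES`.
#' @export
default_lag_curves <- function() {
  out <- lapply(OUTCOMES, function(o) {
    if (grepl("^cancer", o)) lag_curve(15, 5) else lag_curve(5, 2.5)
  })
  names(out) <- OUTCOMES
  out
}

#' @export
print.health_impact_result <- function(x, ...) {
  cat(sprintf("<health_impact_result> %s / %s: %+.0f life-years per %s over %d years (joint run)\n",
              x$pattern_name, x$scenario_name, x$life_years_joint,
              format(x$per, big.mark = " ", scientific = FALSE),
              x$horizon_years))
  for (o in names(x$life_years_by_outcome)) {
    cat(sprintf("  %-28s %+10.1f (RR %.4f)\n", o, x$life_years_by_outcome[[o]],
                x$rr_by_outcome[[o]]))
  }
  invisible(x)
}
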