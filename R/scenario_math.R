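# National water-budget arithmetic linking irrigation volumes, population
# growth and per-person reduction targets.

#' Construct a national water budget
#'
#' Defaults are the published Indian figures: 1869 BCM/year available,
#' 1123 BCM/year useable, 557 BCM/year demanded for irrigation, and a 2010
#' population of 1.15 billion.
#'
#' @param total_available BCM/year of available water.
#' @param useable BCM/year considered useable (0 < useable <= total).
#' @param irrigation_demand BCM/year demanded for irrigation.
#' @param population_base persons at the baseline year.
#' @param population_future projected persons at the scenario year.
#' @return object of class `water_budget`.
#' @export
water_budget <- function(total_available = 1869, useable = 1123,
                         irrigation_demand = 557,
                         population_base = 1.15e9,
                         population_future = 1.64e9) {
  if (useable <= 0 || useable > total_available) {
    stop_validation("water budget: need 0 < useable <= total_available")
  }
  if (irrigation_demand < 0) stop_validation("water budget: negative irrigation demand")
  if (population_base <= 0 || population_future <= 0) {
    stop_validation("water budget: populations must be positive")
  }
  structure(list(total_available = total_available, useable = useable,
                 irrigation_demand = irrigation_demand,
                 population_base = population_base,
                 population_future = population_future),
            class = "water_budget")
}

#' Share of useable water demanded by irrigation today
#'
#' @param budget a `water_budget`.
#' @return percent: `100 * irrigation_demand / useable`.
#' @export
demand_share <- function(budget) {
  100 * budget$irrigation_demand / budget$useable
}

#' Projected share of useable water demanded by irrigation
#'
#' Holds per-person irrigation demand constant while the population grows.
#' @param budget a `water_budget`.
#' @return percent.
#' @export
future_demand_share <- function(budget) {
  100 * (budget$irrigation_demand * budget$population_future /
           budget$population_base) / budget$useable
}

#' Per-person water reduction implied by constant total irrigation volume
#'
#' @param budget a `water_budget`.
#' @return fraction: `1 - population_base / population_future`.
#' @export
per_person_reduction <- function(budget) {
  1 - budget$population_base / budget$population_future
}

#' @export
print.water_budget <- function(x, ...) {
  cat(sprintf("<water_budget> useable %.0f BCM/yr, irrigation %.0f BCM/yr (%.1f%% of useable)\n",
              x$useable, x$irrigation_demand, demand_share(x)))
  cat(sprintf("  population %.2fB -> %.2fB: per-person reduction %.1f%%, future share %.1f%%\n",
              x$population_base / 1e9, x$population_future / 1e9,
              100 * per_person_reduction(x), future_demand_share(x)))
  invisible(x)
}
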