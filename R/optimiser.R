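# Constrained optimisation of dietary patterns.
#
# Each pattern is moved as little as possible (weighted sum of squared
# percentage changes in food-group consumption) subject to: a common
# per-person blue-water level L, WHO nutrient guidelines, unchanged total
# dietary energy, and non-negative consumption. With fixed energy every
# constraint is linear in consumption and the objective is a positive
# diagonal quadratic, so the problem is a convex QP. It is solved by an
# augmented Lagrangian (inner L-BFGS-B with analytic gradients) followed by
# an exact KKT polish on the identified active set; a multi-start loop with
# log-normal jitter guards against inner-solver failures and mirrors the
# best-of-n selection used in practice.

#' Consumer-preference weights from expenditure shares and price elasticities
#'
#' Each food group is weighted by the ratio of its share of dietary
#' expenditure to the magnitude of its own-price elasticity, rescaled so the
#' mean weight is 1 (rescaling does not move the argmin).
#'
#' @param foods a `food_table` with non-zero elasticities.
#' @return numeric weight vector named by food id.
#' @export
expenditure_weights <- function(foods) {
  if (any(foods$elasticity == 0)) {
    stop_validation("expenditure_weights: zero elasticity for food '%s'",
                    foods$id[foods$elasticity == 0][1])
  }
  w <- foods$exp_share / abs(foods$elasticity)
  if (mean(w) > 0) w <- w / mean(w)
  stats::setNames(w, foods$id)
}

#' Common per-person blue-water target level
#'
#' The level L that every optimised pattern must not exceed. It is the
#' population-share-weighted mean of the baseline footprints scaled by
#' (1 - r), so that when every pattern lands exactly on L the
#' population-weighted mean reduction is exactly r; patterns with high
#' baselines must cut more, which is the equitable-target rule.
#'
#' @param baseline_bwfs positive L/day per pattern.
#' @param pop_shares population shares summing to 1.
#' @param r reduction fraction in `[0, 1)`.
#' @return L in L/day.
#' @export
common_target_level <- function(baseline_bwfs, pop_shares, r) {
  if (r < 0 || r >= 1) stop_validation("common_target_level: r must lie in [0,1)")
  if (abs(sum(pop_shares) - 1) > 1e-9) {
    stop_validation("common_target_level: pop_shares must sum to 1")
  }
  if (any(baseline_bwfs <= 0)) {
    stop_validation("common_target_level: baseline footprints must be positive")
  }
  (1 - r) * sum(pop_shares * baseline_bwfs)
}

#' Weighted sum of squared percentage changes
#'
#' The deviation objective: `sum_g w_g * (100 * (candidate_g - baseline_g) /
#' baseline_g)^2`. Food groups with zero baseline are excluded (they are
#' frozen at zero by the optimiser, where a percentage change is undefined).
#'
#' @param baseline,candidate g/day vectors of equal length.
#' @param weights per-food weights (default all 1).
#' @return non-negative scalar.
#' @export
deviation_objective <- function(baseline, candidate, weights = rep(1, length(baseline))) {
  if (length(candidate) != length(baseline)) {
    stop_validation("deviation_objective: length mismatch")
  }
  if (any(candidate < 0)) {
    stop_validation("deviation_objective: negative candidate consumption")
  }
  keep <- baseline > 0
  pct <- 100 * (candidate[keep] - baseline[keep]) / baseline[keep]
  sum(weights[keep] * pct^2)
}

#' Build the linear constraint set for one pattern
#'
#' Constraints (all linear in consumption once energy is pinned to the
#' baseline value E0): blue water <= L; energy = E0 (equality, relative
#' tolerance from the rules); carbohydrate/fat/protein energy fractions
#' within bounds; free-sugar energy fraction below its maximum; sodium below
#' its maximum; fruit plus vegetables above the minimum. Fraction bounds are
#' expressed against E0, which the energy equality makes equivalent to
#' bounds against realised energy.
#'
#' @param baseline g/day vector (defines E0).
#' @param foods a `food_table`.
#' @param L blue-water level, L/day.
#' @param rules a `nutrient_rules`.
#' @return object of class `diet_constraints` with equality and inequality
#'   matrices, right-hand sides, names, and per-constraint scales.
#' @export
build_constraints <- function(baseline, foods, L, rules) {
  e_row <- foods$energy_kcal_per_g
  E0 <- sum(baseline * e_row)
  rows <- list(
    bwf = list(a = foods$bwf_l_per_g, b = L),
    carb_lo = list(a = -ATWATER[["carb"]] * foods$carb_g_per_g,
                   b = -rules$carb_energy_bounds[1] * E0),
    carb_hi = list(a = ATWATER[["carb"]] * foods$carb_g_per_g,
                   b = rules$carb_energy_bounds[2] * E0),
    fat_lo = list(a = -ATWATER[["fat"]] * foods$fat_g_per_g,
                  b = -rules$fat_energy_bounds[1] * E0),
    fat_hi = list(a = ATWATER[["fat"]] * foods$fat_g_per_g,
                  b = rules$fat_energy_bounds[2] * E0),
    protein_lo = list(a = -ATWATER[["protein"]] * foods$protein_g_per_g,
                      b = -rules$protein_energy_bounds[1] * E0),
    protein_hi = list(a = ATWATER[["protein"]] * foods$protein_g_per_g,
                      b = rules$protein_energy_bounds[2] * E0),
    free_sugar = list(a = ATWATER[["free_sugar"]] * foods$free_sugar_g_per_g,
                      b = rules$free_sugar_energy_max * E0),
    sodium = list(a = foods$sodium_mg_per_g, b = rules$sodium_max),
    fruit_veg = list(a = -as.numeric(has_tag(foods, "fruit") |
                                       has_tag(foods, "vegetable")),
                     b = -rules$fruit_veg_min)
  )
  A_in <- do.call(rbind, lapply(rows, `[[`, "a"))
  b_in <- vapply(rows, `[[`, numeric(1), "b")
  structure(list(
    A_eq = matrix(e_row, nrow = 1, dimnames = list("energy", NULL)),
    b_eq = E0,
    A_in = A_in, b_in = b_in,
    names_in = names(rows),
    scale_eq = max(1, abs(E0)),
    scale_in = pmax(1, abs(b_in)),
    E0 = E0,
    tol = 1e-6,
    energy_tolerance = rules$energy_tolerance
  ), class = "diet_constraints")
}

#' Evaluate a constraint set at a consumption vector
#'
#' @param constraints a `diet_constraints`.
#' @param consumption g/day vector.
#' @return data.frame with columns name, kind ("equality"/"inequality"),
#'   residual (signed, native units; positive inequality residual =
#'   violation) and satisfied (at the relative tolerances of the set).
#' @export
evaluate_constraints <- function(constraints, consumption) {
  h <- drop(constraints$A_eq %*% consumption) - constraints$b_eq
  g <- drop(constraints$A_in %*% consumption) - constraints$b_in
  data.frame(
    name = c("energy", constraints$names_in),
    kind = c("equality", rep("inequality", length(g))),
    residual = c(h, g),
    satisfied = c(abs(h) / constraints$scale_eq <= constraints$energy_tolerance,
                  g / constraints$scale_in <= constraints$tol),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Smallest blue-water footprint achievable at fixed energy
#'
#' The linear-programming lower bound over non-negative diets constrained
#' only by the energy equality: all energy from the food with the smallest
#' water cost per kcal, so `E0 * min_g(bwf_g / energy_g)`. Any water level
#' below this bound is infeasible for every nutrient rule set.
#'
#' @param foods a `food_table`.
#' @param E0 dietary energy to supply, kcal/day.
#' @return L/day lower bound.
#' @export
min_bwf_at_energy <- function(foods, E0) {
  pos <- foods$energy_kcal_per_g > 0
  if (!any(pos)) stop_validation("min_bwf_at_energy: no energy-supplying foods")
  E0 * min(foods$bwf_l_per_g[pos] / foods$energy_kcal_per_g[pos])
}

# ---------------------------------------------------------------------------
# Augmented Lagrangian solver with KKT polish (internal)

# Minimise sum(q * (x - b)^2) s.t. A_eq x = b_eq, A_in x <= b_in,
# x >= lower. q, b over the free coordinates only. Callers pre-scale the
# problem so q is well conditioned (percentage-change coordinates).
auglag_qp <- function(x0, q, b, cons, lower = 0, max_outer = 40L,
                      warm = NULL) {
  A_eq <- cons$A_eq; b_eq <- cons$b_eq
  A_in <- cons$A_in; b_in <- cons$b_in
  s_eq <- cons$scale_eq; s_in <- cons$scale_in
  lam <- if (is.null(warm)) 0 else warm$lam
  mu <- if (is.null(warm)) rep(0, length(b_in)) else warm$mu
  rho <- 1
  x <- pmax(x0, lower)
  viol <- function(x) {
    h <- drop(A_eq %*% x) - b_eq
    g <- drop(A_in %*% x) - b_in
    max(abs(h) / s_eq, max(g / s_in), 0)
  }
  v_prev <- Inf
  best <- NULL
  stall <- 0L
  for (outer in seq_len(max_outer)) {
    fn <- function(x) {
      h <- drop(A_eq %*% x) - b_eq
      g <- drop(A_in %*% x) - b_in
      t_in <- pmax(0, mu + rho * g)
      sum(q * (x - b)^2) + lam * h + 0.5 * rho * h^2 +
        sum(t_in^2 - mu^2) / (2 * rho)
    }
    gr <- function(x) {
      h <- drop(A_eq %*% x) - b_eq
      g <- drop(A_in %*% x) - b_in
      t_in <- pmax(0, mu + rho * g)
      2 * q * (x - b) + (lam + rho * h) * drop(A_eq) + drop(t_in %*% A_in)
    }
    fit <- stats::optim(x, fn, gr, method = "L-BFGS-B", lower = lower,
                        control = list(maxit = 200L, factr = 1e6))
    x <- fit$par
    h <- drop(A_eq %*% x) - b_eq
    g <- drop(A_in %*% x) - b_in
    v <- viol(x)
    if (is.null(best) || v < best$viol) {
      best <- list(x = x, viol = v, objective = sum(q * (x - b)^2))
    }
    if (v < 1e-2) {
      # Exact solve on the current active-set guess; a dual-feasible result
      # is a KKT point of the convex QP, i.e. the global optimum.
      polished <- kkt_polish(x, q, b, cons, mu, g, lower)
      if (!is.null(polished)) {
        return(list(x = polished$x, viol = viol(polished$x),
                    objective = sum(q * (polished$x - b)^2), polished = TRUE,
                    duals = polished$duals))
      }
    }
    if (v < 1e-9) break
    # Infeasible instances stall at a positive minimal violation; stop once
    # the violation has not improved materially for several rounds.
    stall <- if (v > 0.99 * v_prev && v > 1e-6) stall + 1L else 0L
    if (stall >= 5L) break
    lam <- lam + rho * h
    mu <- pmax(0, mu + rho * g)
    if (v > 0.5 * v_prev) rho <- min(rho * 5, 1e12)
    v_prev <- v
  }
  c(best, list(polished = FALSE))
}

# Exact equality-constrained QP solve on the guessed active set. Returns the
# polished point only if it passes the full KKT test for the convex QP
# (primal feasibility, non-negative inequality multipliers, non-negative
# reduced gradients at pinned lower bounds), in which case it is the global
# optimum; otherwise NULL and the augmented Lagrangian continues.
kkt_polish <- function(x, q, b, cons, mu, g, lower = 0) {
  lower_vec <- rep_len(lower, length(x))
  act <- which(mu > 1e-9 | g / cons$scale_in > -1e-6)
  free <- which(x > lower_vec + 1e-7)
  if (length(free) == 0) return(NULL)
  A_full <- rbind(cons$A_eq, cons$A_in[act, , drop = FALSE])
  pinned <- setdiff(seq_along(x), free)
  rhs <- c(cons$b_eq, cons$b_in[act]) -
    drop(A_full[, pinned, drop = FALSE] %*% lower_vec[pinned])
  A <- A_full[, free, drop = FALSE]
  m <- nrow(A)
  K <- rbind(cbind(diag(2 * q[free], nrow = length(free)), t(A)),
             cbind(A, matrix(0, m, m)))
  sol <- tryCatch(solve(K, c(2 * q[free] * b[free], rhs)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  xf <- sol[seq_along(free)]
  nu <- sol[-seq_along(free)]
  # Dual feasibility: inequality multipliers must be non-negative.
  n_eq <- nrow(cons$A_eq)
  if (m > n_eq && any(nu[-seq_len(n_eq)] < -1e-7)) return(NULL)
  if (any(xf < lower_vec[free] - 1e-9)) return(NULL)
  out <- lower_vec
  out[free] <- pmax(xf, lower_vec[free])
  # Reduced gradient of the Lagrangian at pinned coordinates must push up.
  if (length(pinned) > 0) {
    grad_L <- 2 * q[pinned] * (out[pinned] - b[pinned]) +
      drop(nu %*% A_full[, pinned, drop = FALSE])
    if (any(grad_L < -1e-6)) return(NULL)
  }
  h <- abs(drop(cons$A_eq %*% out) - cons$b_eq) / cons$scale_eq
  gg <- (drop(cons$A_in %*% out) - cons$b_in) / cons$scale_in
  if (h > 1e-9 || max(gg) > 1e-9) return(NULL)
  mu_full <- rep(0, nrow(cons$A_in))
  if (m > n_eq) mu_full[act] <- pmax(nu[-seq_len(n_eq)], 0)
  list(x = out, duals = list(lam = nu[seq_len(n_eq)], mu = mu_full))
}

#' Optimise one dietary pattern against a common blue-water level
#'
#' Multi-start augmented-Lagrangian minimisation of the weighted deviation
#' objective subject to [build_constraints()]. Restart 1 starts at the
#' baseline; restarts 2..n start at the baseline jittered by independent
#' log-normal factors (sd 0.2 on the log scale). The feasible candidate with
#' the smallest objective wins; if no restart is feasible the best attempt is
#' returned with `feasible = FALSE`. Food groups with zero baseline
#' consumption are frozen at zero.
#'
#' @param pattern a `dietary_pattern` (or bare named baseline vector).
#' @param foods a `food_table`.
#' @param L common per-person blue-water level, L/day.
#' @param rules a `nutrient_rules`.
#' @param weights per-food objective weights; default
#'   [expenditure_weights()] of `foods`.
#' @param n_restarts number of starts (>= 1), default 20.
#' @param seed integer seed for the restart jitter.
#' @return object of class `optimisation_result` with fields pattern_name,
#'   consumption_opt, objective, bwf_baseline, bwf_opt, constraint_report,
#'   feasible, n_restarts_used, best_restart_index.
#' @export
optimise_pattern <- function(pattern, foods, L, rules = nutrient_rules(),
                             weights = NULL, n_restarts = 20L, seed = 1L) {
  if (inherits(pattern, "dietary_pattern")) {
    baseline <- pattern$consumption_mean
    pname <- pattern$name
  } else {
    baseline <- pattern
    pname <- "pattern"
  }
  if (!is.null(names(baseline))) baseline <- baseline[foods$id]
  baseline <- unname(baseline)
  if (is.null(weights)) weights <- unname(expenditure_weights(foods))
  weights <- unname(weights)
  n_restarts <- max(1L, as.integer(n_restarts))

  free <- baseline > 0
  cons_full <- build_constraints(baseline, foods, L, rules)
  bf <- baseline[free]
  # Solve in percentage-change coordinates u = 100 (x - b) / b, where the
  # objective is the perfectly conditioned sum(w * u^2) and the constraints
  # stay linear: (A diag(b/100)) u <= rhs - A b. Frozen (zero-baseline)
  # coordinates are dropped before scaling.
  D <- bf / 100
  cons <- cons_full
  A_eq_f <- cons_full$A_eq[, free, drop = FALSE]
  A_in_f <- cons_full$A_in[, free, drop = FALSE]
  cons$A_eq <- sweep(A_eq_f, 2, D, `*`)
  cons$A_in <- sweep(A_in_f, 2, D, `*`)
  cons$b_eq <- cons_full$b_eq - sum(cons_full$A_eq[, free] * bf)
  cons$b_in <- cons_full$b_in - drop(A_in_f %*% bf)
  cons$scale_eq <- cons_full$scale_eq
  cons$scale_in <- cons_full$scale_in
  q <- pmax(weights[free], 1e-12)

  starts <- with_seed(seed, {
    n_jit <- max(n_restarts - 1L, 0L)
    jitter <- matrix(stats::rnorm(n_jit * length(bf), 0, 0.2), nrow = n_jit,
                     ncol = length(bf))
    rbind(rep(0, length(bf)), 100 * (exp(jitter) - 1), deparse.level = 0)
  })

  best <- NULL
  best_idx <- NA_integer_
  warm <- NULL
  for (k in seq_len(n_restarts)) {
    fit <- tryCatch(auglag_qp(starts[k, ], q, rep(0, length(bf)), cons,
                              lower = -100, warm = warm),
                    error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$x))) next  # discarded restart
    if (is.null(warm) && !is.null(fit$duals)) warm <- fit$duals
    full <- numeric(length(baseline))
    full[free] <- pmax(bf * (1 + fit$x / 100), 0)
    rep_k <- evaluate_constraints(cons_full, full)
    feas_k <- all(rep_k$satisfied)
    obj_k <- deviation_objective(baseline, full, weights)
    cand <- list(x = full, objective = obj_k, feasible = feas_k,
                 report = rep_k, viol = fit$viol)
    better <- if (is.null(best)) {
      TRUE
    } else if (feas_k != best$feasible) {
      feas_k
    } else if (feas_k) {
      obj_k < best$objective
    } else {
      fit$viol < best$viol
    }
    if (better) {
      best <- cand
      best_idx <- k
    }
  }
  if (is.null(best)) {
    stop_validation("optimise_pattern('%s'): every restart failed", pname)
  }
  structure(list(
    pattern_name = pname,
    consumption_opt = stats::setNames(best$x, foods$id),
    objective = best$objective,
    bwf_baseline = sum(baseline * foods$bwf_l_per_g),
    bwf_opt = sum(best$x * foods$bwf_l_per_g),
    constraint_report = best$report,
    feasible = best$feasible,
    n_restarts_used = n_restarts,
    best_restart_index = best_idx
  ), class = "optimisation_result")
}

#' Optimise every pattern of a study against one common level
#'
#' Computes the common level L once from all baseline footprints and
#' population shares, then optimises each pattern against that same L.
#' Per-pattern infeasibility is recorded, not raised; the full list is always
#' returned (with the level as attribute `L`).
#'
#' @param patterns list of `dietary_pattern`.
#' @param foods a `food_table`.
#' @param scenario a [scenario()].
#' @param rules a `nutrient_rules`.
#' @param n_restarts starts per pattern (default 20).
#' @param seed master seed; per-pattern seeds are derived deterministically.
#' @return list of `optimisation_result`, attribute `L`.
#' @export
optimise_all <- function(patterns, foods, scenario, rules = nutrient_rules(),
                         n_restarts = 20L, seed = 1L) {
  patterns <- validate_patterns(patterns, foods)
  bwfs <- vapply(patterns, function(p) sum(p$consumption_mean * foods$bwf_l_per_g),
                 numeric(1))
  shares <- vapply(patterns, `[[`, numeric(1), "pop_share")
  L <- common_target_level(bwfs, shares, scenario$reduction)
  seeds <- with_seed(seed, child_seeds(length(patterns)))
  weights <- unname(expenditure_weights(foods))
  out <- lapply(seq_along(patterns), function(i) {
    optimise_pattern(patterns[[i]], foods, L, rules, weights,
                     n_restarts = n_restarts, seed = seeds[i])
  })
  attr(out, "L") <- L
  out
}

#' Population-weighted blue-water reduction achieved by optimised diets
#'
#' Percentage change of the population-mean footprint: `100 * (1 -
#' sum(s_i * bwf_opt_i) / sum(s_i * bwf_baseline_i))`, the quantity the
#' common level L targets.
#'
#' @param results list of `optimisation_result` from [optimise_all()].
#' @param patterns the matching list of `dietary_pattern` (for shares).
#' @return reduction in percent (positive = less water).
#' @export
weighted_bwf_reduction <- function(results, patterns) {
  shares <- vapply(patterns, `[[`, numeric(1), "pop_share")
  base <- vapply(results, `[[`, numeric(1), "bwf_baseline")
  opt <- vapply(results, `[[`, numeric(1), "bwf_opt")
  100 * (1 - sum(shares * opt) / sum(shares * base))
}

#' @export
print.optimisation_result <- function(x, ...) {
  cat(sprintf("<optimisation_result> %s: %s, objective %.4g\n  blue water %.1f -> %.1f L/day (%.1f%% change), best restart %d/%d\n",
              x$pattern_name, if (x$feasible) "feasible" else "INFEASIBLE",
              x$objective, x$bwf_baseline, x$bwf_opt,
              percent_change(x$bwf_baseline, x$bwf_opt),
              x$best_restart_index, x$n_restarts_used))
  bad <- x$constraint_report[!x$constraint_report$satisfied, ]
  if (nrow(bad) > 0) {
    cat("  violated:", paste(bad$name, collapse = ", "), "\n")
  }
  invisible(x)
}
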