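# Constrained diet optimisation: weights, targets, constraints, solver.

test_that("expenditure weights are share over |elasticity|, mean-1 rescaled", {
  foods <- as.data.frame(toy_foods())
  foods$exp_share <- c(0.10, 0.10, 0.10)
  foods$elasticity <- c(-0.5, -0.5, -0.5)
  w <- expenditure_weights(food_table(foods))
  expect_equal(unname(w), c(1, 1, 1))  # equal shares/elasticities -> all 1

  foods$exp_share <- c(0.10, 0.30, 0.10)
  foods$elasticity <- c(-0.5, -1, -2)
  w <- expenditure_weights(food_table(foods))
  raw <- c(0.10 / 0.5, 0.30 / 1, 0.10 / 2)
  expect_equal(unname(w), raw / mean(raw))
  expect_equal(unname(w)[1], 0.2 / mean(raw))  # raw weight 0.20 for 0.10/-0.5

  # scale invariance in the shares
  foods2 <- foods
  foods2$exp_share <- 2 * foods$exp_share * 0.5  # keep within [0,1]
  expect_equal(expenditure_weights(food_table(foods)),
               expenditure_weights(food_table(foods2)))
})

test_that("common target level reproduces the equitable-target arithmetic", {
  # r = 0: the weighted mean itself
  expect_equal(common_target_level(c(600, 800), c(0.5, 0.5), 0), 700)
  # equal shares over the five baseline footprints at the 2050 reduction
  base <- c(566, 640, 836, 883, 677)
  expect_equal(common_target_level(base, rep(0.2, 5), 0.303), 502.12,
               tolerance = 0.01 / 502)
  expect_equal(common_target_level(800, 1, 0.25), 600)
  expect_error(common_target_level(800, 1, 1), "r must lie")
  expect_error(common_target_level(c(600, 800), c(0.5, 0.4), 0.1), "sum to 1")
})

test_that("deviation objective is the weighted squared-percentage sum", {
  b <- c(100, 200, 50)
  expect_equal(deviation_objective(b, b), 0)
  cand <- b; cand[1] <- 110
  expect_equal(deviation_objective(b, cand), 100)  # one group +10%
  cand <- b
  cand[1] <- 110; cand[2] <- 190
  expect_equal(deviation_objective(b, cand, weights = c(2, 1, 1)), 225)
  expect_error(deviation_objective(b, c(-1, 200, 50)), "negative")
  # zero-baseline groups are excluded
  expect_equal(deviation_objective(c(100, 0), c(110, 5)), 100)
})

test_that("constraint sets evaluate correctly at the baseline", {
  toy <- feasible_toy()
  m <- compute_metrics(toy$baseline, toy$foods)
  cons <- build_constraints(unname(toy$baseline), toy$foods, m$bwf,
                            nutrient_rules())
  rep0 <- evaluate_constraints(cons, unname(toy$baseline))
  expect_true(all(rep0$satisfied))  # the toy baseline meets every WHO rule
  expect_true(all(rep0$residual[rep0$kind == "inequality"] <= 1e-9))

  # a raised fruit&veg floor violates exactly that one constraint
  cons2 <- build_constraints(unname(toy$baseline), toy$foods, m$bwf,
                             nutrient_rules(fruit_veg_min = m$fruit_veg + 100))
  rep2 <- evaluate_constraints(cons2, unname(toy$baseline))
  expect_identical(rep2$name[!rep2$satisfied], "fruit_veg")
  expect_equal(rep2$residual[rep2$name == "fruit_veg"], 100)
})

test_that("a nutrient-feasible baseline with r = 0 is its own optimum", {
  toy <- feasible_toy()
  sc0 <- scenario("none", 0)
  res <- optimise_all(list(toy$pattern), toy$foods, sc0, n_restarts = 5,
                      seed = 3)[[1]]
  expect_true(res$feasible)
  expect_equal(res$objective, 0, tolerance = 1e-8)
  expect_equal(unname(res$consumption_opt), unname(toy$baseline),
               tolerance = 1e-6)
})

test_that("the optimiser matches the closed-form optimum of the analytic fixture", {
  fx <- make_analytic_fixture()
  oracle <- analytic_fixture_optimum(fx)
  res <- optimise_pattern(fx$pattern, fx$foods, fx$L, fx$rules,
                          weights = rep(1, 3), n_restarts = 20, seed = 1)
  expect_true(res$feasible)
  expect_lt(abs(res$objective - oracle$objective) / oracle$objective, 1e-4)
  expect_equal(unname(res$consumption_opt), unname(oracle$consumption),
               tolerance = 1e-6)
})

test_that("water levels below the fixed-energy LP bound are declared infeasible", {
  fx <- make_analytic_fixture()
  E0 <- sum(fx$pattern$consumption_mean * fx$foods$energy_kcal_per_g)
  L_impossible <- 0.9 * min_bwf_at_energy(fx$foods, E0)
  res <- optimise_pattern(fx$pattern, fx$foods, L_impossible, fx$rules,
                          weights = rep(1, 3), n_restarts = 5, seed = 2)
  expect_false(res$feasible)
  expect_false(all(res$constraint_report$satisfied))
})

test_that("feasible optima satisfy every constraint on re-evaluation", {
  study <- test_study()
  res <- optimise_all(study$patterns, study$foods,
                      default_scenarios()[["2025"]], study$rules,
                      n_restarts = 5, seed = 4)
  L <- attr(res, "L")
  for (i in seq_along(res)) {
    expect_true(res[[i]]$feasible)
    cons <- build_constraints(unname(study$patterns[[i]]$consumption_mean),
                              study$foods, L, study$rules)
    rep_i <- evaluate_constraints(cons, unname(res[[i]]$consumption_opt))
    expect_true(all(rep_i$satisfied), info = res[[i]]$pattern_name)
  }
  # and the population-weighted reduction meets the scenario target
  expect_gte(weighted_bwf_reduction(res, study$patterns), 18.0 - 1e-6)
})

test_that("no single-food +/-0.1% perturbation of an optimum is feasibly better", {
  study <- test_study()
  res <- optimise_all(study$patterns, study$foods,
                      default_scenarios()[["2050"]], study$rules,
                      n_restarts = 5, seed = 4)
  L <- attr(res, "L")
  weights <- unname(expenditure_weights(study$foods))
  i <- 3  # one representative pattern keeps this quick
  base <- unname(study$patterns[[i]]$consumption_mean)
  opt <- unname(res[[i]]$consumption_opt)
  cons <- build_constraints(base, study$foods, L, study$rules)
  for (j in seq_along(opt)) {
    for (eps in c(-0.001, 0.001)) {
      cand <- opt
      cand[j] <- cand[j] * (1 + eps)
      rep_j <- evaluate_constraints(cons, cand)
      if (all(rep_j$satisfied)) {
        expect_gte(deviation_objective(base, cand, weights),
                   res[[i]]$objective - 1e-7 * res[[i]]$objective)
      }
    }
  }
})

test_that("tightening the water target never lowers the deviation objective", {
  study <- test_study()
  objs <- sapply(c(0, 0.1, 0.2, 0.3), function(r) {
    res <- optimise_all(study$patterns, study$foods, scenario("r", r),
                        study$rules, n_restarts = 3, seed = 11)
    vapply(res, `[[`, numeric(1), "objective")
  })
  for (i in seq_len(nrow(objs))) {
    expect_true(all(diff(objs[i, ]) >= -1e-6 * pmax(objs[i, -4], 1)),
                info = sprintf("pattern %d: %s", i,
                               paste(signif(objs[i, ], 6), collapse = ", ")))
  }
})

test_that("optimisation is deterministic under a fixed seed", {
  study <- test_study()
  r1 <- optimise_all(study$patterns, study$foods,
                     default_scenarios()[["2025"]], study$rules,
                     n_restarts = 4, seed = 21)
  r2 <- optimise_all(study$patterns, study$foods,
                     default_scenarios()[["2025"]], study$rules,
                     n_restarts = 4, seed = 21)
  expect_identical(r1, r2)
})

test_that("a pattern below the common level can gain water to meet nutrition", {
  # The low pattern sits far below L but short of the fruit&veg floor; the
  # only tagged foods carry positive water, so meeting the floor must raise
  # its footprint (a negative signed reduction), while the study-wide
  # weighted reduction still meets the target.
  foods <- food_table(data.frame(
    id = c("rice_hi", "millet", "fruit_hi", "veg", "dal", "ghee"),
    name = c("irrigated rice", "millet", "orchard fruit", "vegetables",
             "red gram", "ghee"),
    energy_kcal_per_g = c(3.54, 3.51, 0.5, 0.36, 3.48, 9.0),
    carb_g_per_g = c(0.75, 0.72, 0.12, 0.06, 0.57, 0),
    fat_g_per_g = c(0.02, 0.03, 0.002, 0.004, 0.03, 1.0),
    protein_g_per_g = c(0.08, 0.10, 0.003, 0.021, 0.24, 0),
    free_sugar_g_per_g = c(0, 0, 0.06, 0, 0, 0),
    sodium_mg_per_g = c(0.05, 0.05, 0.02, 0.3, 0.1, 0),
    bwf_l_per_g = c(1.3, 0.15, 0.8, 0.06, 0.9, 0.5),
    bwf_sd_l_per_g = 0.2 * c(1.3, 0.15, 0.8, 0.06, 0.9, 0.5),
    ghg_kgco2e_per_g = c(0.003, 0.001, 0.0006, 0.0005, 0.001, 0.0025),
    exp_share = c(0.2, 0.1, 0.1, 0.15, 0.1, 0.1),
    exp_share_se = rep(0.01, 6),
    elasticity = c(-0.4, -0.5, -1.1, -0.8, -0.6, -1.2),
    tags = c("cereal", "cereal", "fruit", "vegetable", "legume", "oil"),
    stringsAsFactors = FALSE))
  low <- stats::setNames(c(0, 450, 20, 80, 100, 50), foods$id)
  high <- stats::setNames(c(480, 60, 100, 300, 100, 60), foods$id)
  patterns <- list(
    dietary_pattern("millet and low diversity", low, pmax(0.25 * low, 1), 0.5),
    dietary_pattern("irrigated rice", high, pmax(0.25 * high, 1), 0.5))
  sc <- scenario("2025-like", 0.18)
  res <- optimise_all(patterns, foods, sc, nutrient_rules(),
                      n_restarts = 8, seed = 5)
  L <- attr(res, "L")
  expect_true(all(vapply(res, `[[`, logical(1), "feasible")))
  expect_lt(res[[1]]$bwf_baseline, L)          # low pattern starts below L
  expect_gt(res[[1]]$bwf_opt, res[[1]]$bwf_baseline)  # and gains water
  expect_lte(res[[1]]$bwf_opt, L * (1 + 1e-6))
  expect_gte(weighted_bwf_reduction(res, patterns), 18 - 1e-6)
})
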