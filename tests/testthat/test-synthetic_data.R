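# Synthetic-data generator: determinism, calibration and sampling laws.

test_that("food-table generation is seed-deterministic and validated", {
  spec <- synthetic_spec(seed = 1)
  f1 <- generate_food_table(spec)
  f2 <- generate_food_table(spec)
  expect_identical(f1, f2)
  f3 <- generate_food_table(synthetic_spec(seed = 2))
  expect_false(identical(f1, f3))
  # re-validation of the generated table succeeds (invariant suite)
  expect_s3_class(food_table(as.data.frame(f1)), "food_table")
})

test_that("generated food tables span the needed structure", {
  foods <- test_study()$foods
  for (tag in c("fruit", "vegetable", "red_meat", "poultry", "dairy",
                "legume", "cereal")) {
    expect_true(any(has_tag(foods, tag)), info = tag)
  }
  expect_gte(max(foods$bwf_l_per_g) / min(foods$bwf_l_per_g), 10)
  expect_lte(sum(foods$exp_share), 1)
  expect_true(all(foods$elasticity >= -2 & foods$elasticity <= -0.1))
})

test_that("generated patterns land in the study magnitude ranges", {
  study <- test_study()
  spec <- study$spec
  expect_length(study$patterns, 5)
  shares <- vapply(study$patterns, `[[`, numeric(1), "pop_share")
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  for (p in study$patterns) {
    m <- compute_metrics(p$consumption_mean, study$foods)
    expect_gte(m$energy, spec$energy_range[1])
    expect_lte(m$energy, spec$energy_range[2])
    expect_gte(m$bwf, spec$bwf_range[1])
    expect_lte(m$bwf, spec$bwf_range[2])
    expect_gte(m$ghg, spec$ghg_range[1])
    expect_lte(m$ghg, spec$ghg_range[2])
    # SDs are 25% of the mean with a 1 g/day floor
    expect_equal(unname(p$consumption_sd),
                 unname(pmax(0.25 * p$consumption_mean, 1)))
  }
})

test_that("generated life tables satisfy hazard structure", {
  lts <- test_study()$life_tables
  expect_length(lts, 3)
  expect_equal(vapply(lts, `[[`, numeric(1), "year"), c(1990, 2000, 2010))
  for (lt in lts) {
    i40 <- match(40, lt$ages); i80 <- match(80, lt$ages)
    expect_gt(lt$all_cause_rate[i80], lt$all_cause_rate[i40])
    adult <- lt$ages >= 30
    expect_true(all(diff(lt$all_cause_rate[adult]) > 0))
    expect_true(all(rowSums(lt$cause_rates) <= lt$all_cause_rate + 1e-12))
  }
  expect_identical(lts, generate_life_tables(synthetic_spec(seed = 1)))
})

test_that("analytic fixture optimum solves its KKT system exactly", {
  fx <- make_analytic_fixture()
  b <- fx$pattern$consumption_mean
  E0 <- sum(b * fx$foods$energy_kcal_per_g)
  opt <- analytic_fixture_optimum(fx)
  # both equality constraints hold to 1e-9
  expect_equal(sum(opt$consumption * fx$foods$bwf_l_per_g), fx$L,
               tolerance = 1e-9)
  expect_equal(sum(opt$consumption * fx$foods$energy_kcal_per_g), E0,
               tolerance = 1e-9)
  expect_true(all(opt$consumption > 0))

  # the closed form beats 1000 random feasible points (rejection oracle on
  # the two-constraint affine subspace intersected with positivity)
  A <- rbind(fx$foods$bwf_l_per_g, fx$foods$energy_kcal_per_g)
  nullsp <- svd(A, nv = 3)$v[, 3]  # 1-dim null space for 3 foods
  set.seed(42)
  worse <- replicate(1000, {
    c_rand <- unname(opt$consumption) + stats::runif(1, -50, 50) * nullsp
    if (any(c_rand < 0)) return(TRUE)
    deviation_objective(unname(b), c_rand) >= opt$objective - 1e-9
  })
  expect_true(all(worse))
})

test_that("sampling with degenerate distributions returns the central inputs", {
  study <- zero_variance_study(test_study())
  drawn <- sample_inputs(study, seed = 11, uniform_halfwidth = 0)
  expect_equal(as.data.frame(drawn$foods), as.data.frame(study$foods))
  for (i in seq_along(study$patterns)) {
    expect_equal(drawn$patterns[[i]]$consumption_mean,
                 study$patterns[[i]]$consumption_mean)
  }
  rr0 <- vapply(study$exposure_responses, `[[`, numeric(1), "rr_per_unit")
  rr1 <- vapply(drawn$exposure_responses, `[[`, numeric(1), "rr_per_unit")
  expect_equal(rr1, rr0)
})

test_that("sampled water footprints are unbiased (CLT check)", {
  study <- test_study()
  target <- study$foods$bwf_l_per_g[1]
  sdv <- study$foods$bwf_sd_l_per_g[1]
  draws <- vapply(seq_len(2000), function(k) {
    sample_inputs(study, seed = 1000 + k)$foods$bwf_l_per_g[1]
  }, numeric(1))
  se <- sdv / sqrt(2000)
  # truncation at zero is negligible at sd = 20% of the mean
  expect_lt(abs(mean(draws) - target), 3 * se)
})

test_that("truncated-normal draws never go negative", {
  set.seed(7)
  x <- waterdiet:::rnorm_trunc0(10000, mean = 1, sd = 5)
  expect_true(all(x >= 0))
  expect_gt(mean(x), 1)  # truncation shifts the mean up
  # and sampled consumption inherits the property
  study <- test_study()
  drawn <- sample_inputs(study, seed = 5)
  for (p in drawn$patterns) expect_true(all(p$consumption_mean >= 0))
})

test_that("sampling preserves structural invariants", {
  study <- test_study()
  for (s in c(21, 22, 23)) {
    drawn <- sample_inputs(study, seed = s)
    expect_s3_class(food_table(as.data.frame(drawn$foods)), "food_table")
    expect_true(all(drawn$foods$elasticity < 0))  # sign preserved
    expect_length(validate_patterns(drawn$patterns, drawn$foods),
                  length(study$patterns))
  }
  # identical seed, identical draw
  expect_equal(sample_inputs(study, seed = 99), sample_inputs(study, seed = 99))
})

test_that("writing a synthetic study produces readable files", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(dir, synthetic_spec(seed = 2))
  expect_true(all(file.exists(paths)))
  foods <- read_food_table(file.path(dir, "foods.csv"))
  patterns <- read_patterns(file.path(dir, "patterns.csv"),
                            file.path(dir, "patterns_meta.csv"), foods)
  expect_length(patterns, 5)
  cfg <- read_config(file.path(dir, "config.yaml"))
  expect_equal(cfg$scenario$reduction, 0.303)
})
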