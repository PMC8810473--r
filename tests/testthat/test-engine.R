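test_that("zero-risk watch-and-wait matches the closed-form annuity", {
  spec <- degenerate_spec("zero_risk")
  expected <- discounted_annuity(0.80)
  traj <- simulate_patient(spec, "WW", seed = 42)
  expect_equal(traj$discounted_qalys, expected, tolerance = 1e-9)
  expect_true(all(traj$states$state == "STABLE_WW"))
  expect_equal(traj$death_cause, "none")
  oracle <- cohort_expected_value(spec, "WW")
  expect_equal(oracle$expected_qalys, expected, tolerance = 1e-9)
  # and the engine equals its own oracle exactly when nothing is stochastic
  res <- simulate_cohort(spec, "WW", n = 3, seed = 1)
  expect_equal(res$mean_qalys, oracle$expected_qalys, tolerance = 1e-9)
  expect_equal(res$mean_cost, oracle$expected_cost, tolerance = 1e-9)
})

test_that("certain perioperative death yields zero QALYs and entry costs only", {
  spec <- degenerate_spec("certain_perioperative_death")
  traj <- simulate_patient(spec, "SURGERY", seed = 7)
  expect_equal(traj$discounted_qalys, 0)
  expect_equal(traj$discounted_cost,
               spec$costs$surgery_apr$mean + spec$costs$death_perioperative$mean)
  expect_equal(traj$death_cause, "perioperative")
  expect_true(all(traj$states$state == "DEAD"))
  oracle <- cohort_expected_value(spec, "SURGERY")
  expect_equal(oracle$expected_qalys, 0)
  expect_equal(oracle$expected_cost, traj$discounted_cost)
})

test_that("forced regrowth with certain salvage routes through salvage surgery", {
  spec <- degenerate_spec("certain_regrowth_certain_salvage")
  # make the path fully deterministic apart from the regrowth timing
  spec <- apply_recipe(scenario_recipe("no_death", "WW_vs_APR",
                                       wwcea:::.zero_mortality_overrides), spec)
  traj <- simulate_patient(spec, "WW", seed = 11)
  expect_true(traj$regrowth_during_ww)
  expect_true(traj$salvage_received)
  expect_true("POSTOP_STABLE" %in% traj$states$state)
  first_po <- min(which(traj$states$state == "POSTOP_STABLE"))
  expect_true(all(traj$states$state[seq_len(first_po - 1)] == "STABLE_WW"))
  # salvage resection billed once: cost covers surgery plus restaging
  expect_gt(traj$discounted_cost, 0.8 * spec$costs$surgery_apr$mean)
})

test_that("state paths never leave the absorbing death state", {
  spec <- apr_spec()
  res <- simulate_cohort(spec, "SURGERY", n = 200, seed = 3, keep_history = TRUE)
  h <- res$history
  dead <- h == 7L
  # once dead, always dead
  expect_true(all(apply(dead, 1, function(x) all(diff(x) >= 0))))
  # only transitions permitted by the state diagram occur
  allowed <- list(
    `1` = c(1, 2, 4, 5, 6, 7), `2` = c(2, 3, 4, 5, 6, 7),
    `3` = c(3, 6, 7), `4` = c(4, 6, 7), `5` = c(5, 7), `6` = c(6, 7), `7` = 7)
  from <- as.vector(h[, -ncol(h)]); to <- as.vector(h[, -1])
  for (s in 1:7) {
    expect_true(all(to[from == s] %in% allowed[[as.character(s)]]),
                info = paste("transitions out of state", s))
  }
})

test_that("occupancy probabilities are conserved every cycle", {
  for (spec in list(apr_spec(), lar_spec(), random_valid_spec(5))) {
    for (arm in c("WW", "SURGERY")) {
      occ <- cohort_expected_value(spec, arm)$occupancy
      expect_equal(rowSums(as.matrix(occ[, -1])), rep(1, nrow(occ)),
                   tolerance = 1e-12)
    }
  }
})

test_that("discounted QALYs are bounded by the undiscounted horizon maximum", {
  for (seed in 1:5) {
    spec <- random_valid_spec(seed)
    res <- simulate_cohort(spec, "WW", n = 100, seed = seed, keep_patients = TRUE)
    expect_true(all(res$patients$qalys >= 0 & res$patients$qalys <= 5))
    expect_true(all(res$patients$cost >= 0))
  }
})

test_that("raising a mortality probability never increases expected QALYs", {
  spec <- apr_spec()
  base <- cohort_expected_value(spec, "WW")$expected_qalys
  for (path in c("transitions.mortality_distant_5y",
                 "transitions.mortality_local_unsalvaged_5y",
                 "transitions.perioperative_death")) {
    bumped <- suppressWarnings(set_param(spec, path, 0.95))
    expect_lte(cohort_expected_value(bumped, "WW")$expected_qalys, base)
  }
  expect_lt(cohort_expected_value(
    set_param(spec, "natural_mortality_monthly", 0.05), "WW")$expected_qalys, base)
})

test_that("microsimulation means agree with the deterministic oracle", {
  spec <- apr_spec()
  for (arm in c("WW", "SURGERY")) {
    oracle <- cohort_expected_value(spec, arm)
    res <- simulate_cohort(spec, arm, n = 10000, seed = 99, keep_patients = TRUE)
    expect_true(within_mc_error(res$mean_qalys, res$patients$qalys,
                                oracle$expected_qalys),
                info = paste(arm, "QALYs"))
    expect_true(within_mc_error(res$mean_cost, res$patients$cost,
                                oracle$expected_cost),
                info = paste(arm, "cost"))
  }
})

test_that("Monte-Carlo error shrinks with cohort size", {
  spec <- apr_spec()
  truth <- cohort_expected_value(spec, "WW")$expected_qalys
  err <- function(n) {
    median(vapply(1:3, function(s)
      abs(simulate_cohort(spec, "WW", n = n, seed = 100 + s)$mean_qalys - truth),
      numeric(1)))
  }
  e_small <- err(100); e_large <- err(10000)
  expect_lt(e_large, e_small)
})

test_that("results are reproducible from the master seed", {
  spec <- lar_spec()
  a <- simulate_cohort(spec, "SURGERY", n = 500, seed = 123, keep_patients = TRUE)
  b <- simulate_cohort(spec, "SURGERY", n = 500, seed = 123, keep_patients = TRUE)
  expect_identical(a$mean_cost, b$mean_cost)
  expect_identical(a$mean_qalys, b$mean_qalys)
  expect_identical(a$patients, b$patients)
  c <- simulate_cohort(spec, "SURGERY", n = 500, seed = 124)
  expect_false(identical(a$mean_cost, c$mean_cost))
})

test_that("a single-patient cohort equals that patient's trajectory", {
  spec <- apr_spec()
  res <- simulate_cohort(spec, "WW", n = 1, seed = 77, keep_patients = TRUE)
  traj <- simulate_patient(spec, "WW", seed = 77)
  expect_equal(res$mean_cost, traj$discounted_cost)
  expect_equal(res$mean_qalys, traj$discounted_qalys)
})

test_that("cancer-specific mortality never exceeds overall mortality", {
  for (seed in 1:3) {
    spec <- random_valid_spec(seed + 10)
    res <- simulate_cohort(spec, "SURGERY", n = 500, seed = seed)
    p <- res$proportions
    expect_lte(p$cancer_specific_5y_mortality, p$overall_5y_mortality)
    expect_true(all(unlist(p[!is.na(p)]) >= 0 & unlist(p[!is.na(p)]) <= 1))
  }
})
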