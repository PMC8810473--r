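test_that("beta method-of-moments inverts exactly", {
  ab <- beta_params_from_moments(0.5, sqrt(1 / 12))
  expect_equal(unname(ab), c(1, 1), tolerance = 1e-12)
  recover <- function(mean, sd) {
    ab <- beta_params_from_moments(mean, sd)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    c(a / (a + b), sqrt(a * b / ((a + b)^2 * (a + b + 1))))
  }
  expect_equal(recover(0.19, 0.04), c(0.19, 0.04), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:25) {
    m <- runif(1, 0.02, 0.98)
    s <- runif(1, 1e-4, 0.99) * sqrt(m * (1 - m))
    expect_equal(recover(m, s), c(m, s), tolerance = 1e-9)
  }
  expect_error(beta_params_from_moments(0.5, 0.5), "variance")
  expect_error(beta_params_from_moments(0, 0.1), "mean")
})

test_that("gamma method-of-moments inverts exactly", {
  expect_equal(unname(gamma_params_from_moments(1, 1)), c(1, 1))
  # printed cost sd is 20% of the mean up to table rounding, so shape ~ 1/0.2^2
  sh <- gamma_params_from_moments(34662.98, 6932.60)
  expect_equal(unname(sh), c(25, 1386.5192), tolerance = 1e-5)
  set.seed(5)
  for (i in 1:25) {
    m <- runif(1, 1, 1e5); s <- runif(1, 0.01, 2) * m
    g <- gamma_params_from_moments(m, s)
    expect_equal(g[["shape"]] * g[["scale"]], m, tolerance = 1e-9)
    expect_equal(sqrt(g[["shape"]]) * g[["scale"]], s, tolerance = 1e-9)
  }
  expect_error(gamma_params_from_moments(0, 1), "positive")
})

test_that("infeasible beta standard deviations are clipped with a warning", {
  expect_warning(out <- clip_beta_sd(0.94, 0.30, "x"), "clipped")
  expect_equal(out, 0.95 * sqrt(0.94 * 0.06))
  expect_silent(expect_equal(clip_beta_sd(0.94, 0.19), 0.19))
})

test_that("parameter sampling recovers means and respects fixed parameters", {
  spec <- apr_spec()
  # zero all sds: the draw is the base case exactly
  frozen <- spec
  for (p in wwcea:::sampled_param_paths(frozen)) {
    node <- get_param(frozen, p); node$sd <- 0
    frozen[[strsplit(p, ".", fixed = TRUE)[[1]]]] <- node
  }
  draw <- sample_spec(frozen, seed = 9)
  for (p in wwcea:::sampled_param_paths(spec)) {
    expect_equal(get_param(draw, p)$mean, get_param(frozen, p)$mean)
  }
  expect_equal(draw$utilities$death$mean, 0)
  # CLT check on a probability and a cost parameter over 400 draws
  n <- 400
  vals <- t(vapply(seq_len(n), function(i) {
    d <- sample_spec(spec, seed = 1000 + i)
    c(get_param(d, "transitions.local_recurrence_2y.WW")$mean,
      get_param(d, "costs.surgery_apr")$mean)
  }, numeric(2)))
  expect_lt(abs(mean(vals[, 1]) - 0.19), 4 * 0.04 / sqrt(n))
  expect_lt(abs(mean(vals[, 2]) - 22015.72), 4 * 4403.14 / sqrt(n))
  expect_true(all(vals[, 1] > 0 & vals[, 1] < 1))
  expect_true(all(vals[, 2] > 0))
})

test_that("PSA is reproducible and degenerates to the base case with zero sds", {
  spec <- apr_spec()
  oracle_eval <- function(spec, arm, n, seed) {
    r <- cohort_expected_value(spec, arm)
    list(cost = r$expected_cost, qalys = r$expected_qalys)
  }
  frozen <- spec
  for (p in wwcea:::sampled_param_paths(frozen)) {
    node <- get_param(frozen, p); node$sd <- 0
    frozen[[strsplit(p, ".", fixed = TRUE)[[1]]]] <- node
  }
  one <- psa(frozen, n_outer = 1, n_inner = 1, master_seed = 2,
             evaluator = oracle_eval)
  base_ww <- cohort_expected_value(spec, "WW")
  expect_equal(one$ww_cost, base_ww$expected_cost)
  expect_equal(one$ww_qalys, base_ww$expected_qalys)

  a <- psa(spec, n_outer = 4, n_inner = 200, master_seed = 11)
  b <- psa(spec, n_outer = 4, n_inner = 200, master_seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)
})

test_that("one-way sweeps classify bands and find thresholds consistently", {
  spec <- apr_spec()
  # sweeping a parameter across its base value reproduces the base classification
  base_cls <- wwcea:::classify_vs_ww(spec, 1e5, wwcea:::.default_oracle_evaluator)
  expect_equal(base_cls, "ww_dominates")
  d <- one_way(spec, "transitions.local_recurrence_2y.WW", 0.19, 0.19)
  expect_equal(nrow(d$bands), 1)
  expect_equal(d$bands$classification, "ww_dominates")

  # a cost parameter swept 5%-195% never changes the conclusion
  d_cost <- one_way(spec, "costs.reirradiation_course",
                    0.05 * 19800, 1.95 * 19800, n_grid = 5)
  expect_true(all(d_cost$bands$classification == "ww_dominates"))
  expect_true(is.na(dsa_threshold(d_cost)))

  # bisection threshold agrees with a brute-force fine grid
  d_thr <- one_way(spec, "utilities.initial_ww", 0.4, 0.95, n_grid = 7)
  grid <- seq(0.4, 0.95, by = 0.005)
  cls <- vapply(grid, function(v) {
    wwcea:::classify_vs_ww(suppressWarnings(set_param(spec, "utilities.initial_ww", v)),
                           1e5, wwcea:::.default_oracle_evaluator)
  }, character(1))
  # lowest WW utility at which WW dominates, from the brute-force grid, must
  # match the upper bisection boundary
  brute <- grid[min(which(cls == "ww_dominates"))]
  expect_lt(abs(max(d_thr$thresholds) - brute), 0.006)
  expect_true(all(d_thr$bands$to >= d_thr$bands$from))
  # bands partition the tested range
  expect_equal(d_thr$bands$from[1], 0.4)
  expect_equal(d_thr$bands$to[nrow(d_thr$bands)], 0.95)
  expect_equal(d_thr$bands$from[-1], d_thr$bands$to[-nrow(d_thr$bands)])
})
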