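#' @title Sensitivity analyses
#' @description One-way deterministic sensitivity analysis with threshold
#'   search over the noise-free cohort evaluator, and probabilistic
#'   sensitivity analysis with beta-distributed probabilities/utilities and
#'   gamma-distributed costs.
#' @name sensitivity
#' @keywords internal
NULL

#' Method-of-moments beta parameters
#'
#' Solves for the shape parameters of a beta distribution with the given mean
#' and standard deviation: `alpha = m (m(1-m)/sd^2 - 1)`,
#' `beta = (1-m) (m(1-m)/sd^2 - 1)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with `0 < sd^2 < mean (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)", call. = FALSE)
  v <- sd^2
  bound <- mean * (1 - mean)
  if (v <= 0 || v >= bound) {
    stop(sprintf(
      "beta variance %.4g outside (0, mean(1-mean) = %.4g); clip sd below sqrt(mean(1-mean)) (see clip_beta_sd)",
      v, bound), call. = FALSE)
  }
  nu <- bound / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`.
#'
#' @param mean Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
gamma_params_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma mean and sd must be positive", call. = FALSE)
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Clip a beta standard deviation to its feasible bound
#'
#' Some parameter rows carry a printed sd at or above the beta feasibility
#' bound `sqrt(mean(1-mean))`; such sds are reduced to 95% of the bound with a
#' warning before sampling.
#'
#' @param mean Mean in (0, 1).
#' @param sd Candidate standard deviation.
#' @param label Parameter name for the warning.
#' @return A feasible sd.
#' @export
clip_beta_sd <- function(mean, sd, label = "parameter") {
  bound <- sqrt(mean * (1 - mean))
  if (sd >= bound) {
    clipped <- 0.95 * bound
    warning(sprintf("%s: sd %.4g >= beta bound %.4g; clipped to %.4g",
                    label, sd, bound, clipped), call. = FALSE)
    return(clipped)
  }
  sd
}

#' Draw one parameter-set realization for the probabilistic analysis
#'
#' Every non-fixed parameter is resampled: beta draws for probabilities and
#' utilities (method-of-moments parameterization, sd clipped to the feasible
#' bound where needed), gamma draws for costs. Parameters with `sd = 0`, a
#' mean at a domain boundary, or family `"fixed"` are left untouched.
#'
#' @param spec A validated `wwcea_spec`.
#' @param seed Integer seed for the draw.
#' @return A new `wwcea_spec` whose means are one joint realization.
#' @export
sample_spec <- function(spec, seed) {
  set.seed(as.integer(seed))
  for (path in sampled_param_paths(spec)) {
    p <- get_param(spec, path)
    if (p$sd <= 0) next
    value <- if (p$family == "beta") {
      if (p$mean <= 0 || p$mean >= 1) next
      sd <- suppressWarnings(clip_beta_sd(p$mean, p$sd, path))
      ab <- beta_params_from_moments(p$mean, sd)
      stats::rbeta(1, ab[["alpha"]], ab[["beta"]])
    } else {
      if (p$mean <= 0) next
      sh <- gamma_params_from_moments(p$mean, p$sd)
      stats::rgamma(1, shape = sh[["shape"]], scale = sh[["scale"]])
    }
    spec <- set_param(spec, path, value, validate = FALSE)
  }
  suppressWarnings(validate_spec(spec))
  spec
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_outer` parameter-set realizations and evaluates each with an
#' `n_inner`-patient microsimulation per arm (or a custom evaluator). Fully
#' reproducible from `master_seed`: per-iteration parameter and simulation
#' seeds are pre-drawn from one stream.
#'
#' @param spec A validated `wwcea_spec`.
#' @param n_outer Number of parameter draws.
#' @param n_inner Patients per microsimulation.
#' @param master_seed Integer master seed.
#' @param evaluator Function `(spec, arm, n, seed) -> list(cost, qalys)`;
#'   defaults to the microsimulation engine.
#' @return A tibble with one row per draw: per-arm discounted cost and QALYs,
#'   seeds, and `ww_dominant` (WW strictly cheaper and more effective).
#' @export
psa <- function(spec, n_outer = spec$timeline$psa_outer_iterations,
                n_inner = spec$timeline$cohort_size, master_seed = 1L,
                evaluator = NULL) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  if (is.null(evaluator)) {
    evaluator <- function(spec, arm, n, seed) {
      r <- simulate_cohort(spec, arm, n = n, seed = seed)
      list(cost = r$mean_cost, qalys = r$mean_qalys)
    }
  }
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_outer),
                  ncol = 3L)  # parameter draw, WW run, surgery run
  rows <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    draw <- sample_spec(spec, seed = seeds[i, 1L])
    ww <- evaluator(draw, "WW", n_inner, seeds[i, 2L])
    sg <- evaluator(draw, "SURGERY", n_inner, seeds[i, 3L])
    rows[[i]] <- tibble::tibble(
      iteration = i, param_seed = seeds[i, 1L],
      ww_cost = ww$cost, ww_qalys = ww$qalys,
      surg_cost = sg$cost, surg_qalys = sg$qalys,
      ww_dominant = ww$cost < sg$cost & ww$qalys > sg$qalys
    )
  }
  dplyr::bind_rows(rows)
}

# Classify one parameter setting from the surgery-versus-WW viewpoint used in
# the one-way sensitivity tables: "ww_dominates", "surgery_not_cost_effective"
# (surgery neither dominant nor preferred at the threshold), or
# "surgery_cost_effective" (surgery dominant or preferred by NMB).
classify_vs_ww <- function(spec, wtp, evaluator) {
  ww <- evaluator(spec, "WW")
  sg <- evaluator(spec, "SURGERY")
  cmp <- compare(sg, ww, wtp)
  if (cmp$classification == "B_dominates") return("ww_dominates")
  if (cmp$classification == "A_dominates" || cmp$preferred == "A") {
    return("surgery_cost_effective")
  }
  "surgery_not_cost_effective"
}

.default_oracle_evaluator <- function(spec, arm) {
  cohort_expected_value(spec, arm)
}

#' One-way deterministic sensitivity analysis
#'
#' Sweeps a single parameter over `[lower, upper]` with all others at their
#' base values, classifies each grid point from the surgery-versus-WW
#' viewpoint (WW dominates / surgery not cost effective / surgery cost
#' effective) using the deterministic cohort evaluator, and refines every band
#' boundary by bisection. The deterministic evaluator is used so thresholds
#' are noise-free.
#'
#' @param spec A validated `wwcea_spec`.
#' @param parameter Dotted parameter path (see [get_param()]), or the virtual
#'   path `"natural_mortality_monthly"`.
#' @param lower,upper Sweep range inside the parameter's legal domain.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @param evaluator Function `(spec, arm) -> list(expected_cost,
#'   expected_qalys)`; defaults to [cohort_expected_value()].
#' @param n_grid Initial grid size (default 9).
#' @param tol Bisection tolerance; defaults to 1e-3 for probabilities and
#'   utilities, $1 for costs.
#' @return A `wwcea_dsa_result`: the `bands` tibble (classification, from,
#'   to), the refined `thresholds`, and the tested range.
#' @export
one_way <- function(spec, parameter, lower, upper, wtp = spec$timeline$wtp_threshold,
                    evaluator = .default_oracle_evaluator, n_grid = 9L, tol = NULL) {
  if (lower > upper) stop("lower must be <= upper", call. = FALSE)
  if (is.null(tol)) {
    tol <- if (startsWith(parameter, "costs.")) 1 else 1e-3
  }
  classify_at <- function(v) {
    s <- suppressWarnings(set_param(spec, parameter, v))
    classify_vs_ww(s, wtp, evaluator)
  }
  grid <- if (lower == upper) lower else seq(lower, upper, length.out = n_grid)
  cls <- vapply(grid, classify_at, character(1))

  thresholds <- numeric(0)
  bands <- list()
  band_start <- grid[1]
  if (length(grid) > 1) {
    for (j in seq_len(length(grid) - 1L)) {
      if (cls[j] != cls[j + 1L]) {
        lo <- grid[j]; hi <- grid[j + 1L]
        cl_lo <- cls[j]
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          if (classify_at(mid) == cl_lo) lo <- mid else hi <- mid
        }
        thr <- (lo + hi) / 2
        thresholds <- c(thresholds, thr)
        bands[[length(bands) + 1L]] <- tibble::tibble(
          classification = cls[j], from = band_start, to = thr)
        band_start <- thr
      }
    }
  }
  bands[[length(bands) + 1L]] <- tibble::tibble(
    classification = cls[length(cls)], from = band_start, to = grid[length(grid)])
  structure(list(
    parameter = parameter, lower = lower, upper = upper, wtp = wtp,
    bands = dplyr::bind_rows(bands), thresholds = thresholds,
    base_value = if (identical(parameter, "natural_mortality_monthly")) NA_real_
                 else get_param(spec, parameter)$mean
  ), class = "wwcea_dsa_result")
}

#' Threshold above which surgery becomes cost effective
#'
#' Convenience accessor: the lower edge of the `surgery_cost_effective` band
#' of a one-way sweep, or `NA` if surgery never becomes cost effective over
#' the tested range ("remains dominated" when WW dominates throughout).
#'
#' @param dsa A `wwcea_dsa_result`.
#' @return The threshold parameter value, or `NA_real_`.
#' @export
dsa_threshold <- function(dsa) {
  b <- dsa$bands[dsa$bands$classification == "surgery_cost_effective", , drop = FALSE]
  if (nrow(b) == 0) return(NA_real_)
  min(b$from)
}

#' @export
print.wwcea_dsa_result <- function(x, ...) {
  cat("<one-way sensitivity> ", x$parameter, " over [",
      format(x$lower), ", ", format(x$upper), "]\n", sep = "")
  for (i in seq_len(nrow(x$bands))) {
    cat(sprintf("  [%.6g, %.6g] %s\n", x$bands$from[i], x$bands$to[i],
                x$bands$classification[i]))
  }
  invisible(x)
}
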