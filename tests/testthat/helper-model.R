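# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from outside the installed package.

# Closed-form discounted annuity: QALYs accrued by a patient who stays in a
# single state with the given utility for the whole horizon, with mid-cycle
# (half-cycle corrected) discounting. Independent oracle for the engine.
discounted_annuity <- function(utility, horizon = 60, rate = 0.03) {
  t <- seq_len(horizon)
  utility * sum((1 + rate)^(-(t - 0.5) / 12)) / 12
}

# Survival-product cumulative incidence for a single competing-risk-free
# hazard schedule: oracle for per-cycle reconstruction checks.
cumulative_from_schedule <- function(schedule) {
  1 - prod(1 - schedule)
}

apr_spec <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- base_case_spec("WW_vs_APR")
    spec
  }
})
lar_spec <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- base_case_spec("WW_vs_LAR")
    spec
  }
})

# Standard-error-based band for comparing a microsimulation mean with the
# deterministic expectation.
within_mc_error <- function(mean_hat, patient_values, truth, n_se = 4) {
  se <- stats::sd(patient_values) / sqrt(length(patient_values))
  abs(mean_hat - truth) <= n_se * se
}
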