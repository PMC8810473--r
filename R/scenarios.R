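#' @title Scenario recipes
#' @description Named parameter-override recipes over the packaged base cases:
#'   degenerate scenarios with closed-form expectations for engine
#'   verification, adjuvant-chemotherapy timing variants, and randomized valid
#'   parameter sets for property tests.
#' @name scenarios
#' @keywords internal
NULL

.zero_risk_overrides <- list(
  "transitions.perioperative_death" = 0,
  "transitions.local_recurrence_2y.WW" = 0,
  "transitions.local_recurrence_2y.TME" = 0,
  "transitions.local_recurrence_5y.WW" = 0,
  "transitions.local_recurrence_5y.TME" = 0,
  "transitions.distant_recurrence_5y.WW" = 0,
  "transitions.distant_recurrence_5y.TME" = 0,
  "transitions.concurrent_distant_given_local" = 0,
  "transitions.concurrent_local_given_distant" = 0,
  "transitions.distant_after_local_3y" = 0,
  "natural_mortality_monthly" = 0
)
.zero_mortality_overrides <- list(
  "transitions.perioperative_death" = 0,
  "transitions.mortality_local_salvaged_5y" = 0,
  "transitions.mortality_local_unsalvaged_5y" = 0,
  "transitions.mortality_distant_5y" = 0,
  "transitions.mortality_local_and_distant_5y" = 0,
  "natural_mortality_monthly" = 0
)

#' Scenario recipe constructor
#'
#' @param name Recipe name.
#' @param comparison Base comparison the recipe applies to.
#' @param overrides Named list: dotted parameter path -> new mean (the virtual
#'   path `"natural_mortality_monthly"` is allowed).
#' @param timeline Named list of timeline constants to replace.
#' @param expected Free-text note on the qualitative outcome the scenario is
#'   expected to produce (used by labelled tests).
#' @return A `wwcea_recipe`.
#' @export
scenario_recipe <- function(name, comparison = "WW_vs_APR", overrides = list(),
                            timeline = list(), expected = "") {
  structure(list(name = name, comparison = comparison, overrides = overrides,
                 timeline = timeline, expected = expected),
            class = "wwcea_recipe")
}

#' Apply a scenario recipe
#'
#' Loads the recipe's base-case spec and applies its parameter and timeline
#' overrides.
#'
#' @param recipe A `wwcea_recipe`.
#' @param base Optional `wwcea_spec` to override instead of the packaged base
#'   case.
#' @return A validated `wwcea_spec`.
#' @export
apply_recipe <- function(recipe, base = NULL) {
  spec <- base %||% base_case_spec(recipe$comparison)
  for (path in names(recipe$overrides)) {
    spec <- suppressWarnings(
      set_param(spec, path, recipe$overrides[[path]], validate = FALSE))
  }
  for (nm in names(recipe$timeline)) {
    if (!nm %in% names(spec$timeline)) {
      stop("unknown timeline constant: ", nm, call. = FALSE)
    }
    spec$timeline[[nm]] <- recipe$timeline[[nm]]
  }
  suppressWarnings(validate_spec(spec))
  spec
}

#' Degenerate test scenarios
#'
#' Scenarios with closed-form or forced outcomes used to verify the engine:
#' all event risks zero (discounted-annuity QALY oracle), certain
#' perioperative death, near-certain regrowth with certain salvage (the
#' cumulative regrowth probability is capped at 0.99 because a cumulative 1
#' implies an infinite monthly hazard), all costs zero, and all utilities one
#' with zero mortality.
#'
#' @param comparison Base comparison for the recipes.
#' @return Named list of `wwcea_recipe` objects.
#' @export
degenerate_scenarios <- function(comparison = "WW_vs_APR") {
  list(
    zero_risk = scenario_recipe(
      "zero_risk", comparison, .zero_risk_overrides,
      expected = "everyone remains stable; QALYs follow the discounted annuity"),
    certain_perioperative_death = scenario_recipe(
      "certain_perioperative_death", comparison,
      list("transitions.perioperative_death" = 1),
      expected = "surgery arm: QALYs 0, cost = surgery + perioperative death cost"),
    certain_regrowth_certain_salvage = scenario_recipe(
      "certain_regrowth_certain_salvage", comparison,
      list("transitions.local_recurrence_2y.WW" = 0.99,
           "transitions.local_recurrence_5y.WW" = 0.99,
           "transitions.salvage_given_local.WW" = 1,
           "transitions.concurrent_distant_given_local" = 0),
      expected = "nearly all WW patients are salvaged into the post-operative state"),
    zero_costs = scenario_recipe(
      "zero_costs", comparison,
      expected = "both arms cost exactly 0"),
    utilities_one_zero_mortality = scenario_recipe(
      "utilities_one_zero_mortality", comparison,
      .zero_mortality_overrides,
      expected = "QALYs equal the discounted annuity in both arms")
  )
}

# zero_costs and utilities_one need path enumeration against a concrete spec,
# so finish them lazily here.
finalize_recipe <- function(recipe, spec) {
  if (recipe$name == "zero_costs") {
    paths <- grep("^costs\\.", sampled_param_paths(spec), value = TRUE)
    recipe$overrides <- stats::setNames(as.list(rep(0, length(paths))), paths)
  }
  if (recipe$name == "utilities_one_zero_mortality") {
    paths <- grep("^utilities\\.", sampled_param_paths(spec), value = TRUE)
    recipe$overrides <- c(recipe$overrides,
                          stats::setNames(as.list(rep(1, length(paths))), paths))
  }
  recipe
}

#' Build a degenerate scenario spec in one call
#'
#' @param name A name from [degenerate_scenarios()].
#' @param comparison Base comparison.
#' @return A validated `wwcea_spec`.
#' @export
degenerate_spec <- function(name, comparison = "WW_vs_APR") {
  recipes <- degenerate_scenarios(comparison)
  if (!name %in% names(recipes)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(recipes), collapse = ", "), call. = FALSE)
  }
  base <- base_case_spec(comparison)
  apply_recipe(finalize_recipe(recipes[[name]], base), base)
}

#' Adjuvant-chemotherapy timing scenarios
#'
#' Variants starting adjuvant chemotherapy 4, 8 or 12 weeks after resection
#' (state-clock offsets of 1, 2 or 3 monthly cycles), used to check that the
#' cost-effectiveness conclusion is insensitive to chemotherapy timing.
#'
#' @param comparison Base comparison.
#' @return Named list of `wwcea_recipe` objects.
#' @export
adjuvant_timing_scenarios <- function(comparison = "WW_vs_APR") {
  mk <- function(weeks, offset) scenario_recipe(
    paste0("adjuvant_start_", weeks, "wk"), comparison,
    timeline = list(adjuvant_chemo_start_offset_cycles = offset),
    expected = "WW remains dominant")
  list(adjuvant_start_4wk = mk(4, 1L),
       adjuvant_start_8wk = mk(8, 2L),
       adjuvant_start_12wk = mk(12, 3L))
}

#' Random valid parameter set
#'
#' Draws every probability uniformly on [0, 0.99], every utility (except the
#' structurally fixed death utility) on [0, 1], and every cost on [0, 2 x
#' base]. The result always passes validation; used in property tests.
#'
#' @param seed Integer seed.
#' @param comparison Base comparison.
#' @return A validated `wwcea_spec`.
#' @export
random_valid_spec <- function(seed, comparison = "WW_vs_APR") {
  set.seed(as.integer(seed))
  spec <- base_case_spec(comparison)
  for (path in sampled_param_paths(spec)) {
    base <- get_param(spec, path)$mean
    value <- if (startsWith(path, "costs.")) {
      stats::runif(1, 0, 2 * max(base, 1))
    } else if (startsWith(path, "utilities.")) {
      stats::runif(1, 0, 1)
    } else {
      stats::runif(1, 0, 0.99)
    }
    spec <- set_param(spec, path, value, validate = FALSE)
  }
  suppressWarnings(validate_spec(spec))
  spec
}
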