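#' @title Model parameter handling
#' @description Loading, validation and serialization of the decision-model
#'   parameter sets: transition probabilities, health-state utilities
#'   (QALY weights), payer-perspective costs (2019 US$), timeline constants,
#'   the surveillance calendar and the background-mortality life table.
#' @name parameters
#' @keywords internal
NULL

.comparisons <- c("WW_vs_APR", "WW_vs_LAR")

# Section-level default uncertainty families: probabilities and utilities are
# beta-distributed in the probabilistic analysis, costs gamma-distributed.
.section_family <- c(transitions = "beta", utilities = "beta", costs = "gamma")

#' Construct a single model parameter
#'
#' A parameter bundles a point estimate (its mean), a standard deviation used
#' by the probabilistic sensitivity analysis, the uncertainty family
#' (`"beta"`, `"gamma"` or `"fixed"`), and a free-text source label. When `sd`
#' is missing it is filled as 20% of the mean, the convention used for
#' parameters whose dispersion is not reported.
#'
#' @param mean Point estimate (probability, utility weight, or US$ amount).
#' @param sd Standard deviation on the same scale; `NULL` fills 0.20 * mean.
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param source Free-text citation tag.
#' @param name Field name used in error messages.
#' @return A list with elements `mean`, `sd`, `family`, `source`.
#' @export
param_value <- function(mean, sd = NULL, family = c("beta", "gamma", "fixed"),
                        source = "", name = "parameter") {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean)) {
    stop(sprintf("'%s': mean must be a single number", name), call. = FALSE)
  }
  if (is.null(sd)) sd <- 0.20 * mean
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop(sprintf("'%s': sd must be a single non-negative number", name),
         call. = FALSE)
  }
  if (family == "beta" && (mean < 0 || mean > 1)) {
    stop(sprintf("'%s': beta-family mean %.4g outside [0, 1]", name, mean),
         call. = FALSE)
  }
  if (family == "gamma" && mean < 0) {
    stop(sprintf("'%s': gamma-family mean %.4g is negative", name, mean),
         call. = FALSE)
  }
  list(mean = mean, sd = sd, family = family, source = source)
}

.is_param <- function(x) {
  is.list(x) && !is.null(x$mean) && !is.null(x$family)
}

# Coerce one raw config entry (a list with mean/sd/source and optional family)
# into a validated parameter, recursing into per-arm {WW, TME} blocks.
.as_param_node <- function(x, name, default_family) {
  if (!is.list(x)) {
    stop(sprintf("'%s': expected a mapping with a 'mean' entry", name),
         call. = FALSE)
  }
  if (is.null(x$mean) && all(c("WW", "TME") %in% names(x))) {
    return(list(
      WW = .as_param_node(x$WW, paste0(name, ".WW"), default_family),
      TME = .as_param_node(x$TME, paste0(name, ".TME"), default_family)
    ))
  }
  if (is.null(x$mean)) {
    stop(sprintf("'%s': missing 'mean' (or incomplete WW/TME arm pair)", name),
         call. = FALSE)
  }
  fam <- if (is.null(x$family)) default_family else x$family
  param_value(as.numeric(x$mean),
              if (is.null(x$sd)) NULL else as.numeric(x$sd),
              family = fam,
              source = if (is.null(x$source)) "" else x$source,
              name = name)
}

.required_transitions <- c(
  "perioperative_death", "local_recurrence_2y", "local_recurrence_5y",
  "salvage_given_local", "distant_recurrence_5y",
  "concurrent_distant_given_local", "concurrent_local_given_distant",
  "distant_after_local_3y", "mortality_local_salvaged_5y",
  "mortality_local_unsalvaged_5y", "mortality_distant_5y",
  "mortality_local_and_distant_5y"
)
.per_arm_transitions <- c(
  "local_recurrence_2y", "local_recurrence_5y", "salvage_given_local",
  "distant_recurrence_5y"
)
.required_utilities <- c(
  "initial_ww", "initial_postop", "salvage_tme_disutility_state",
  "local_recurrence", "distant_recurrence", "local_and_distant", "death"
)
.required_costs <- c(
  "adjuvant_chemo_per_cycle", "ostomy_care_monthly", "restaging_local",
  "restaging_distant", "reirradiation_course",
  "palliative_capecitabine_per_cycle", "palliative_mfolfox6_per_cycle",
  "death_perioperative", "death_cancer", "death_noncancer"
)

#' Load and validate a model specification from a YAML document
#'
#' The configuration schema mirrors the base-case parameter tables: a
#' `comparison` label, `timeline` constants, `transitions`, `utilities` and
#' `costs` sections whose entries are `{mean, sd, source}` mappings (per-arm
#' parameters hold a `WW`/`TME` pair), a `surveillance` calendar mapping cost
#' items to the state-clock cycles at which they are billed, and a
#' `life_table` file reference (columns `age`, `annual_death_probability`).
#' Missing standard deviations are filled as 20% of the mean.
#'
#' @param path Path to a YAML configuration document.
#' @return A validated `wwcea_spec` object.
#' @seealso [base_case_spec()], [write_spec()], [validate_spec()]
#' @export
load_spec <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  spec <- build_spec(raw, config_dir = dirname(path))
  spec
}

# Assemble a wwcea_spec from a raw nested list (parsed YAML or programmatic).
build_spec <- function(raw, config_dir = NULL) {
  if (is.null(raw$comparison) || !raw$comparison %in% .comparisons) {
    stop("'comparison' must be one of: ", paste(.comparisons, collapse = ", "),
         call. = FALSE)
  }
  for (sec in c("timeline", "transitions", "utilities", "costs", "surveillance")) {
    if (is.null(raw[[sec]])) stop("missing config section '", sec, "'", call. = FALSE)
  }
  parse_section <- function(sec) {
    out <- list()
    for (nm in names(raw[[sec]])) {
      out[[nm]] <- .as_param_node(raw[[sec]][[nm]], paste0(sec, ".", nm),
                                  .section_family[[sec]])
    }
    out
  }
  tl <- raw$timeline
  timeline <- list(
    cycle_length_months = as.integer(tl$cycle_length_months %||% 1L),
    horizon_cycles = as.integer(tl$horizon_cycles %||% 60L),
    annual_discount_rate = as.numeric(tl$annual_discount_rate %||% 0.03),
    postop_recovery_cycles = as.integer(tl$postop_recovery_cycles %||% 2L),
    adjuvant_chemo_duration_cycles =
      as.integer(tl$adjuvant_chemo_duration_cycles %||% 4L),
    adjuvant_chemo_start_offset_cycles =
      as.integer(tl$adjuvant_chemo_start_offset_cycles %||% 2L),
    lar_ostomy_duration_cycles = as.integer(tl$lar_ostomy_duration_cycles %||% 6L),
    wtp_threshold = as.numeric(tl$wtp_threshold %||% 1e5),
    cohort_size = as.integer(tl$cohort_size %||% 10000L),
    psa_outer_iterations = as.integer(tl$psa_outer_iterations %||% 100L),
    baseline_age_years = as.numeric(tl$baseline_age_years %||% 65),
    ww_adjuvant_chemo = isTRUE(tl$ww_adjuvant_chemo),
    local_interpolation = match.arg(tl$local_interpolation %||% "row_horizon",
                                    c("row_horizon", "conditional_residual"))
  )
  surveillance <- lapply(raw$surveillance, function(arm) {
    lapply(arm, function(v) sort(as.integer(v)))
  })
  life_table_file <- raw$life_table %||% "life_table_2015_synthetic.tsv"
  life_table <- load_life_table(resolve_life_table_path(life_table_file, config_dir))

  spec <- structure(
    list(
      comparison = raw$comparison,
      timeline = timeline,
      transitions = parse_section("transitions"),
      utilities = parse_section("utilities"),
      costs = parse_section("costs"),
      surveillance = surveillance,
      life_table = life_table,
      life_table_file = life_table_file,
      overrides = list(natural_mortality_monthly = NULL)
    ),
    class = "wwcea_spec"
  )
  validate_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_life_table_path <- function(file, config_dir) {
  if (file.exists(file)) return(file)
  if (!is.null(config_dir) && file.exists(file.path(config_dir, file))) {
    return(file.path(config_dir, file))
  }
  pkg <- system.file("extdata", file, package = "wwcea")
  if (nzchar(pkg)) return(pkg)
  stop("life table file not found: ", file, call. = FALSE)
}

#' Load a background-mortality life table
#'
#' Reads a delimited text file with columns `age` (integer years) and
#' `annual_death_probability`, checks range and monotonicity over adult ages,
#' and returns it as a data frame. The packaged fixture is an abridged,
#' sex-averaged reconstruction of a 2015 US period life table (synthetic; see
#' the package vignette).
#'
#' @param path Path to the tab-separated life-table file.
#' @return A `data.frame` with columns `age` and `annual_death_probability`.
#' @export
load_life_table <- function(path) {
  lt <- utils::read.delim(path, sep = "\t", header = TRUE)
  if (!all(c("age", "annual_death_probability") %in% names(lt))) {
    stop("life table must have columns 'age' and 'annual_death_probability'",
         call. = FALSE)
  }
  q <- lt$annual_death_probability
  if (any(q < 0 | q > 1)) stop("life table probabilities outside [0, 1]", call. = FALSE)
  adult <- lt$age >= 18
  if (any(diff(q[adult]) < 0)) {
    stop("life table probabilities must be non-decreasing over adult ages",
         call. = FALSE)
  }
  lt[, c("age", "annual_death_probability")]
}

#' Validate a model specification
#'
#' Checks structural completeness (all required transition, utility and cost
#' rows for the spec's comparison), probability and utility ranges, cost
#' non-negativity, timeline constants, and that every surveillance calendar
#' item refers to a defined cost parameter. Errors name the offending field.
#'
#' @param spec A `wwcea_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "wwcea_spec"))
  tl <- spec$timeline
  if (tl$horizon_cycles < 1L) stop("timeline.horizon_cycles must be >= 1", call. = FALSE)
  if (tl$cycle_length_months != 1L) {
    stop("timeline.cycle_length_months: only monthly cycles are supported", call. = FALSE)
  }
  durations <- c(tl$postop_recovery_cycles, tl$adjuvant_chemo_duration_cycles,
                 tl$adjuvant_chemo_start_offset_cycles, tl$lar_ostomy_duration_cycles)
  if (any(durations < 1L) || any(durations > tl$horizon_cycles)) {
    stop("timeline durations must be positive and within the horizon", call. = FALSE)
  }
  if (tl$annual_discount_rate < 0) stop("timeline.annual_discount_rate < 0", call. = FALSE)

  miss <- setdiff(.required_transitions, names(spec$transitions))
  if (length(miss)) stop("missing transitions: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in .per_arm_transitions) {
    node <- spec$transitions[[nm]]
    if (!all(c("WW", "TME") %in% names(node))) {
      stop(sprintf("transitions.%s must define both WW and TME arms", nm), call. = FALSE)
    }
  }
  miss <- setdiff(.required_utilities, names(spec$utilities))
  if (length(miss)) stop("missing utilities: ", paste(miss, collapse = ", "), call. = FALSE)
  surg <- surgery_type(spec)
  if (surg == "APR" && is.null(spec$utilities$longterm_apr)) {
    stop("utilities.longterm_apr required for WW_vs_APR", call. = FALSE)
  }
  if (surg == "LAR" &&
      (is.null(spec$utilities$longterm_lar_with_ostomy) ||
       is.null(spec$utilities$longterm_lar_without_ostomy))) {
    stop("utilities.longterm_lar_with_ostomy and longterm_lar_without_ostomy required for WW_vs_LAR",
         call. = FALSE)
  }
  miss <- setdiff(.required_costs, names(spec$costs))
  if (length(miss)) stop("missing costs: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(spec$costs[[paste0("surgery_", tolower(surg))]])) {
    stop("costs.surgery_", tolower(surg), " required for ", spec$comparison, call. = FALSE)
  }
  if (surg == "LAR" && is.null(spec$costs$ostomy_takedown)) {
    stop("costs.ostomy_takedown required for WW_vs_LAR", call. = FALSE)
  }

  check_leaves <- function(sec, check) {
    for (nm in names(spec[[sec]])) {
      node <- spec[[sec]][[nm]]
      leaves <- if (.is_param(node)) {
        stats::setNames(list(node), paste0(sec, ".", nm))
      } else {
        stats::setNames(node, paste0(sec, ".", nm, ".", names(node)))
      }
      for (lname in names(leaves)) check(leaves[[lname]], lname)
    }
  }
  check_leaves("transitions", function(p, nm) {
    if (p$mean < 0 || p$mean > 1) {
      stop(sprintf("%s: probability %.4g outside [0, 1]", nm, p$mean), call. = FALSE)
    }
  })
  check_leaves("utilities", function(p, nm) {
    if (p$mean < 0 || p$mean > 1) {
      stop(sprintf("%s: utility %.4g outside [0, 1]", nm, p$mean), call. = FALSE)
    }
  })
  if (spec$utilities$death$mean != 0) stop("utilities.death must be exactly 0", call. = FALSE)
  check_leaves("costs", function(p, nm) {
    if (p$mean < 0) stop(sprintf("%s: cost %.4g is negative", nm, p$mean), call. = FALSE)
  })

  if (!all(c("WW", "postop") %in% names(spec$surveillance))) {
    stop("surveillance must define 'WW' and 'postop' calendars", call. = FALSE)
  }
  for (arm in names(spec$surveillance)) {
    cal <- spec$surveillance[[arm]]
    unknown <- setdiff(names(cal), names(spec$costs))
    if (length(unknown)) {
      stop("surveillance.", arm, ": unknown cost items: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (item in names(cal)) {
      cyc <- cal[[item]]
      if (any(cyc < 1L) || any(cyc > tl$horizon_cycles)) {
        stop("surveillance.", arm, ".", item, ": cycles outside 1..horizon", call. = FALSE)
      }
    }
  }
  # Warn (once, at load) about non-monotone local-recurrence inputs: the
  # printed 2-year cumulative exceeds the 5-year one. Under the
  # conditional-residual interpolation the years-2-5 residual risk clamps to 0.
  for (arm in c("WW", "TME")) {
    p2 <- spec$transitions$local_recurrence_2y[[arm]]$mean
    p5 <- spec$transitions$local_recurrence_5y[[arm]]$mean
    if (p5 < p2) {
      warning(sprintf(
        "%s local recurrence: non-monotone cumulative inputs (5-year %.3g < 2-year %.3g)",
        arm, p5, p2), call. = FALSE)
    }
  }
  invisible(spec)
}

#' Load a packaged base-case model specification
#'
#' Returns the packaged parameter set for one of the two comparisons,
#' reproducing every row of the base-case transition-probability, utility and
#' cost tables.
#'
#' @param comparison `"WW_vs_APR"` or `"WW_vs_LAR"`.
#' @return A validated `wwcea_spec`.
#' @examples
#' spec <- base_case_spec("WW_vs_APR")
#' spec$costs$surgery_apr$mean
#' @export
base_case_spec <- function(comparison = c("WW_vs_APR", "WW_vs_LAR")) {
  comparison <- match.arg(comparison)
  file <- paste0("base_case_", tolower(comparison), ".yaml")
  path <- system.file("extdata", file, package = "wwcea")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  suppressWarnings(load_spec(path))
}

#' Serialize a model specification back to YAML
#'
#' Writes a YAML document that [load_spec()] parses back to an equal spec
#' (round-trip property). The life table is written as a file reference, not
#' inlined.
#'
#' @param spec A `wwcea_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "wwcea_spec"))
  doc <- list(
    comparison = spec$comparison,
    timeline = spec$timeline,
    transitions = spec$transitions,
    utilities = spec$utilities,
    costs = spec$costs,
    surveillance = spec$surveillance,
    life_table = spec$life_table_file
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Surgical arm of a comparison
#'
#' @param spec A `wwcea_spec`.
#' @return `"APR"` or `"LAR"`.
#' @export
surgery_type <- function(spec) {
  if (identical(spec$comparison, "WW_vs_APR")) "APR" else "LAR"
}

# Dotted-path access to a parameter node, e.g. "transitions.local_recurrence_2y.WW"
# or "utilities.longterm_apr". The virtual path "natural_mortality_monthly"
# addresses the constant monthly background-mortality override.
.param_path <- function(spec, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- spec
  for (p in parts) {
    node <- node[[p]]
    if (is.null(node)) stop("unknown parameter path: ", path, call. = FALSE)
  }
  node
}

#' Read a parameter by dotted path
#' @param spec A `wwcea_spec`.
#' @param path Dotted path such as `"transitions.local_recurrence_2y.WW"`.
#' @return The parameter (list with `mean`, `sd`, `family`, `source`).
#' @export
get_param <- function(spec, path) {
  node <- .param_path(spec, path)
  if (!.is_param(node)) stop("path does not address a parameter: ", path, call. = FALSE)
  node
}

#' Set a parameter's mean by dotted path
#'
#' Used by the one-way sensitivity analysis. The virtual path
#' `"natural_mortality_monthly"` overrides the life-table lookup with a
#' constant monthly probability.
#'
#' @param spec A `wwcea_spec`.
#' @param path Dotted parameter path (see [get_param()]).
#' @param value New mean.
#' @param validate Re-run [validate_spec()] (default `TRUE`).
#' @return The modified spec.
#' @export
set_param <- function(spec, path, value, validate = TRUE) {
  if (identical(path, "natural_mortality_monthly")) {
    if (value < 0 || value > 1) stop("natural_mortality_monthly outside [0, 1]", call. = FALSE)
    spec$overrides$natural_mortality_monthly <- value
    return(spec)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- get_param(spec, path)  # errors on bad path
  node$mean <- value
  spec[[parts]] <- node
  if (validate) validate_spec(spec)
  spec
}

# Enumerate every sampled (non-fixed) parameter leaf as dotted paths.
sampled_param_paths <- function(spec) {
  out <- character(0)
  for (sec in c("transitions", "utilities", "costs")) {
    for (nm in names(spec[[sec]])) {
      node <- spec[[sec]][[nm]]
      if (.is_param(node)) {
        if (node$family != "fixed") out <- c(out, paste(sec, nm, sep = "."))
      } else {
        for (arm in names(node)) {
          if (node[[arm]]$family != "fixed") {
            out <- c(out, paste(sec, nm, arm, sep = "."))
          }
        }
      }
    }
  }
  out
}

#' @export
print.wwcea_spec <- function(x, ...) {
  cat("<wwcea_spec> ", x$comparison, "\n", sep = "")
  cat("  horizon: ", x$timeline$horizon_cycles, " monthly cycles, ",
      "discount ", 100 * x$timeline$annual_discount_rate, "%/yr, WTP $",
      format(x$timeline$wtp_threshold, big.mark = ","), "/QALY\n", sep = "")
  cat("  parameters: ", length(sampled_param_paths(x)), " sampled, baseline age ",
      x$timeline$baseline_age_years, "\n", sep = "")
  invisible(x)
}
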