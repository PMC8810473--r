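#' @title Report generation
#' @description Paper-parity report drivers: base-case outcome and
#'   cost-effectiveness tables, the one-way sensitivity table, and the
#'   probabilistic sensitivity analysis exports, each with a reproducibility
#'   manifest.
#' @name reporting
#' @keywords internal
NULL

collect_warnings <- function(expr) {
  warnings <- character(0)
  value <- withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warnings)
}

write_manifest <- function(path, command, args, warnings) {
  manifest <- list(
    command = command,
    arguments = args,
    package = "wwcea",
    version = as.character(utils::packageVersion("wwcea")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the base-case microsimulation and write its report tables
#'
#' Simulates both arms, writes a five-year outcome table (recurrence and
#' mortality proportions, in percent), a cost-effectiveness table (per-arm
#' discounted cost and QALYs, incrementals versus WW, ICER or dominance), and
#' a run manifest.
#'
#' @param comparison `"WW_vs_APR"` or `"WW_vs_LAR"`.
#' @param n Patients per arm.
#' @param seed Master seed.
#' @param outdir Output directory (created if missing); `NULL` skips writing.
#' @param spec Optional spec overriding the packaged base case.
#' @return Invisibly, a list with the two tables, both microsimulation
#'   results, and the [compare()] result.
#' @export
run_base_case <- function(comparison = c("WW_vs_APR", "WW_vs_LAR"),
                          n = NULL, seed = 1L, outdir = "results", spec = NULL) {
  comparison <- match.arg(comparison)
  cw <- collect_warnings({
    spec <- spec %||% base_case_spec(comparison)
    n <- n %||% spec$timeline$cohort_size
    surg_label <- surgery_type(spec)
    ww <- simulate_cohort(spec, "WW", n = n, seed = seed)
    sg <- simulate_cohort(spec, "SURGERY", n = n, seed = seed + 1L)
    cmp <- compare(sg, ww, wtp = spec$timeline$wtp_threshold)
    pct <- function(x) round(100 * x, 2)
    outcomes <- tibble::tibble(
      outcome = c("Local regrowth (during the WW period)",
                  "Local recurrence (following first operation)",
                  "Distant only", "Local and distant",
                  "Overall 5-year mortality", "Cancer-specific 5-year mortality"),
      !!surg_label := pct(c(NA, sg$proportions$local_recurrence_post_op,
                            sg$proportions$distant_only,
                            sg$proportions$local_and_distant,
                            sg$proportions$overall_5y_mortality,
                            sg$proportions$cancer_specific_5y_mortality)),
      WW = pct(c(ww$proportions$regrowth_during_ww,
                 ww$proportions$local_recurrence_post_op,
                 ww$proportions$distant_only, ww$proportions$local_and_distant,
                 ww$proportions$overall_5y_mortality,
                 ww$proportions$cancer_specific_5y_mortality))
    )
    icer_label <- if (cmp$classification == "B_dominates") "Dominated"
      else if (is.na(cmp$icer)) cmp$classification
      else sprintf("%.2f", cmp$icer)
    cea_table <- tibble::tibble(
      metric = c("Cost", "Effectiveness (QALY)", "Incremental cost (vs. WW)",
                 "Incremental effectiveness (vs. WW)", "ICER ($/QALY)"),
      !!surg_label := c(sprintf("%.2f", sg$mean_cost),
                        sprintf("%.4f", sg$mean_qalys),
                        sprintf("%.2f", cmp$incremental_cost),
                        sprintf("%.4f", cmp$incremental_effect), icer_label),
      WW = c(sprintf("%.2f", ww$mean_cost), sprintf("%.4f", ww$mean_qalys),
             "", "", "")
    )
    list(outcomes = outcomes, cea_table = cea_table, ww = ww, surgery = sg,
         comparison_result = cmp)
  })
  out <- cw$value
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stem <- tolower(comparison)
    utils::write.csv(out$outcomes, file.path(outdir, paste0("base_case_outcomes_", stem, ".csv")),
                     row.names = FALSE)
    utils::write.csv(out$cea_table, file.path(outdir, paste0("base_case_cea_", stem, ".csv")),
                     row.names = FALSE)
    write_manifest(file.path(outdir, paste0("base_case_manifest_", stem, ".json")),
                   "run_base_case",
                   list(comparison = comparison, n = n, seed = seed,
                        wtp = spec$timeline$wtp_threshold),
                   cw$warnings)
  }
  invisible(out)
}

#' Default one-way sensitivity sweep ranges
#'
#' Probability and utility rows ship as a packaged fixture (per-row sweep
#' ranges, with cumulative-probability uppers capped at 0.999 because a
#' cumulative 1 implies an infinite monthly hazard); cost rows are generated
#' as 5%-195% of the base value.
#'
#' @param spec A validated `wwcea_spec`.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
default_dsa_ranges <- function(spec) {
  path <- system.file("extdata", "dsa_ranges.csv", package = "wwcea")
  ranges <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  surg <- surgery_type(spec)
  ranges <- ranges[ranges$comparison %in% c("ALL", surg), c("parameter", "lower", "upper")]
  cost_paths <- grep("^costs\\.", sampled_param_paths(spec), value = TRUE)
  costs <- tibble::tibble(
    parameter = cost_paths,
    lower = vapply(cost_paths, function(p) 0.05 * get_param(spec, p)$mean,
                   numeric(1), USE.NAMES = FALSE),
    upper = vapply(cost_paths, function(p) 1.95 * get_param(spec, p)$mean,
                   numeric(1), USE.NAMES = FALSE)
  )
  dplyr::bind_rows(ranges, costs)
}

#' Run the full one-way deterministic sensitivity analysis
#'
#' Sweeps every parameter in [default_dsa_ranges()] (or a custom subset) with
#' the deterministic cohort evaluator and writes one row per parameter: range,
#' classification bands, and the threshold above which surgery becomes cost
#' effective ("remains dominated" rows have none).
#'
#' @param comparison `"WW_vs_APR"` or `"WW_vs_LAR"`.
#' @param ranges Optional tibble `parameter, lower, upper`.
#' @param outdir Output directory; `NULL` skips writing.
#' @param spec Optional spec overriding the packaged base case.
#' @param n_grid Grid size passed to [one_way()].
#' @return Invisibly, a tibble with one row per swept parameter.
#' @export
run_dsa <- function(comparison = c("WW_vs_APR", "WW_vs_LAR"), ranges = NULL,
                    outdir = "results", spec = NULL, n_grid = 9L) {
  comparison <- match.arg(comparison)
  cw <- collect_warnings({
    spec <- spec %||% base_case_spec(comparison)
    ranges <- ranges %||% default_dsa_ranges(spec)
    rows <- lapply(seq_len(nrow(ranges)), function(i) {
      d <- one_way(spec, ranges$parameter[i], ranges$lower[i], ranges$upper[i],
                   n_grid = n_grid)
      bands_txt <- paste(sprintf("[%.6g, %.6g] %s", d$bands$from, d$bands$to,
                                 d$bands$classification), collapse = "; ")
      thr <- dsa_threshold(d)
      tibble::tibble(
        parameter = ranges$parameter[i], base_value = d$base_value,
        lower = ranges$lower[i], upper = ranges$upper[i],
        bands = bands_txt,
        surgery_cost_effective_above = thr,
        result = if (all(d$bands$classification == "ww_dominates"))
          "Remains dominated" else "Threshold(s) found"
      )
    })
    dplyr::bind_rows(rows)
  })
  tab <- cw$value
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stem <- tolower(comparison)
    utils::write.csv(tab, file.path(outdir, paste0("dsa_", stem, ".csv")),
                     row.names = FALSE)
    write_manifest(file.path(outdir, paste0("dsa_manifest_", stem, ".json")),
                   "run_dsa",
                   list(comparison = comparison, n_parameters = nrow(tab),
                        wtp = spec$timeline$wtp_threshold, n_grid = n_grid),
                   cw$warnings)
  }
  invisible(tab)
}

#' Run the probabilistic sensitivity analysis and write its exports
#'
#' Runs [psa()], writes the per-draw table, the cost-effectiveness
#' acceptability curve over the WTP grid, and a manifest.
#'
#' @param comparison `"WW_vs_APR"` or `"WW_vs_LAR"`.
#' @param n_outer Parameter draws.
#' @param n_inner Patients per inner microsimulation.
#' @param seed Master seed.
#' @param wtp_grid Willingness-to-pay grid (default $0-250,000 by $10,000).
#' @param outdir Output directory; `NULL` skips writing.
#' @param spec Optional spec overriding the packaged base case.
#' @return Invisibly, a list with `draws` and `ceac` tibbles.
#' @export
run_psa <- function(comparison = c("WW_vs_APR", "WW_vs_LAR"), n_outer = NULL,
                    n_inner = NULL, seed = 1L,
                    wtp_grid = seq(0, 250000, by = 10000),
                    outdir = "results", spec = NULL) {
  comparison <- match.arg(comparison)
  cw <- collect_warnings({
    spec <- spec %||% base_case_spec(comparison)
    n_outer <- n_outer %||% spec$timeline$psa_outer_iterations
    n_inner <- n_inner %||% spec$timeline$cohort_size
    draws <- psa(spec, n_outer = n_outer, n_inner = n_inner, master_seed = seed)
    ceac <- acceptability_curve(draws, wtp_grid)
    list(draws = draws, ceac = ceac)
  })
  out <- cw$value
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stem <- tolower(comparison)
    utils::write.csv(out$draws, file.path(outdir, paste0("psa_draws_", stem, ".csv")),
                     row.names = FALSE)
    utils::write.csv(out$ceac, file.path(outdir, paste0("psa_ceac_", stem, ".csv")),
                     row.names = FALSE)
    write_manifest(file.path(outdir, paste0("psa_manifest_", stem, ".json")),
                   "run_psa",
                   list(comparison = comparison, n_outer = n_outer,
                        n_inner = n_inner, seed = seed,
                        wtp_grid = range(wtp_grid)),
                   cw$warnings)
  }
  invisible(out)
}
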