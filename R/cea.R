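#' @title Cost-effectiveness arithmetic
#' @description Incremental cost-effectiveness ratios, dominance
#'   classification, net monetary benefit and acceptability curves.
#' @name cea
#' @keywords internal
NULL

# Accept a microsimulation result, a deterministic-evaluator result, or a
# plain list/vector with cost and QALYs.
as_cost_qaly <- function(x) {
  if (inherits(x, "wwcea_microsim_result")) {
    return(c(cost = x$mean_cost, qalys = x$mean_qalys))
  }
  if (is.list(x)) {
    cost <- x$expected_cost %||% x$cost %||% x$mean_cost
    qalys <- x$expected_qalys %||% x$qalys %||% x$mean_qalys
    if (!is.null(cost) && !is.null(qalys)) return(c(cost = cost, qalys = qalys))
  }
  if (is.numeric(x) && length(x) == 2) return(c(cost = x[[1]], qalys = x[[2]]))
  stop("cannot extract (cost, qalys) from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Compare two strategies
#'
#' Computes incremental cost and effectiveness of strategy `a` relative to
#' strategy `b`, the ICER where defined, the dominance classification, and the
#' preferred strategy by net monetary benefit at the given willingness-to-pay
#' threshold. A strategy dominates when it costs no more and yields no fewer
#' QALYs (strictly better on at least one axis). The ICER is undefined inside
#' dominance quadrants and when incremental effectiveness is zero.
#'
#' @param a,b Strategy results: microsimulation results, deterministic
#'   evaluator results, or `list(cost=, qalys=)`.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @return A `wwcea_cea_result` with costs, QALYs, incrementals, `icer`,
#'   `classification` (`A_dominates`, `B_dominates`, `icer_below_wtp`,
#'   `icer_above_wtp`, `equal`) and `preferred` (`"A"`, `"B"`, `"tie"`).
#' @export
compare <- function(a, b, wtp = 1e5) {
  av <- as_cost_qaly(a); bv <- as_cost_qaly(b)
  dc <- av[["cost"]] - bv[["cost"]]
  de <- av[["qalys"]] - bv[["qalys"]]
  nmb_a <- nmb(av, wtp); nmb_b <- nmb(bv, wtp)
  icer <- NA_real_
  if (dc == 0 && de == 0) {
    classification <- "equal"
  } else if (dc <= 0 && de >= 0) {
    classification <- "A_dominates"
  } else if (dc >= 0 && de <= 0) {
    classification <- "B_dominates"
  } else {
    icer <- dc / de
    classification <- if (icer < wtp) "icer_below_wtp" else "icer_above_wtp"
  }
  preferred <- if (nmb_a > nmb_b) "A" else if (nmb_b > nmb_a) "B" else "tie"
  structure(list(
    cost_a = av[["cost"]], cost_b = bv[["cost"]],
    qaly_a = av[["qalys"]], qaly_b = bv[["qalys"]],
    incremental_cost = dc, incremental_effect = de,
    icer = icer, classification = classification,
    wtp = wtp, nmb_a = nmb_a, nmb_b = nmb_b, preferred = preferred
  ), class = "wwcea_cea_result")
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALYs - cost`; strategies are ranked by NMB at a given
#' willingness-to-pay threshold.
#'
#' @param result A strategy result (see [compare()]).
#' @param wtp Willingness-to-pay threshold, US$/QALY (>= 0).
#' @return Net monetary benefit in US$.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  v <- as_cost_qaly(result)
  wtp * v[["qalys"]] - v[["cost"]]
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic
#' sensitivity analysis iterations in which watch-and-wait has the higher net
#' monetary benefit than surgery.
#'
#' @param psa_draws Tibble from [psa()] with columns `ww_cost`, `ww_qalys`,
#'   `surg_cost`, `surg_qalys`.
#' @param wtp_grid Sorted vector of willingness-to-pay values (default
#'   $0-250,000 in $10,000 steps).
#' @return A tibble with columns `wtp` and `ww_optimal_fraction`.
#' @export
acceptability_curve <- function(psa_draws, wtp_grid = seq(0, 250000, by = 10000)) {
  if (is.null(psa_draws) || nrow(psa_draws) == 0) {
    stop("psa_draws is empty", call. = FALSE)
  }
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be sorted", call. = FALSE)
  frac <- vapply(wtp_grid, function(w) {
    mean(w * psa_draws$ww_qalys - psa_draws$ww_cost >
           w * psa_draws$surg_qalys - psa_draws$surg_cost)
  }, numeric(1))
  tibble::tibble(wtp = wtp_grid, ww_optimal_fraction = frac)
}

#' @export
print.wwcea_cea_result <- function(x, ...) {
  cat("<cost-effectiveness comparison>\n")
  cat(sprintf("  A: $%s, %.3f QALYs   B: $%s, %.3f QALYs\n",
              format(round(x$cost_a, 2), big.mark = ","), x$qaly_a,
              format(round(x$cost_b, 2), big.mark = ","), x$qaly_b))
  cat(sprintf("  incremental (A - B): $%s, %.3f QALYs\n",
              format(round(x$incremental_cost, 2), big.mark = ","),
              x$incremental_effect))
  icer_txt <- if (is.na(x$icer)) "undefined" else
    paste0("$", format(round(x$icer), big.mark = ","), "/QALY")
  cat(sprintf("  ICER: %s; classification: %s; preferred at $%s/QALY: %s\n",
              icer_txt, x$classification,
              format(x$wtp, big.mark = ","), x$preferred))
  invisible(x)
}
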