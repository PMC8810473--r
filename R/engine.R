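#' @title Microsimulation engine
#' @description Patient-level Markov simulation over the six health states
#'   (stable disease, local recurrence with and without salvage, distant
#'   recurrence, combined local and distant recurrence, death), with monthly
#'   cycles, discounted cost and QALY accrual, and a deterministic
#'   cohort-expected-value evaluator over the identical event logic.
#' @name engine
#' @keywords internal
NULL

# State codes shared by the simulator and the oracle.
.STABLE_WW <- 1L; .POSTOP <- 2L; .LOCAL_SALVAGED <- 3L
.LOCAL_UNSALVAGED <- 4L; .DISTANT <- 5L; .LOCAL_AND_DISTANT <- 6L; .DEAD <- 7L

.state_labels <- c("STABLE_WW", "POSTOP_STABLE", "LOCAL_SALVAGED",
                   "LOCAL_UNSALVAGED", "DISTANT", "LOCAL_AND_DISTANT", "DEAD")

#' Precompute all per-cycle model tables
#'
#' Assembles everything one cycle of the model needs: monthly transition
#' probabilities (see [build_schedules()]), discount factors, utility vectors
#' by state clock, recurring-cost vectors by state clock (surveillance
#' calendar, adjuvant chemotherapy window, ostomy care and takedown), and the
#' one-time event costs. Both the stochastic engine and the deterministic
#' evaluator consume this object, so they share the model's substance by
#' construction.
#'
#' @param spec A validated `wwcea_spec`.
#' @return A list of class `wwcea_tables`.
#' @export
build_model_tables <- function(spec) {
  tl <- spec$timeline
  H <- tl$horizon_cycles
  sched <- build_schedules(spec)
  surg <- surgery_type(spec)
  r <- tl$annual_discount_rate
  t_seq <- seq_len(H)
  # Half-cycle correction: recurring accruals at cycle midpoints, one-time
  # event costs at the event-cycle boundary (t = 0 for model entry).
  dhalf <- (1 + r)^(-(t_seq - 0.5) / 12)
  done <- (1 + r)^(-(0:H) / 12)  # index t + 1

  cost_mean <- function(nm) spec$costs[[nm]]$mean
  calendar_cost <- function(arm) {
    v <- numeric(H)
    cal <- spec$surveillance[[arm]]
    for (item in names(cal)) {
      cyc <- cal[[item]][cal[[item]] <= H]
      v[cyc] <- v[cyc] + cost_mean(item)
    }
    v
  }
  chemo_window <- tl$adjuvant_chemo_start_offset_cycles +
    seq_len(tl$adjuvant_chemo_duration_cycles)
  chemo_window <- chemo_window[chemo_window <= H]

  c_stable_ww <- calendar_cost("WW")
  if (tl$ww_adjuvant_chemo) {
    c_stable_ww[chemo_window] <- c_stable_ww[chemo_window] +
      cost_mean("adjuvant_chemo_per_cycle")
  }
  c_postop <- calendar_cost("postop")
  c_postop[chemo_window] <- c_postop[chemo_window] + cost_mean("adjuvant_chemo_per_cycle")
  if (surg == "APR") {
    c_postop <- c_postop + cost_mean("ostomy_care_monthly")
  } else {
    ost <- seq_len(min(tl$lar_ostomy_duration_cycles, H))
    c_postop[ost] <- c_postop[ost] + cost_mean("ostomy_care_monthly")
    kd <- tl$lar_ostomy_duration_cycles
    if (kd <= H) c_postop[kd] <- c_postop[kd] + cost_mean("ostomy_takedown")
  }

  # Utility by cycles-since-entry into the post-operative stable state. The
  # acute window after the initial resection uses the early post-operative
  # utility; after salvage resection it uses the salvage disutility state.
  longterm <- function(k) {
    if (surg == "APR") {
      rep(spec$utilities$longterm_apr$mean, length(k))
    } else {
      ifelse(k <= tl$lar_ostomy_duration_cycles,
             spec$utilities$longterm_lar_with_ostomy$mean,
             spec$utilities$longterm_lar_without_ostomy$mean)
    }
  }
  k_seq <- seq_len(H)
  rec <- k_seq <= tl$postop_recovery_cycles
  u_postop_initial <- ifelse(rec, spec$utilities$initial_postop$mean, longterm(k_seq))
  u_postop_salvage <- ifelse(rec, spec$utilities$salvage_tme_disutility_state$mean,
                             longterm(k_seq))

  structure(list(
    horizon = H, sched = sched, surgery = surg,
    dhalf = dhalf, done = done,
    u_stable_ww = spec$utilities$initial_ww$mean,
    u_postop_initial = u_postop_initial,
    u_postop_salvage = u_postop_salvage,
    u_local = spec$utilities$local_recurrence$mean,
    u_distant = spec$utilities$distant_recurrence$mean,
    u_lad = spec$utilities$local_and_distant$mean,
    c_stable_ww = c_stable_ww,
    c_postop = c_postop,
    c_local_salvaged = 0,
    c_local_unsalvaged = cost_mean("palliative_capecitabine_per_cycle"),
    c_distant = cost_mean("palliative_mfolfox6_per_cycle"),
    c_lad = cost_mean("palliative_mfolfox6_per_cycle"),
    c_surgery = cost_mean(paste0("surgery_", tolower(surg))),
    c_restage_local = cost_mean("restaging_local"),
    c_restage_distant = cost_mean("restaging_distant"),
    c_reirradiation = cost_mean("reirradiation_course"),
    c_death_periop = cost_mean("death_perioperative"),
    c_death_cancer = cost_mean("death_cancer"),
    c_death_natural = cost_mean("death_noncancer")
  ), class = "wwcea_tables")
}

#' Simulate a cohort of patients
#'
#' Runs the patient-level Markov simulation for one treatment arm. All
#' patients are simulated in lockstep: each cycle draws a fixed block of
#' uniform random numbers (one row per patient), so results are
#' bit-reproducible for identical `(spec, arm, n, seed)` and patient `i`'s
#' path depends only on row `i` of the blocks.
#'
#' Within-cycle event order: natural death, then cancer (or perioperative)
#' death, then progression draws, then accrual in the post-transition state.
#' Recurring costs and utilities accrue at cycle midpoints (half-cycle
#' correction); one-time transition costs at the event cycle.
#'
#' @param spec A validated `wwcea_spec`.
#' @param arm `"WW"` or `"SURGERY"`.
#' @param n Number of patients.
#' @param seed Master seed (integer).
#' @param keep_patients Also return the per-patient cost/QALY/flag table.
#' @param keep_history Also return the n x horizon state-code matrix.
#' @return A `wwcea_microsim_result`: mean discounted cost and QALYs,
#'   outcome proportions (local regrowth during surveillance, post-operative
#'   local recurrence, distant-only recurrence, combined recurrence, overall
#'   and cancer-specific 5-year mortality), `n`, `seed`, `arm`.
#' @export
simulate_cohort <- function(spec, arm = c("WW", "SURGERY"), n = spec$timeline$cohort_size,
                            seed = 1L, keep_patients = FALSE, keep_history = FALSE) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  tb <- build_model_tables(spec)
  sc <- tb$sched
  H <- tb$horizon

  set.seed(as.integer(seed))
  state <- integer(n)
  entry <- integer(n)          # cycle of entry into the current state
  kind <- integer(n)           # post-op context: 1 initial resection, 2 salvage
  cost <- numeric(n)
  qaly <- numeric(n)
  death_cause <- integer(n)    # 0 none, 1 perioperative, 2 cancer, 3 natural
  death_cycle <- rep(NA_integer_, n)
  f_regrowth <- logical(n); f_local_postop <- logical(n)
  f_distant <- logical(n); f_lad <- logical(n); f_salvage <- logical(n)
  history <- if (keep_history) matrix(NA_integer_, n, H) else NULL

  if (arm == "WW") {
    state[] <- .STABLE_WW
  } else {
    # Entry: resection cost for everyone, then the one-time perioperative
    # death draw; survivors start the post-operative stable state at cycle 0.
    cost <- cost + tb$c_surgery
    u0 <- stats::runif(n)
    dies <- u0 < sc$p_periop
    state[dies] <- .DEAD
    death_cause[dies] <- 1L
    death_cycle[dies] <- 0L
    cost[dies] <- cost[dies] + tb$c_death_periop
    state[!dies] <- .POSTOP
    kind[!dies] <- 1L
  }

  for (t in seq_len(H)) {
    u_nat <- stats::runif(n); u_can <- stats::runif(n)
    u_loc <- stats::runif(n); u_cd <- stats::runif(n)
    u_sal <- stats::runif(n); u_pd <- stats::runif(n)
    u_dis <- stats::runif(n); u_cl <- stats::runif(n)
    d1 <- tb$done[t + 1L]

    alive <- state != .DEAD
    # (1) background mortality
    i <- alive & u_nat < sc$q_nat[t]
    if (any(i)) {
      state[i] <- .DEAD; death_cause[i] <- 3L; death_cycle[i] <- t
      cost[i] <- cost[i] + tb$c_death_natural * d1
    }
    # (2) cancer mortality in recurrence states
    m_state <- c(NA, NA, sc$m_local_salvaged, sc$m_local_unsalvaged,
                 sc$m_distant, sc$m_local_and_distant, NA)
    i <- state %in% c(.LOCAL_SALVAGED, .LOCAL_UNSALVAGED, .DISTANT, .LOCAL_AND_DISTANT) &
      u_can < m_state[state]
    if (any(i)) {
      state[i] <- .DEAD; death_cause[i] <- 2L; death_cycle[i] <- t
      cost[i] <- cost[i] + tb$c_death_cancer * d1
    }
    # (3) progression from the watch-and-wait stable state
    sww <- state == .STABLE_WW
    if (any(sww)) {
      locev <- sww & u_loc < sc$h_local_ww[t]
      if (any(locev)) {
        f_regrowth[locev] <- TRUE
        cost[locev] <- cost[locev] + tb$c_restage_local * d1
        conc <- locev & u_cd < sc$p_conc_distant
        state[conc] <- .LOCAL_AND_DISTANT; entry[conc] <- t; f_lad[conc] <- TRUE
        cost[conc] <- cost[conc] + tb$c_restage_distant * d1
        salv <- locev & !conc & u_sal < sc$p_salvage_ww
        if (any(salv)) {
          f_salvage[salv] <- TRUE
          cost[salv] <- cost[salv] + tb$c_surgery * d1
          pd <- salv & u_pd < sc$p_periop
          state[pd] <- .DEAD; death_cause[pd] <- 1L; death_cycle[pd] <- t
          cost[pd] <- cost[pd] + tb$c_death_periop * d1
          ok <- salv & !pd
          state[ok] <- .POSTOP; entry[ok] <- t; kind[ok] <- 2L
        }
        uns <- locev & !conc & !(u_sal < sc$p_salvage_ww)
        state[uns] <- .LOCAL_UNSALVAGED; entry[uns] <- t
      }
      distev <- sww & !locev & u_dis < sc$h_distant_ww
      if (any(distev)) {
        f_distant[distev] <- TRUE
        cost[distev] <- cost[distev] + tb$c_restage_distant * d1
        concl <- distev & u_cl < sc$p_conc_local
        state[concl] <- .LOCAL_AND_DISTANT; entry[concl] <- t; f_lad[concl] <- TRUE
        cost[concl] <- cost[concl] + tb$c_restage_local * d1
        state[distev & !concl] <- .DISTANT; entry[distev & !concl] <- t
      }
    }
    # (4) progression from the post-operative stable state
    po <- state == .POSTOP & entry < t   # exclude patients who entered this cycle
    if (any(po)) {
      k <- t - entry
      locev <- po & u_loc < sc$h_local_tme[ifelse(po, k, 1L)]
      if (any(locev)) {
        f_local_postop[locev] <- TRUE
        cost[locev] <- cost[locev] + tb$c_restage_local * d1
        conc <- locev & u_cd < sc$p_conc_distant
        state[conc] <- .LOCAL_AND_DISTANT; entry[conc] <- t; f_lad[conc] <- TRUE
        cost[conc] <- cost[conc] + tb$c_restage_distant * d1
        salv <- locev & !conc & u_sal < sc$p_salvage_tme
        if (any(salv)) {
          f_salvage[salv] <- TRUE
          cost[salv] <- cost[salv] + (tb$c_surgery + tb$c_reirradiation) * d1
          pd <- salv & u_pd < sc$p_periop
          state[pd] <- .DEAD; death_cause[pd] <- 1L; death_cycle[pd] <- t
          cost[pd] <- cost[pd] + tb$c_death_periop * d1
          ok <- salv & !pd
          state[ok] <- .LOCAL_SALVAGED; entry[ok] <- t
        }
        uns <- locev & !conc & !(u_sal < sc$p_salvage_tme)
        state[uns] <- .LOCAL_UNSALVAGED; entry[uns] <- t
      }
      distev <- po & !locev & u_dis < sc$h_distant_tme
      if (any(distev)) {
        f_distant[distev] <- TRUE
        cost[distev] <- cost[distev] + tb$c_restage_distant * d1
        concl <- distev & u_cl < sc$p_conc_local
        state[concl] <- .LOCAL_AND_DISTANT; entry[concl] <- t; f_lad[concl] <- TRUE
        cost[concl] <- cost[concl] + tb$c_restage_local * d1
        state[distev & !concl] <- .DISTANT; entry[distev & !concl] <- t
      }
    }
    # (5) distant progression while in a local-recurrence state
    lc <- (state == .LOCAL_SALVAGED | state == .LOCAL_UNSALVAGED) & entry < t
    i <- lc & u_dis < sc$h_distant_after_local
    if (any(i)) {
      f_distant[i] <- TRUE; f_lad[i] <- TRUE
      cost[i] <- cost[i] + tb$c_restage_distant * d1
      state[i] <- .LOCAL_AND_DISTANT; entry[i] <- t
    }
    # (6) accrual in the post-transition state, mid-cycle discounted
    alive <- state != .DEAD
    if (any(alive)) {
      k <- pmax(t - entry, 1L)
      u <- numeric(n); cc <- numeric(n)
      g <- alive & state == .STABLE_WW
      u[g] <- tb$u_stable_ww; cc[g] <- tb$c_stable_ww[t]
      g <- alive & state == .POSTOP
      if (any(g)) {
        gi <- g & kind == 1L; gs <- g & kind == 2L
        u[gi] <- tb$u_postop_initial[k[gi]]; u[gs] <- tb$u_postop_salvage[k[gs]]
        cc[g] <- tb$c_postop[k[g]]
      }
      g <- alive & state == .LOCAL_SALVAGED
      u[g] <- tb$u_local; cc[g] <- tb$c_local_salvaged
      g <- alive & state == .LOCAL_UNSALVAGED
      u[g] <- tb$u_local; cc[g] <- tb$c_local_unsalvaged
      g <- alive & state == .DISTANT
      u[g] <- tb$u_distant; cc[g] <- tb$c_distant
      g <- alive & state == .LOCAL_AND_DISTANT
      u[g] <- tb$u_lad; cc[g] <- tb$c_lad
      qaly[alive] <- qaly[alive] + u[alive] / 12 * tb$dhalf[t]
      cost[alive] <- cost[alive] + cc[alive] * tb$dhalf[t]
    }
    if (keep_history) history[, t] <- state
  }

  dead <- state == .DEAD
  res <- structure(list(
    mean_cost = mean(cost),
    mean_qalys = mean(qaly),
    proportions = list(
      regrowth_during_ww = if (arm == "WW") mean(f_regrowth) else NA_real_,
      local_recurrence_post_op = mean(f_local_postop),
      distant_only = mean(f_distant & !f_lad),
      local_and_distant = mean(f_lad),
      overall_5y_mortality = mean(dead),
      cancer_specific_5y_mortality = mean(death_cause == 2L)
    ),
    n_patients = n, seed = as.integer(seed), arm = arm,
    comparison = spec$comparison
  ), class = "wwcea_microsim_result")
  if (keep_patients) {
    res$patients <- tibble::tibble(
      patient = seq_len(n), cost = cost, qalys = qaly,
      death_cause = c("none", "perioperative", "cancer", "natural")[death_cause + 1L],
      death_cycle = death_cycle,
      regrowth_during_ww = f_regrowth, salvage_received = f_salvage,
      local_recurrence_post_op = f_local_postop,
      distant_recurrence = f_distant, combined_recurrence = f_lad
    )
  }
  if (keep_history) res$history <- history
  res
}

#' Simulate a single patient trajectory
#'
#' Runs the engine for one patient and returns the trajectory: the health
#' state occupied at every cycle, discounted accruals, death cause, and event
#' flags. Identical `(spec, arm, seed)` reproduce the trajectory exactly.
#'
#' @inheritParams simulate_cohort
#' @return A `wwcea_trajectory`: `states` tibble (cycle, state), discounted
#'   cost and QALYs, `death_cause`, and logical event flags.
#' @export
simulate_patient <- function(spec, arm = c("WW", "SURGERY"), seed = 1L) {
  arm <- match.arg(arm)
  res <- simulate_cohort(spec, arm, n = 1L, seed = seed,
                         keep_patients = TRUE, keep_history = TRUE)
  p <- res$patients[1, ]
  structure(list(
    states = tibble::tibble(
      cycle = seq_len(ncol(res$history)),
      state = .state_labels[res$history[1, ]]
    ),
    discounted_cost = p$cost,
    discounted_qalys = p$qalys,
    death_cause = p$death_cause,
    death_cycle = p$death_cycle,
    regrowth_during_ww = p$regrowth_during_ww,
    salvage_received = p$salvage_received,
    local_recurrence_post_op = p$local_recurrence_post_op,
    distant_recurrence = p$distant_recurrence,
    combined_recurrence = p$combined_recurrence,
    arm = arm, seed = as.integer(seed)
  ), class = "wwcea_trajectory")
}

#' @export
print.wwcea_microsim_result <- function(x, ...) {
  cat(sprintf("<microsimulation> %s arm, %s, n = %d, seed = %d\n",
              x$arm, x$comparison, x$n_patients, x$seed))
  cat(sprintf("  mean discounted cost:  $%s\n",
              format(round(x$mean_cost, 2), big.mark = ",")))
  cat(sprintf("  mean discounted QALYs: %.3f\n", x$mean_qalys))
  cat(sprintf("  5-year mortality: %.1f%% overall, %.1f%% cancer-specific\n",
              100 * x$proportions$overall_5y_mortality,
              100 * x$proportions$cancer_specific_5y_mortality))
  invisible(x)
}

#' Deterministic cohort expected value
#'
#' Propagates state-occupancy probabilities forward through the identical
#' per-cycle event logic, schedules and accrual rules as [simulate_cohort()],
#' yielding exact expected discounted cost and QALYs (the post-operative
#' stable state is expanded by entry cycle because its schedules depend on the
#' state clock). Serves as the noise-free evaluator for sensitivity analyses
#' and as the oracle against which the stochastic engine is verified.
#'
#' @inheritParams simulate_cohort
#' @return A list: `expected_cost`, `expected_qalys`, and `occupancy`, a
#'   tibble of state-occupancy probabilities by cycle.
#' @export
cohort_expected_value <- function(spec, arm = c("WW", "SURGERY")) {
  arm <- match.arg(arm)
  tb <- build_model_tables(spec)
  sc <- tb$sched
  H <- tb$horizon

  p_sww <- 0; p_po_init <- 0
  p_po_salv <- numeric(H)   # indexed by entry cycle e = 1..H
  p_ls <- 0; p_lu <- 0; p_d <- 0; p_lad <- 0; p_dead <- 0
  ecost <- 0; eqaly <- 0
  occ <- matrix(0, H, length(.state_labels),
                dimnames = list(NULL, .state_labels))

  if (arm == "WW") {
    p_sww <- 1
  } else {
    ecost <- ecost + tb$c_surgery
    p_dead <- sc$p_periop
    ecost <- ecost + sc$p_periop * tb$c_death_periop
    p_po_init <- 1 - sc$p_periop
  }

  # Splits the mass leaving a stable state on a local-recurrence event into
  # its destinations, returning flows and accruing one-time costs.
  for (t in seq_len(H)) {
    d1 <- tb$done[t + 1L]
    q <- sc$q_nat[t]

    # (1) background mortality on every alive mass
    masses <- c(p_sww, p_po_init, sum(p_po_salv), p_ls, p_lu, p_d, p_lad)
    nat_flow <- q * sum(masses)
    ecost <- ecost + nat_flow * tb$c_death_natural * d1
    p_dead <- p_dead + nat_flow
    p_sww <- p_sww * (1 - q); p_po_init <- p_po_init * (1 - q)
    p_po_salv <- p_po_salv * (1 - q)
    p_ls <- p_ls * (1 - q); p_lu <- p_lu * (1 - q)
    p_d <- p_d * (1 - q); p_lad <- p_lad * (1 - q)

    # (2) cancer mortality in recurrence states
    can_flow <- p_ls * sc$m_local_salvaged + p_lu * sc$m_local_unsalvaged +
      p_d * sc$m_distant + p_lad * sc$m_local_and_distant
    ecost <- ecost + can_flow * tb$c_death_cancer * d1
    p_dead <- p_dead + can_flow
    p_ls <- p_ls * (1 - sc$m_local_salvaged)
    p_lu <- p_lu * (1 - sc$m_local_unsalvaged)
    p_d <- p_d * (1 - sc$m_distant)
    p_lad <- p_lad * (1 - sc$m_local_and_distant)

    new_po_salv_entry <- 0; new_ls <- 0; new_lu <- 0; new_d <- 0; new_lad <- 0

    progress_stable <- function(mass, h_local, h_distant, p_salvage, salvaged_to_ls) {
      # returns c(stay, to_po_or_ls, to_lu, to_d, to_lad, to_dead_periop)
      # and accrues one-time costs via <<-.
      loc <- mass * h_local
      if (loc > 0) ecost <<- ecost + loc * tb$c_restage_local * d1
      conc <- loc * sc$p_conc_distant
      if (conc > 0) ecost <<- ecost + conc * tb$c_restage_distant * d1
      salv <- (loc - conc) * p_salvage
      if (salv > 0) {
        extra <- if (salvaged_to_ls) tb$c_reirradiation else 0
        ecost <<- ecost + salv * (tb$c_surgery + extra) * d1
        ecost <<- ecost + salv * sc$p_periop * tb$c_death_periop * d1
      }
      pd <- salv * sc$p_periop
      uns <- (loc - conc) * (1 - p_salvage)
      nonloc <- mass * (1 - h_local)
      dist <- nonloc * h_distant
      if (dist > 0) ecost <<- ecost + dist * tb$c_restage_distant * d1
      concl <- dist * sc$p_conc_local
      if (concl > 0) ecost <<- ecost + concl * tb$c_restage_local * d1
      c(stay = nonloc - dist, salvaged = salv - pd, unsalvaged = uns,
        distant = dist - concl, lad = conc + concl, dead = pd)
    }

    # (3) watch-and-wait stable state (state clock equals model clock)
    if (p_sww > 0) {
      fl <- progress_stable(p_sww, sc$h_local_ww[t], sc$h_distant_ww,
                            sc$p_salvage_ww, salvaged_to_ls = FALSE)
      p_sww <- fl[["stay"]]
      new_po_salv_entry <- new_po_salv_entry + fl[["salvaged"]]
      new_lu <- new_lu + fl[["unsalvaged"]]
      new_d <- new_d + fl[["distant"]]
      new_lad <- new_lad + fl[["lad"]]
      p_dead <- p_dead + fl[["dead"]]
    }
    # (4) post-operative stable states, by entry cycle (clock k = t - e)
    po_masses <- c(init = p_po_init, stats::setNames(p_po_salv, seq_len(H)))
    for (nm in names(po_masses)) {
      mass <- po_masses[[nm]]
      if (mass <= 0) next
      e <- if (nm == "init") 0L else as.integer(nm)
      if (e >= t) next  # entered this cycle; first draws next cycle
      k <- t - e
      fl <- progress_stable(mass, sc$h_local_tme[k], sc$h_distant_tme,
                            sc$p_salvage_tme, salvaged_to_ls = TRUE)
      if (nm == "init") p_po_init <- fl[["stay"]] else p_po_salv[e] <- fl[["stay"]]
      new_ls <- new_ls + fl[["salvaged"]]
      new_lu <- new_lu + fl[["unsalvaged"]]
      new_d <- new_d + fl[["distant"]]
      new_lad <- new_lad + fl[["lad"]]
      p_dead <- p_dead + fl[["dead"]]
    }
    # (5) distant progression from local-recurrence states
    h <- sc$h_distant_after_local
    flow <- (p_ls + p_lu) * h
    if (flow > 0) ecost <- ecost + flow * tb$c_restage_distant * d1
    p_ls <- p_ls * (1 - h); p_lu <- p_lu * (1 - h)
    new_lad <- new_lad + flow

    p_po_salv[t] <- p_po_salv[t] + new_po_salv_entry
    p_ls <- p_ls + new_ls; p_lu <- p_lu + new_lu
    p_d <- p_d + new_d; p_lad <- p_lad + new_lad

    # (6) accrual in post-transition states
    k_po <- t - seq_len(H)  # clock for each salvage-entry bucket
    valid <- k_po >= 1
    u_po_salv <- sum(p_po_salv[valid] * tb$u_postop_salvage[k_po[valid]])
    c_po_salv <- sum(p_po_salv[valid] * tb$c_postop[k_po[valid]])
    # entries made this cycle (k = 0) accrue their first cycle now, clock 1?
    # No: a patient entering at t accrues in the new state during cycle t with
    # clock k = t - entry = 0 in the simulator's pmax(., 1). Mirror that:
    just <- p_po_salv[t]
    u_po_salv <- u_po_salv + just * tb$u_postop_salvage[1L]
    c_po_salv <- c_po_salv + just * tb$c_postop[1L]

    eq <- p_sww * tb$u_stable_ww +
      p_po_init * tb$u_postop_initial[max(t, 1L)] +
      u_po_salv +
      (p_ls + p_lu) * tb$u_local + p_d * tb$u_distant + p_lad * tb$u_lad
    ec <- p_sww * tb$c_stable_ww[t] +
      p_po_init * tb$c_postop[max(t, 1L)] +
      c_po_salv +
      p_ls * tb$c_local_salvaged + p_lu * tb$c_local_unsalvaged +
      p_d * tb$c_distant + p_lad * tb$c_lad
    eqaly <- eqaly + eq / 12 * tb$dhalf[t]
    ecost <- ecost + ec * tb$dhalf[t]

    occ[t, ] <- c(p_sww, p_po_init + sum(p_po_salv), p_ls, p_lu, p_d, p_lad, p_dead)
  }

  list(
    expected_cost = ecost,
    expected_qalys = eqaly,
    occupancy = tibble::as_tibble(cbind(cycle = seq_len(H), as.data.frame(occ))),
    arm = arm
  )
}
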