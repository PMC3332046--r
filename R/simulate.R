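# ---- scenario specification -------------------------------------------------

.scenarios <- c("PRIMARY", "SCREEN_ALL", "SCREEN_APOE4")

#' Define a simulation scenario
#'
#' `PRIMARY` models 70-year-old memory-clinic patients consulting for
#' cognitive-impairment symptoms, tested once over a three-year horizon.
#' `SCREEN_ALL` and `SCREEN_APOE4` model systematic screening of 60-year-old
#' individuals (population-wide, or restricted to ApoE4 carriers with
#' doubled incidence) over fifteen years with rescreening every five years;
#' both screening scenarios presuppose that the early-stage drug T exists.
#' Horizon and rescreening interval live in the parameter document
#' (`econ.horizon`, `econ.rescreen_interval`) so they can be swept.
#'
#' @param kind `"PRIMARY"`, `"SCREEN_ALL"` or `"SCREEN_APOE4"`.
#' @param treatment_T_enabled is the hypothetical early-stage drug
#'   available? Defaults to `FALSE` for the memory-clinic scenario and
#'   `TRUE` for screening.
#' @param entry_age cohort age at entry (years).
#' @export
scenario_spec <- function(kind = "PRIMARY",
                          treatment_T_enabled = kind != "PRIMARY",
                          entry_age = if (kind == "PRIMARY") 70 else 60) {
  kind <- match.arg(kind, .scenarios)
  structure(list(kind = kind,
                 treatment_T_enabled = treatment_T_enabled,
                 entry_age = entry_age,
                 has_early = kind != "PRIMARY"),
            class = "adcea_scenario")
}

#' Initial true-stage distribution of the cohort
#'
#' Memory-clinic cohort: the AD prevalence among consulters split over
#' mild/moderate/severe. Screening cohort: total AD prevalence (including
#' asymptomatic early AD) partitioned so that early-stage prevalence is a
#' fixed ratio of mild-stage prevalence and the symptomatic stages keep
#' their relative split. Everyone starts at home, undetected.
#'
#' @param p a `ParameterSet`.
#' @param s a [scenario_spec()].
#' @return named probability vector over true stages.
#' @export
initial_distribution <- function(p, s) {
  epi <- p$epidemiology
  split <- epi$primary_stage_split
  if (s$kind == "PRIMARY") {
    prev <- epi$primary_prevalence
    c(NO_AD = 1 - prev,
      MILD = prev * split$mild,
      MODERATE = prev * split$moderate,
      SEVERE = prev * split$severe)
  } else {
    prev <- epi$screen_prevalence
    rho <- epi$early_to_mild_ratio
    rel <- c(EARLY = rho,
             MILD = 1,
             MODERATE = split$moderate / split$mild,
             SEVERE = split$severe / split$mild)
    mass <- prev * rel / sum(rel)
    c(NO_AD = 1 - prev, mass)
  }
}

#' Cycle indices at which scheduled screenings occur
#'
#' @param s a screening [scenario_spec()].
#' @param p a `ParameterSet` (supplies `econ.horizon` and
#'   `econ.rescreen_interval`).
#' @return integer vector of cycle indices, starting at 0.
#' @export
schedule_screens <- function(s, p) {
  if (s$kind == "PRIMARY")
    stop("the memory-clinic scenario tests once, at entry", call. = FALSE)
  n_cycles <- round(p$econ$horizon / p$econ$cycle_length)
  step <- round(p$econ$rescreen_interval / p$econ$cycle_length)
  seq(0L, max(n_cycles - 1L, 0L), by = step)
}

# ---- cohort evolution -------------------------------------------------------

# map a classification data frame onto the state space (everyone at HOME)
classification_to_occupancy <- function(cls, states) {
  occ <- stats::setNames(numeric(length(states)), states)
  for (i in seq_len(nrow(cls))) {
    lbl <- state_label(cls$stage[i], "HOME", cls$status[i])
    occ[[lbl]] <- occ[[lbl]] + cls$prob[i]
  }
  occ
}

#' Simulate one diagnostic strategy over a full scenario
#'
#' Cycle 0 classifies the initial cohort through the decision tree (the full
#' work-up cost is charged to the tested mass; severe patients bypass
#' testing and are diagnosed over a consultation). Each subsequent cycle the
#' cohort evolves under the per-cycle matrix for its current age band; then
#' newly severe undiagnosed patients are auto-diagnosed (consultation cost);
#' in screening scenarios, every undetected individual is retested at
#' scheduled screens (false positives are also re-evaluated then, and
#' revert to undetected on a negative result), and individuals newly
#' developing dementia symptoms between screens are tested immediately.
#'
#' @param p a `ParameterSet`.
#' @param s a [scenario_spec()].
#' @param strategy `"standard"`, `"mri"` or `"mri_clp"`.
#' @param matrices optional pre-built list of per-cycle matrices keyed by
#'   age band (shared across strategies for speed, see [cycle_matrices()]).
#' @return list with `outcome` (strategy, discounted cost, discounted QALY)
#'   and `trace` (cycle-start occupancy matrix plus event-cost ledger).
#' @export
run_strategy <- function(p, s, strategy, matrices = NULL) {
  strategy <- match.arg(strategy, .strategies)
  states <- state_space(s)
  n_cycles <- round(p$econ$horizon / p$econ$cycle_length)
  t <- test_profile(p, strategy)
  tc <- test_cost(p, strategy)
  consult <- p$costs$specialist_consult_diag
  hm_frac <- if (s$kind == "PRIMARY" && s$treatment_T_enabled)
    p$scenario$high_mmse_mild_fraction else 0

  init <- initial_distribution(p, s)
  cls <- classify_cohort(init, t, s$treatment_T_enabled, hm_frac)
  occ <- classification_to_occupancy(cls, states)
  sev_mass <- sum(init[names(init) == "SEVERE"])
  ev0 <- (1 - sev_mass) * tc + sev_mass * consult

  if (n_cycles == 0) {
    return(list(
      outcome = list(strategy = strategy, cost = ev0, qaly = 0),
      trace = list(occupancy = matrix(occ, 1, dimnames = list(NULL, states)),
                   event_costs = ev0)))
  }

  if (is.null(matrices)) matrices <- cycle_matrices(p, s)
  screens <- if (s$has_early) schedule_screens(s, p) else integer()
  info <- state_parts(states)
  idx <- function(stage, setting, status)
    which(info$stage == stage & info$setting == setting & info$status == status)
  undet_sev <- vapply(.settings, function(set) idx("SEVERE", set, "UNDETECTED"), 1L)
  std_sev   <- vapply(.settings, function(set) idx("SEVERE", set, "TREATED_STD"), 1L)
  mild_undet <- vapply(.settings, function(set) idx("MILD", set, "UNDETECTED"), 1L)
  mild_std   <- vapply(.settings, function(set) idx("MILD", set, "TREATED_STD"), 1L)

  occ_mat <- matrix(0, n_cycles, length(states), dimnames = list(NULL, states))
  ev <- numeric(n_cycles)
  occ_mat[1, ] <- occ
  ev[1] <- ev0

  for (k in seq_len(n_cycles - 1L)) {
    age <- s$entry_age + p$econ$cycle_length * (k - 1)
    m <- matrices[[age_band(age)]]
    prev <- occ_mat[k, ]
    cur <- drop(prev %*% m)
    ev_k <- 0

    # auto-diagnosis of newly severe undiagnosed patients (consultation only)
    sev_new <- sum(cur[undet_sev])
    if (sev_new > 0) {
      cur[std_sev] <- cur[std_sev] + cur[undet_sev]
      cur[undet_sev] <- 0
      ev_k <- ev_k + sev_new * consult
    }

    if (s$has_early && k %in% screens) {
      # scheduled screen: retest every undetected individual ...
      for (i in which(info$status == "UNDETECTED" & info$stage != "DEAD")) {
        mass <- cur[i]
        if (mass == 0) next
        pp <- positive_probability(info$stage[i], t)
        stt <- assign_status(info$stage[i], "POSITIVE", s$treatment_T_enabled)
        j <- idx(info$stage[i], info$setting[i], stt)
        cur[j] <- cur[j] + mass * pp
        cur[i] <- mass * (1 - pp)
        ev_k <- ev_k + mass * tc
      }
      # ... and re-evaluate false positives, who revert on a negative result
      fp <- idx("NO_AD", "HOME", "FP_TREATED")
      if (cur[fp] > 0) {
        neg <- cur[fp] * t$specificity
        ev_k <- ev_k + cur[fp] * tc
        cur[idx("NO_AD", "HOME", "UNDETECTED")] <-
          cur[idx("NO_AD", "HOME", "UNDETECTED")] + neg
        cur[fp] <- cur[fp] - neg
      }
    } else if (s$has_early) {
      # between screens: symptom development triggers immediate testing of
      # the mass newly entering mild undetected from asymptomatic states
      for (set_i in seq_along(.settings)) {
        j <- mild_undet[set_i]
        inflow <- sum(prev[info$stage != "MILD"] * m[info$stage != "MILD", j])
        if (inflow <= 0) next
        pos <- inflow * t$sens_mild
        cur[mild_std[set_i]] <- cur[mild_std[set_i]] + pos
        cur[j] <- cur[j] - pos
        ev_k <- ev_k + inflow * tc
      }
    }

    occ_mat[k + 1, ] <- cur
    ev[k + 1] <- ev_k
  }

  age_last <- s$entry_age + p$econ$cycle_length * (n_cycles - 1)
  final <- drop(occ_mat[n_cycles, ] %*% matrices[[age_band(age_last)]])
  trace <- list(occupancy = occ_mat, event_costs = ev, final_occupancy = final)
  out <- accumulate(trace, p, treatment_T_enabled = s$treatment_T_enabled)
  list(outcome = list(strategy = strategy, cost = out$cost, qaly = out$qaly),
       trace = trace)
}

#' Pre-build per-cycle transition matrices for every age band of a run
#'
#' The transition matrix depends on the parameter set and scenario but not
#' on the diagnostic strategy, so one set serves all three strategies.
#'
#' @inheritParams run_strategy
#' @return named list of per-cycle matrices keyed by age band.
#' @export
cycle_matrices <- function(p, s) {
  n_cycles <- round(p$econ$horizon / p$econ$cycle_length)
  ages <- s$entry_age + p$econ$cycle_length * (seq_len(max(n_cycles, 1)) - 1)
  bands <- unique(vapply(ages, age_band, ""))
  stats::setNames(
    lapply(bands, function(b) {
      lo <- if (b == "age_85_plus") 85 else as.numeric(sub("age_(\\d+)_.*", "\\1", b))
      build_cycle_matrix(p, s, lo)
    }),
    bands)
}

#' Run all diagnostic strategies on one scenario
#'
#' @inheritParams run_strategy
#' @param strategies strategies to compare (default all three).
#' @return list with `outcomes` (data frame: strategy, cost, qaly) and
#'   `traces` (named list of cohort traces).
#' @export
run_scenario <- function(p, s, strategies = .strategies) {
  matrices <- cycle_matrices(p, s)
  runs <- lapply(strategies, function(st) run_strategy(p, s, st, matrices))
  outcomes <- do.call(rbind, lapply(runs, function(r)
    data.frame(strategy = r$outcome$strategy, cost = r$outcome$cost,
               qaly = r$outcome$qaly, stringsAsFactors = FALSE)))
  list(outcomes = outcomes,
       traces = stats::setNames(lapply(runs, `[[`, "trace"), strategies))
}
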