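# ---- diagnostic work-up costs ----------------------------------------------

#' Cost of one diagnostic work-up
#'
#' Standard diagnosis sums the specialist consultation, the cognition test
#' and laboratory tests; standard MRI adds the MRI examination; the
#' contrast-enhanced strategy further adds one injection of the contrast
#' agent.
#'
#' @param p a `ParameterSet`.
#' @param strategy one of `"standard"`, `"mri"`, `"mri_clp"`.
#' @return cost in euros of testing one individual once.
#' @export
test_cost <- function(p, strategy) {
  strategy <- match.arg(strategy, .strategies)
  co <- p$costs
  base <- co$specialist_consult_diag + co$mmse + co$labs
  switch(strategy,
    standard = base,
    mri      = base + co$mri_exam,
    mri_clp  = base + co$mri_exam + co$clp_contrast
  )
}

#' Productivity loss of an AD patient per six-month cycle
#'
#' Values the foregone informal volunteering and non-profit activity of a
#' pensioner (hours times wage, scaled by an efficiency coefficient),
#' counted in full for moderate-to-severe patients and at a reduced factor
#' for mild patients; asymptomatic and disease-free individuals lose
#' nothing.
#'
#' @param stage disease stage label.
#' @param p a `ParameterSet`.
#' @export
productivity_cost <- function(stage, p) {
  co <- p$costs
  base <- (co$informal_volunteer_hours * co$informal_volunteer_wage +
             co$npo_hours * co$npo_wage) * co$efficiency_coefficient
  switch(stage,
    MODERATE = , SEVERE = base,
    MILD = co$mild_productivity_factor * base,
    0
  )
}

#' Societal cost of one cohort state per six-month cycle
#'
#' Sums, for a living state: the follow-up consultation for anyone under a
#' diagnosis; drug cost by status and current stage (donepezil at
#' mild/moderate, memantine at severe, the early-stage drug T for
#' `TREATED_T` and for false positives when T is available, donepezil for
#' false positives otherwise); care costs (professional caregiving plus
#' hostel in institution; basic costs, informal-care opportunity cost, and
#' the caregiver-health burden at home for symptomatic stages); and the
#' patient's productivity loss. False positives are healthy and accrue no
#' care or productivity cost; the dead accrue nothing.
#'
#' @param state a state label as produced by [state_space()].
#' @param p a `ParameterSet`.
#' @param treatment_T_enabled is drug T available (affects the drug given to
#'   false positives)?
#' @param breakdown if `TRUE`, return the named component vector instead of
#'   the total (for per-cycle audit export).
#' @export
cycle_cost <- function(state, p, treatment_T_enabled = FALSE, breakdown = FALSE) {
  parts <- c(followup = 0, drug = 0, care = 0, productivity = 0)
  if (state != "DEAD") {
    st <- state_parts(state)
    co <- p$costs
    if (st$status != "UNDETECTED") parts[["followup"]] <- co$followup_consult
    parts[["drug"]] <- switch(st$status,
      TREATED_STD = if (st$stage == "SEVERE") co$memantine_per_cycle
                    else co$donepezil_per_cycle,
      TREATED_T   = co$treatment_T_per_cycle,
      FP_TREATED  = if (treatment_T_enabled) co$treatment_T_per_cycle
                    else co$donepezil_per_cycle,
      0
    )
    symptomatic <- st$stage %in% c("MILD", "MODERATE", "SEVERE")
    hours <- co$professional_caregiver_hours_per_cycle
    if (st$setting == "INSTITUTION") {
      parts[["care"]] <- co$institution_hostel + hours * co$professional_wage
    } else if (symptomatic) {
      parts[["care"]] <- co$home_basic_costs[[tolower(st$stage)]] +
        hours * co$informal_wage +
        co$caregiver_medicated_fraction * co$caregiver_health_cost_per_cycle
    }
    parts[["productivity"]] <- productivity_cost(st$stage, p)
  }
  if (breakdown) parts else sum(parts)
}

#' Quality-of-life weight of a cohort state
#'
#' Annual utility weight: the general-population over-60 weight for
#' disease-free individuals (including false positives), a near-healthy
#' weight for asymptomatic early AD, published stage-and-setting weights for
#' symptomatic stages, and zero when dead.
#'
#' @param state a state label.
#' @param p a `ParameterSet`.
#' @export
state_utility <- function(state, p) {
  if (state == "DEAD") return(0)
  st <- state_parts(state)
  switch(st$stage,
    NO_AD = p$utilities$no_ad,
    EARLY = p$utilities$early,
    p$utilities$stage_setting[[tolower(st$stage)]][[tolower(st$setting)]]
  )
}

#' Discount factor of a six-month cycle
#'
#' @param k cycle index (0-based; cycle 0 is undiscounted).
#' @param r annual discount rate.
#' @return `(1 + r)^(-0.5 k)`.
#' @export
discount_factor <- function(k, r) (1 + r)^(-0.5 * k)

#' Accumulate discounted cost and QALYs over a cohort trace
#'
#' Rewards accrue on cycle-start occupancy with no half-cycle correction
#' (switchable): each cycle contributes the occupancy-weighted state costs
#' plus that cycle's event (testing) costs, and half a year of
#' occupancy-weighted utility, both scaled by [discount_factor()].
#'
#' @param trace a `CohortTrace`: list with `occupancy` (cycles x states
#'   matrix of cycle-start occupancy) and `event_costs` (per-cycle testing
#'   cost, same number of rows).
#' @param p a `ParameterSet`.
#' @param treatment_T_enabled passed to [cycle_cost()].
#' @param half_cycle if `TRUE`, weight each cycle's rewards by the average of
#'   its start and end occupancy (sensitivity check; default off).
#' @return list with `cost` and `qaly` (discounted totals).
#' @export
accumulate <- function(trace, p, treatment_T_enabled = FALSE, half_cycle = FALSE) {
  occ <- trace$occupancy
  ev <- trace$event_costs
  if (length(ev) != nrow(occ))
    stop("event-cost ledger length ", length(ev),
         " does not match trace length ", nrow(occ), call. = FALSE)
  states <- colnames(occ)
  cost_vec <- vapply(states, cycle_cost, numeric(1), p = p,
                     treatment_T_enabled = treatment_T_enabled)
  util_vec <- vapply(states, state_utility, numeric(1), p = p)
  r <- p$econ$annual_discount_rate
  w <- occ
  if (half_cycle) {
    nxt <- rbind(occ[-1, , drop = FALSE], occ[nrow(occ), , drop = FALSE])
    if (!is.null(trace$final_occupancy)) nxt[nrow(occ), ] <- trace$final_occupancy
    w <- (occ + nxt) / 2
  }
  df <- discount_factor(seq_len(nrow(occ)) - 1, r)
  cost <- sum(df * (drop(w %*% cost_vec) + ev))
  qaly <- sum(df * 0.5 * drop(w %*% util_vec))
  list(cost = cost, qaly = qaly)
}
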