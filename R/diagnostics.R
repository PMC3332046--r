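# ---- test profiles ----------------------------------------------------------

.strategies <- c("standard", "mri", "mri_clp")

#' Operating characteristics of a diagnostic strategy
#'
#' Returns the per-stage sensitivities and the specificity of one of the
#' three compared strategies. The amyloid-targeted contrast strategy
#' (`mri_clp`) is parameterized by a single stage-independent sensitivity
#' (amyloid deposition plateaus by the early clinical stages), expanded here
#' to the per-stage representation. The standard cognitive work-up performs
#' in asymptomatic early AD exactly as in non-AD patients, so its early
#' sensitivity equals one minus its specificity.
#'
#' @param p a `ParameterSet`.
#' @param strategy one of `"standard"`, `"mri"`, `"mri_clp"`.
#' @return list with `sens_early`, `sens_mild`, `sens_moderate`,
#'   `specificity`, `label`.
#' @export
test_profile <- function(p, strategy) {
  strategy <- match.arg(strategy, .strategies)
  t <- p$tests[[strategy]]
  if (strategy == "mri_clp") {
    list(sens_early = t$sensitivity, sens_mild = t$sensitivity,
         sens_moderate = t$sensitivity, specificity = t$specificity,
         label = strategy)
  } else {
    list(sens_early = t$sens_early, sens_mild = t$sens_mild,
         sens_moderate = t$sens_moderate, specificity = t$specificity,
         label = strategy)
  }
}

#' Probability of a positive diagnosis by true stage
#'
#' Severe dementia symptoms allow direct diagnosis over a consultation, so
#' `SEVERE` is positive with probability one regardless of the test; `NO_AD`
#' is positive at the false-positive rate (one minus specificity); the
#' remaining stages at their stage sensitivity.
#'
#' @param stage one of `NO_AD`, `EARLY`, `MILD`, `MODERATE`, `SEVERE`.
#' @param t a [test_profile()].
#' @export
positive_probability <- function(stage, t) {
  switch(stage,
    SEVERE   = 1,
    NO_AD    = 1 - t$specificity,
    EARLY    = t$sens_early,
    MILD     = t$sens_mild,
    MODERATE = t$sens_moderate,
    DEAD     = stop("dead patients are not tested", call. = FALSE),
    stop("unknown stage: ", stage, call. = FALSE)
  )
}

#' Clinical status assigned after a test result
#'
#' Negatives remain undetected. Positive false positives enter follow-up
#' (`FP_TREATED`); positive early-stage patients receive the early-stage
#' drug T where enabled; positive symptomatic patients receive standard
#' treatment (donepezil at mild/moderate, memantine at severe, resolved at
#' costing time by current stage).
#'
#' @param true_stage disease stage of the tested patient.
#' @param label `"POSITIVE"` or `"NEGATIVE"`.
#' @param treatment_T_enabled is drug T available?
#' @export
assign_status <- function(true_stage, label, treatment_T_enabled = FALSE) {
  if (label == "NEGATIVE") return("UNDETECTED")
  switch(true_stage,
    NO_AD = "FP_TREATED",
    EARLY = if (treatment_T_enabled) "TREATED_T" else "TREATED_STD",
    MILD = , MODERATE = , SEVERE = "TREATED_STD",
    stop("unknown stage: ", true_stage, call. = FALSE)
  )
}

#' Classify a cohort through the diagnostic decision tree
#'
#' Applies [positive_probability()] per true stage and assigns clinical
#' status per [assign_status()], returning the joint distribution over
#' (true stage, label, status). Probability mass is conserved: the marginal
#' over labels equals the input stage distribution.
#'
#' In the memory-clinic scenario with drug T enabled, positive mild-stage
#' patients split between T (those with high MMSE scores, a fixed fraction)
#' and standard treatment.
#'
#' @param stage_distribution named numeric vector over stages, summing to 1.
#' @param t a [test_profile()].
#' @param treatment_T_enabled is drug T available?
#' @param high_mmse_mild_fraction fraction of positive mild patients with
#'   high MMSE scores, who receive T instead of donepezil (memory-clinic
#'   scenario with T only).
#' @return data frame with columns `stage`, `label`, `status`, `prob`.
#' @export
classify_cohort <- function(stage_distribution, t, treatment_T_enabled = FALSE,
                            high_mmse_mild_fraction = 0) {
  stopifnot(abs(sum(stage_distribution) - 1) <= 1e-9)
  stg <- character(); lab <- character(); stt <- character(); prb <- numeric()
  add <- function(stage, label, status, prob) {
    stg <<- c(stg, stage); lab <<- c(lab, label)
    stt <<- c(stt, status); prb <<- c(prb, prob)
  }
  for (stage in names(stage_distribution)) {
    mass <- stage_distribution[[stage]]
    if (mass == 0) next
    pp <- positive_probability(stage, t)
    pos_status <- assign_status(stage, "POSITIVE", treatment_T_enabled)
    pos <- mass * pp
    if (stage == "MILD" && treatment_T_enabled && high_mmse_mild_fraction > 0) {
      add(stage, "POSITIVE", "TREATED_T", pos * high_mmse_mild_fraction)
      pos <- pos * (1 - high_mmse_mild_fraction)
    }
    add(stage, "POSITIVE", pos_status, pos)
    add(stage, "NEGATIVE", "UNDETECTED", mass * (1 - pp))
  }
  keep <- prb > 0 | lab == "NEGATIVE"
  data.frame(stage = stg[keep], label = lab[keep], status = stt[keep],
             prob = prb[keep], stringsAsFactors = FALSE)
}
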