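# ---- state space ------------------------------------------------------------

.stages    <- c("NO_AD", "EARLY", "MILD", "MODERATE", "SEVERE")
.settings  <- c("HOME", "INSTITUTION")
.statuses  <- c("UNDETECTED", "TREATED_STD", "TREATED_T", "FP_TREATED")

state_label <- function(stage, setting, status) paste(stage, setting, status, sep = "|")

.state_info_cache <- new.env(parent = emptyenv())

state_parts <- function(labels) {
  key <- paste(labels, collapse = ";")
  hit <- .state_info_cache[[key]]
  if (!is.null(hit)) return(hit)
  parts <- strsplit(labels, "|", fixed = TRUE)
  out <- list(
    label   = labels,
    stage   = vapply(parts, `[`, "", 1),
    setting = vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, ""),
    status  = vapply(parts, function(x) if (length(x) > 2) x[3] else NA_character_, "")
  )
  .state_info_cache[[key]] <- out
  out
}

#' Enumerate the cohort state space of a scenario
#'
#' States are the product (disease stage x care setting x clinical status),
#' restricted to reachable combinations, plus a single absorbing `DEAD`
#' state. The asymptomatic `EARLY` stage exists only in screening scenarios;
#' `FP_TREATED` (healthy but labelled positive) only in `NO_AD`; the
#' early-stage drug status `TREATED_T` only where that treatment is enabled.
#'
#' @param s a [scenario_spec()].
#' @return character vector of state labels, `DEAD` last.
#' @export
state_space <- function(s) {
  st <- c(
    state_label("NO_AD", "HOME", c("UNDETECTED", "FP_TREATED")),
    if (s$has_early) state_label("EARLY", "HOME",
      c("UNDETECTED", if (s$treatment_T_enabled) "TREATED_T" else "TREATED_STD")),
    as.vector(t(outer(c("MILD", "MODERATE", "SEVERE"), .settings,
                      function(a, b) state_label(a, b, "UNDETECTED")))),
    as.vector(t(outer(c("MILD", "MODERATE", "SEVERE"), .settings,
                      function(a, b) state_label(a, b, "TREATED_STD")))),
    if (s$kind == "PRIMARY" && s$treatment_T_enabled)
      state_label("MILD", .settings, "TREATED_T")
  )
  c(st, "DEAD")
}

# ---- treatment effects ------------------------------------------------------

#' Construct a treatment-effect multiplier set
#'
#' Multipliers act on transition probabilities of treated cohort states:
#' `f_mM`, `f_MS` scale treated progression (mild to moderate, moderate to
#' severe) and lie in `[0.5, 1]`; `f_Mm`, `f_SM` scale treated improvement
#' (moderate to mild, severe to moderate) and lie in `[1, 2]`; `f_T` in
#' `[0, 1]` scales progression out of the stage at which the hypothetical
#' early-stage drug T is given. The neutral element is all ones.
#'
#' @param f_mM,f_MS,f_Mm,f_SM,f_T multipliers; defaults neutral.
#' @export
treatment_effect <- function(f_mM = 1, f_MS = 1, f_Mm = 1, f_SM = 1, f_T = 1) {
  stopifnot(f_mM >= 0.5, f_mM <= 1, f_MS >= 0.5, f_MS <= 1,
            f_Mm >= 1, f_Mm <= 2, f_SM >= 1, f_SM <= 2,
            f_T >= 0, f_T <= 1)
  structure(list(f_mM = f_mM, f_MS = f_MS, f_Mm = f_Mm, f_SM = f_SM, f_T = f_T),
            class = "adcea_effect")
}

#' Expand a scalar drug-improvement parameter into multipliers
#'
#' A single improvement parameter `f` in `[0, 1]` is mapped linearly between
#' the neutral effect (`f = 0`: current drugs) and the maximal effect
#' (`f = 1`: progression halved, improvement doubled):
#' `f_mM = f_MS = 1 - 0.5 f`, `f_Mm = f_SM = 1 + f`.
#'
#' @param f scalar in `[0, 1]`.
#' @param f_T early-stage multiplier, passed through untouched (default 1).
#' @export
expand_f <- function(f, f_T = 1) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("f must be a scalar in [0, 1]", call. = FALSE)
  treatment_effect(f_mM = 1 - 0.5 * f, f_MS = 1 - 0.5 * f,
                   f_Mm = 1 + f, f_SM = 1 + f, f_T = f_T)
}

#' Apply treatment-effect multipliers to a transition matrix
#'
#' Rows of `TREATED_STD` states have stage-progression entries multiplied by
#' `f_mM`/`f_MS` and improvement entries by `f_Mm`/`f_SM`; rows of
#' `TREATED_T` states have progression out of the treated stage multiplied
#' by `f_T`. Each modified row is rebalanced through its self-transition
#' (diagonal) entry so the matrix stays row-stochastic. `UNDETECTED` and
#' `FP_TREATED` rows are untouched.
#'
#' @param m labelled transition matrix (state labels as dimnames).
#' @param e a [treatment_effect()].
#' @export
apply_treatment <- function(m, e) {
  info <- state_parts(rownames(m))
  cinfo <- state_parts(colnames(m))
  for (i in seq_len(nrow(m))) {
    f_stage <- info$stage[i]; f_status <- info$status[i]
    if (is.na(f_status)) next
    mult <- rep(1, ncol(m))
    if (f_status == "TREATED_STD") {
      if (f_stage == "MILD")     mult[cinfo$stage == "MODERATE"] <- e$f_mM
      if (f_stage == "MODERATE") mult[cinfo$stage == "SEVERE"]   <- e$f_MS
      if (f_stage == "MODERATE") mult[cinfo$stage == "MILD"]     <- e$f_Mm
      if (f_stage == "SEVERE")   mult[cinfo$stage == "MODERATE"] <- e$f_SM
    } else if (f_status == "TREATED_T") {
      if (f_stage == "EARLY")
        mult[cinfo$stage %in% c("MILD", "MODERATE")] <- e$f_T
      if (f_stage == "MILD")
        mult[cinfo$stage == "MODERATE"] <- e$f_T
    } else {
      next
    }
    new_row <- m[i, ] * mult
    diff <- sum(m[i, ]) - sum(new_row)
    new_row[i] <- new_row[i] + diff
    if (new_row[i] < -1e-12) {
      stop("treatment rebalancing drives self-transition negative in row ",
           rownames(m)[i], call. = FALSE)
    }
    new_row[i] <- max(new_row[i], 0)
    m[i, ] <- new_row
  }
  m
}

# ---- annual matrix assembly -------------------------------------------------

age_band <- function(age) {
  if (age < 60) stop("age below table coverage (60+): ", age, call. = FALSE)
  if (age >= 85) return("age_85_plus")
  lo <- 60 + 5 * ((age - 60) %/% 5)
  sprintf("age_%d_%d", lo, lo + 4)
}

# annual probability of incident AD out of NO_AD, by scenario and age
incidence_rate <- function(p, s, age) {
  if (s$kind == "PRIMARY") return(p$epidemiology$mci_annual_incidence)
  r <- p$epidemiology$age_incidence_table[[age_band(age)]]
  if (s$kind == "SCREEN_APOE4") r <- r * p$epidemiology$apoe4_incidence_multiplier
  min(r, 1)
}

# destination status when a state's stage changes, given its current status
next_status <- function(status, from_stage, to_stage, s) {
  if (status == "UNDETECTED") return("UNDETECTED")
  if (status == "TREATED_STD") return("TREATED_STD")
  if (status == "TREATED_T") {
    # drug T is stage-specific; on progression the patient (already
    # diagnosed) moves to standard symptomatic treatment
    if (s$has_early && to_stage %in% c("MILD", "MODERATE")) return("TREATED_STD")
    if (!s$has_early && to_stage == "MODERATE") return("TREATED_STD")
    return("TREATED_T")
  }
  if (status == "FP_TREATED") {
    # a false positive who develops AD is already under follow-up
    if (to_stage == "EARLY" && s$treatment_T_enabled) return("TREATED_T")
    return("TREATED_STD")
  }
  stop("unknown status: ", status)
}

#' Assemble the annual cohort transition matrix
#'
#' Composes, per row: all-cause age-band mortality plus additive stage excess
#' mortality into `DEAD`; incident AD out of `NO_AD` (fixed annual incidence
#' for the memory-clinic cohort, age-specific rates -- doubled for ApoE4
#' carriers -- in screening scenarios); baseline stage transitions with
#' treated/untreated values by clinical status; home-to-institution
#' transitions by stage; and the treatment-effect multipliers of the
#' parameter set via [apply_treatment()].
#'
#' The composition is carried out on the half-year scale (each annual
#' probability `q` enters as `1 - (1 - q)^(1/2)`) and the annual matrix is
#' the square of that half-year composition. This guarantees the annual
#' matrix is embeddable -- it possesses a non-negative six-month root, which
#' is exactly what the square-root cycle conversion presumes -- and gives
#' the annual matrix correct one-year mass on two-step paths such as
#' mild to severe.
#'
#' @param p a `ParameterSet`.
#' @param s a [scenario_spec()].
#' @param age cohort age in years (determines mortality/incidence bands).
#' @return row-stochastic matrix over [state_space()], annual period.
#' @export
build_annual_matrix <- function(p, s, age) {
  h <- halfyear_composition(p, s, age)
  m <- h %*% h
  dimnames(m) <- dimnames(h)
  attr(m, "period") <- "ANNUAL"
  m
}

# half-year composition of all transition components; annual probabilities q
# enter on the cycle scale as 1 - sqrt(1 - q)
halfyear_composition <- function(p, s, age) {
  states <- state_space(s)
  info <- state_parts(states)
  n <- length(states)
  m <- matrix(0, n, n, dimnames = list(states, states))
  epi <- p$epidemiology
  tr <- p$transitions
  sp <- tr$speed_multiplier
  mort <- epi$age_mortality_table[[age_band(age)]]
  excess <- function(stage_lc) {
    v <- epi$stage_excess_mortality[[stage_lc]]
    if (is.null(v)) 0 else v
  }
  to_cycle <- function(q) 1 - sqrt(1 - min(q, 1))
  # institutionalization probabilities are already per cycle
  inst_cycle <- function(stage) {
    ic <- epi$institutionalization_probs[[tolower(stage)]]
    if (is.null(ic)) 0 else ic
  }

  for (i in seq_len(n)) {
    st <- list(label = info$label[i], stage = info$stage[i],
               setting = info$setting[i], status = info$status[i])
    if (st$stage == "DEAD") { m[i, "DEAD"] <- 1; next }
    q_dead <- to_cycle(mort + excess(tolower(st$stage)))
    m[i, "DEAD"] <- q_dead
    alive <- 1 - q_dead

    # stage moves (annual probabilities, conditional on survival)
    moves <- list()  # list of c(stage, prob)  -- annual scale until converted
    if (st$stage == "NO_AD") {
      inc <- incidence_rate(p, s, age)
      dest <- if (s$has_early) "EARLY" else "MILD"
      moves[[dest]] <- inc
    } else if (st$stage == "EARLY") {
      moves[["MILD"]]     <- min(1, tr$untreated$early_to_mild * sp)
      moves[["MODERATE"]] <- min(1, tr$untreated$early_to_moderate * sp)
    } else if (st$stage == "MILD") {
      pr <- if (st$status == "TREATED_STD") tr$treated$mild_to_moderate
            else tr$untreated$mild_to_moderate
      moves[["MODERATE"]] <- min(1, pr * sp)
    } else if (st$stage == "MODERATE") {
      pr <- if (st$status == "TREATED_STD") tr$treated$moderate_to_severe
            else tr$untreated$moderate_to_severe
      moves[["SEVERE"]] <- min(1, pr * sp)
      if (st$status == "TREATED_STD")
        moves[["MILD"]] <- min(1, tr$treated$moderate_to_mild * sp)
    } else if (st$stage == "SEVERE") {
      if (st$status == "TREATED_STD")
        moves[["MODERATE"]] <- min(1, tr$treated$severe_to_moderate * sp)
    }
    moves <- lapply(moves, to_cycle)
    tot <- sum(unlist(moves))
    if (tot > 1) stop("stage exit probabilities exceed 1 in row ", st$label,
                      call. = FALSE)
    moves[[st$stage]] <- 1 - tot

    i_inst <- inst_cycle(st$stage)
    for (to_stage in names(moves)) {
      pr <- moves[[to_stage]]
      if (pr <= 0) next
      to_status <- if (to_stage == st$stage) st$status
                   else next_status(st$status, st$stage, to_stage, s)
      settings <- if (st$setting == "INSTITUTION") {
        c(INSTITUTION = 1)
      } else if (i_inst > 0 && to_stage %in% c("MILD", "MODERATE", "SEVERE")) {
        c(HOME = 1 - i_inst, INSTITUTION = i_inst)
      } else {
        c(HOME = 1)
      }
      for (to_set in names(settings)) {
        lbl <- state_label(to_stage, to_set, to_status)
        if (!lbl %in% states) {
          stop("transition into unmodelled state ", lbl, " from ", st$label,
               call. = FALSE)
        }
        m[i, lbl] <- m[i, lbl] + alive * pr * settings[[to_set]]
      }
    }
  }
  e <- do.call(treatment_effect, p$treatment_effect)
  m <- apply_treatment(m, e)
  m
}

# ---- annual -> cycle conversion ---------------------------------------------

#' Convert an annual transition matrix to six-month cycles
#'
#' Six-month transition probabilities are the principal square root of the
#' annual matrix, computed by a Denman-Beavers iteration (cohort matrices
#' here have repeated eigenvalues and can be defective, which rules out an
#' eigendecomposition root). Entries with tiny negative values (numerical
#' artefacts of roots of stochastic matrices) are clamped to zero and rows
#' are renormalized; the result squared must reproduce the input to an
#' infinity-norm tolerance of `1e-6`, otherwise an error reports the
#' offending entries. Absorbing rows (e.g. `DEAD`) are preserved exactly.
#'
#' @param m row-stochastic annual matrix.
#' @return row-stochastic six-month matrix with `attr(., "period") == "CYCLE"`.
#' @export
annual_to_cycle <- function(m) {
  n <- nrow(m)
  y <- unname(m)
  z <- diag(n)
  for (it in seq_len(60)) {
    y_new <- 0.5 * (y + solve(z))
    z_new <- 0.5 * (z + solve(y))
    delta <- max(abs(y_new - y))
    y <- y_new; z <- z_new
    if (delta < 1e-14) break
  }
  s <- y
  s[s < 0] <- 0
  rs <- rowSums(s)
  s <- s / rs
  # keep exactly-absorbing rows exact
  for (i in seq_len(nrow(m))) {
    if (m[i, i] == 1 && sum(m[i, ]) == 1) {
      s[i, ] <- 0; s[i, i] <- 1
    }
  }
  err <- abs(s %*% s - m)
  if (max(err) > 1e-6) {
    bad <- which(err > 1e-6, arr.ind = TRUE)
    lab <- apply(bad, 1, function(ix)
      paste0("(", rownames(m)[ix[1]], " -> ", colnames(m)[ix[2]], ")"))
    stop("cycle conversion failed to reproduce the annual matrix at: ",
         paste(utils::head(lab, 5), collapse = ", "),
         " (max error ", format(max(err)), ")", call. = FALSE)
  }
  dimnames(s) <- dimnames(m)
  attr(s, "period") <- "CYCLE"
  s
}

#' Build the per-cycle cohort transition matrix
#'
#' [build_annual_matrix()] followed by [annual_to_cycle()].
#'
#' @inheritParams build_annual_matrix
#' @export
build_cycle_matrix <- function(p, s, age) {
  annual_to_cycle(build_annual_matrix(p, s, age))
}

#' Advance cohort occupancy by one cycle
#'
#' @param occupancy numeric vector over the state space, summing to 1.
#' @param m per-cycle transition matrix.
#' @return occupancy after one cycle (`occupancy %*% m`).
#' @export
step_cohort <- function(occupancy, m) {
  if (length(occupancy) != nrow(m))
    stop("occupancy length ", length(occupancy), " does not match matrix order ",
         nrow(m), call. = FALSE)
  drop(occupancy %*% m)
}

# ---- absorption analysis ----------------------------------------------------

#' Expected years until a cohort state first reaches a target stage
#'
#' Mean absorption time (in the matrix's period units) treating every state
#' of `target_stage`, plus `DEAD`, as absorbing. Used to verify that
#' treatment slows progression.
#'
#' @param m labelled transition matrix.
#' @param from state label to start from.
#' @param target_stage stage whose first hitting time is measured.
#' @export
expected_time_to_stage <- function(m, from, target_stage) {
  info <- state_parts(rownames(m))
  absorbing <- info$stage %in% c(target_stage, "DEAD")
  q <- m[!absorbing, !absorbing, drop = FALSE]
  fund <- solve(diag(nrow(q)) - q)
  times <- rowSums(fund)
  times[[which(rownames(q) == from)]]
}

# ---- labelled CSV interchange ------------------------------------------------

#' Write / read a labelled transition matrix as CSV
#'
#' State labels form the header row and first column; the `period`
#' attribute is restored on read from the `period` argument.
#'
#' @param m labelled matrix.
#' @param file path to a CSV file.
#' @param period `"ANNUAL"` or `"CYCLE"` (attached on read).
#' @export
write_matrix_csv <- function(m, file) {
  utils::write.csv(as.data.frame(m), file, row.names = TRUE)
  invisible(file)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(file, period = "CYCLE") {
  d <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  attr(m, "period") <- period
  m
}
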