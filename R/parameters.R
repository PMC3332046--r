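# ---- dotted-path helpers ----------------------------------------------------

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Fetch a parameter by dotted path
#'
#' Parameter sets are nested lists; every leaf is addressable by a dotted
#' path such as `"costs.clp_contrast"` or
#' `"epidemiology.age_mortality_table.age_70_74"`.
#'
#' @param p a `ParameterSet` (or any nested list).
#' @param path dotted key, e.g. `"econ.wtp"`.
#' @return the value stored at `path`.
#' @export
param_get <- function(p, path) {
  keys <- split_path(path)
  node <- p
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

param_exists <- function(p, path) {
  keys <- split_path(path)
  node <- p
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) return(FALSE)
    node <- node[[k]]
  }
  TRUE
}

param_set <- function(p, path, value) {
  keys <- split_path(path)
  rec <- function(node, keys) {
    k <- keys[[1]]
    if (length(keys) == 1L) {
      node[[k]] <- value
    } else {
      if (!is.list(node[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
      node[[k]] <- rec(node[[k]], keys[-1])
    }
    node
  }
  rec(p, keys)
}

#' Flatten a parameter set to named numeric leaves
#'
#' @param p nested parameter list.
#' @return named numeric vector; names are dotted paths to every numeric leaf.
#' @export
param_flatten <- function(p) {
  out <- c()
  rec <- function(node, prefix) {
    for (nm in names(node)) {
      path <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      v <- node[[nm]]
      if (is.list(v)) {
        rec(v, path)
      } else if (is.numeric(v) && length(v) == 1L) {
        out[[path]] <<- v
      }
    }
  }
  # attributes (class, provenance) are not leaves
  rec(unclass(p), "")
  unlist(out)
}

# ---- schema -----------------------------------------------------------------

# Required top-level sections and a few mandatory leaves; load_parameters
# fails closed on unknown keys so that a typo in an override document cannot
# silently leave the base-case value in place.
.required_paths <- c(
  "epidemiology.primary_prevalence",
  "epidemiology.primary_stage_split.mild",
  "epidemiology.primary_stage_split.moderate",
  "epidemiology.primary_stage_split.severe",
  "epidemiology.screen_prevalence",
  "epidemiology.early_to_mild_ratio",
  "epidemiology.mci_annual_incidence",
  "epidemiology.apoe4_incidence_multiplier",
  "transitions.speed_multiplier",
  "transitions.untreated.mild_to_moderate",
  "transitions.untreated.moderate_to_severe",
  "transitions.untreated.early_to_mild",
  "transitions.untreated.early_to_moderate",
  "transitions.treated.mild_to_moderate",
  "transitions.treated.moderate_to_severe",
  "transitions.treated.moderate_to_mild",
  "transitions.treated.severe_to_moderate",
  "treatment_effect.f_mM", "treatment_effect.f_MS",
  "treatment_effect.f_Mm", "treatment_effect.f_SM",
  "treatment_effect.f_T",
  "tests.standard.sens_early", "tests.standard.sens_mild",
  "tests.standard.sens_moderate", "tests.standard.specificity",
  "tests.mri.sens_early", "tests.mri.sens_mild",
  "tests.mri.sens_moderate", "tests.mri.specificity",
  "tests.mri_clp.sensitivity", "tests.mri_clp.specificity",
  "costs.specialist_consult_diag", "costs.mmse", "costs.labs",
  "costs.mri_exam", "costs.clp_contrast", "costs.followup_consult",
  "costs.donepezil_per_cycle", "costs.memantine_per_cycle",
  "costs.treatment_T_per_cycle",
  "costs.professional_caregiver_hours_per_cycle",
  "costs.professional_wage", "costs.informal_wage",
  "costs.institution_hostel", "costs.caregiver_medicated_fraction",
  "costs.caregiver_health_cost_per_cycle",
  "costs.informal_volunteer_hours", "costs.informal_volunteer_wage",
  "costs.npo_hours", "costs.npo_wage",
  "costs.efficiency_coefficient", "costs.mild_productivity_factor",
  "utilities.no_ad", "utilities.early",
  as.vector(outer(paste0("utilities.stage_setting.",
                         c("mild", "moderate", "severe")),
                  c("home", "institution"), paste, sep = ".")),
  "econ.annual_discount_rate", "econ.wtp", "econ.cycle_length",
  "econ.horizon", "econ.rescreen_interval",
  "scenario.high_mmse_mild_fraction"
)

.age_bands <- c("age_60_64", "age_65_69", "age_70_74",
                "age_75_79", "age_80_84", "age_85_plus")

.symptomatic_stages <- c("mild", "moderate", "severe")

# paths that are structurally lists-of-leaves and accept any of a fixed key set
.table_paths <- list(
  "epidemiology.age_incidence_table"     = .age_bands,
  "epidemiology.age_mortality_table"     = .age_bands,
  "epidemiology.stage_excess_mortality"  = c("early", .symptomatic_stages),
  "epidemiology.institutionalization_probs" = .symptomatic_stages,
  "costs.home_basic_costs"               = .symptomatic_stages
)

known_leaf <- function(path) {
  if (path %in% .required_paths) return(TRUE)
  for (tp in names(.table_paths)) {
    if (startsWith(path, paste0(tp, "."))) {
      key <- sub(paste0(tp, "."), "", path, fixed = TRUE)
      return(key %in% .table_paths[[tp]])
    }
  }
  if (startsWith(path, "utilities.stage_setting.")) {
    key <- split_path(path)
    return(length(key) == 4L && key[3] %in% .symptomatic_stages &&
             key[4] %in% c("home", "institution"))
  }
  if (startsWith(path, "psa_ranges.")) return(TRUE)
  FALSE
}

# ---- load / serialize -------------------------------------------------------

#' Load a model parameter document
#'
#' Reads a YAML parameter document (the package's single configuration
#' dialect), checks that every required path is present, rejects unknown
#' keys, and validates the resulting set.
#'
#' @param document path to a YAML file, or a YAML string.
#' @return a validated `ParameterSet` (class `adcea_parameters`).
#' @export
load_parameters <- function(document) {
  p <- if (file.exists(document)) yaml::read_yaml(document) else
    yaml::yaml.load(document)
  prov <- p$provenance
  p$provenance <- NULL
  leaves <- names(param_flatten(p))
  missing <- setdiff(.required_paths, leaves)
  # table/utility leaves required too
  for (tp in names(.table_paths)) {
    want <- paste(tp, .table_paths[[tp]], sep = ".")
    missing <- c(missing, setdiff(want, leaves))
  }
  if (length(missing)) {
    stop("configuration error: missing parameter path(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- leaves[!vapply(leaves, known_leaf, logical(1))]
  if (length(unknown)) {
    stop("configuration error: unknown parameter path(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- structure(p, class = "adcea_parameters")
  if (!is.null(prov)) attr(p, "provenance") <- unlist(prov)
  v <- validate_parameters(p)
  if (nrow(v)) {
    stop("invalid parameter document:\n",
         paste(sprintf("  %s: %s", v$path, v$message), collapse = "\n"),
         call. = FALSE)
  }
  p
}

#' Serialize a parameter set to YAML
#'
#' Round-trips through [load_parameters()] with full numeric precision.
#'
#' @param p a `ParameterSet`.
#' @param file optional path to write to; if `NULL` the YAML text is returned.
#' @export
serialize_parameters <- function(p, file = NULL) {
  x <- unclass(p)
  prov <- attr(p, "provenance")
  if (!is.null(prov)) x$provenance <- as.list(prov)
  attributes(x) <- list(names = names(x))
  # emit numerics at 17 significant digits so round-trips are bit-exact
  txt <- yaml::as.yaml(x, handlers = list(
    numeric = function(v) {
      if (length(v) == 1L) structure(format(v, digits = 17), class = "verbatim")
      else v
    }))
  if (is.null(file)) txt else { writeLines(txt, file); invisible(file) }
}

# ---- validation -------------------------------------------------------------

violation <- function(path, message) data.frame(path = path, message = message,
                                                stringsAsFactors = FALSE)

#' Validate a parameter set
#'
#' Violations are data, not exceptions: the return value is a data frame
#' with one row per problem (possibly zero rows), suitable for export as CSV.
#'
#' @param p a `ParameterSet`.
#' @return data frame with columns `path`, `message`.
#' @export
validate_parameters <- function(p) {
  v <- violation(character(), character())
  leaves <- param_flatten(p)
  chk <- function(cond, path, msg) {
    if (!isTRUE(cond)) v <<- rbind(v, violation(path, msg))
  }

  prob_paths <- grep(
    "prevalence|split|incidence|mortality|sens|specificity|fraction|probs|ratio$",
    names(leaves), value = TRUE)
  prob_paths <- setdiff(prob_paths,
    c("epidemiology.early_to_mild_ratio", "epidemiology.apoe4_incidence_multiplier"))
  prob_paths <- grep("^psa_ranges", prob_paths, value = TRUE, invert = TRUE)
  for (pp in prob_paths) {
    chk(leaves[[pp]] >= 0 && leaves[[pp]] <= 1, pp,
        sprintf("probability out of [0,1]: %g", leaves[[pp]]))
  }

  split_sum <- sum(unlist(p$epidemiology$primary_stage_split))
  chk(abs(split_sum - 1) <= 1e-12, "epidemiology.primary_stage_split",
      sprintf("stage split sums to %.15g, expected 1", split_sum))
  chk(p$epidemiology$apoe4_incidence_multiplier >= 1,
      "epidemiology.apoe4_incidence_multiplier", "multiplier must be >= 1")
  chk(p$epidemiology$early_to_mild_ratio > 0,
      "epidemiology.early_to_mild_ratio", "ratio must be positive")

  for (pp in grep("^costs\\.", names(leaves), value = TRUE)) {
    chk(leaves[[pp]] >= 0, pp, sprintf("cost must be non-negative: %g", leaves[[pp]]))
  }

  for (pp in grep("^utilities\\.", names(leaves), value = TRUE)) {
    chk(leaves[[pp]] >= 0 && leaves[[pp]] <= 1, pp,
        sprintf("utility weight out of [0,1]: %g", leaves[[pp]]))
  }
  # utilities non-increasing with stage within each setting
  u <- p$utilities$stage_setting
  if (is.list(u)) {
    for (set in c("home", "institution")) {
      w <- vapply(.symptomatic_stages, function(s) u[[s]][[set]], numeric(1))
      chk(all(diff(w) <= 0), paste0("utilities.stage_setting.*.", set),
          "stage utilities must be non-increasing with stage")
    }
    chk(u$mild$home <= p$utilities$no_ad, "utilities.stage_setting.mild.home",
        "symptomatic utility exceeds the disease-free weight")
  }

  te <- p$treatment_effect
  chk(te$f_mM >= 0.5 && te$f_mM <= 1, "treatment_effect.f_mM", "f_mM outside [0.5, 1]")
  chk(te$f_MS >= 0.5 && te$f_MS <= 1, "treatment_effect.f_MS", "f_MS outside [0.5, 1]")
  chk(te$f_Mm >= 1 && te$f_Mm <= 2, "treatment_effect.f_Mm", "f_Mm outside [1, 2]")
  chk(te$f_SM >= 1 && te$f_SM <= 2, "treatment_effect.f_SM", "f_SM outside [1, 2]")
  chk(te$f_T >= 0 && te$f_T <= 1, "treatment_effect.f_T", "f_T outside [0, 1]")

  ec <- p$econ
  chk(ec$annual_discount_rate >= 0, "econ.annual_discount_rate", "discount must be >= 0")
  chk(ec$wtp > 0, "econ.wtp", "willingness-to-pay must be positive")
  chk(identical(as.numeric(ec$cycle_length), 0.5), "econ.cycle_length",
      "cycle length must be 0.5 years")
  chk(ec$rescreen_interval >= 1, "econ.rescreen_interval",
      "rescreening interval must be >= 1 year")

  # standard-diagnosis rule: early-stage sensitivity equals the false-positive rate
  chk(abs(p$tests$standard$sens_early - (1 - p$tests$standard$specificity)) <= 1e-12,
      "tests.standard.sens_early",
      "standard diagnosis must perform in early AD as in non-AD (sens = 1 - spec)")

  # untreated early/mild/moderate row masses must leave room for self-transition
  tu <- p$transitions$untreated
  chk(tu$early_to_mild + tu$early_to_moderate <= 1, "transitions.untreated",
      "early-stage exit probabilities exceed 1")
  chk(p$transitions$speed_multiplier > 0, "transitions.speed_multiplier",
      "speed multiplier must be positive")

  # every PSA range refers to an existing path and is ordered low <= mode <= high
  for (nm in names(p$psa_ranges)) {
    r <- p$psa_ranges[[nm]]
    chk(param_exists(p, nm), paste0("psa_ranges.", nm), "range targets unknown path")
    chk(r$low <= r$mode && r$mode <= r$high, paste0("psa_ranges.", nm),
        sprintf("triangular range not ordered: (%g, %g, %g)", r$low, r$mode, r$high))
  }

  # assembled annual matrices must be row-stochastic
  for (sc in c("PRIMARY", "SCREEN_ALL")) {
    m <- try(build_annual_matrix(p, scenario_spec(sc),
                                 age = if (sc == "PRIMARY") 70 else 60),
             silent = TRUE)
    if (inherits(m, "try-error")) {
      v <- rbind(v, violation(paste0("transitions (", sc, ")"),
                              attr(m, "condition")$message))
    } else {
      rs <- rowSums(m)
      bad <- which(abs(rs - 1) > 1e-9)
      for (b in bad) {
        v <- rbind(v, violation(
          sprintf("transitions (%s) row %s", sc, rownames(m)[b]),
          sprintf("row sums to %.12g, expected 1", rs[b])))
      }
    }
  }
  v
}

#' Override a single parameter
#'
#' Returns a new set identical to `p` except at `path`; `p` itself is never
#' modified. The result is re-validated; an override that breaks an invariant
#' fails and leaves the original untouched.
#'
#' @param p a `ParameterSet`.
#' @param path dotted key that must already exist.
#' @param value replacement value.
#' @param revalidate check invariants after the override (default `TRUE`).
#' @export
override_parameter <- function(p, path, value, revalidate = TRUE) {
  if (!param_exists(p, path)) stop("unknown parameter path: ", path, call. = FALSE)
  q <- param_set(p, path, value)
  if (revalidate) {
    viol <- validate_parameters(q)
    if (nrow(viol)) {
      stop("override produces invalid parameter set:\n",
           paste(sprintf("  %s: %s", viol$path, viol$message), collapse = "\n"),
           call. = FALSE)
    }
  }
  q
}

#' Provenance of a parameter set
#'
#' @param p a `ParameterSet`.
#' @return named character vector mapping each numeric leaf path to `"PAPER"`
#'   (value printed in the source literature) or `"STAND_IN"` (documented
#'   stand-in pending a primary source).
#' @export
parameter_provenance <- function(p) attr(p, "provenance")

#' @export
print.adcea_parameters <- function(x, ...) {
  leaves <- param_flatten(x)
  prov <- attr(x, "provenance")
  cat("<adcea_parameters> ", length(leaves), " numeric leaves\n", sep = "")
  if (!is.null(prov)) {
    cat("  provenance: ", sum(prov == "PAPER"), " literature values, ",
        sum(prov == "STAND_IN"), " stand-ins\n", sep = "")
  }
  invisible(x)
}
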