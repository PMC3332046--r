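# ---- incremental ratio of the contrast strategy ------------------------------

#' ICER of the contrast-enhanced strategy against its comparator
#'
#' The comparator is standard MRI (the next best strategy) unless it is
#' dominated, in which case the next non-dominated frontier strategy is
#' used. A zero QALY difference yields a signed infinity.
#'
#' @param outcomes data frame with `strategy`, `cost`, `qaly` for the three
#'   strategies.
#' @export
icer_mri_clp <- function(outcomes) {
  tab <- build_icer_table(outcomes)
  clp <- tab[tab$strategy == "mri_clp", ]
  front <- tab[tab$status == "ON_FRONTIER" & tab$strategy != "mri_clp", ]
  comp <- if ("mri" %in% front$strategy) {
    tab[tab$strategy == "mri", ]
  } else if (nrow(front)) {
    front[which.max(front$qaly), ]
  } else {
    tab[tab$strategy == "mri", ]
  }
  dq <- clp$qaly - comp$qaly
  dc <- clp$cost - comp$cost
  if (dq == 0) sign(dc) * Inf else dc / dq
}

# ---- univariate sweeps -------------------------------------------------------

#' Univariate sensitivity sweep
#'
#' Re-runs the full three-strategy comparison with a single parameter
#' overridden at each supplied value, reporting the ICER of the
#' contrast-enhanced strategy against its comparator and the preferred
#' strategy at the configured willingness-to-pay.
#'
#' @param p base `ParameterSet`.
#' @param path dotted path of the swept parameter.
#' @param values values to evaluate.
#' @param s a [scenario_spec()].
#' @return data frame with columns `value`, `icer`, `preferred`.
#' @export
univariate_sweep <- function(p, path, values, s) {
  if (!param_exists(p, path)) stop("unknown parameter path: ", path, call. = FALSE)
  rows <- lapply(values, function(v) {
    q <- canonicalize_parameters(param_set(p, path, v))
    res <- run_scenario(q, s)
    tab <- build_icer_table(res$outcomes)
    data.frame(value = v,
               icer = icer_mri_clp(res$outcomes),
               preferred = preferred_strategy(tab, q$econ$wtp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- probabilistic sensitivity analysis --------------------------------------

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from independent triangular priors and runs all
#' three diagnostic strategies on each identical draw. Reproducible given
#' the seed: the uniform deviates are generated once up front and mapped
#' through the triangular quantile function.
#'
#' @param p base `ParameterSet`.
#' @param s a [scenario_spec()].
#' @param n number of Monte-Carlo trials.
#' @param seed integer seed.
#' @param ranges named triangular ranges (default `p$psa_ranges`).
#' @return object of class `adcea_psa`: list with `draws` (n x k data frame
#'   of parameter values), `costs` and `qalys` (n x 3 matrices), `icer`
#'   (n-vector, contrast strategy vs comparator) and `strategies`.
#' @export
run_psa <- function(p, s, n, seed, ranges = p$psa_ranges) {
  stopifnot(n >= 1)
  if (!length(ranges)) stop("no ranges to draw from", call. = FALSE)
  k <- length(ranges)
  paths <- names(ranges)
  set.seed(seed)
  u <- matrix(stats::runif(n * k), n, k)
  draws <- matrix(NA_real_, n, k, dimnames = list(NULL, paths))
  costs <- matrix(NA_real_, n, 3, dimnames = list(NULL, .strategies))
  qalys <- matrix(NA_real_, n, 3, dimnames = list(NULL, .strategies))
  icer <- numeric(n)
  for (i in seq_len(n)) {
    q <- p
    for (j in seq_len(k)) {
      r <- ranges[[j]]
      val <- qtriangular(u[i, j], r$low, r$mode, r$high)
      draws[i, j] <- val
      q <- param_set(q, paths[j], val)
    }
    q <- canonicalize_parameters(q)
    res <- run_scenario(q, s)
    costs[i, res$outcomes$strategy] <- res$outcomes$cost
    qalys[i, res$outcomes$strategy] <- res$outcomes$qaly
    icer[i] <- icer_mri_clp(res$outcomes)
  }
  structure(list(draws = as.data.frame(draws), costs = costs, qalys = qalys,
                 icer = icer, strategies = .strategies, seed = seed),
            class = "adcea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of each strategy is
#' the fraction of Monte-Carlo draws in which it attains the maximal net
#' monetary benefit (ties resolved by the fixed strategy order), so the
#' probabilities sum to one.
#'
#' @param psa an [run_psa()] result.
#' @param wtp_grid willingness-to-pay values (euros per QALY).
#' @return data frame with `wtp` and one probability column per strategy.
#' @export
ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("empty willingness-to-pay grid", call. = FALSE)
  out <- lapply(wtp_grid, function(w) {
    ben <- psa$qalys * w - psa$costs
    best <- psa$strategies[apply(ben, 1, which.max)]
    prop <- vapply(psa$strategies, function(s) mean(best == s), numeric(1))
    as.data.frame(c(list(wtp = w), as.list(prop)))
  })
  do.call(rbind, out)
}

# ---- partial rank correlation ------------------------------------------------

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the response (average ranks at
#' ties), then computes for each parameter the correlation between the
#' residuals of linear regressions of its ranks, and of the response ranks,
#' on the ranks of all other parameters. Significance uses the t statistic
#' `r * sqrt(df / (1 - r^2))` with `df = n - 2 - (k - 1)` degrees of
#' freedom, `k - 1` being the number of conditioning parameters.
#'
#' @param draws n x k data frame or matrix of parameter draws.
#' @param response numeric response vector (here: the ICER per draw).
#' @return data frame with `parameter`, `prcc`, `p_value`.
#' @export
prcc <- function(draws, response) {
  x <- as.matrix(draws)
  n <- nrow(x); k <- ncol(x)
  if (n <= k + 2) stop("need more draws than parameters plus two", call. = FALSE)
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant parameter column(s): ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  }
  rx <- apply(x, 2, rank)
  ry <- rank(response)
  df <- n - 2 - (k - 1)
  out <- lapply(seq_len(k), function(j) {
    z <- cbind(1, rx[, -j, drop = FALSE])
    fit_x <- stats::lm.fit(z, rx[, j])
    fit_y <- stats::lm.fit(z, ry)
    if (fit_x$rank < ncol(z) || fit_y$rank < ncol(z))
      stop("singular regression while conditioning for ", colnames(x)[j],
           call. = FALSE)
    r <- stats::cor(fit_x$residuals, fit_y$residuals)
    tstat <- r * sqrt(df / (1 - r^2))
    data.frame(parameter = colnames(x)[j], prcc = r,
               p_value = 2 * stats::pt(-abs(tstat), df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
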