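# ---- triangular distribution ------------------------------------------------

#' Triangular distribution
#'
#' Quantile, distribution and sampling functions for the three-parameter
#' triangular distribution `(low, mode, high)` used as the prior of the
#' probabilistic sensitivity analysis. Degenerate ranges (`low == high`)
#' yield a point mass at the mode; `low == mode` or `mode == high` are the
#' one-sided triangles.
#'
#' @param u probabilities (for `qtriangular`), quantiles (for `ptriangular`).
#' @param n number of draws (for `rtriangular`).
#' @param low,mode,high distribution parameters, `low <= mode <= high`.
#' @name triangular
NULL

#' @rdname triangular
#' @export
qtriangular <- function(u, low, mode, high) {
  stopifnot(low <= mode, mode <= high, all(u >= 0), all(u <= 1))
  if (high == low) return(rep(mode, length(u)))
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' @rdname triangular
#' @export
ptriangular <- function(u, low, mode, high) {
  stopifnot(low <= mode, mode <= high)
  if (high == low) return(as.numeric(u >= mode))
  out <- numeric(length(u))
  left <- u <= mode
  if (mode > low)
    out[left] <- pmax(0, (u[left] - low))^2 / ((high - low) * (mode - low))
  out[!left] <- 1 - pmin(high - u[!left], high - mode)^2 /
    ((high - low) * (high - mode))
  out[u <= low] <- 0
  out[u >= high] <- 1
  out
}

#' @rdname triangular
#' @export
rtriangular <- function(n, low, mode, high) {
  qtriangular(stats::runif(n), low, mode, high)
}
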