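# ---- cost-effectiveness ranking ---------------------------------------------

#' Cost-effectiveness ratio
#'
#' Average cost per QALY of a single strategy, rounded to the nearest
#' integer euro per QALY as reported in results tables. Internal frontier
#' arithmetic elsewhere uses full precision.
#'
#' @param cost discounted cost in euros.
#' @param qaly discounted QALYs; must be positive.
#' @export
ce_ratio <- function(cost, qaly) {
  if (any(qaly <= 0)) stop("C/E ratio requires positive QALYs", call. = FALSE)
  round(cost / qaly)
}

#' Net monetary benefit
#'
#' @param cost,qaly discounted outcomes of a strategy.
#' @param wtp willingness-to-pay threshold in euros per QALY.
#' @return `qaly * wtp - cost`.
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(wtp >= 0)
  qaly * wtp - cost
}

#' Rank strategies by dominance and incremental cost-effectiveness
#'
#' Sorts strategies by ascending cost, flags as `DOMINATED` any strategy for
#' which another has lower-or-equal cost and greater-or-equal QALYs (at
#' least one strictly), removes by `EXTENDED_DOMINATED` any remaining
#' strategy whose incremental ratio exceeds that of the next more effective
#' one, and computes each frontier strategy's ICER against the preceding
#' frontier strategy. Exact ties in both cost and QALYs (within `1e-9`) are
#' kept on the frontier with an undefined (`NaN`) ICER.
#'
#' @param outcomes data frame with columns `strategy`, `cost`, `qaly`.
#' @return data frame of class `icer_table`: `strategy`, `cost`, `qaly`,
#'   `ce`, `status`, `icer` (full precision) and `icer_rounded`.
#' @export
build_icer_table <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  tab <- outcomes[order(outcomes$cost, outcomes$qaly), , drop = FALSE]
  n <- nrow(tab)
  status <- rep("ON_FRONTIER", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tie <- abs(tab$cost[j] - tab$cost[i]) <= 1e-9 &&
             abs(tab$qaly[j] - tab$qaly[i]) <= 1e-9
      if (tie) next
      if (tab$cost[j] <= tab$cost[i] && tab$qaly[j] >= tab$qaly[i]) {
        status[i] <- "DOMINATED"
        break
      }
    }
  }

  repeat {
    front <- which(status == "ON_FRONTIER")
    if (length(front) < 3) break
    icers <- diff(tab$cost[front]) / diff(tab$qaly[front])
    drop_i <- NULL
    for (k in seq_len(length(icers) - 1)) {
      if (isTRUE(icers[k] > icers[k + 1])) { drop_i <- front[k + 1]; break }
    }
    if (is.null(drop_i)) break
    status[drop_i] <- "EXTENDED_DOMINATED"
  }

  icer <- rep(NA_real_, n)
  front <- which(status == "ON_FRONTIER")
  if (length(front) > 1) {
    for (k in 2:length(front)) {
      dq <- tab$qaly[front[k]] - tab$qaly[front[k - 1]]
      dc <- tab$cost[front[k]] - tab$cost[front[k - 1]]
      icer[front[k]] <- if (abs(dq) <= 1e-12 && abs(dc) <= 1e-12) NaN else dc / dq
    }
  }

  tab$ce <- ce_ratio(tab$cost, tab$qaly)
  tab$status <- status
  tab$icer <- icer
  tab$icer_rounded <- ifelse(is.finite(icer), round(icer), icer)
  rownames(tab) <- NULL
  class(tab) <- c("icer_table", "data.frame")
  tab
}

#' Preferred strategy under a willingness-to-pay threshold
#'
#' Among frontier strategies, the most effective one whose ICER against the
#' preceding frontier strategy does not exceed the threshold; the cheapest
#' frontier strategy if none qualifies. Coincides with the strategy of
#' maximal net monetary benefit except at exact ties.
#'
#' @param table an [build_icer_table()] result.
#' @param wtp willingness-to-pay in euros per QALY.
#' @return the preferred strategy id.
#' @export
preferred_strategy <- function(table, wtp) {
  front <- table[table$status == "ON_FRONTIER", , drop = FALSE]
  ok <- is.na(front$icer) | is.nan(front$icer) | front$icer <= wtp
  # ICERs are non-decreasing along the frontier: take the last qualifying row
  sel <- front[ok, , drop = FALSE]
  if (!nrow(sel)) front$strategy[1] else sel$strategy[nrow(sel)]
}

#' @export
print.icer_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$icer <- ifelse(is.finite(y$icer), format(round(y$icer), big.mark = " "), "")
  y$icer_rounded <- NULL
  print(y, ...)
  invisible(x)
}
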