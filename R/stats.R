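# Cross-condition comparison: pooled-variance unpaired two-tailed t-test
# and fold differences.

#' Compare a metric between two conditions
#'
#' Student's unpaired, two-tailed t-test with pooled variance (no Welch
#' correction), plus the fold difference of the group means
#' (`mean(valuesA) / mean(valuesB)`). When the pooled variance is zero the
#' convention is `p = 1` for equal means and `p = 0` otherwise.
#'
#' @param valuesA,valuesB numeric vectors of per-cell values (each n >= 2).
#' @param labels condition labels, length 2.
#' @param metric name of the compared quantity.
#' @return A [ConditionComparison-class].
#' @examples
#' compareConditions(c(25, 26, 24), c(10, 11, 9),
#'                   labels = c("Early-On", "Late-On"), metric = "bundle GFP")
#' @export
compareConditions <- function(valuesA, valuesB, labels = c("A", "B"),
                              metric = "intensity") {
  valuesA <- valuesA[!is.na(valuesA)]
  valuesB <- valuesB[!is.na(valuesB)]
  nA <- length(valuesA)
  nB <- length(valuesB)
  if (nA < 2L || nB < 2L) stop("each group needs n >= 2")
  mA <- mean(valuesA)
  mB <- mean(valuesB)
  sA <- stats::sd(valuesA)
  sB <- stats::sd(valuesB)
  df <- nA + nB - 2L
  sp2 <- ((nA - 1L) * sA^2 + (nB - 1L) * sB^2) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  if (se == 0) {
    tStat <- if (mA == mB) 0 else sign(mA - mB) * Inf
    p <- if (mA == mB) 1 else 0
  } else {
    tStat <- (mA - mB) / se
    p <- 2 * stats::pt(-abs(tStat), df)
  }
  new("ConditionComparison", metric = metric, labels = labels,
      means = c(mA, mB), sds = c(sA, sB), ns = c(nA, nB),
      foldDifference = mA / mB, tStatistic = tStat, pValue = p)
}
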