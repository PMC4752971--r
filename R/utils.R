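# Small shared utilities.

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Area under the ROC curve
#'
#' Rank-statistic AUROC (equivalent to the Wilcoxon statistic), with average
#' ranks for ties.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) vector, `TRUE` = positive.
#' @return AUROC in \[0, 1\]; `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' @param predicted logical (or 0/1) predicted class.
#' @param actual logical (or 0/1) true class.
#' @return MCC in \[-1, 1\]; 0 when a marginal is degenerate.
#' @export
mcc <- function(predicted, actual) {
  p <- as.logical(predicted); a <- as.logical(actual)
  tp <- sum(p & a); tn <- sum(!p & !a)
  fp <- sum(p & !a); fn <- sum(!p & a)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}
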