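#' Holm sequentially rejective multiple-testing procedure
#'
#' Sorts the p-values ascending and compares the i-th smallest against
#' `alpha / (m - i + 1)`, rejecting while the comparison (non-strict, <=)
#' succeeds and stopping at the first failure; all later hypotheses are
#' retained. Controls the family-wise error rate at `alpha` and is uniformly
#' more powerful than the Bonferroni correction.
#'
#' Ties are ordered stably by input position; because the thresholds are
#' applied sequentially in sorted order, tied p-values at the stopping
#' boundary are all rejected or all retained together.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error level in (0, 1).
#' @return Data frame in input order with columns `p`, `rank` (position in
#'   the sorted order), `threshold` (`alpha / (m - rank + 1)`) and `reject`;
#'   the number of hypotheses `m` is attached as attribute `"m"`.
#' @examples
#' holm(c(0.01, 0.02, 0.03), alpha = 0.05)$reject  # all TRUE
#' @export
holm <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  m <- length(p)
  if (m == 0L) {
    out <- data.frame(p = numeric(0), rank = integer(0),
                      threshold = numeric(0), reject = logical(0))
    attr(out, "m") <- 0L
    return(out)
  }
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  ord <- order(p)                      # stable: ties keep input order
  thresholds <- alpha / (m - seq_len(m) + 1L)
  ok <- p[ord] <= thresholds
  first_fail <- match(FALSE, ok, nomatch = m + 1L)
  reject_sorted <- seq_len(m) < first_fail
  out <- data.frame(p = p, rank = NA_integer_, threshold = NA_real_,
                    reject = NA)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thresholds
  out$reject[ord] <- reject_sorted
  attr(out, "m") <- m
  out
}

#' Bonferroni correction (comparator)
#'
#' Rejects hypothesis i iff `p[i] <= alpha / m`. Provided as the classical
#' comparator; its rejection set is always a subset of Holm's at the same
#' level.
#'
#' @inheritParams holm
#' @return Logical vector of rejection flags in input order.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(p) == 0L) return(logical(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p <= alpha / length(p)
}
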