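#' Collapse one prediction-CFA cell to its fourfold table
#'
#' Dichotomizes a contingency table over predictors plus criterion into
#' "this predictor configuration vs all others" against "this criterion
#' category vs all others", giving the 2x2 table (a, b, c, d) whose joint
#' cell a is the observed count of the configuration-category pair.
#'
#' @param table A `cfa_table` over the predictor attributes followed by the
#'   criterion attribute (the criterion is the last attribute).
#' @param predictor_configuration Integer vector of category codes, one per
#'   predictor.
#' @param criterion_category Integer code of the criterion category.
#' @return Named numeric vector `c(a, b, c, d)` with
#'   `a + b + c + d == table$N`.
#' @export
derive_fourfold <- function(table, predictor_configuration, criterion_category) {
  np <- length(table$attributes) - 1L
  if (length(predictor_configuration) != np)
    stop("predictor_configuration must have ", np, " codes")
  crit_attr <- table$attributes[[np + 1L]]
  if (criterion_category < 1L || criterion_category > n_categories(crit_attr))
    stop("criterion category out of range")
  pred_codes <- table$configs[, seq_len(np), drop = FALSE]
  in_config <- colSums(t(pred_codes) != as.integer(predictor_configuration)) == 0L
  in_cat <- table$configs[, np + 1L] == criterion_category
  a <- sum(table$counts[in_config & in_cat])
  b <- sum(table$counts[in_config & !in_cat])
  cc <- sum(table$counts[!in_config & in_cat])
  d <- table$N - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher exact test of a fourfold table
#'
#' Exact upper-tail probability `P(A >= a)` of the joint cell under the
#' hypergeometric distribution with both margins of the 2x2 table fixed --
#' the test of over-representation of the joint incidence used for
#' prediction types. Point probabilities are accumulated in log space, so
#' the tail is accurate even at cohort sizes in the thousands.
#'
#' @param a,b,c,d Cell counts of the fourfold table (vectors are paired
#'   elementwise). `a` is the joint configuration-category cell.
#' @param lower Also return the lower tail `P(A <= a)` (antitype direction)
#'   as attribute `"p_lower"`.
#' @return Numeric vector of upper-tail p-values in (0, 1]; `p = 1` whenever
#'   `a` is at its minimum feasible value given the margins.
#' @examples
#' fisher_one_sided(5, 0, 0, 5)   # 1/252
#' fisher_one_sided(3, 1, 1, 3)   # 17/70
#' @export
fisher_one_sided <- function(a, b, c, d, lower = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  p_up <- numeric(n)
  p_lo <- if (lower) numeric(n) else NULL
  for (i in seq_len(n)) {
    N <- a[i] + b[i] + c[i] + d[i]
    m <- a[i] + b[i]          # configuration margin
    k <- a[i] + c[i]          # criterion-category margin
    j_min <- max(0, m + k - N)
    j_max <- min(m, k)
    j <- j_min:j_max
    # log point masses of the noncentral-free hypergeometric at fixed margins
    logp <- lchoose(k, j) + lchoose(N - k, m - j) - lchoose(N, m)
    p_up[i] <- log_tail_sum(logp, j >= a[i])
    if (lower) p_lo[i] <- log_tail_sum(logp, j <= a[i])
  }
  p_up <- pmin(p_up, 1)
  if (lower) attr(p_up, "p_lower") <- pmin(p_lo, 1)
  p_up
}

# sum exp(logp[sel]) stably
log_tail_sum <- function(logp, sel) {
  lp <- logp[sel]
  if (!length(lp)) return(0)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

#' Run a prediction CFA over all (or selected) cells
#'
#' For every predictor-configuration x criterion-category cell, derives the
#' fourfold table and computes the one-sided Fisher exact p-value for
#' over-representation of the joint incidence. With `p` predictor
#' configurations and a `K`-category criterion this tests `p * K` cells
#' (144 in the dialysis-cohort design).
#'
#' @param records Data frame of categorized records with one column per
#'   design attribute; ignored when `table` is given.
#' @param design A [design_spec()].
#' @param cells Optional data frame restricting testing to a subset of
#'   cells (confirmatory use): predictor code columns named as in the
#'   design plus a `criterion` column. Cells are tested in full-table row
#'   order regardless of the order given.
#' @param table Optional pre-built `cfa_table` over predictors + criterion.
#' @param antitypes If `TRUE`, also report the lower-tail p-value
#'   (`p_lower` column); prediction types use the upper tail only.
#' @return Data frame with one row per tested cell, ordered by predictor
#'   configuration (lexicographic, last predictor fastest) and criterion
#'   category within configuration: predictor code columns, `criterion`,
#'   `criterion_label`, fourfold counts `a`, `b`, `c`, `d`, `expected_a`
#'   (independence expectation of the joint cell) and `p`.
#' @export
run_prediction_cfa <- function(records = NULL, design, cells = NULL,
                               table = NULL, antitypes = FALSE) {
  attrs <- design_attributes(design)
  if (is.null(table)) {
    if (is.null(records) || nrow(records) == 0L)
      stop("no records to analyze")
    table <- tabulate_records(records, attrs)
  }
  if (table$N == 0L) stop("no records to analyze")
  np <- length(design$predictors)
  K <- n_categories(design$criterion)
  pred_configs <- enumerate_configurations(design$predictors)
  grid <- pred_configs[rep(seq_len(nrow(pred_configs)), each = K), ,
                       drop = FALSE]
  crit <- rep(seq_len(K), nrow(pred_configs))
  if (!is.null(cells)) {
    keep <- match_cells(grid, crit, cells, predictor_names(design))
    grid <- grid[keep, , drop = FALSE]
    crit <- crit[keep]
  }
  # margins once, joint counts per cell
  pred_key <- config_string(table$configs[, seq_len(np), drop = FALSE])
  cfg_totals <- rowsum(table$counts, pred_key, reorder = FALSE)
  cfg_key <- rownames(cfg_totals)
  crit_codes <- table$configs[, np + 1L]
  cat_totals <- vapply(seq_len(K), function(k)
    sum(table$counts[crit_codes == k]), 0)
  cell_key <- paste(pred_key, crit_codes)
  a <- table$counts[match(paste(config_string(grid), crit), cell_key)]
  a[is.na(a)] <- 0L
  m <- cfg_totals[match(config_string(grid), cfg_key), 1L]
  m[is.na(m)] <- 0L
  b <- m - a
  cc <- cat_totals[crit] - a
  d <- table$N - a - b - cc
  p <- fisher_one_sided(a, b, cc, d, lower = antitypes)
  out <- as.data.frame(grid)
  out$criterion <- crit
  out$criterion_label <- design$criterion$categories[crit]
  out$a <- as.integer(a); out$b <- as.integer(b)
  out$c <- as.integer(cc); out$d <- as.integer(d)
  out$expected_a <- (a + b) * (a + cc) / table$N
  out$p <- as.numeric(p)
  if (antitypes) out$p_lower <- attr(p, "p_lower")
  rownames(out) <- NULL
  out
}

# row indices of (grid, crit) present in a candidate cell data frame
match_cells <- function(grid, crit, cells, pred_names) {
  missing_cols <- setdiff(c(pred_names, "criterion"), names(cells))
  if (length(missing_cols))
    stop("cells must have columns: ", paste(missing_cols, collapse = ", "))
  want <- paste(do.call(paste, c(cells[pred_names], sep = "")), cells$criterion)
  have <- paste(config_string(grid), crit)
  keep <- have %in% want
  if (sum(keep) != length(unique(want)))
    stop("some requested cells are not cells of this design")
  which(keep)
}
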