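#' Cross-classify records into a multiway contingency table
#'
#' Counts how many records exhibit each configuration of the given
#' attributes. Every cell of the full cross-product is present, zero cells
#' explicitly so.
#'
#' @param records Data frame with one column per attribute (matched by
#'   attribute name) holding 1-based integer category codes, or character /
#'   factor values matching the attribute's category labels.
#' @param attributes List of [attribute_spec()] objects.
#' @return An object of class `cfa_table`: a list with elements
#'   `attributes`, `configs` (integer matrix, one row per cell in
#'   enumeration order), `counts` (integer vector aligned with `configs`)
#'   and `N` (total count).
#' @examples
#' d <- control_preference_design()
#' rec <- data.frame(M1_info = c(1, 1, 2), M2_trust = c(2, 2, 1))
#' tabulate_records(rec, d$predictors[1:2])
#' @export
tabulate_records <- function(records, attributes) {
  if (inherits(attributes, "cfa_attribute")) attributes <- list(attributes)
  configs <- enumerate_configurations(attributes)
  nms <- colnames(configs)
  missing_cols <- setdiff(nms, names(records))
  if (length(missing_cols))
    stop("records lack attribute column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(records)
  codes <- matrix(0L, nrow = n, ncol = length(attributes))
  for (j in seq_along(attributes)) {
    codes[, j] <- encode_category(records[[nms[j]]], attributes[[j]])
  }
  # map each record to its cell index in enumeration order
  # (last attribute varies fastest)
  card <- vapply(attributes, n_categories, 0L)
  if (n > 0L) {
    idx <- rep(0L, n)
    for (j in seq_along(attributes)) idx <- idx * card[j] + (codes[, j] - 1L)
    counts <- tabulate(idx + 1L, nbins = prod(card))
  } else {
    counts <- integer(prod(card))
  }
  structure(list(attributes = attributes, configs = configs,
                 counts = as.integer(counts), N = n),
            class = "cfa_table")
}

# integer codes from raw column values; validates range and labels
encode_category <- function(x, attr) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    code <- match(x, attr$categories)
    if (anyNA(code)) {
      bad <- which(is.na(code))[1L]
      stop("record ", bad, ": value '", x[bad], "' is not a category of '",
           attr$name, "' (", paste(attr$categories, collapse = ", "), ")")
    }
    return(as.integer(code))
  }
  code <- as.integer(x)
  bad <- which(is.na(code) | code < 1L | code > n_categories(attr))
  if (length(bad))
    stop("record ", bad[1L], ": code ", x[bad[1L]], " out of range for '",
         attr$name, "' (1..", n_categories(attr), ")")
  code
}

#' @export
print.cfa_table <- function(x, ...) {
  cat("<contingency table> ", nrow(x$configs), " cells over ",
      paste(vapply(x$attributes, `[[`, "", "name"), collapse = " x "),
      ", N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cfa_table <- function(x, ...) {
  out <- as.data.frame(x$configs)
  out$count <- x$counts
  out
}

# marginal count of category k of attribute j, by explicit summation
marginal_counts <- function(table) {
  lapply(seq_along(table$attributes), function(j) {
    k <- n_categories(table$attributes[[j]])
    vapply(seq_len(k), function(cat)
      sum(table$counts[table$configs[, j] == cat]), 0)
  })
}

#' Expected cell frequencies under total independence
#'
#' The first-order CFA base model: all attributes mutually independent, so
#' the expected frequency of a configuration is N times the product of its
#' categories' marginal proportions.
#'
#' @param table A `cfa_table` from [tabulate_records()], with `N > 0`.
#' @param configuration Optional integer vector (one code per attribute)
#'   selecting a single cell; by default expected frequencies for all cells
#'   are returned in enumeration order.
#' @return Numeric vector of expected frequencies (summing to N over the
#'   full table), or a single value when `configuration` is given.
#' @export
expected_independence <- function(table, configuration = NULL) {
  if (table$N == 0L) stop("expected frequencies undefined for an empty table (N = 0)")
  marg <- marginal_counts(table)
  expected <- rep(as.numeric(table$N), nrow(table$configs))
  for (j in seq_along(table$attributes))
    expected <- expected * marg[[j]][table$configs[, j]] / table$N
  if (is.null(configuration)) return(expected)
  stopifnot(length(configuration) == length(table$attributes))
  i <- config_row_index(table$configs, configuration)
  expected[i]
}

config_row_index <- function(configs, configuration) {
  hit <- which(colSums(t(configs) != as.integer(configuration)) == 0L)
  if (length(hit) != 1L) stop("configuration not found in table")
  hit
}

#' Per-cell chi-square statistic and p-value
#'
#' The classical CFA cell test: `(observed - expected)^2 / expected`
#' referred to the chi-square distribution with one degree of freedom
#' (upper tail).
#'
#' @param observed,expected Observed count(s) and expected frequency(ies);
#'   vectors are paired elementwise. All `expected` must be positive.
#' @return Data frame with columns `x2` and `p`.
#' @export
cell_chi_square <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected frequency must be positive (degenerate cell)")
  x2 <- (observed - expected)^2 / expected
  data.frame(x2 = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Classify a cell as CFA type, antitype or neither
#'
#' A type is a configuration observed significantly more often than its
#' base-model expectation, an antitype one observed significantly less
#' often.
#'
#' @param observed,expected,p Cell count, expected frequency and cell-test
#'   p-value (vectors recycled elementwise).
#' @param alpha Per-cell significance level.
#' @return Character vector: `"type"`, `"antitype"` or `"neither"`.
#' @export
classify_cell <- function(observed, expected, p, alpha = 0.05) {
  ifelse(p < alpha & observed > expected, "type",
         ifelse(p < alpha & observed < expected, "antitype", "neither"))
}

#' First-order chi-square CFA of a record set
#'
#' Runs the per-cell chi-square test against the total-independence base
#' model for every configuration of the given attributes. This is the
#' classical (non-prediction) CFA; it treats all attributes symmetrically
#' and is reported separately from the Fisher-based prediction CFA.
#' Cells with expected frequency zero (a zero marginal) are untestable and
#' returned with `NA` statistics.
#'
#' @param records Data frame of categorized records (see
#'   [tabulate_records()]); alternatively pass a ready `cfa_table` as
#'   `table`.
#' @param attributes List of [attribute_spec()] objects (ignored when
#'   `table` is given).
#' @param alpha Per-cell significance level for type/antitype flags.
#' @param table Optional pre-built `cfa_table`.
#' @return Data frame with one row per configuration: category codes,
#'   `observed`, `expected`, `x2`, `p`, `classification`.
#' @export
cfa_chisq <- function(records = NULL, attributes = NULL, alpha = 0.05,
                      table = NULL) {
  if (is.null(table)) table <- tabulate_records(records, attributes)
  expected <- expected_independence(table)
  out <- as.data.frame(table$configs)
  out$observed <- table$counts
  out$expected <- expected
  out$x2 <- NA_real_
  out$p <- NA_real_
  out$classification <- "untestable"
  ok <- expected > 0
  if (any(ok)) {
    cs <- cell_chi_square(out$observed[ok], expected[ok])
    out$x2[ok] <- cs$x2
    out$p[ok] <- cs$p
    out$classification[ok] <- classify_cell(out$observed[ok], expected[ok],
                                            cs$p, alpha)
  }
  out
}

#' Write / read a contingency table in delimited long format
#'
#' One row per configuration (integer codes) plus the cell count;
#' round-trips bit-exactly.
#'
#' @param table A `cfa_table`.
#' @param path File path.
#' @param sep Field delimiter.
#' @return `read_cfa_table()` returns a `cfa_table`; the attribute list must
#'   be supplied since labels are not stored in the file.
#' @export
write_cfa_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cfa_table
#' @param attributes List of [attribute_spec()] matching the stored columns.
#' @export
read_cfa_table <- function(path, attributes, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  configs <- enumerate_configurations(attributes)
  nms <- colnames(configs)
  if (!all(c(nms, "count") %in% names(df)))
    stop("file does not match the attribute list: expected columns ",
         paste(c(nms, "count"), collapse = ", "))
  key_file <- do.call(paste, c(df[nms], sep = "\r"))
  key_full <- do.call(paste, c(as.data.frame(configs), sep = "\r"))
  counts <- df$count[match(key_full, key_file)]
  if (anyNA(counts)) stop("file is missing cells of the full cross-product")
  structure(list(attributes = attributes, configs = configs,
                 counts = as.integer(counts), N = sum(counts)),
            class = "cfa_table")
}
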