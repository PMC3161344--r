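#' Read survey or categorized records from a delimited text file
#'
#' Comma- or tab-separated, one header row, one row per respondent. Blank
#' fields are read as missing and preserved (missingness is resolved by
#' [categorize_records()], never here). Unknown columns relative to the
#' expected layout raise an error naming them.
#'
#' @param path File path.
#' @param sep Field delimiter; guessed from the file extension by default
#'   (`.csv` comma, otherwise tab).
#' @param expected Optional character vector of required column names.
#' @return Data frame of records.
#' @export
read_records <- function(path, sep = NULL, expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(expected)) {
    missing_cols <- setdiff(expected, names(df))
    if (length(missing_cols))
      stop("file ", path, " lacks expected column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname read_records
#' @param records Data frame to write.
#' @export
write_records <- function(records, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write a pipeline report as delimited result tables
#'
#' Emits up to four files under a common prefix, all deterministic given
#' the report: the wide per-half p-value matrix (one row per predictor
#' configuration, one p column per criterion category and half, flagged
#' rows carrying the confirmed labels), the candidate list, the confirmed
#' types in profile layout (one column per type, one row per attribute),
#' and a stage-by-stage run log sufficient to audit the two-stage flow
#' (seed, alpha levels, counts in/out, Holm family size and thresholds).
#'
#' @param report A `cfa_report` from [run_full_pipeline()] or
#'   [reproduce_published_analysis()].
#' @param prefix Output path prefix (directory must exist); files are
#'   `<prefix>_pvalues.tsv`, `<prefix>_candidates.tsv`,
#'   `<prefix>_confirmed.tsv`, `<prefix>_log.txt`.
#' @param digits Decimal places for printed p-values.
#' @param sep Field delimiter.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(report, prefix, digits = 6, sep = "\t") {
  design <- report$design
  pred <- predictor_names(design)
  K <- n_categories(design$criterion)
  fmt <- function(p) formatC(p, format = "f", digits = digits)

  # wide matrix: predictor codes, then exploratory and confirmatory p per
  # criterion category
  expl <- report$exploratory
  conf <- report$confirmatory
  base <- expl[expl$criterion == 1L, pred, drop = FALSE]
  wide <- base
  for (k in seq_len(K))
    wide[[paste0("expl_", design$criterion$categories[k])]] <-
      fmt(expl$p[expl$criterion == k])
  for (k in seq_len(K))
    wide[[paste0("conf_", design$criterion$categories[k])]] <-
      fmt(conf$p[conf$criterion == k])
  confirmed <- report$confirmed[report$confirmed$reject %in% TRUE, ,
                                drop = FALSE]
  wide$flag <- ""
  if (nrow(confirmed)) {
    key_wide <- do.call(paste, c(base, sep = ""))
    key_conf <- do.call(paste, c(confirmed[pred], sep = ""))
    wide$flag[match(key_conf, key_wide)] <- confirmed$label
  }
  paths <- c(pvalues = paste0(prefix, "_pvalues.tsv"),
             candidates = paste0(prefix, "_candidates.tsv"),
             confirmed = paste0(prefix, "_confirmed.tsv"),
             log = paste0(prefix, "_log.txt"))
  utils::write.table(wide, paths["pvalues"], sep = sep, row.names = FALSE,
                     quote = FALSE)

  cand <- report$candidates
  cand_out <- cand[c(pred, "criterion", "criterion_label")]
  cand_out$p <- fmt(cand$p)
  utils::write.table(cand_out, paths["candidates"], sep = sep,
                     row.names = FALSE, quote = FALSE)

  # profile layout: one column per confirmed type, rows = attributes
  if (nrow(confirmed)) {
    prof <- data.frame(attribute = c(pred, design$criterion$name, "p", "n"))
    for (r in seq_len(nrow(confirmed))) {
      col <- c(vapply(seq_along(pred), function(j)
        design$predictors[[j]]$categories[confirmed[[pred[j]]][r]], ""),
        design$criterion$categories[confirmed$criterion[r]],
        fmt(confirmed$p[r]),
        as.character(confirmed$n_joint[r]))
      prof[[confirmed$label[r]]] <- col
    }
  } else {
    prof <- data.frame(attribute = character(0))
  }
  utils::write.table(prof, paths["confirmed"], sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")

  m <- attr(report$confirmed, "m")
  log_lines <- c(
    "stage\tdetail",
    paste0("seed\t", if (!is.null(report$seed)) report$seed else "fixture"),
    paste0("alpha_explore\t", design$alpha_explore),
    paste0("alpha_family\t", design$alpha_family),
    paste0("records_half_A\t",
           if (!is.null(report$split)) nrow(report$split$half_A) else "fixture"),
    paste0("records_half_B\t",
           if (!is.null(report$split)) nrow(report$split$half_B) else "fixture"),
    paste0("cells_tested_per_half\t", nrow(report$exploratory)),
    paste0("exploratory_candidates\t", nrow(report$candidates)),
    paste0("holm_family_size\t", if (!is.null(m)) m else nrow(report$candidates)),
    paste0("holm_thresholds\t",
           paste(fmt(sort(report$confirmed$threshold)), collapse = ",")),
    paste0("confirmed_types\t", nrow(confirmed)))
  writeLines(log_lines, paths["log"])
  invisible(paths)
}
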