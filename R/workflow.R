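# run code with a private RNG stream so package randomness never disturbs
# (or depends on) the caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Randomly split records into two equal-sized halves
#'
#' Uniform random partition into halves of size ceiling(n/2) and
#' floor(n/2) (configurable proportion), deterministic given the seed.
#' Half A is used for the exploratory screen, half B for confirmation.
#'
#' @param records Data frame of records (>= 2 rows).
#' @param seed Integer seed; the split is a pure function of
#'   (records, seed, prop).
#' @param prop Fraction of records assigned to half A.
#' @return List with elements `half_A`, `half_B` (disjoint row subsets
#'   whose union is the input) and `seed`.
#' @export
split_sample <- function(records, seed, prop = 0.5) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split")
  stopifnot(prop > 0, prop < 1)
  n_a <- ceiling(n * prop)
  idx <- with_seed(seed, sample.int(n, n_a))
  list(half_A = records[sort(idx), , drop = FALSE],
       half_B = records[setdiff(seq_len(n), sort(idx)), , drop = FALSE],
       seed = seed)
}

#' Exploratory screen: flag candidate prediction types
#'
#' Flags every cell whose unadjusted one-sided Fisher p-value falls
#' strictly below the screening level. No multiplicity adjustment is
#' applied at this stage; the flagged cells are hypotheses to be confirmed
#' in the held-out half.
#'
#' @param results Prediction-CFA results from [run_prediction_cfa()] on the
#'   exploratory half.
#' @param alpha_explore Screening level (strict `<` comparison).
#' @return The subset of `results` with `p < alpha_explore`, in table row
#'   order, with an `exploratory_p` column aliasing `p`.
#' @export
exploratory_screen <- function(results, alpha_explore = 0.05) {
  out <- results[results$p < alpha_explore, , drop = FALSE]
  out$exploratory_p <- out$p
  rownames(out) <- NULL
  out
}

#' Confirmatory test of the screened candidates under Holm control
#'
#' Computes (or takes) the confirmatory-half Fisher p-values at exactly the
#' candidate cells and applies the Holm procedure over those m tests.
#' Confirmed types are labelled `T1`, `T2`, ... in the row order of the
#' full results table (not by p-value rank), matching the published
#' labelling convention.
#'
#' @param results Prediction-CFA results on the confirmatory half (all
#'   cells, or at least the candidate cells).
#' @param candidates Candidate cells from [exploratory_screen()] (predictor
#'   code columns + `criterion`).
#' @param alpha_family Family-wise level for Holm.
#' @param design The [design_spec()] (for predictor column names).
#' @return Data frame of all candidate cells in table row order with the
#'   confirmatory `p`, `holm_rank`, `threshold`, `reject`, `n_joint` (the
#'   fourfold `a` in the confirmatory half, when available) and `label`
#'   (`T1`.. for confirmed cells, `NA` otherwise). Attribute `"m"` records
#'   the family size. Zero candidates yields an empty frame with a warning.
#' @export
confirmatory_test <- function(results, candidates, alpha_family = 0.05,
                              design = control_preference_design()) {
  pred <- predictor_names(design)
  if (nrow(candidates) == 0L) {
    warning("no candidate cells to confirm")
    out <- candidates
    out$label <- character(0)
    attr(out, "m") <- 0L
    return(out)
  }
  key_res <- paste(do.call(paste, c(results[pred], sep = "")),
                   results$criterion)
  key_cand <- paste(do.call(paste, c(candidates[pred], sep = "")),
                    candidates$criterion)
  hit <- match(key_cand, key_res)
  if (anyNA(hit))
    stop("candidate cell(s) absent from confirmatory results: ",
         paste(key_cand[is.na(hit)], collapse = "; "))
  out <- results[sort(hit), , drop = FALSE]          # table row order
  h <- holm(out$p, alpha_family)
  out$holm_rank <- h$rank
  out$threshold <- h$threshold
  out$reject <- h$reject
  out$n_joint <- if ("a" %in% names(out)) out$a else NA_integer_
  out$label <- NA_character_
  out$label[out$reject] <- paste0("T", seq_len(sum(out$reject)))
  rownames(out) <- NULL
  attr(out, "m") <- attr(h, "m")
  out
}

#' Run the full two-stage split-half prediction-CFA pipeline
#'
#' Random split, exploratory prediction CFA without alpha adjustment on
#' half A, confirmatory prediction CFA restricted to the flagged cells on
#' half B with Holm family-wise control.
#'
#' @param records Categorized complete-case records (integer codes, one
#'   column per design attribute).
#' @param design A [design_spec()].
#' @param seed Integer seed driving the split.
#' @param prop Split proportion, see [split_sample()].
#' @return A list of class `cfa_report`: `split`, `exploratory` (full
#'   results for half A), `candidates`, `confirmatory` (full results for
#'   half B), `confirmed` (Holm table over the candidates), and `design`.
#' @export
run_full_pipeline <- function(records, design = control_preference_design(),
                              seed = 1L, prop = 0.5) {
  split <- split_sample(records, seed, prop)
  exploratory <- run_prediction_cfa(split$half_A, design)
  candidates <- exploratory_screen(exploratory, design$alpha_explore)
  confirmatory <- run_prediction_cfa(split$half_B, design)
  confirmed <- if (nrow(candidates) > 0L)
    confirmatory_test(confirmatory, candidates, design$alpha_family, design)
  else {
    warning("exploratory screen flagged no candidates")
    cbind(candidates, label = character(0))
  }
  structure(list(split = split, exploratory = exploratory,
                 candidates = candidates, confirmatory = confirmatory,
                 confirmed = confirmed, design = design, seed = seed),
            class = "cfa_report")
}

#' @export
print.cfa_report <- function(x, ...) {
  n_conf <- sum(x$confirmed$reject %in% TRUE)
  cat("<prediction-CFA report>\n")
  if (!is.null(x$split)) {
    cat("  split: ", nrow(x$split$half_A), " + ", nrow(x$split$half_B),
        " records (seed ", x$split$seed, ")\n", sep = "")
  } else {
    cat("  input: packaged printed p-value matrix (fixture mode)\n")
  }
  cat("  cells tested per half:", nrow(x$exploratory), "\n")
  cat("  exploratory candidates (p <", x$design$alpha_explore, "):",
      nrow(x$candidates), "\n")
  cat("  confirmed types (Holm, family-wise", x$design$alpha_family, "):",
      n_conf, "\n")
  if (n_conf > 0) {
    conf <- x$confirmed[x$confirmed$reject %in% TRUE, , drop = FALSE]
    pred <- predictor_names(x$design)
    cat("   ", paste0(conf$label, " = (",
                      do.call(paste, c(conf[pred], sep = "")), ")x",
                      conf$criterion, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Re-run the two-stage analysis on the packaged printed p-value matrix
#'
#' Fixture mode: the published application's raw cohort is not deposited,
#' but its full 48 x 3 x 2 matrix of Fisher p-values is. This entry point
#' applies the exploratory screen and the confirmatory Holm adjustment
#' directly to those printed values, reproducing the candidate list and the
#' confirmed type labels without access to the raw data. Fourfold counts
#' are unavailable in this mode (`n_joint` is `NA`).
#'
#' @param alpha_explore,alpha_family Significance levels.
#' @return A list of class `cfa_report` (without `split`): `exploratory`
#'   and `confirmatory` cell tables carrying the printed p-values,
#'   `candidates`, `confirmed`, and `fixture` (the packaged matrix).
#' @export
reproduce_published_analysis <- function(alpha_explore = 0.05,
                                         alpha_family = 0.05) {
  design <- control_preference_design(alpha_explore, alpha_family)
  fx <- fixture_table2()
  long <- fixture_as_results(fx, design)
  candidates <- exploratory_screen(long$exploratory, alpha_explore)
  confirmed <- confirmatory_test(long$confirmatory, candidates,
                                 alpha_family, design)
  structure(list(split = NULL, exploratory = long$exploratory,
                 candidates = candidates, confirmatory = long$confirmatory,
                 confirmed = confirmed, design = design, fixture = fx),
            class = "cfa_report")
}

# reshape the wide fixture into the long per-cell layout of
# run_prediction_cfa (p-values only; counts unknown)
fixture_as_results <- function(fx, design = control_preference_design()) {
  pred <- predictor_names(design)
  K <- n_categories(design$criterion)
  idx <- rep(seq_len(nrow(fx)), each = K)
  base <- fx[idx, paste0("M", seq_along(pred)), drop = FALSE]
  names(base) <- pred
  base$criterion <- rep(seq_len(K), nrow(fx))
  base$criterion_label <- design$criterion$categories[base$criterion]
  rownames(base) <- NULL
  expl <- conf <- base
  expl$p <- as.vector(t(as.matrix(
    fx[c("expl_active", "expl_collaborative", "expl_passive")])))
  conf$p <- as.vector(t(as.matrix(
    fx[c("conf_active", "conf_collaborative", "conf_passive")])))
  list(exploratory = expl, confirmatory = conf)
}
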