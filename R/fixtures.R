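#' The packaged printed p-value matrix of the dialysis-cohort application
#'
#' 48 predictor configurations x (3 exploratory + 3 confirmatory)
#' one-sided Fisher p-values, as printed to six decimals, plus the four
#' confirmed-type flags. The printed strings are preserved verbatim
#' alongside their numeric parse: one exploratory/confirmatory entry is
#' printed as `0.000000` (truncated or underflowed at the source; the raw
#' cell counts were never published, so it cannot be re-derived) and is
#' parsed as 0.
#'
#' @return Data frame with integer code columns `M1`..`M5`, numeric columns
#'   `expl_active`, `expl_collaborative`, `expl_passive`, `conf_active`,
#'   `conf_collaborative`, `conf_passive`, and `flag` / `flag_category`
#'   (`T1`..`T4` on the four confirmed cells, `NA` elsewhere). The printed
#'   6-decimal strings are attached as attribute `"printed"` (character
#'   matrix parallel to the six p columns).
#' @export
fixture_table2 <- function() {
  path <- system.file("extdata", "table2_pvalues.tsv", package = "predcfa",
                      mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = c(rep("integer", 5),
                                               rep("character", 6),
                                               "character", "integer"),
                          fill = TRUE, na.strings = c("", "NA"))
  pcols <- c("expl_active", "expl_collaborative", "expl_passive",
             "conf_active", "conf_collaborative", "conf_passive")
  printed <- as.matrix(df[pcols])
  for (col in pcols) df[[col]] <- as.numeric(df[[col]])
  stopifnot(nrow(df) == 48L,
            all(as.matrix(df[pcols]) >= 0 & as.matrix(df[pcols]) <= 1),
            sum(!is.na(df$flag)) == 4L)
  attr(df, "printed") <- printed
  df
}

#' Printed marginal distributions of the two half-samples
#'
#' The per-attribute category counts and proportions of the exploratory
#' (n = 1969) and confirmatory (n = 1914) complete-case half-samples, used
#' as the default marginals of the synthetic cohort generator and as the
#' targets of [reconstruct_paper_like_cohort()].
#'
#' @param sample `"exploratory"` or `"confirmatory"`.
#' @return List with `n` and, per design attribute (names as in
#'   [control_preference_design()]), the integer category counts in code
#'   order.
#' @export
table1_marginals <- function(sample = c("exploratory", "confirmatory")) {
  sample <- match.arg(sample)
  if (sample == "exploratory") {
    list(n = 1969L,
         M1_info = c(765L, 1204L),
         M2_trust = c(672L, 1297L),
         M3_pdm = c(750L, 1219L),
         M4_education = c(1297L, 672L),
         M5_age_band = c(519L, 947L, 503L),
         M6_control_pref = c(442L, 616L, 911L))
  } else {
    list(n = 1914L,
         M1_info = c(744L, 1170L),
         M2_trust = c(677L, 1237L),
         M3_pdm = c(747L, 1167L),
         M4_education = c(1313L, 601L),
         M5_age_band = c(462L, 935L, 517L),
         M6_control_pref = c(424L, 589L, 901L))
  }
}

#' Profiles of the four confirmed patient types
#'
#' The confirmed prediction types of the dialysis-cohort application:
#' predictor configuration, predicted control-preference role, and the
#' joint count n in the confirmatory half.
#'
#' @return Data frame with one row per type (`T1`..`T4`): integer code
#'   columns `M1`..`M5`, `criterion` (code) and `criterion_label`, and `n`.
#' @export
table3_types <- function() {
  data.frame(
    label = c("T1", "T2", "T3", "T4"),
    M1 = c(1L, 1L, 2L, 2L), M2 = c(2L, 2L, 1L, 2L),
    M3 = c(2L, 2L, 1L, 2L), M4 = c(1L, 1L, 2L, 2L),
    M5 = c(2L, 3L, 1L, 1L),
    criterion = c(3L, 3L, 1L, 1L),
    criterion_label = c("passive", "passive", "active", "active"),
    n = c(91L, 45L, 29L, 26L)
  )
}
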