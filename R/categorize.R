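#' Sum score of a set of ordinal items
#'
#' @param items Numeric vector (or one-row data frame) of item responses.
#' @param bounds Length-2 vector giving the legal response range.
#' @return The integer sum, or `NA` if any item is missing (records with
#'   missing items are excluded downstream, never imputed).
#' @export
sum_score <- function(items, bounds) {
  items <- as.numeric(unlist(items, use.names = FALSE))
  if (anyNA(items)) return(NA_integer_)
  if (any(items < bounds[1] | items > bounds[2]))
    stop("item response outside scale bounds [", bounds[1], ", ", bounds[2], "]")
  as.integer(sum(items))
}

# row-wise sum scores over a matrix of items; NA rows -> NA
sum_scores <- function(item_mat, bounds) {
  item_mat <- as.matrix(item_mat)
  out_of_bounds <- !is.na(item_mat) & (item_mat < bounds[1] | item_mat > bounds[2])
  if (any(out_of_bounds))
    stop("item response outside scale bounds [", bounds[1], ", ", bounds[2],
         "] in row ", which(rowSums(out_of_bounds) > 0)[1L])
  s <- rowSums(item_mat)
  as.integer(round(s))
}

#' Median dichotomization of sum scores
#'
#' Splits scores at the sample median into `low` and `high`. The split
#' point is computed once on the full (pre-split) sample and is meant to be
#' reused for both halves of the split-half workflow; pass it back via
#' `cut` to categorize further records against the same point.
#'
#' @param scores Numeric vector of sum scores (may contain `NA`; these stay
#'   `NA`). The cut is computed from the non-missing scores.
#' @param tie Side to which scores exactly equal to the median fall;
#'   default `"low"` (the conventional "<= median -> low" dichotomization).
#' @param cut Optional pre-computed split point overriding the sample
#'   median.
#' @return Character vector `"low"`/`"high"` with the split point attached
#'   as attribute `"cut"`.
#' @export
median_dichotomize <- function(scores, tie = c("low", "high"), cut = NULL) {
  tie <- match.arg(tie)
  if (length(scores) == 0L || all(is.na(scores))) stop("no scores to dichotomize")
  if (is.null(cut)) cut <- stats::median(scores, na.rm = TRUE)
  out <- ifelse(is.na(scores), NA_character_,
                ifelse(scores > cut, "high",
                       ifelse(scores < cut, "low",
                              if (tie == "low") "low" else "high")))
  attr(out, "cut") <- cut
  out
}

#' Mean split of sum scores
#'
#' Splits scores at the sample mean into `below_average` and
#' `above_average` (used where the median is degenerate, e.g. piled on the
#' scale maximum). Scores exactly equal to the mean follow `tie`
#' (default `"above"`); for non-integer means this case never occurs.
#'
#' @inheritParams median_dichotomize
#' @param tie Side for scores exactly equal to the mean.
#' @return Character vector `"below_average"`/`"above_average"` with
#'   attribute `"cut"`.
#' @export
mean_split <- function(scores, tie = c("above", "below"), cut = NULL) {
  tie <- match.arg(tie)
  if (length(scores) == 0L || all(is.na(scores))) stop("no scores to split")
  if (is.null(cut)) cut <- mean(scores, na.rm = TRUE)
  out <- ifelse(is.na(scores), NA_character_,
                ifelse(scores > cut, "above_average",
                       ifelse(scores < cut, "below_average",
                              if (tie == "above") "above_average" else "below_average")))
  attr(out, "cut") <- cut
  out
}

#' Majority-direction categorization of the PDM items
#'
#' The three participatory decision-making (PDM) items use different
#' response scales, so instead of a sum score each response level is mapped
#' to a direction (positive / negative / neutral) and the record is
#' categorized by a 2-of-3 majority: at least two items in the positive
#' direction gives `positive`, at least two negative gives `negative`, and
#' anything else is `undetermined` (treated as missing downstream).
#'
#' @param pdm_items Matrix or data frame with 3 columns of item responses
#'   (or a length-3 vector for a single record).
#' @param direction_map Integer-indexed character vector mapping each
#'   response level to `"positive"`, `"negative"` or `"neutral"`. The
#'   default treats levels 1-2 of a 5-point scale as positive, 3 as
#'   neutral, 4-5 as negative (items keyed so that low codes are the
#'   favorable pole); override to match the instrument in hand.
#' @return Character vector `"positive"`/`"negative"`/`"undetermined"`
#'   (`NA` when any item is missing).
#' @export
pdm_categorize <- function(pdm_items,
                           direction_map = c("positive", "positive", "neutral",
                                             "negative", "negative")) {
  if (is.null(dim(pdm_items))) pdm_items <- matrix(pdm_items, nrow = 1L)
  pdm_items <- as.matrix(pdm_items)
  if (ncol(pdm_items) != 3L) stop("pdm_categorize expects 3 items")
  bad <- !is.na(pdm_items) &
    (pdm_items < 1 | pdm_items > length(direction_map))
  if (any(bad)) stop("PDM response level outside the direction map")
  dir <- matrix(direction_map[as.integer(pdm_items)], ncol = 3L)
  npos <- rowSums(dir == "positive")
  nneg <- rowSums(dir == "negative")
  out <- rep("undetermined", nrow(pdm_items))
  out[npos >= 2L] <- "positive"
  out[nneg >= 2L] <- "negative"
  out[rowSums(is.na(pdm_items)) > 0L] <- NA_character_
  out
}

#' Age banding
#'
#' Maps age in years into the three analysis bands: `le55` (<= 55),
#' `56to75` (56-75), `ge76` (>= 76); boundaries inclusive as written.
#'
#' @param age_years Numeric vector of ages (positive).
#' @return Character vector of band labels (`NA` preserved).
#' @export
band_age <- function(age_years) {
  if (any(!is.na(age_years) & age_years <= 0))
    stop("age must be positive")
  ifelse(is.na(age_years), NA_character_,
         ifelse(age_years <= 55, "le55",
                ifelse(age_years <= 75, "56to75", "ge76")))
}

#' Binary education coding
#'
#' Codebook-driven mapping of raw credential labels to `low` (no secondary
#' school certificate or lower secondary school certificate) vs `high`
#' (secondary school certificate and higher).
#'
#' @param education_raw Character vector of credential labels.
#' @param codebook Named list with elements `low` and `high`, each a
#'   character vector of accepted labels.
#' @return Character vector `"low"`/`"high"` (`NA` preserved).
#' @export
binarize_education <- function(education_raw,
                               codebook = default_codebook()$education) {
  known <- c(codebook$low, codebook$high)
  bad <- !is.na(education_raw) & !(education_raw %in% known)
  if (any(bad))
    stop("unknown education label '", education_raw[which(bad)[1L]],
         "'; accepted labels: ", paste(known, collapse = ", "))
  ifelse(is.na(education_raw), NA_character_,
         ifelse(education_raw %in% codebook$low, "low", "high"))
}

#' Control-preference role from the five-option scale
#'
#' The control preferences scale offers five role descriptions: two
#' autonomous options (codes 1-2, active role), one shared option (code 3,
#' collaborative role) and two delegating options (codes 4-5, passive
#' role).
#'
#' @param option Integer vector of chosen options in 1..5.
#' @return Character vector `"active"`/`"collaborative"`/`"passive"`
#'   (`NA` preserved).
#' @export
map_control_preference <- function(option) {
  if (any(!is.na(option) & !(option %in% 1:5)))
    stop("control-preference option must be in 1..5")
  ifelse(is.na(option), NA_character_,
         ifelse(option <= 2, "active",
                ifelse(option == 3, "collaborative", "passive")))
}

#' Default categorization codebook
#'
#' Scale bounds, item counts, the PDM direction map, the education label
#' codebook, tie rules and (optionally) pre-computed split points, bundled
#' as the single source of categorization rules. Item keying and the
#' education label set are survey-specific; override the relevant entries
#' to match the instrument actually fielded.
#'
#' @param info_cut,trust_cut Optional pre-computed split points (sum-score
#'   scale) for the information and trust scales; by default the sample
#'   median / mean is used.
#' @param age_floor Minimum age for inclusion (adult cohort).
#' @return Named list of codebook entries.
#' @export
default_codebook <- function(info_cut = NULL, trust_cut = NULL,
                             age_floor = 18) {
  list(
    info = list(n_items = 8L, bounds = c(1, 5), cut = info_cut,
                tie = "low", higher_is_high = TRUE),
    trust = list(n_items = 5L, bounds = c(1, 4), cut = trust_cut,
                 tie = "above"),
    pdm = list(direction_map = c("positive", "positive", "neutral",
                                 "negative", "negative")),
    education = list(
      low = c("no certificate", "lower secondary school certificate"),
      high = c("secondary school certificate", "higher education entrance",
               "university degree")),
    age_floor = age_floor
  )
}

#' Categorize raw survey records into the six analysis attributes
#'
#' Applies the full measurement pipeline -- sum scores and median
#' dichotomization for information-seeking preference, sum scores and mean
#' split for trust, 2-of-3 majority direction for the PDM style, the
#' education codebook, age banding and the control-preference mapping --
#' and keeps complete cases only (listwise deletion; undetermined PDM
#' counts as missing).
#'
#' @param records Data frame with columns `respondent_id`, `info_1` ..
#'   `info_8`, `trust_1` .. `trust_5`, `pdm_1` .. `pdm_3`,
#'   `education_raw`, `age_years`, `control_pref_option`.
#' @param codebook See [default_codebook()].
#' @return Data frame of complete cases with columns `respondent_id` and
#'   the six integer-coded attributes `M1_info`, `M2_trust`, `M3_pdm`,
#'   `M4_education`, `M5_age_band`, `M6_control_pref` (codes follow
#'   [control_preference_design()]). Attributes: `"log"`, a named count of
#'   exclusions per reason, and `"cuts"`, the split points used.
#' @export
categorize_records <- function(records, codebook = default_codebook()) {
  need <- c("respondent_id",
            paste0("info_", seq_len(codebook$info$n_items)),
            paste0("trust_", seq_len(codebook$trust$n_items)),
            paste0("pdm_", 1:3), "education_raw", "age_years",
            "control_pref_option")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))

  info_items <- records[paste0("info_", seq_len(codebook$info$n_items))]
  trust_items <- records[paste0("trust_", seq_len(codebook$trust$n_items))]
  info_score <- sum_scores(info_items, codebook$info$bounds)
  trust_score <- sum_scores(trust_items, codebook$trust$bounds)

  info_cat <- median_dichotomize(info_score, tie = codebook$info$tie,
                                 cut = codebook$info$cut)
  if (!isTRUE(codebook$info$higher_is_high))
    info_cat[] <- c(low = "high", high = "low")[info_cat]
  trust_cat <- mean_split(trust_score, tie = codebook$trust$tie,
                          cut = codebook$trust$cut)
  pdm_cat <- pdm_categorize(records[paste0("pdm_", 1:3)],
                            codebook$pdm$direction_map)
  edu_cat <- binarize_education(records$education_raw, codebook$education)
  age_ok <- !is.na(records$age_years) & records$age_years >= codebook$age_floor
  age_cat <- ifelse(age_ok, band_age(records$age_years), NA_character_)
  cp_cat <- map_control_preference(records$control_pref_option)

  design <- control_preference_design()
  labels <- list(info_cat, trust_cat, pdm_cat, edu_cat, age_cat, cp_cat)
  reasons <- c("info_missing", "trust_missing", "pdm_missing_or_undetermined",
               "education_missing", "age_missing_or_underage",
               "control_pref_missing")
  incomplete <- vapply(labels, function(x)
    is.na(x) | x == "undetermined", logical(nrow(records)))
  if (nrow(records) == 1L) incomplete <- matrix(incomplete, nrow = 1L)
  drop <- rowSums(incomplete) > 0L
  log_counts <- stats::setNames(colSums(incomplete), reasons)
  log_counts <- c(log_counts, excluded_total = sum(drop),
                  retained = sum(!drop))

  attrs <- design_attributes(design)
  out <- data.frame(respondent_id = records$respondent_id[!drop])
  for (j in seq_along(attrs)) {
    lab <- labels[[j]][!drop]
    out[[attrs[[j]]$name]] <- match(lab, attrs[[j]]$categories)
  }
  attr(out, "log") <- log_counts
  attr(out, "cuts") <- c(info = attr(info_cat, "cut"),
                         trust = attr(trust_cat, "cut"))
  out
}

#' Decode integer-coded attributes back to labels
#'
#' @param records Data frame of integer-coded categorized records.
#' @param design The [design_spec()] supplying labels.
#' @return Data frame with the attribute columns as label strings.
#' @export
decode_records <- function(records, design = control_preference_design()) {
  out <- records
  for (a in design_attributes(design)) {
    if (a$name %in% names(out))
      out[[a$name]] <- a$categories[out[[a$name]]]
  }
  out
}
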