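#' Define a categorical attribute
#'
#' An attribute is a named categorical variable with an ordered set of
#' category labels. Categories are addressed throughout the package by their
#' 1-based integer code, in the order given here.
#'
#' @param name Attribute name (single string).
#' @param categories Character vector of category labels, length at least 2,
#'   no duplicates.
#' @return An object of class `cfa_attribute`.
#' @examples
#' attribute_spec("age_band", c("le55", "56to75", "ge76"))
#' @export
attribute_spec <- function(name, categories) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("attribute '", name, "' needs at least 2 categories")
  if (anyDuplicated(categories))
    stop("attribute '", name, "' has duplicate category labels")
  structure(list(name = name, categories = categories),
            class = "cfa_attribute")
}

#' @export
print.cfa_attribute <- function(x, ...) {
  cat("<attribute>", x$name, ":", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

n_categories <- function(attr) length(attr$categories)

#' Define a prediction-CFA design
#'
#' Binds a set of predictor attributes to a single criterion attribute and
#' carries the two significance levels of the split-half workflow: the
#' unadjusted exploratory screening level and the family-wise level used by
#' the Holm procedure in the confirmatory stage.
#'
#' @param predictors List of [attribute_spec()] objects (the predictors, in
#'   the order used for configuration codes).
#' @param criterion A single [attribute_spec()] (the variable to be
#'   predicted).
#' @param alpha_explore Unadjusted per-cell screening level, in (0,1).
#' @param alpha_family Family-wise level for the confirmatory Holm
#'   adjustment, in (0,1).
#' @return An object of class `cfa_design`.
#' @seealso [control_preference_design()] for the ready-made design of the
#'   dialysis-cohort application.
#' @export
design_spec <- function(predictors, criterion,
                        alpha_explore = 0.05, alpha_family = 0.05) {
  if (inherits(predictors, "cfa_attribute")) predictors <- list(predictors)
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  for (p in predictors)
    if (!inherits(p, "cfa_attribute")) stop("predictors must be attribute_spec objects")
  if (!inherits(criterion, "cfa_attribute"))
    stop("criterion must be an attribute_spec object")
  nms <- c(vapply(predictors, `[[`, "", "name"), criterion$name)
  if (anyDuplicated(nms))
    stop("attribute names must be pairwise distinct: ",
         paste(nms[duplicated(nms)], collapse = ", "))
  for (a in list(alpha_explore, alpha_family))
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
      stop("alpha levels must lie in (0,1)")
  structure(list(predictors = predictors, criterion = criterion,
                 alpha_explore = alpha_explore, alpha_family = alpha_family),
            class = "cfa_design")
}

#' @export
print.cfa_design <- function(x, ...) {
  card <- vapply(x$predictors, n_categories, 0L)
  cat("<prediction-CFA design>\n")
  cat("  predictors:", paste(sprintf("%s(%d)", predictor_names(x), card),
                             collapse = " x "), "\n")
  cat("  criterion: ", sprintf("%s(%d)", x$criterion$name,
                               n_categories(x$criterion)), "\n")
  cat("  cells tested:", prod(card) * n_categories(x$criterion), "\n")
  cat("  alpha (exploratory / family-wise):",
      x$alpha_explore, "/", x$alpha_family, "\n")
  invisible(x)
}

predictor_names <- function(design)
  vapply(design$predictors, `[[`, "", "name")

design_attributes <- function(design) c(design$predictors, list(design$criterion))

#' The dialysis-cohort control-preference design
#'
#' Five predictors -- information-seeking preference (low/high), trust in
#' physician (below/above average), perceived participatory decision-making
#' (PDM) style of the physician (negative/positive), educational level
#' (low/high), and age band (<=55, 56-75, >=76 years) -- predicting the
#' control-preference criterion (active, collaborative, passive role in
#' treatment decisions). Integer codes follow the conventional M1..M6 order:
#' code 1 is the first label listed for each attribute.
#'
#' @param alpha_explore,alpha_family Significance levels, see [design_spec()].
#' @return A `cfa_design` with 48 predictor configurations and 144 testable
#'   cells.
#' @export
control_preference_design <- function(alpha_explore = 0.05,
                                      alpha_family = 0.05) {
  design_spec(
    predictors = list(
      attribute_spec("M1_info",      c("low", "high")),
      attribute_spec("M2_trust",     c("below_average", "above_average")),
      attribute_spec("M3_pdm",       c("negative", "positive")),
      attribute_spec("M4_education", c("low", "high")),
      attribute_spec("M5_age_band",  c("le55", "56to75", "ge76"))
    ),
    criterion = attribute_spec("M6_control_pref",
                               c("active", "collaborative", "passive")),
    alpha_explore = alpha_explore, alpha_family = alpha_family
  )
}

#' Enumerate all configurations of a set of attributes
#'
#' Generates the full Cartesian product of category codes in lexicographic
#' order with the last attribute varying fastest, the row order used in all
#' result tables.
#'
#' @param attributes List of [attribute_spec()] objects.
#' @return Integer matrix with one row per configuration and one column per
#'   attribute (named after the attributes).
#' @examples
#' d <- control_preference_design()
#' nrow(enumerate_configurations(d$predictors))  # 48
#' @export
enumerate_configurations <- function(attributes) {
  if (inherits(attributes, "cfa_attribute")) attributes <- list(attributes)
  if (length(attributes) == 0L) stop("need at least one attribute")
  card <- vapply(attributes, n_categories, 0L)
  # expand.grid varies the first factor fastest; reverse to get the
  # last-attribute-fastest convention, then restore column order
  grid <- expand.grid(rev(lapply(card, seq_len)),
                      KEEP.OUT.ATTRS = FALSE)[, length(card):1, drop = FALSE]
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, vapply(attributes, `[[`, "", "name"))
  storage.mode(m) <- "integer"
  m
}

# collapse configuration rows to a compact code string like "12212"
config_string <- function(configs) {
  apply(configs, 1L, paste0, collapse = "")
}
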