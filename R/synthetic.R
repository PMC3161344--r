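#' Configure the synthetic cohort generator
#'
#' Describes a generative model with independent categorical predictors and
#' a criterion linked to chosen predictor configurations by planted
#' odds-multiplier effects -- exactly the alternative against which
#' prediction CFA tests (over-representation of a joint incidence). With no
#' planted effects the generator produces the total-independence null.
#'
#' Defaults emulate the published dialysis cohort: the marginal category
#' distributions of the exploratory half-sample and its size.
#'
#' @param n Cohort size.
#' @param predictor_marginals Named list (one entry per predictor, in
#'   design order) of category probability vectors, each summing to 1.
#' @param criterion_base Probability vector of the criterion categories
#'   under no planted effect.
#' @param planted_effects List of effects from [planted_effect()].
#' @param seed Integer seed; generation is a pure function of the config.
#' @param item_level If `TRUE`, [generate_cohort()] emits raw item-level
#'   survey records instead of categorized records.
#' @param design The [design_spec()] the cohort is generated for.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 3883L,
                             predictor_marginals = NULL,
                             criterion_base = NULL,
                             planted_effects = list(),
                             seed = 1L,
                             item_level = FALSE,
                             design = control_preference_design()) {
  marg <- table1_marginals("exploratory")
  if (is.null(predictor_marginals))
    predictor_marginals <- lapply(
      stats::setNames(predictor_names(design), predictor_names(design)),
      function(nm) marg[[nm]] / marg$n)
  if (is.null(criterion_base))
    criterion_base <- marg[[design$criterion$name]] / marg$n
  stopifnot(n >= 1L, length(predictor_marginals) == length(design$predictors))
  for (j in seq_along(predictor_marginals)) {
    p <- predictor_marginals[[j]]
    if (length(p) != n_categories(design$predictors[[j]]))
      stop("marginal length mismatch for predictor ", j)
    check_prob_vector(p, predictor_names(design)[j])
  }
  check_prob_vector(criterion_base, design$criterion$name)
  stopifnot(length(criterion_base) == n_categories(design$criterion))
  for (e in planted_effects)
    if (!inherits(e, "planted_effect")) stop("planted_effects must come from planted_effect()")
  structure(list(n = as.integer(n), predictor_marginals = predictor_marginals,
                 criterion_base = criterion_base,
                 planted_effects = planted_effects, seed = as.integer(seed),
                 item_level = isTRUE(item_level), design = design),
            class = "synthetic_config")
}

check_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("probabilities for ", what, " must be non-negative and sum to 1")
  invisible(p)
}

#' Plant a configuration-criterion association
#'
#' While generating the criterion for a record whose predictor codes match
#' `pattern` (with `NA` as wildcard -- e.g. an effect shared across age
#' bands), the odds of `category` are multiplied by `odds` and the
#' distribution renormalized. `odds = 1` is a no-op; `odds > 1` plants a
#' prediction type at the matching cells.
#'
#' @param pattern Integer vector of predictor category codes, `NA` for
#'   "any".
#' @param category Criterion category code receiving the odds multiplier.
#' @param odds Positive odds multiplier.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(pattern, category, odds) {
  stopifnot(is.numeric(odds), length(odds) == 1L, odds > 0,
            length(category) == 1L, category >= 1L)
  structure(list(pattern = as.integer(pattern), category = as.integer(category),
                 odds = as.numeric(odds)),
            class = "planted_effect")
}

#' Generate a synthetic cohort
#'
#' Draws predictors independently from their marginals and the criterion
#' from the base distribution with planted odds effects applied per record,
#' deterministically for a given config (seed included). In item-level
#' mode the categorized truth is expanded into raw survey responses
#' (item scores drawn from the category's side of the split point) so the
#' categorization stage can be exercised end to end; the split points used
#' are attached as attribute `"cuts"` and the generating categories as
#' attribute `"truth"`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame of categorized records (integer codes, columns named
#'   as the design attributes, plus `respondent_id`), or raw item-level
#'   records when `config$item_level`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- config$design
  n <- config$n
  with_seed(config$seed, {
    rec <- data.frame(respondent_id = sprintf("S%05d", seq_len(n)))
    for (j in seq_along(design$predictors)) {
      rec[[predictor_names(design)[j]]] <-
        sample.int(length(config$predictor_marginals[[j]]), n, replace = TRUE,
                   prob = config$predictor_marginals[[j]])
    }
    K <- n_categories(design$criterion)
    P <- matrix(config$criterion_base, nrow = n, ncol = K, byrow = TRUE)
    for (e in config$planted_effects) {
      m <- rep(TRUE, n)
      for (j in which(!is.na(e$pattern)))
        m <- m & rec[[predictor_names(design)[j]]] == e$pattern[j]
      P[m, e$category] <- P[m, e$category] * e$odds
    }
    P <- P / rowSums(P)
    u <- stats::runif(n)
    cum <- P
    for (k in seq_len(K)[-1L]) cum[, k] <- cum[, k - 1L] + P[, k]
    rec[[design$criterion$name]] <-
      as.integer(rowSums(u > cum) + 1L)
    if (config$item_level) rec <- expand_to_items(rec, design) else rec
  })
}

# expand categorized records to raw item-level survey records; must be
# called inside the generator's RNG scope
expand_to_items <- function(rec, design) {
  needed <- c("M1_info", "M2_trust", "M3_pdm", "M4_education",
              "M5_age_band", "M6_control_pref")
  if (!all(needed %in% names(rec)))
    stop("item-level generation is defined for the control-preference design")
  n <- nrow(rec)
  info_cut <- 24L   # 8 items on 1..5: scores 8..40, low <= 24 < high
  trust_cut <- 12.5 # 5 items on 1..4: scores 5..20, below < 12.5 < above
  info_score <- ifelse(rec$M1_info == 1L,
                       sample(8:24, n, replace = TRUE),
                       sample(25:40, n, replace = TRUE))
  trust_score <- ifelse(rec$M2_trust == 1L,
                        sample(5:12, n, replace = TRUE),
                        sample(13:20, n, replace = TRUE))
  info_items <- compose_items(info_score, 8L, 1L, 5L)
  trust_items <- compose_items(trust_score, 5L, 1L, 4L)
  # PDM: two items forced into the category's direction, third free
  pdm <- matrix(sample(1:5, 3L * n, replace = TRUE), ncol = 3L)
  forced <- replicate(n, sample.int(3L, 2L))
  for (i in seq_len(n)) {
    lv <- if (rec$M3_pdm[i] == 2L) sample(1:2, 2L, replace = TRUE)
          else sample(4:5, 2L, replace = TRUE)
    pdm[i, forced[, i]] <- lv
  }
  edu_book <- default_codebook()$education
  out <- data.frame(respondent_id = rec$respondent_id)
  colnames(info_items) <- paste0("info_", 1:8)
  colnames(trust_items) <- paste0("trust_", 1:5)
  colnames(pdm) <- paste0("pdm_", 1:3)
  out <- cbind(out, info_items, trust_items, pdm)
  out$education_raw <- ifelse(rec$M4_education == 1L,
                              sample(edu_book$low, n, replace = TRUE),
                              sample(edu_book$high, n, replace = TRUE))
  age_draw <- cbind(sample(18:55, n, replace = TRUE),
                    sample(56:75, n, replace = TRUE),
                    sample(76:95, n, replace = TRUE))
  out$age_years <- age_draw[cbind(seq_len(n), rec$M5_age_band)]
  out$control_pref_option <- c(1L, 3L, 4L)[rec$M6_control_pref] +
    ifelse(rec$M6_control_pref != 2L, stats::rbinom(n, 1L, 0.5), 0L)
  attr(out, "cuts") <- c(info = info_cut, trust = trust_cut)
  attr(out, "truth") <- rec
  out
}

# random item vectors with a prescribed sum, k items each in [lo, hi]
compose_items <- function(score, k, lo, hi) {
  n <- length(score)
  if (any(score < k * lo | score > k * hi))
    stop("sum score outside the feasible range [", k * lo, ", ", k * hi, "]")
  items <- matrix(lo, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    x <- as.vector(stats::rmultinom(1L, score[i] - k * lo, rep(1, k)))
    # shift overflow beyond the item maximum onto items with slack
    while (any(x > hi - lo)) {
      over <- which.max(x)
      slack <- which(x < hi - lo)
      j <- slack[sample.int(length(slack), 1L)]
      x[over] <- x[over] - 1L
      x[j] <- x[j] + 1L
    }
    items[i, ] <- lo + x
  }
  items
}

#' Reconstruct margin-exact cohorts in the image of the published tables
#'
#' Builds two synthetic record sets whose per-attribute marginal counts
#' equal the printed half-sample margins exactly (integer equality) and
#' whose joint counts at the four confirmed type cells equal the printed
#' type sizes in the confirmatory half. The remaining probability mass is
#' filled by independence-proportional largest-remainder rounding; because
#' some type cells are far above their independence expectation, the rows
#' holding a planted cell get that joint count plus the independence share
#' of the remaining criterion categories before the rest of the mass is
#' allocated. Margins are then repaired exactly by paired single-unit
#' moves that each touch only one attribute.
#'
#' This is a synthetic stand-in for the undeposited study microdata: it
#' matches the published margins and type counts, not the (unknown) full
#' joint distribution.
#'
#' @param types Data frame of planted cells as in [table3_types()]
#'   (columns `M1`..`M5`, `criterion`, `n`); applied to the confirmatory
#'   half.
#' @param design The [design_spec()].
#' @return List with `exploratory` and `confirmatory` record data frames
#'   (integer-coded attribute columns).
#' @export
reconstruct_paper_like_cohort <- function(types = table3_types(),
                                          design = control_preference_design()) {
  halves <- list(
    exploratory = build_margin_exact_records(
      table1_marginals("exploratory"), fixed = NULL, design = design),
    confirmatory = build_margin_exact_records(
      table1_marginals("confirmatory"), fixed = types, design = design))
  halves
}

# core construction: integer cell counts over the full cross-product with
# exact attribute margins and optional fixed cells, expanded to records
build_margin_exact_records <- function(marginals, fixed, design) {
  attrs <- design_attributes(design)
  nms <- vapply(attrs, `[[`, "", "name")
  n <- marginals$n
  configs <- enumerate_configurations(attrs)
  ncell <- nrow(configs)
  target <- lapply(nms, function(nm) marginals[[nm]])
  for (j in seq_along(target))
    if (sum(target[[j]]) != n)
      stop("margin counts for ", nms[j], " do not sum to n = ", n)

  # independence mass
  mass <- rep(1, ncell)
  for (j in seq_along(attrs))
    mass <- mass * (target[[j]] / n)[configs[, j]]
  mass <- n * mass

  fixed_idx <- integer(0)
  counts <- numeric(ncell)
  if (!is.null(fixed) && nrow(fixed)) {
    K <- n_categories(design$criterion)
    for (r in seq_len(nrow(fixed))) {
      cfg <- c(as.integer(unlist(fixed[r, paste0("M", seq_len(length(attrs) - 1L))])),
               fixed$criterion[r])
      i <- config_row_index(configs, cfg)
      crit_margin <- target[[length(attrs)]][fixed$criterion[r]]
      if (fixed$n[r] > crit_margin)
        stop("infeasible target: joint count ", fixed$n[r],
             " exceeds criterion margin ", crit_margin)
      counts[i] <- fixed$n[r]
      fixed_idx <- c(fixed_idx, i)
      # boost the sibling cells of the same predictor row so the row total
      # is the planted joint plus the independence share of the rest
      row_cells <- which(colSums(t(configs[, -length(attrs), drop = FALSE]) !=
                                   cfg[-length(attrs)]) == 0L)
      sibs <- setdiff(row_cells, i)
      counts[sibs] <- mass[sibs]
    }
  }
  free <- setdiff(seq_len(ncell), which(counts > 0))
  free <- setdiff(free, fixed_idx)
  scale <- (n - sum(counts)) / sum(mass[free])
  counts[free] <- mass[free] * scale
  counts <- round_largest_remainder(counts, n, keep = fixed_idx)
  counts <- repair_margins(counts, configs, target, fixed_idx,
                           vapply(attrs, n_categories, 0L))
  # expand to records
  idx <- rep.int(seq_len(ncell), counts)
  rec <- as.data.frame(configs[idx, , drop = FALSE])
  names(rec) <- nms
  rec$respondent_id <- sprintf("R%05d", seq_len(nrow(rec)))
  rec
}

# largest-remainder rounding to integers summing to n, keeping `keep`
# entries untouched (they must already be integers)
round_largest_remainder <- function(x, n, keep = integer(0)) {
  out <- floor(x)
  out[keep] <- x[keep]
  deficit <- n - sum(out)
  frac <- x - floor(x)
  frac[keep] <- -1
  if (deficit > 0) {
    add <- order(frac, decreasing = TRUE)[seq_len(deficit)]
    out[add] <- out[add] + 1
  }
  as.integer(round(out))
}

# exact margin repair by paired unit moves: a move between two cells that
# differ only in attribute j changes only attribute j's margin
repair_margins <- function(counts, configs, target, fixed_idx, card) {
  for (j in seq_along(target)) {
    marg <- vapply(seq_len(card[j]), function(k)
      sum(counts[configs[, j] == k]), 0)
    err <- marg - target[[j]]
    guard <- 0L
    while (any(err != 0)) {
      from_lvl <- which(err > 0)[1L]
      to_lvl <- which(err < 0)[1L]
      donors <- which(configs[, j] == from_lvl & counts > 0 &
                        !(seq_len(nrow(configs)) %in% fixed_idx))
      moved <- FALSE
      for (dcell in donors) {
        partner_cfg <- configs[dcell, ]
        partner_cfg[j] <- to_lvl
        pcell <- config_row_index(configs, partner_cfg)
        if (pcell %in% fixed_idx) next
        counts[dcell] <- counts[dcell] - 1L
        counts[pcell] <- counts[pcell] + 1L
        moved <- TRUE
        break
      }
      if (!moved)
        stop("infeasible margin targets: cannot repair attribute ", j)
      err[from_lvl] <- err[from_lvl] - 1L
      err[to_lvl] <- err[to_lvl] + 1L
      guard <- guard + 1L
      if (guard > 100000L) stop("margin repair did not converge")
    }
  }
  counts
}
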