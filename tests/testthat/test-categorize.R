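test_that("sum scores are plain arithmetic sums with missing items flagged", {
  expect_identical(sum_score(rep(1, 8), c(1, 5)), 8L)
  expect_identical(sum_score(rep(5, 8), c(1, 5)), 40L)
  expect_identical(sum_score(c(1, 2, 3, 4, 5, 1, 2, 3), c(1, 5)), 21L)
  expect_true(is.na(sum_score(c(1, NA, 3), c(1, 5))))
  expect_error(sum_score(c(1, 6), c(1, 5)), "bounds")
})

test_that("median dichotomization sends ties to low and splits around the median", {
  s <- c(1, 2, 3, 4, 5)
  out <- median_dichotomize(s)
  expect_identical(unclass(out)[1:5],
                   c("low", "low", "low", "high", "high"))
  expect_equal(attr(out, "cut"), 3)
  # tie side is configurable
  out_hi <- median_dichotomize(s, tie = "high")
  expect_identical(out_hi[3], "high")
  expect_error(median_dichotomize(numeric(0)), "no scores")
})

test_that("both median tie rules give splits as balanced as the score distribution permits", {
  # brute force: for integer scores with mass at the median, the better of
  # the two tie rules minimizes |#low - #high| over the two assignments
  set.seed(41)
  for (rep_i in 1:20) {
    s <- sample(5:15, 101, replace = TRUE)
    lo <- sum(median_dichotomize(s, tie = "low") == "low")
    hi <- sum(median_dichotomize(s, tie = "high") == "low")
    med <- median(s)
    best <- min(abs(2 * sum(s <= med) - length(s)),
                abs(2 * sum(s < med) - length(s)))
    expect_equal(min(abs(2 * lo - length(s)), abs(2 * hi - length(s))), best)
  }
})

test_that("mean split sends scores across the sample mean, ties upward", {
  s <- c(10, 10, 20)
  expect_identical(mean_split(s)[3], "above_average")
  expect_identical(mean_split(s)[1], "below_average")
  # degenerate constant sample: every score equals the mean, so the tie
  # rule routes the whole sample into a single non-empty category
  const <- mean_split(rep(7, 10))
  expect_true(all(const == "above_average"))
  expect_true(all(mean_split(rep(7, 10), tie = "below") == "below_average"))
  expect_error(mean_split(numeric(0)), "no scores")
})

test_that("PDM majority rule partitions exactly the strict 2-of-3 majorities", {
  map <- c("positive", "neutral", "negative")  # level j -> direction
  grid <- expand.grid(1:3, 1:3, 1:3)
  got <- pdm_categorize(as.matrix(grid), direction_map = map)
  dirs <- matrix(map[as.matrix(grid)], ncol = 3)
  want <- ifelse(rowSums(dirs == "positive") >= 2, "positive",
                 ifelse(rowSums(dirs == "negative") >= 2, "negative",
                        "undetermined"))
  expect_identical(got, unname(want))
  # spot checks including the unanimous and the no-majority case
  expect_identical(pdm_categorize(c(1, 1, 3), map), "positive")
  expect_identical(pdm_categorize(c(3, 3, 3), map), "negative")
  expect_identical(pdm_categorize(c(1, 3, 2), map), "undetermined")
  expect_true(is.na(pdm_categorize(c(1, NA, 1), map)))
})

test_that("age bands use inclusive printed boundaries", {
  expect_identical(band_age(c(55, 56, 75, 76, 18, 94)),
                   c("le55", "56to75", "56to75", "ge76", "le55", "ge76"))
  expect_error(band_age(0), "positive")
})

test_that("education and control-preference codebook mappings", {
  expect_identical(binarize_education(c("no certificate",
                                        "lower secondary school certificate",
                                        "secondary school certificate")),
                   c("low", "low", "high"))
  expect_error(binarize_education("doctorate of nothing"), "accepted labels")
  expect_identical(map_control_preference(1:5),
                   c("active", "active", "collaborative", "passive", "passive"))
  expect_error(map_control_preference(6), "1..5")
})

test_that("categorization is deterministic, order-invariant, and codes round-trip", {
  cfg <- synthetic_config(n = 400, seed = 9, item_level = TRUE)
  raw <- generate_cohort(cfg)
  cb <- default_codebook(info_cut = attr(raw, "cuts")["info"],
                         trust_cut = attr(raw, "cuts")["trust"])
  one <- categorize_records(raw, cb)
  two <- categorize_records(raw, cb)
  expect_identical(one, two)
  # shuffling records changes nothing but row order
  perm <- sample(nrow(raw))
  shuffled <- categorize_records(raw[perm, ], cb)
  reord <- shuffled[order(shuffled$respondent_id), ]
  rownames(reord) <- NULL
  attributes(reord)[c("log", "cuts")] <- NULL
  base <- one[order(one$respondent_id), ]
  rownames(base) <- NULL
  attributes(base)[c("log", "cuts")] <- NULL
  expect_equal(reord, base)
  # integer coding round-trips through labels
  design <- control_preference_design()
  dec <- decode_records(one, design)
  for (a in predcfa:::design_attributes(design)) {
    expect_true(all(dec[[a$name]] %in% a$categories))
    expect_identical(match(dec[[a$name]], a$categories), one[[a$name]])
  }
})

test_that("categorize recovers planted categories exactly from item-level data", {
  cfg <- synthetic_config(n = 800, seed = 23, item_level = TRUE)
  raw <- generate_cohort(cfg)
  truth <- attr(raw, "truth")
  cb <- default_codebook(info_cut = attr(raw, "cuts")["info"],
                         trust_cut = attr(raw, "cuts")["trust"])
  got <- categorize_records(raw, cb)
  expect_identical(nrow(got), nrow(truth))
  m <- merge(got, truth, by = "respondent_id", suffixes = c("", ".t"))
  for (v in c("M1_info", "M2_trust", "M3_pdm", "M4_education",
              "M5_age_band", "M6_control_pref"))
    expect_identical(m[[v]], m[[paste0(v, ".t")]])
})

test_that("empirical split points recover intended categories on a balanced cohort", {
  # five records on each side of both scale cuts: the sample median (24)
  # and mean (12.5) fall between the blocks, so no explicit cut is needed
  info <- rbind(matrix(2L, 5, 8), matrix(4L, 5, 8))   # sums 16 vs 32
  trust <- rbind(matrix(2L, 5, 5), matrix(3L, 5, 5))  # sums 10 vs 15
  colnames(info) <- paste0("info_", 1:8)
  colnames(trust) <- paste0("trust_", 1:5)
  raw <- data.frame(respondent_id = sprintf("r%02d", 1:10), info, trust,
                    pdm_1 = rep(c(1L, 5L), 5), pdm_2 = rep(c(2L, 4L), 5),
                    pdm_3 = 3L,
                    education_raw = rep(c("no certificate",
                                          "secondary school certificate"), 5),
                    age_years = rep(c(40L, 60L, 80L, 50L, 70L), 2),
                    control_pref_option = rep(1:5, 2))
  got <- categorize_records(raw, default_codebook())
  expect_identical(got$M1_info, rep(1:2, each = 5))
  expect_identical(got$M2_trust, rep(1:2, each = 5))
  expect_identical(got$M3_pdm, rep(c(2L, 1L), 5))
  expect_identical(got$M4_education, rep(1:2, 5))
  expect_identical(got$M5_age_band, rep(c(1L, 2L, 3L, 1L, 2L), 2))
  expect_identical(got$M6_control_pref, rep(c(1L, 1L, 2L, 3L, 3L), 2))
  expect_equal(unname(attr(got, "cuts")), c(24, 12.5))
})

test_that("missing items are excluded listwise and logged by reason", {
  cfg <- synthetic_config(n = 60, seed = 13, item_level = TRUE)
  raw <- generate_cohort(cfg)
  raw$info_3[1] <- NA
  raw$trust_1[2] <- NA
  raw$pdm_1[3] <- NA
  raw$age_years[4] <- 17          # under the adult floor
  raw$control_pref_option[5] <- NA
  cb <- default_codebook(info_cut = attr(raw, "cuts")["info"],
                         trust_cut = attr(raw, "cuts")["trust"])
  got <- categorize_records(raw, cb)
  lg <- attr(got, "log")
  expect_identical(nrow(got), 55L)
  expect_identical(unname(lg["excluded_total"]), 5)
  expect_identical(unname(lg["info_missing"]), 1)
  expect_identical(unname(lg["age_missing_or_underage"]), 1)
  expect_false(any(raw$respondent_id[1:5] %in% got$respondent_id))
})
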