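# small record builders shared across test files

# categorized records with the control-preference design's columns,
# drawn uniformly (seeded); codes only, no labels
random_records <- function(n, seed = 1L) {
  design <- control_preference_design()
  cfg <- synthetic_config(
    n = n,
    predictor_marginals = lapply(design$predictors,
                                 function(a) rep(1, length(a$categories)) /
                                   length(a$categories)),
    criterion_base = rep(1 / 3, 3),
    seed = seed)
  generate_cohort(cfg)
}

# brute-force fourfold recount straight from a record data frame
fourfold_by_recount <- function(records, design, configuration, category) {
  pred <- vapply(design$predictors, `[[`, "", "name")
  in_cfg <- rep(TRUE, nrow(records))
  for (j in seq_along(pred)) in_cfg <- in_cfg & records[[pred[j]]] == configuration[j]
  in_cat <- records[[design$criterion$name]] == category
  c(a = sum(in_cfg & in_cat), b = sum(in_cfg & !in_cat),
    c = sum(!in_cfg & in_cat), d = sum(!in_cfg & !in_cat))
}

# tiny attribute sets for combinatorial checks
toy_attrs <- function(cards) {
  lapply(seq_along(cards), function(j)
    attribute_spec(paste0("A", j), paste0("c", seq_len(cards[j]))))
}
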