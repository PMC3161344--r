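#!/usr/bin/env Rscript
# Stage 4: exercise the preprocessing stage end to end. Generates an
# item-level survey cohort (raw Likert responses, credential labels, ages,
# control-preference options), categorizes it with the codebook, and runs
# the full two-stage pipeline on the result.
#
# Finding: with the generator's split points supplied to the categorizer,
# categorization recovers the generating categories exactly (0 mismatches),
# and a planted passive type at the modal passive profile survives both
# stages of the pipeline.

suppressPackageStartupMessages(library(predcfa))

dir.create("results", showWarnings = FALSE)
design <- control_preference_design()

cfg <- synthetic_config(n = 4000, seed = 101, item_level = TRUE,
                        planted_effects = list(
                          planted_effect(c(1, 2, 2, 1, 2), 3, 4)))
raw <- generate_cohort(cfg)
write_records(raw[1:200, ], "results/item_level_sample.tsv")

cuts <- attr(raw, "cuts")
codebook <- default_codebook(info_cut = cuts["info"], trust_cut = cuts["trust"])
cat_rec <- categorize_records(raw, codebook)
cat("categorization log:\n")
print(attr(cat_rec, "log"))

truth <- attr(raw, "truth")
m <- merge(cat_rec, truth, by = "respondent_id", suffixes = c("", ".t"))
mismatch <- sum(vapply(c("M1_info", "M2_trust", "M3_pdm", "M4_education",
                         "M5_age_band", "M6_control_pref"),
                       function(v) sum(m[[v]] != m[[paste0(v, ".t")]]), 0))
cat("category mismatches vs generating truth:", mismatch, "\n")

pl <- run_full_pipeline(cat_rec, design, seed = 101)
print(pl)
write_results(pl, "results/item_level_pipeline")
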