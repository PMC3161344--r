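#!/usr/bin/env Rscript
# Stage 3: simulate the two operating characteristics of the two-stage
# design on synthetic cohorts with realistic (printed) marginals, n = 4000.
#   (a) family-wise false-confirmation rate under the independence null:
#       fraction of replicates in which any type is (falsely) confirmed;
#       the split-half screen plus Holm should hold this at or below 0.05.
#   (b) recovery power with two planted types at odds multiplier 3
#       (the modal passive profile (12212)->passive and a prevalent active
#       profile (22211)->active): fraction of runs confirming both.
#
# Finding (seeds below, 500 null / 100 planted replicates): the null
# false-confirmation rate lands near 1-2% (conservative, as expected from
# the exact test in sparse cells) and both planted types are recovered in
# ~99% of runs.

suppressPackageStartupMessages(library(predcfa))

dir.create("results", showWarnings = FALSE)
design <- control_preference_design()

n_null <- 500
false_conf <- logical(n_null)
for (s in seq_len(n_null)) {
  coh <- generate_cohort(synthetic_config(n = 4000, seed = 20000L + s))
  pl <- suppressWarnings(run_full_pipeline(coh, design, seed = s))
  false_conf[s] <- any(pl$confirmed$reject %in% TRUE)
}
fwer <- mean(false_conf)
cat(sprintf("null cohorts: %d replicates, family-wise false-confirmation rate = %.4f (MC SE %.4f)\n",
            n_null, fwer, sqrt(fwer * (1 - fwer) / n_null)))

n_pow <- 100
effects <- list(planted_effect(c(1, 2, 2, 1, 2), 3, 3),
                planted_effect(c(2, 2, 2, 1, 1), 1, 3))
both <- logical(n_pow)
for (s in seq_len(n_pow)) {
  coh <- generate_cohort(synthetic_config(n = 4000, seed = 30000L + s,
                                          planted_effects = effects))
  pl <- suppressWarnings(run_full_pipeline(coh, design, seed = s))
  conf <- pl$confirmed[pl$confirmed$reject %in% TRUE, , drop = FALSE]
  key <- paste(do.call(paste0, conf[c("M1_info", "M2_trust", "M3_pdm",
                                      "M4_education", "M5_age_band")]),
               conf$criterion)
  both[s] <- ("12212 3" %in% key) && ("22211 1" %in% key)
}
cat(sprintf("planted cohorts: %d runs, both types confirmed in %.0f%%\n",
            n_pow, 100 * mean(both)))

summary <- data.frame(
  quantity = c("null_false_confirmation_rate", "planted_recovery_rate"),
  value = c(fwer, mean(both)),
  replicates = c(n_null, n_pow))
write_records(summary, "results/error_control_summary.tsv")
cat("wrote results/error_control_summary.tsv\n")
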