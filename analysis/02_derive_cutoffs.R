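#!/usr/bin/env Rscript
# Derive genotype-stratified Youden cut-offs for plasma Abeta42 from
# synthetic cohorts, and measure how often the carrier cut-off exceeds the
# non-carrier one. Under the default configuration (PET status fully
# mediates the markers) both strata share one population-optimal threshold,
# so the ordering is a coin flip; with genotype offsets calibrated to the
# published carrier/non-carrier class means, the published ordering
# (carrier cut-off higher) emerges in nearly every cohort.

suppressPackageStartupMessages(library(abetascreen))
seed <- local({
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 2 && a[1] == "--seed") as.integer(a[2]) else 1L
})
dir.create("results", showWarnings = FALSE)

offsets <- genotype_offsets_calibrated()
cat("Calibrated genotype-class offsets for Abeta42 (pg/ml):\n")
print(round(sapply(offsets, `[[`, "abeta42"), 3))

mc <- function(use_offsets, n_seeds = 100L, n = 1000L) {
  higher <- used <- 0L
  cuts <- matrix(NA_real_, n_seeds, 2)
  for (s in seq_len(n_seeds)) {
    cfg <- default_config(
      n_subjects = n, seed = seed * 1000L + s,
      genotype_marker_offsets = if (use_offsets) offsets else NULL
    )
    co <- simulate_cohort(cfg)
    e4 <- is_e4_carrier(co$genotype)
    if (min(sum(co$pet_positive[e4]), sum(!co$pet_positive[e4]),
            sum(co$pet_positive[!e4]), sum(!co$pet_positive[!e4])) < 1) next
    used <- used + 1L
    sc <- derive_stratified_cutoffs(co)
    cuts[s, ] <- c(sc$cutoff_e4, sc$cutoff_non_e4)
    if (sc$cutoff_e4 > sc$cutoff_non_e4) higher <- higher + 1L
  }
  list(prop = higher / used, used = used,
       mean_e4 = mean(cuts[, 1], na.rm = TRUE),
       mean_non = mean(cuts[, 2], na.rm = TRUE))
}

plain <- mc(FALSE)
shifted <- mc(TRUE)
tab <- data.frame(
  configuration = c("default (no genotype offsets)", "calibrated genotype offsets"),
  prop_carrier_higher = c(plain$prop, shifted$prop),
  mean_cutoff_e4 = c(plain$mean_e4, shifted$mean_e4),
  mean_cutoff_non_e4 = c(plain$mean_non, shifted$mean_non),
  cohorts = c(plain$used, shifted$used)
)
write.csv(tab, "results/cutoff_ordering.csv", row.names = FALSE)
print(tab, digits = 3)

cat(sprintf(
  "\nWith offsets, the carrier cut-off exceeded the non-carrier cut-off in %.0f%% of %d cohorts\n(reference values: 18.68 vs 15.58 pg/ml); without offsets the ordering is uninformative (%.0f%%).\n",
  100 * shifted$prop, shifted$used, 100 * plain$prop))
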