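#!/usr/bin/env Rscript
# Evaluate screening pathways I-V. Two runs:
#  (a) replay of the reference cut-offs (18.68 / 15.58 pg/ml) on the
#      margin-constructed 52-subject cohort, whose genotype-by-PET cells
#      match the published counts, so every count-determined metric of the
#      genotype-only pathway is reproduced exactly;
#  (b) cut-offs re-derived from a simulated cohort and evaluated on it.

suppressPackageStartupMessages(library(abetascreen))
seed <- local({
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 2 && a[1] == "--seed") as.integer(a[2]) else 1L
})
dir.create("results", showWarnings = FALSE)

margins <- cohort_from_margins(seed = seed)
replay <- evaluate_pathways(margins, digits = 3)
write.csv(replay, "results/pathways_replay.csv", row.names = FALSE)
cat("Reference cut-offs replayed on the margin-matched 52-subject cohort:\n")
print(replay)
cat("\nPathway II is fully count-determined: SP 0.933, accuracy 0.769, PPV 0.857,",
    "NPV 0.737\n(marker-based rows III-V depend on the synthetic marker draws).\n")

co <- simulate_cohort(default_config(
  n_subjects = 1000L, seed = seed,
  genotype_marker_offsets = genotype_offsets_calibrated()
))
sc <- derive_stratified_cutoffs(co)
cat("\nCut-offs derived from a 1000-subject genotype-shifted cohort:\n")
print(sc)
rules <- lapply(c("I", "II", "III", "IV", "V"), pathway_rule,
                cutoff_e4 = sc$cutoff_e4, cutoff_non_e4 = sc$cutoff_non_e4)
derived <- evaluate_pathways(co, rules = rules, digits = 3)
write.csv(derived, "results/pathways_derived.csv", row.names = FALSE)
cat("\nPathways with the derived cut-offs on the same cohort:\n")
print(derived)

man <- run_manifest(
  input_source = "margin-constructed (published counts) + simulated n=1000",
  seed = seed,
  cutoff_provenance = list(
    replay = list(origin = "reference", cutoff_e4 = 18.68, cutoff_non_e4 = 15.58),
    derived = list(origin = "derived", cutoff_e4 = sc$cutoff_e4,
                   cutoff_non_e4 = sc$cutoff_non_e4)
  ),
  outputs = c("results/pathways_replay.csv", "results/pathways_derived.csv")
)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(unclass(man), "results/manifest_03.json",
                       auto_unbox = TRUE)
}
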