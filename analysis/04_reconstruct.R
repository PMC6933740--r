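#!/usr/bin/env Rscript
# Invert the published, rounded diagnostic metrics back to the latent
# integer 2x2 tables. The published table prints SS/SP/accuracy/PPV/NPV to
# 3 decimals over 22 PET+ and 30 PET- subjects; exhaustive enumeration of
# all 23 x 31 candidate tables recovers the unique table behind each
# pathway, and shows the genotype-only pathway's printed sensitivity
# (0.595) to be inconsistent with any integer count.

suppressPackageStartupMessages(library(abetascreen))
dir.create("results", showWarnings = FALSE)

printed <- list(
  II = list(sensitivity = 0.595, specificity = 0.933, accuracy = 0.769,
            ppv = 0.857, npv = 0.737),
  III = list(sensitivity = 0.591, specificity = 0.600, accuracy = 0.596,
             ppv = 0.520, npv = 0.667),
  IV = list(sensitivity = 0.864, specificity = 0.600, accuracy = 0.711,
            ppv = 0.613, npv = 0.857),
  V = list(sensitivity = 0.864, specificity = 0.733, accuracy = 0.788,
           ppv = 0.704, npv = 0.880)
)

rows <- list()
for (pw in names(printed)) {
  p <- printed[[pw]]
  # SS/SP determine tp and fp; full-metric reconstruction cross-checks them
  rec <- reconstruct_confusion(22, 30, p[c("sensitivity", "specificity")], 3)
  cat(sprintf("\n== Pathway %s: SS %.3f, SP %.3f ==\n",
              pw, p$sensitivity, p$specificity))
  print(rec)
  if (rec$consistent) {
    full <- reconstruct_confusion(22, 30, p, 3)
    cat(sprintf("  all five printed metrics jointly feasible: %s\n",
                full$consistent))
    best <- rec$feasible[1, ]
    rows[[pw]] <- data.frame(pathway = pw, tp = best$tp, fp = best$fp,
                             tn = best$tn, fn = best$fn,
                             unique = rec$unique,
                             ppv_exact = best$ppv,
                             accuracy_exact = best$accuracy)
  } else {
    # drop the inconsistent sensitivity and rebuild from the other metrics
    rec2 <- reconstruct_confusion(22, 30,
                                  p[c("specificity", "ppv", "npv", "accuracy")],
                                  3)
    cat("  reconstruction from the remaining printed metrics instead:\n")
    print(rec2)
    best <- rec2$feasible[1, ]
    rows[[pw]] <- data.frame(pathway = pw, tp = best$tp, fp = best$fp,
                             tn = best$tn, fn = best$fn,
                             unique = rec2$unique,
                             ppv_exact = best$ppv,
                             accuracy_exact = best$accuracy)
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/reconstructed_tables.csv", row.names = FALSE)
cat("\nRecovered latent 2x2 tables:\n")
print(out, digits = 4)
cat("\nThe genotype-only pathway resolves to (tp 12, fp 2): its printed",
    "sensitivity should read 0.545,\nand the full cascade's (tp 19, fp 8)",
    "gives the headline PPV 19/27 = 0.704.\n")
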