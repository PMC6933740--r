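test_that("pathway rules encode their gates and default cut-offs", {
  v <- pathway_rule("V")
  expect_equal(v$cutoff_e4, 18.68)
  expect_equal(v$cutoff_non_e4, 15.58)
  expect_true(is.na(pathway_rule("I")$cutoff_e4))
  expect_true(is.na(pathway_rule("II")$cutoff_non_e4))
  expect_error(pathway_rule("VI"))
  expect_error(pathway_rule("IV", cutoff_e4 = -1), "positive")
})

test_that("classification follows the genotype gates and the strict-< boundary", {
  co <- cohort_from_margins(data.frame(
    genotype = c("e3e4", "e2e3", "e3e3", "e2e4"),
    pet_positive = c(TRUE, FALSE, FALSE, TRUE),
    n = rep(1L, 4)
  ))
  co$abeta42 <- c(17.0, 10.0, 15.58, 19.0)
  # e4 carrier below the carrier cut-off
  expect_equal(classify_pathway(co, pathway_rule("V")),
               c(TRUE, FALSE, FALSE, FALSE))
  # under IV the e2e3 subject is screened by the non-carrier cut-off
  expect_equal(classify_pathway(co, pathway_rule("IV")),
               c(TRUE, TRUE, FALSE, FALSE))
  # boundary equality (15.58) is screen-negative under III/IV/V
  expect_false(classify_pathway(co, pathway_rule("III"))[3])
  # e2e4 counts as an e4 carrier: gated at 18.68, so 19.0 is negative
  expect_false(classify_pathway(co, pathway_rule("V"))[4])
  expect_equal(classify_pathway(co, pathway_rule("I")), rep(TRUE, 4))
  expect_equal(classify_pathway(co, pathway_rule("II")),
               c(TRUE, FALSE, FALSE, TRUE))
  co$abeta42[2] <- NA
  expect_error(classify_pathway(co, pathway_rule("IV")), "M00002")
  expect_equal(classify_pathway(co, pathway_rule("II")),
               c(TRUE, FALSE, FALSE, TRUE))  # II never touches the marker
})

test_that("pathway II on the study margins reproduces the count-determined metrics", {
  co <- cohort_from_margins()
  ev <- evaluate_pathway(co, pathway_rule("II"))
  expect_equal(ev$confusion$tp, 12L)
  expect_equal(ev$confusion$fp, 2L)
  expect_equal(ev$confusion$tn, 28L)
  expect_equal(ev$confusion$fn, 10L)
  expect_equal(round(ev$metrics$specificity, 3), 0.933)
  expect_equal(round(ev$metrics$ppv, 3), 0.857)
  expect_equal(round(ev$metrics$npv, 3), 0.737)
  expect_equal(round(ev$metrics$accuracy, 3), 0.769)
  # the count-consistent sensitivity is 12/22, not the printed 0.595
  expect_equal(ev$metrics$sensitivity, 12 / 22)
})

test_that("pathway I is the no-test baseline with PPV equal to prevalence", {
  co <- cohort_from_margins()
  ev <- evaluate_pathway(co, pathway_rule("I"))
  expect_equal(ev$metrics$sensitivity, 1)
  expect_equal(ev$metrics$specificity, 0)
  expect_equal(ev$metrics$ppv, 22 / 52)
  expect_true(is.na(ev$metrics$npv))  # no screen-negatives: undefined
})

test_that("stratified cut-off derivation matches the brute-force scan per stratum", {
  # separated carrier stratum: cut-off strictly between the groups, J = 1
  co <- cohort_from_margins(data.frame(
    genotype = c("e3e4", "e3e4", "e3e4", "e3e4", "e3e3", "e3e3", "e3e3", "e3e3"),
    pet_positive = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    n = rep(1L, 8)
  ))
  co$abeta42 <- c(12, 13, 20, 21, 14, 15, 16, 22)
  sc <- derive_stratified_cutoffs(co)
  # cut-offs sit at observed score values, so a separated stratum places the
  # cut-off on the highest screen-positive marker value
  expect_gte(sc$cutoff_e4, 13)
  expect_lt(sc$cutoff_e4, 20)
  expect_equal(sc$stratum_e4$youden_j, 1)
  expect_equal(sc$cutoff_e4, 1 / sc$stratum_e4$score_cutoff)
  # oracle agreement on simulated cohorts, stratum by stratum
  for (seed in 1:5) {
    sim <- simulate_cohort(default_config(n_subjects = 120L, seed = seed))
    e4 <- is_e4_carrier(sim$genotype)
    ok <- sum(sim$pet_positive[e4]) >= 1 && sum(!sim$pet_positive[e4]) >= 1 &&
      sum(sim$pet_positive[!e4]) >= 1 && sum(!sim$pet_positive[!e4]) >= 1
    if (!ok) next
    got <- derive_stratified_cutoffs(sim)
    for (stratum in list(e4, !e4)) {
      ref <- oracle_youden_scan(1 / sim$abeta42[stratum],
                                sim$pet_positive[stratum])
      cut <- if (identical(stratum, e4)) got$stratum_e4 else got$stratum_non_e4
      expect_equal(cut$youden_j, ref$j, tolerance = 1e-12)
      expect_equal(cut$sensitivity, ref$se, tolerance = 1e-12)
      expect_equal(cut$specificity, ref$sp, tolerance = 1e-12)
      if (is.finite(cut$score_cutoff)) {
        expect_equal(cut$score_cutoff, ref$t, tolerance = 1e-12)
      }
    }
  }
  # single-class stratum errors with the stratum name
  all_pos <- cohort_from_margins(data.frame(
    genotype = c("e3e4", "e3e3", "e3e3"),
    pet_positive = c(TRUE, TRUE, FALSE),
    n = c(2L, 1L, 1L)
  ))
  expect_error(derive_stratified_cutoffs(all_pos), "e4 carriers")
})

test_that("pathway V screens out a subset of pathway IV's false positives", {
  set.seed(9)
  co <- simulate_cohort(default_config(n_subjects = 400L, seed = 15L))
  iv <- classify_pathway(co, pathway_rule("IV"))
  v <- classify_pathway(co, pathway_rule("V"))
  expect_true(all(which(v) %in% which(iv)))  # V's positives nest in IV's
  flipped <- which(iv & !v)
  expect_true(all(is_e2_only(co$genotype[flipped])))
  # with no PET+ e2-only subjects (the generator's configuration),
  # specificity can only improve and sensitivity is untouched
  ev_iv <- evaluate_pathway(co, pathway_rule("IV"))
  ev_v <- evaluate_pathway(co, pathway_rule("V"))
  expect_gte(ev_v$metrics$specificity, ev_iv$metrics$specificity)
  expect_equal(ev_v$metrics$sensitivity, ev_iv$metrics$sensitivity)
})

test_that("pathway II depends only on genotype and PET label", {
  co <- simulate_cohort(default_config(n_subjects = 100L, seed = 5L))
  ev1 <- evaluate_pathway(co, pathway_rule("II"))
  co$abeta42 <- rev(co$abeta42)
  co$abeta40 <- sample(co$abeta40)
  ev2 <- evaluate_pathway(co, pathway_rule("II"))
  expect_identical(ev1$confusion, ev2$confusion)
})

test_that("the pathway report has the published table's shape", {
  co <- cohort_from_margins()
  tab <- evaluate_pathways(co, digits = 3)
  expect_equal(names(tab), c("pathway", "SS", "SP", "accuracy", "PPV", "NPV", "AUC"))
  expect_equal(tab$pathway, c("I", "II", "III", "IV", "V"))
  expect_equal(tab$SP[tab$pathway == "II"], 0.933)
  expect_equal(tab$AUC[tab$pathway == "II"], round((12 / 22 + 28 / 30) / 2, 3))
})
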