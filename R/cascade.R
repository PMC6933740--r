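#' Screening pathway rules
#'
#' The pre-screening cascade is a family of five decision rules determining
#' who proceeds to a confirmatory amyloid PET scan:
#'
#' * **I** — scan everyone (the no-test baseline; its PPV is the cohort
#'   prevalence).
#' * **II** — scan APOE e4 carriers only.
#' * **III** — scan subjects with plasma Abeta42 below a single cut-off.
#' * **IV** — genotype-stratified cut-offs: carriers screen positive below
#'   `cutoff_e4`, non-carriers below `cutoff_non_e4`.
#' * **V** — as IV, but subjects carrying an e2 allele and no e4 allele
#'   (e2e2/e2e3) are excluded (forced screen-negative).
#'
#' Boundary convention: a marker value exactly equal to its cut-off is
#' screen-negative (strict "lower than"). The default cut-offs, 18.68 pg/ml
#' for e4 carriers and 15.58 pg/ml for non-carriers, are the stratified
#' Youden cut-offs proposed for this cascade in the reference cohort;
#' pathway III uses the non-carrier (all-subject) cut-off.
#'
#' @param pathway_id one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param cutoff_e4,cutoff_non_e4 plasma Abeta42 cut-offs in pg/ml.
#' @return object of class `ab_pathway`.
#' @export
pathway_rule <- function(pathway_id, cutoff_e4 = 18.68, cutoff_non_e4 = 15.58) {
  pathway_id <- match.arg(pathway_id, c("I", "II", "III", "IV", "V"))
  uses_marker <- pathway_id %in% c("III", "IV", "V")
  if (uses_marker && (!is.finite(cutoff_non_e4) || cutoff_non_e4 <= 0)) {
    stop("cutoff_non_e4 must be a positive marker value", call. = FALSE)
  }
  if (pathway_id %in% c("IV", "V") && (!is.finite(cutoff_e4) || cutoff_e4 <= 0)) {
    stop("cutoff_e4 must be a positive marker value", call. = FALSE)
  }
  desc <- switch(pathway_id,
    I = "scan all subjects (no pre-screen)",
    II = "scan APOE e4 carriers",
    III = sprintf("scan subjects with Abeta42 < %.4g pg/ml", cutoff_non_e4),
    IV = sprintf("scan e4 carriers with Abeta42 < %.4g and non-carriers with Abeta42 < %.4g pg/ml",
                 cutoff_e4, cutoff_non_e4),
    V = sprintf("as IV (%.4g / %.4g pg/ml) with e2e2/e2e3 subjects excluded",
                cutoff_e4, cutoff_non_e4)
  )
  structure(list(
    pathway_id = pathway_id,
    cutoff_e4 = if (pathway_id %in% c("IV", "V")) cutoff_e4 else NA_real_,
    cutoff_non_e4 = if (uses_marker) cutoff_non_e4 else NA_real_,
    description = desc
  ), class = "ab_pathway")
}

#' @export
print.ab_pathway <- function(x, ...) {
  cat(sprintf("Pathway %s: %s\n", x$pathway_id, x$description))
  invisible(x)
}

#' Apply a screening pathway to a cohort
#'
#' @param cohort an `ab_cohort` (or data.frame with `subject_id`, `genotype`
#'   and, for pathways III-V, `abeta42`).
#' @param rule an `ab_pathway`.
#' @return logical vector of screen results (TRUE = proceed to PET).
#' @export
classify_pathway <- function(cohort, rule) {
  stopifnot(inherits(rule, "ab_pathway"))
  e4 <- is_e4_carrier(cohort$genotype)
  e2 <- is_e2_only(cohort$genotype)
  if (rule$pathway_id %in% c("III", "IV", "V")) {
    miss <- which(is.na(cohort$abeta42))
    if (length(miss) > 0L) {
      stop("pathway ", rule$pathway_id,
           " needs abeta42; missing for subject(s): ",
           paste(cohort$subject_id[miss], collapse = ", "), call. = FALSE)
    }
  }
  switch(rule$pathway_id,
    I = rep(TRUE, nrow(cohort)),
    II = e4,
    III = cohort$abeta42 < rule$cutoff_non_e4,
    IV = ifelse(e4, cohort$abeta42 < rule$cutoff_e4,
                cohort$abeta42 < rule$cutoff_non_e4),
    V = !e2 & ifelse(e4, cohort$abeta42 < rule$cutoff_e4,
                     cohort$abeta42 < rule$cutoff_non_e4)
  )
}

#' Derive genotype-stratified Youden cut-offs from a cohort
#'
#' Reproduces the stratified cut-off derivation: within the e4-carrier and
#' non-carrier strata separately, the Abeta42 values are reciprocally
#' oriented, an empirical ROC against PET status is built, and the
#' Youden-optimal threshold is mapped back to the marker scale.
#'
#' @param cohort an `ab_cohort` with PET labels and `abeta42`.
#' @return object of class `ab_strat_cutoffs`: `cutoff_e4`, `cutoff_non_e4`
#'   (pg/ml) and the per-stratum [`ab_cutoff`][youden_cutoff] provenance.
#' @export
derive_stratified_cutoffs <- function(cohort) {
  e4 <- is_e4_carrier(cohort$genotype)
  one <- function(idx, stratum) {
    y <- cohort$pet_positive[idx]
    if (sum(y) < 1L || sum(!y) < 1L) {
      stop("stratum '", stratum,
           "' needs at least one PET+ and one PET- subject", call. = FALSE)
    }
    scores <- orient_marker(cohort$abeta42[idx], "lower_is_positive",
                            ids = cohort$subject_id[idx])
    youden_cutoff(empirical_roc(scores, y))
  }
  res_e4 <- one(which(e4), "e4 carriers")
  res_non <- one(which(!e4), "e4 non-carriers")
  structure(list(
    cutoff_e4 = res_e4$marker_cutoff,
    cutoff_non_e4 = res_non$marker_cutoff,
    stratum_e4 = res_e4,
    stratum_non_e4 = res_non
  ), class = "ab_strat_cutoffs")
}

#' @export
print.ab_strat_cutoffs <- function(x, ...) {
  cat(sprintf("Stratified Abeta42 cut-offs: e4 carriers %.4g pg/ml (SS %.3f, SP %.3f); non-carriers %.4g pg/ml (SS %.3f, SP %.3f)\n",
              x$cutoff_e4, x$stratum_e4$sensitivity, x$stratum_e4$specificity,
              x$cutoff_non_e4, x$stratum_non_e4$sensitivity,
              x$stratum_non_e4$specificity))
  invisible(x)
}

#' Evaluate a screening pathway on a cohort
#'
#' Applies the rule to every subject, tallies the 2x2 table against the PET
#' label, and summarises it. The reported AUC is the area under the two-point
#' ROC of the binary screen, (sensitivity + specificity) / 2.
#'
#' @inheritParams classify_pathway
#' @return list with elements `pathway_id`, `confusion` (an `ab_confusion`),
#'   `metrics` (an `ab_metrics`) and `auc`.
#' @export
evaluate_pathway <- function(cohort, rule) {
  if (is.null(cohort) || nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  pred <- classify_pathway(cohort, rule)
  cm <- tabulate_confusion(cohort$pet_positive, pred)
  met <- confusion_metrics(cm)
  list(pathway_id = rule$pathway_id, confusion = cm, metrics = met,
       auc = (met$sensitivity + met$specificity) / 2)
}

#' Tabulate all pathways on a cohort
#'
#' @param cohort an `ab_cohort`.
#' @param rules list of `ab_pathway` rules; defaults to pathways I-V with the
#'   reference cut-offs.
#' @param digits decimals for the printed columns (`NULL` keeps full
#'   precision).
#' @return data.frame with columns `pathway,SS,SP,accuracy,PPV,NPV,AUC`.
#' @export
evaluate_pathways <- function(cohort,
                              rules = lapply(c("I", "II", "III", "IV", "V"),
                                             pathway_rule),
                              digits = NULL) {
  rows <- lapply(rules, function(rule) {
    ev <- evaluate_pathway(cohort, rule)
    data.frame(pathway = ev$pathway_id,
               SS = ev$metrics$sensitivity, SP = ev$metrics$specificity,
               accuracy = ev$metrics$accuracy, PPV = ev$metrics$ppv,
               NPV = ev$metrics$npv, AUC = ev$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) out[-1] <- lapply(out[-1], round, digits = digits)
  out
}
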