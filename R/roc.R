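#' Orient a plasma marker into a risk score
#'
#' Diagnostic scores are conventionally "higher = more likely positive".
#' Plasma Abeta42 falls with amyloid positivity, so the screening analyses
#' run on its reciprocal, `1/Abeta42` in (pg/ml)^-1. The transform applied is
#' recorded on the result so cut-offs can be mapped back to pg/ml.
#'
#' @param values numeric marker values (pg/ml).
#' @param direction `"lower_is_positive"` (reciprocal transform, the Abeta42
#'   convention) or `"higher_is_positive"` (identity).
#' @param ids optional subject identifiers used in error messages.
#' @return numeric score vector with attribute `orientation`.
#' @export
orient_marker <- function(values,
                          direction = c("lower_is_positive", "higher_is_positive"),
                          ids = NULL) {
  direction <- match.arg(direction)
  if (direction == "lower_is_positive") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad) > 0L) {
      who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
             else paste("position", paste(bad, collapse = ", "))
      stop("reciprocal orientation requires positive marker values; offending subject(s): ",
           who, call. = FALSE)
    }
    out <- 1 / values
  } else {
    out <- values
  }
  attr(out, "orientation") <- direction
  out
}

#' Empirical ROC curve
#'
#' Enumerates every distinct score as a threshold for the rule
#' "score >= threshold => predicted positive", plus a sentinel above the
#' maximum (the (0, 0) operating point). Tied scores collapse to a single
#' operating point, so TPR and FPR are non-decreasing along the curve from
#' (0, 0) to (1, 1).
#'
#' @param scores numeric risk scores (see [orient_marker()]).
#' @param labels logical (or 0/1) true condition status.
#' @return object of class `ab_roc` with fields `thresholds`, `tpr`, `fpr`,
#'   `n_pos`, `n_neg`, `orientation`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must not contain missing values", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("labels must contain at least one positive and one negative (AUC undefined otherwise)",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  structure(list(
    thresholds = c(Inf, s[last]),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg),
    n_pos = n_pos,
    n_neg = n_neg,
    orientation = attr(scores, "orientation") %||% "unspecified"
  ), class = "ab_roc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under an empirical ROC curve
#'
#' Trapezoidal area over the operating points; identical to the rank
#' statistic P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param curve an `ab_roc`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "ab_roc"))
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-index optimal cut-off
#'
#' Selects the operating point maximising J = TPR - FPR (= sensitivity +
#' specificity - 1) over every enumerated threshold. Ties in J are broken in
#' favour of higher specificity, then lower threshold; the tie-break applied
#' is recorded in the result. When the curve was built from
#' reciprocally-oriented scores, the cut-off is also reported back on the
#' marker scale (pg/ml), where "score >= cut-off" corresponds to
#' "marker <= 1/cut-off".
#'
#' @param curve an `ab_roc`.
#' @return object of class `ab_cutoff`: `score_cutoff`, `marker_cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`, `auc`, `tie_break`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "ab_roc"))
  j <- curve$tpr - curve$fpr
  spec <- 1 - curve$fpr
  # lexicographic: max J, then max specificity, then min threshold
  best <- order(-j, -spec, curve$thresholds)[1]
  score_cutoff <- curve$thresholds[best]
  marker_cutoff <- if (identical(curve$orientation, "lower_is_positive")) {
    1 / score_cutoff
  } else {
    score_cutoff
  }
  structure(list(
    score_cutoff = score_cutoff,
    marker_cutoff = marker_cutoff,
    sensitivity = curve$tpr[best],
    specificity = spec[best],
    youden_j = j[best],
    auc = roc_auc(curve),
    orientation = curve$orientation,
    tie_break = "max J, then max specificity, then min threshold"
  ), class = "ab_cutoff")
}

#' @export
print.ab_cutoff <- function(x, ...) {
  cat("Youden cut-off\n")
  cat(sprintf("  score cut-off : %.6g (%s)\n", x$score_cutoff, x$orientation))
  if (identical(x$orientation, "lower_is_positive")) {
    cat(sprintf("  marker cut-off: %.4g pg/ml (screen-positive below)\n",
                x$marker_cutoff))
  }
  cat(sprintf("  sensitivity %.3f, specificity %.3f, J = %.3f, AUC = %.3f\n",
              x$sensitivity, x$specificity, x$youden_j, x$auc))
  invisible(x)
}

#' Export ROC operating points
#'
#' @param curve an `ab_roc`.
#' @param path optional CSV path; when omitted the table is only returned.
#' @return data.frame `threshold,tpr,fpr,youden_j`, invisibly when written.
#' @export
roc_points <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "ab_roc"))
  df <- data.frame(threshold = curve$thresholds, tpr = curve$tpr,
                   fpr = curve$fpr, youden_j = curve$tpr - curve$fpr)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
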