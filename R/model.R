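#' Logistic risk model for PET positivity
#'
#' Fits a plain (unpenalised) logistic regression of amyloid-PET status on a
#' subset of the cascade's predictors: the e4-carrier indicator, the e2-only
#' indicator, and the reciprocal Abeta42 score in (pg/ml)^-1. The fit is
#' maximum likelihood by iteratively reweighted least squares, run
#' in-package so its convergence trace is available: iteration stops when
#' the largest absolute coefficient change falls below `tol` or after
#' `max_iter` iterations. Non-convergence — typically complete separation,
#' under which the MLE diverges — is flagged on the returned object and
#' warned about, never silently returned.
#'
#' @param cohort an `ab_cohort` with both PET classes.
#' @param predictors character subset of `c("e4", "e2", "inv_abeta42")`;
#'   may be empty for an intercept-only model.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter iteration cap.
#' @return object of class `ab_logistic`: `coefficients`, `converged`,
#'   `separated`, `iterations`, `log_likelihood`, `loglik_trace`,
#'   `predictors`.
#' @export
fit_logistic <- function(cohort, predictors = c("e4", "inv_abeta42"),
                         tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(cohort$pet_positive)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  X <- model_design(cohort, predictors)
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    stop("constant predictor(s): ",
         paste(colnames(X)[-1][const], collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  trace <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    trace <- c(trace, loglik(beta))
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  separated <- all(ifelse(y == 1, eta > 0, eta < 0)) && max(abs(eta)) > 10
  if (!converged || separated) {
    converged <- converged && !separated
    warning("logistic fit did not converge",
            if (separated) " (complete separation detected)" else "",
            call. = FALSE)
  }
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    converged = converged,
    separated = separated,
    iterations = iter,
    log_likelihood = loglik(beta),
    loglik_trace = trace,
    predictors = predictors
  ), class = "ab_logistic")
}

model_design <- function(cohort, predictors) {
  allowed <- c("e4", "e2", "inv_abeta42")
  if (!all(predictors %in% allowed)) {
    stop("predictors must be a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  if ("e4" %in% predictors) cols$e4 <- as.numeric(is_e4_carrier(cohort$genotype))
  if ("e2" %in% predictors) cols$e2 <- as.numeric(is_e2_only(cohort$genotype))
  if ("inv_abeta42" %in% predictors) {
    if (anyNA(cohort$abeta42)) {
      stop("missing abeta42 for subject(s): ",
           paste(cohort$subject_id[is.na(cohort$abeta42)], collapse = ", "),
           call. = FALSE)
    }
    cols$inv_abeta42 <- as.numeric(orient_marker(cohort$abeta42,
                                                 "lower_is_positive",
                                                 ids = cohort$subject_id))
  }
  do.call(cbind, cols)
}

#' Linear risk scores from a fitted logistic model
#'
#' Returns the linear predictor per subject. It is monotone in the fitted
#' probability, so ROC/AUC computed from it equal those of the fitted
#' probabilities.
#'
#' @param model an `ab_logistic`.
#' @param cohort an `ab_cohort` with the model's predictors.
#' @return numeric score vector.
#' @export
risk_scores <- function(model, cohort) {
  stopifnot(inherits(model, "ab_logistic"))
  X <- model_design(cohort, model$predictors)
  drop(X %*% model$coefficients)
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired nonparametric test for the difference between the AUCs of two risk
#' scores measured on the same subjects with the same labels. Per-subject
#' placement values (the structural components of the Mann-Whitney
#' statistic) give each AUC, their empirical covariance across the two
#' score sets gives the variance of the difference, and
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)` is referred to the
#' standard normal.
#'
#' @param scores_a,scores_b numeric score vectors over the same subjects.
#' @param labels logical true condition status.
#' @return object of class `ab_delong`: `auc_a`, `auc_b`, `variance_a`,
#'   `variance_b`, `covariance`, `z`, `p_two_sided`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("scores and labels must cover the same subjects", call. = FALSE)
  }
  if (sum(labels) < 1L || sum(!labels) < 1L) {
    stop("both classes must be present", call. = FALSE)
  }
  comp <- placement_components(scores_a, labels)
  comp_b <- placement_components(scores_b, labels)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(comp$v_pos, comp_b$v_pos))
  s01 <- stats::cov(cbind(comp$v_neg, comp_b$v_neg))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  covar <- s10[1, 2] / m + s01[1, 2] / n
  vd <- var_a + var_b - 2 * covar
  if (!is.finite(vd) || vd <= 0) {
    z <- if (abs(comp$auc - comp_b$auc) < 1e-15) 0 else NA_real_
    p <- if (is.na(z)) NA_real_ else 1
    msg <- if (is.na(z)) "degenerate variance: placement values carry no variability" else NULL
  } else {
    z <- (comp$auc - comp_b$auc) / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
    msg <- NULL
  }
  structure(list(
    auc_a = comp$auc, auc_b = comp_b$auc,
    variance_a = var_a, variance_b = var_b, covariance = covar,
    z = z, p_two_sided = p, message = msg
  ), class = "ab_delong")
}

# placement values: for each positive, the fraction of negatives it beats
# (ties count 1/2); for each negative, the fraction of positives it is
# beaten by. Means of either set equal the AUC.
placement_components <- function(scores, labels) {
  xp <- scores[labels]
  xn <- scores[!labels]
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  v_pos <- rowMeans(cmp)
  v_neg <- colMeans(cmp)
  list(v_pos = v_pos, v_neg = v_neg, auc = mean(cmp))
}

#' @export
print.ab_delong <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: AUC_a = %.4f, AUC_b = %.4f, z = %s, p = %s\n",
              x$auc_a, x$auc_b, format(x$z, digits = 4),
              format(x$p_two_sided, digits = 4)))
  if (!is.null(x$message)) cat(" ", x$message, "\n")
  invisible(x)
}

#' Bootstrap comparison of two correlated AUCs
#'
#' Seeded paired-bootstrap sensitivity check for [delong_compare()]:
#' subjects are resampled with replacement (keeping both score columns and
#' the label together), the AUC difference is recomputed per resample, and a
#' two-sided p-value is taken from the fraction of resampled differences on
#' either side of zero.
#'
#' @inheritParams delong_compare
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return list with `auc_diff`, `p_two_sided`, `n_boot`, `n_degenerate`
#'   (resamples with a single class, skipped).
#' @export
auc_compare_bootstrap <- function(scores_a, scores_b, labels,
                                  n_boot = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  n <- length(labels)
  set.seed(seed)
  diffs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    l <- labels[idx]
    if (sum(l) < 1L || sum(!l) < 1L) next
    diffs[b] <- placement_components(scores_a[idx], l)$auc -
      placement_components(scores_b[idx], l)$auc
  }
  used <- diffs[!is.na(diffs)]
  p <- 2 * min(mean(used <= 0), mean(used >= 0))
  list(auc_diff = placement_components(scores_a, labels)$auc -
         placement_components(scores_b, labels)$auc,
       p_two_sided = min(1, p), n_boot = n_boot,
       n_degenerate = sum(is.na(diffs)))
}
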