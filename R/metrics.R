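#' Confusion matrix for a screening rule
#'
#' @param tp,fp,tn,fn non-negative integer cell counts (condition = amyloid
#'   PET status, prediction = screen result).
#' @return object of class `ab_confusion`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "ab_confusion")
}

#' Tabulate predictions against true status
#'
#' @param truth logical true condition status.
#' @param predicted logical screen result.
#' @return an `ab_confusion`.
#' @export
tabulate_confusion <- function(truth, predicted) {
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted))
  confusion_matrix(
    tp = sum(predicted & truth),
    fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth),
    fn = sum(!predicted & truth)
  )
}

#' Diagnostic-accuracy metrics of a 2x2 table
#'
#' Sensitivity, specificity, PPV, NPV, accuracy and prevalence. A metric
#' whose denominator is zero is reported as `NA` (undefined), never coerced
#' to 0 or 1. The metrics satisfy the Bayes identity
#' PPV = SS*pi / (SS*pi + (1-SP)(1-pi)) with pi the prevalence, whenever all
#' terms are defined.
#'
#' @param cm an `ab_confusion`.
#' @return object of class `ab_metrics` (named list of proportions).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "ab_confusion"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  structure(list(
    sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    ppv = frac(cm$tp, cm$tp + cm$fp),
    npv = frac(cm$tn, cm$tn + cm$fn),
    accuracy = frac(cm$tp + cm$tn, total),
    prevalence = frac(cm$tp + cm$fn, total)
  ), class = "ab_metrics")
}

# rounding half away from zero (the convention most often behind printed
# clinical tables); base round() is IEC half-to-even and is accepted as an
# alternative in feasibility checks
round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

rounds_to <- function(x, target, digits) {
  if (is.na(x)) return(FALSE)
  isTRUE(all.equal(round_half_away(x, digits), target, tolerance = 1e-9)) ||
    isTRUE(all.equal(round(x, digits), target, tolerance = 1e-9))
}

#' Reconstruct confusion matrices from rounded published metrics
#'
#' Published diagnostic tables print rounded SS/SP/PPV/NPV/accuracy but not
#' the underlying 2x2 counts. Given the class sizes, this exhaustively
#' enumerates every `tp` in `0..n_pos` and `fp` in `0..n_neg` and returns all
#' matrices whose recomputed metrics round to the printed values at the
#' stated number of decimals (half away from zero, with half-to-even also
#' accepted, since the publisher's rounding rule is unknown). An empty
#' feasible set is an explicit result flagging the printed values as
#' count-inconsistent, together with the nearest matrices.
#'
#' @param n_pos,n_neg positive integer class sizes.
#' @param printed named list giving any subset of `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` as printed.
#' @param decimals integer, decimals the table prints (3 in the reference
#'   tables).
#' @return object of class `ab_reconstruction`: `feasible` (data.frame of
#'   matrices with exact metrics), `n_feasible`, `unique`, `consistent`, and
#'   (when inconsistent) `nearest`.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, printed, decimals = 3L) {
  stopifnot(n_pos > 0, n_neg > 0)
  allowed <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  printed <- printed[!vapply(printed, is.null, logical(1))]
  if (length(printed) == 0L || !all(names(printed) %in% allowed)) {
    stop("printed must supply at least one of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(tp = 0:n_pos, fp = 0:n_neg)
  grid$fn <- n_pos - grid$tp
  grid$tn <- n_neg - grid$fp
  total <- n_pos + n_neg
  exact <- data.frame(
    sensitivity = grid$tp / n_pos,
    specificity = grid$tn / n_neg,
    ppv = ifelse(grid$tp + grid$fp > 0, grid$tp / (grid$tp + grid$fp), NA_real_),
    npv = ifelse(grid$tn + grid$fn > 0, grid$tn / (grid$tn + grid$fn), NA_real_),
    accuracy = (grid$tp + grid$tn) / total
  )
  ok <- rep(TRUE, nrow(grid))
  dev <- rep(0, nrow(grid))
  for (nm in names(printed)) {
    tgt <- printed[[nm]]
    hit <- vapply(exact[[nm]], rounds_to, logical(1), target = tgt,
                  digits = decimals)
    ok <- ok & hit
    dev <- pmax(dev, abs(ifelse(is.na(exact[[nm]]), Inf, exact[[nm]]) - tgt))
  }
  feasible <- cbind(grid[ok, c("tp", "fp", "tn", "fn")], exact[ok, ])
  rownames(feasible) <- NULL
  res <- list(
    n_pos = n_pos, n_neg = n_neg, printed = printed, decimals = decimals,
    feasible = feasible,
    n_feasible = nrow(feasible),
    unique = nrow(feasible) == 1L,
    consistent = nrow(feasible) >= 1L
  )
  if (!res$consistent) {
    near <- which(dev <= min(dev) + 1e-12)
    res$nearest <- cbind(grid[near, c("tp", "fp", "tn", "fn")], exact[near, ])
    rownames(res$nearest) <- NULL
    res$message <- "inconsistent printed metrics: no integer 2x2 table rounds to them"
  }
  structure(res, class = "ab_reconstruction")
}

#' @export
print.ab_reconstruction <- function(x, ...) {
  cat(sprintf("Confusion reconstruction over n_pos = %d, n_neg = %d (%d dp)\n",
              x$n_pos, x$n_neg, x$decimals))
  cat("  printed:",
      paste(sprintf("%s = %s", names(x$printed), unlist(x$printed)),
            collapse = ", "), "\n")
  if (x$consistent) {
    cat(sprintf("  feasible matrices: %d%s\n", x$n_feasible,
                if (x$unique) " (unique)" else ""))
    print(x$feasible, digits = 4)
  } else {
    cat(" ", x$message, "\n  nearest:\n")
    print(x$nearest, digits = 4)
  }
  invisible(x)
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Sample Pearson correlation between two equally-long numeric vectors,
#' undefined (`NA` with a message attribute) when either has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "message") <- "undefined: zero variance in at least one variable"
    return(out)
  }
  stats::cor(x, y, method = "pearson")
}
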