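# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# AUC as the exhaustive pairwise Mann-Whitney statistic
oracle_auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  xp <- scores[labels]
  xn <- scores[!labels]
  total <- 0
  for (a in xp) for (b in xn) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(xp) * length(xn))
}

# Youden cut-off by brute-force scan over every candidate threshold
# (every observed score plus one above the maximum), rule: score >= t
oracle_youden_scan <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- c(max(scores) + 1, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    se <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 && sp > best$sp + 1e-15) ||
        (abs(j - best$j) <= 1e-15 && abs(sp - best$sp) <= 1e-15 && t < best$t)) {
      best <- list(t = t, j = j, se = se, sp = sp)
    }
  }
  best
}

# logistic log-likelihood, maximised numerically (independent of IRLS):
# quasi-Newton on the closed-form likelihood and gradient
oracle_logistic_optim <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p))
  }
  fit <- stats::nlminb(rep(0, ncol(X)), nll, gradient = grad,
                       control = list(iter.max = 2000, eval.max = 4000,
                                      rel.tol = 1e-14))
  fit$par
}

# DeLong variance/covariance recomputed from first principles: explicit
# double loops over placement values
oracle_delong <- function(sa, sb, labels) {
  labels <- as.logical(labels)
  pos <- which(labels)
  neg <- which(!labels)
  m <- length(pos)
  n <- length(neg)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- matrix(0, m, 2)
  v01 <- matrix(0, n, 2)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    v10[i, 1] <- v10[i, 1] + psi(sa[pos[i]], sa[neg[j]]) / n
    v10[i, 2] <- v10[i, 2] + psi(sb[pos[i]], sb[neg[j]]) / n
    v01[j, 1] <- v01[j, 1] + psi(sa[pos[i]], sa[neg[j]]) / m
    v01[j, 2] <- v01[j, 2] + psi(sb[pos[i]], sb[neg[j]]) / m
  }
  auc <- colMeans(v10)
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  list(auc_a = auc[1], auc_b = auc[2],
       var_a = s10[1, 1] / m + s01[1, 1] / n,
       var_b = s10[2, 2] / m + s01[2, 2] / n,
       cov = s10[1, 2] / m + s01[1, 2] / n)
}

# mean of a normal truncated below at `floor`
truncnorm_mean <- function(mu, sd, floor) {
  a <- (floor - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# small random score/label instance with ties
random_instance <- function(n, n_levels = 6) {
  scores <- sample(seq_len(n_levels), n, replace = TRUE) +
    sample(c(0, 0.5), n, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
  if (all(labels)) labels[1] <- FALSE
  if (!any(labels)) labels[1] <- TRUE
  list(scores = scores, labels = labels)
}
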