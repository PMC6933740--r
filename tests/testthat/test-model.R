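make_cohort <- function(n, seed) {
  simulate_cohort(default_config(n_subjects = n, seed = seed))
}

test_that("intercept-only fit recovers the closed-form MLE", {
  co <- cohort_from_margins()  # 22 of 52 PET+
  fit <- fit_logistic(co, predictors = character(0))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), log(22 / 30), tolerance = 1e-8)
  expect_true(all(risk_scores(fit, co) == risk_scores(fit, co)[1]))
})

test_that("IRLS matches an independent likelihood maximiser and glm", {
  co <- make_cohort(120L, seed = 21L)
  fit <- fit_logistic(co, c("e4", "inv_abeta42"))
  expect_true(fit$converged)
  X <- cbind(1, as.numeric(is_e4_carrier(co$genotype)), 1 / co$abeta42)
  ref <- oracle_logistic_optim(X, as.numeric(co$pet_positive))
  expect_equal(unname(fit$coefficients), ref, tolerance = 1e-4)
  ref_glm <- stats::glm(co$pet_positive ~ is_e4_carrier(co$genotype) +
                          I(1 / co$abeta42), family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref_glm)),
               tolerance = 1e-6)
  # the three-predictor model needs e2-only subjects in both PET classes
  # (under the calibrated rates they are all PET-, which quasi-separates the
  # e2 coefficient, as in the cohort the rates come from)
  cfg3 <- default_config(n_subjects = 150L, seed = 22L)
  cfg3$pet_rate_by_class[["e2_only"]] <- 0.15
  co3 <- simulate_cohort(cfg3)
  fit3 <- fit_logistic(co3, c("e4", "e2", "inv_abeta42"))
  expect_true(fit3$converged)
  expect_length(fit3$coefficients, 4L)
  X3 <- cbind(1, as.numeric(is_e4_carrier(co3$genotype)),
              as.numeric(is_e2_only(co3$genotype)), 1 / co3$abeta42)
  expect_equal(unname(fit3$coefficients),
               oracle_logistic_optim(X3, as.numeric(co3$pet_positive)),
               tolerance = 1e-4)
})

test_that("log-likelihood is monotone over IRLS iterations and under nesting", {
  co <- make_cohort(150L, seed = 31L)
  fit <- fit_logistic(co, c("e4", "inv_abeta42"))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  small <- fit_logistic(co, "e4")
  expect_gte(fit$log_likelihood, small$log_likelihood - 1e-10)
  # the e2 indicator is quasi-separated under the calibrated rates (e2-only
  # subjects are never PET+), which the fit reports; its likelihood still
  # dominates the nested model's
  expect_warning(larger <- fit_logistic(co, c("e4", "e2", "inv_abeta42")),
                 "converge")
  expect_gte(larger$log_likelihood, fit$log_likelihood - 1e-10)
})

test_that("degenerate fits are reported, not silently returned", {
  co <- make_cohort(60L, seed = 41L)
  co$pet_positive <- co$abeta42 < stats::median(co$abeta42)  # separation
  expect_warning(fit <- fit_logistic(co, "inv_abeta42"), "separation|converge")
  expect_false(fit$converged)
  expect_true(fit$separated)
  co2 <- make_cohort(40L, seed = 42L)
  co2$pet_positive <- rep(TRUE, nrow(co2))
  expect_error(fit_logistic(co2, "e4"), "single class")
  co3 <- make_cohort(40L, seed = 43L)
  co3$genotype <- rep("e3e3", nrow(co3))
  expect_error(fit_logistic(co3, "e4"), "constant")
})

test_that("risk scores are monotone in the marker for a single-marker model", {
  co <- make_cohort(100L, seed = 51L)
  fit <- fit_logistic(co, "inv_abeta42")
  s <- risk_scores(fit, co)
  auc_model <- roc_auc(empirical_roc(s, co$pet_positive))
  auc_marker <- roc_auc(empirical_roc(
    orient_marker(co$abeta42, "lower_is_positive"), co$pet_positive))
  if (fit$coefficients[["inv_abeta42"]] > 0) {
    expect_equal(auc_model, auc_marker, tolerance = 1e-12)
  } else {
    expect_equal(auc_model, 1 - auc_marker, tolerance = 1e-12)
  }
})

test_that("DeLong components match the brute-force placement oracle", {
  set.seed(61)
  for (k in 1:10) {
    n <- 12L
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sa <- sample(seq_len(5), n, replace = TRUE) + 0.5 * sample(0:1, n, TRUE)
    sb <- sa + stats::rnorm(n)
    got <- delong_compare(sa, sb, labels)
    ref <- oracle_delong(sa, sb, labels)
    expect_equal(got$auc_a, unname(ref$auc_a), tolerance = 1e-12)
    expect_equal(got$auc_b, unname(ref$auc_b), tolerance = 1e-12)
    expect_equal(got$variance_a, ref$var_a, tolerance = 1e-12)
    expect_equal(got$variance_b, ref$var_b, tolerance = 1e-12)
    expect_equal(got$covariance, ref$cov, tolerance = 1e-12)
    # AUC from the placement machinery equals the trapezoidal ROC AUC
    expect_equal(got$auc_a, roc_auc(empirical_roc(sa, labels)),
                 tolerance = 1e-12)
  }
})

test_that("DeLong agrees with pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(71)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
  labels[1:2] <- c(TRUE, FALSE)
  sa <- stats::rnorm(40) + labels
  sb <- stats::rnorm(40) + 0.5 * labels
  got <- delong_compare(sa, sb, labels)
  ra <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(got$z), abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("DeLong is symmetric under label flips and exact under self-comparison", {
  set.seed(81)
  labels <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  labels[1:2] <- c(TRUE, FALSE)
  sa <- stats::rnorm(30)
  sb <- stats::rnorm(30)
  self <- delong_compare(sa, sa, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)
  a <- delong_compare(sa, sb, labels)
  b <- delong_compare(-sa, -sb, !labels)
  expect_equal(abs(a$z), abs(b$z), tolerance = 1e-12)
})

test_that("bootstrap comparator is seeded and directionally consistent with DeLong", {
  set.seed(91)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  labels[1:2] <- c(TRUE, FALSE)
  sa <- stats::rnorm(60) + 1.5 * labels
  sb <- stats::rnorm(60)
  b1 <- auc_compare_bootstrap(sa, sb, labels, n_boot = 400L, seed = 5L)
  b2 <- auc_compare_bootstrap(sa, sb, labels, n_boot = 400L, seed = 5L)
  expect_identical(b1, b2)
  d <- delong_compare(sa, sb, labels)
  expect_equal(b1$auc_diff, d$auc_a - d$auc_b, tolerance = 1e-12)
  expect_lt(b1$p_two_sided, 0.05)
  expect_lt(d$p_two_sided, 0.05)
})
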