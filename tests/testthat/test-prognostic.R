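pts <- function(n) sprintf("P%03d", seq_len(n))

test_that("prognostic eligibility enforces the 50% / 5% rules", {
  n <- 100
  # 40% valid -> ineligible
  r1 <- c(rep(0.2, 40), rep(NA, 60))
  expect_false(prognostic_eligibility(r1))
  # 80% valid but only 2% above 0.1 -> ineligible
  r2 <- c(rep(0.05, 78), rep(0.2, 2), rep(NA, 20))
  expect_false(prognostic_eligibility(r2))
  # 80% valid, 10% above 0.1 -> eligible
  r3 <- c(rep(0.05, 72), rep(0.2, 8), rep(NA, 20))
  expect_true(prognostic_eligibility(r3))
  # confident zeros count as valid observations
  r4 <- c(rep(0, 72), rep(0.2, 8), rep(NA, 20))
  expect_true(prognostic_eligibility(r4))
})

test_that("median-split Cox recovers a planted hazard", {
  set.seed(12)
  n <- 150
  row <- stats::setNames(stats::rbeta(n, 2, 5), pts(n))
  ir <- matrix(row, nrow = 1, dimnames = list("I1", pts(n)))
  hrs <- vapply(1:10, function(s) {
    surv <- simulate_survival(ir, c(I1 = 1), h0 = 0.002, censor_frac = 0.2,
                              seed = 100 + s)
    median_split_cox(row, surv)$hr
  }, numeric(1))
  expect_gt(median(hrs), 2.0)
  expect_lt(median(hrs), 3.8)
})

test_that("median-split Cox rejects degenerate inputs", {
  n <- 40
  surv <- data.frame(patient_id = pts(n), time = stats::rexp(n, 0.01) + 1,
                     event = rep(1L, n))
  expect_error(median_split_cox(stats::setNames(rep(0.3, n), pts(n)), surv),
               "degenerate|group")
  expect_error(median_split_cox(stats::setNames(rep(0, n), pts(n)), surv),
               "fewer than 4")
  row <- stats::setNames(stats::runif(n), pts(n))
  surv0 <- transform(surv, event = 0L)
  expect_error(median_split_cox(row, surv0), "events")
})

test_that("null screening holds the nominal type-I error", {
  set.seed(33)
  n <- 200
  surv <- simulate_survival(
    matrix(stats::runif(n), 1, dimnames = list("x", pts(n))),
    numeric(0), h0 = 0.002, censor_frac = 0.2, seed = 44)
  pvals <- vapply(1:300, function(i) {
    row <- stats::setNames(stats::rbeta(n, 2, 5), pts(n))
    median_split_cox(row, surv)$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("expression analog skips low-TPM genes and recovers effects", {
  n <- 120
  expect_null(expression_survival(
    stats::setNames(rep(0.5, n), pts(n)),
    data.frame(patient_id = pts(n), time = 1:n, event = 1L)))
  set.seed(3)
  tpm <- stats::setNames(stats::rlnorm(n, meanlog = 1.5), pts(n))
  ir <- matrix(tpm, nrow = 1, dimnames = list("G1", pts(n)))
  surv <- simulate_survival(ir, c(G1 = 1), h0 = 0.002, censor_frac = 0.2,
                            seed = 21)
  r <- expression_survival(tpm, surv)
  expect_gt(r$hr, 1.5)
  expect_lt(r$p, 0.05)
  expect_error(
    expression_survival(stats::setNames(rep(5, n), pts(n)), surv),
    "constant")
})

test_that("fit_irr selects planted introns and scores patients", {
  set.seed(61)
  n <- 120; p <- 50
  m <- matrix(stats::rbeta(n * p, 2, 5), nrow = p,
              dimnames = list(sprintf("I%03d", 1:p), pts(n)))
  beta <- stats::setNames(c(1.2, 1.2), c("I001", "I002"))
  surv <- simulate_survival(m, beta, h0 = 0.002, censor_frac = 0.2,
                            seed = 62)
  fit <- fit_irr(m, surv, lambda_rule = "min", seed = 63)
  expect_s3_class(fit, "irr_model")
  expect_true(all(c("I001", "I002") %in% fit$intron_ids))
  # IRR is the stated dot product
  manual <- as.vector(t(m[fit$intron_ids, , drop = FALSE]) %*%
                        fit$coefficients)
  expect_equal(unname(fit$irr), manual)
  # median split differs in size by at most 1
  expect_lte(abs(sum(fit$groups == "high") - sum(fit$groups == "low")), 1L)
  # predict on the training matrix reproduces training scores
  pr <- predict(fit, m)
  expect_equal(pr$irr, unname(fit$irr))
  expect_identical(coef(fit),
                   stats::setNames(fit$coefficients, fit$intron_ids))
})

test_that("fit_irr respects the 20% missing-rate gate and errors cleanly", {
  set.seed(71)
  n <- 60; p <- 10
  m <- matrix(stats::rbeta(n * p, 2, 5), nrow = p,
              dimnames = list(sprintf("I%02d", 1:p), pts(n)))
  m[1, 1:20] <- NA  # 33% missing: excluded from candidates
  surv <- simulate_survival(m[2:3, ], numeric(0), h0 = 0.002,
                            censor_frac = 0.2, seed = 72)
  fit <- fit_irr(m, surv, seed = 73)
  expect_false("I01" %in% fit$intron_ids)
  expect_error(fit_irr(m[2:3, 1:5], surv[1:5, ], seed = 1), "patients")
  surv_noev <- transform(surv, event = 0L)
  expect_error(fit_irr(m, surv_noev, seed = 1), "events")
})

test_that("IRR coefficients are zero-sparse under a null signal", {
  set.seed(81)
  n <- 100; p <- 60
  m <- matrix(stats::rbeta(n * p, 2, 5), nrow = p,
              dimnames = list(sprintf("I%03d", 1:p), pts(n)))
  surv <- simulate_survival(m, numeric(0), h0 = 0.002, censor_frac = 0.3,
                            seed = 82)
  hits <- vapply(1:5, function(s) {
    fit <- suppressWarnings(fit_irr(m, surv, lambda_rule = "1se",
                                    seed = 82 + s))
    length(fit$intron_ids)
  }, numeric(1))
  expect_gte(mean(hits <= 1), 0.8)
})

test_that("KM estimator matches a hand-computed product-limit table", {
  # 6 patients per group, worked by hand:
  # low:  times 1,2,3+,4,5+,6  -> S = 5/6, 2/3, 2/3, 4/9, 4/9, 0
  # high: times 2,3+,4,5,6+,7  -> S = 5/6, 5/6, 5/8, 5/12, 5/12, 0
  surv <- data.frame(
    patient_id = pts(12),
    time = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 7),
    event = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1))
  groups <- stats::setNames(factor(rep(c("low", "high"), each = 6),
                                   levels = c("low", "high")), pts(12))
  km <- km_logrank(groups, surv)
  s <- summary(km$fit)
  surv_low <- s$surv[s$strata == "group=low"]
  surv_high <- s$surv[s$strata == "group=high"]
  expect_equal(surv_low, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_equal(surv_high, c(5 / 6, 5 / 8, 5 / 12, 0))
  expect_true(km$logrank_p > 0 && km$logrank_p <= 1)
})

test_that("log-rank separates groups with early events", {
  n <- 100
  groups <- stats::setNames(factor(rep(c("low", "high"), each = n / 2),
                                   levels = c("low", "high")), pts(n))
  surv <- data.frame(patient_id = pts(n),
                     time = c(stats::rexp(n / 2, 0.001),
                              stats::rexp(n / 2, 0.02)) + 0.1,
                     event = 1L)
  km <- km_logrank(groups, surv)
  expect_lt(km$logrank_p, 0.01)
  expect_gt(km$hr, 1)
  expect_error(km_logrank(stats::setNames(factor(rep("low", n),
                                                 levels = c("low", "high")),
                                          pts(n)), surv), "empty")
})

test_that("Cox HR of a group indicator is invariant to time rescaling", {
  set.seed(90)
  n <- 80
  row <- stats::setNames(stats::rbeta(n, 2, 5), pts(n))
  ir <- matrix(row, nrow = 1, dimnames = list("I1", pts(n)))
  surv <- simulate_survival(ir, c(I1 = 0.8), h0 = 0.002, censor_frac = 0.2,
                            seed = 91)
  r1 <- median_split_cox(row, surv)
  surv2 <- transform(surv, time = time * 365.25)
  r2 <- median_split_cox(row, surv2)
  expect_equal(r1$hr, r2$hr, tolerance = 1e-8)
})
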