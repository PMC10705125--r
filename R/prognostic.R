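#' Prognostic eligibility of an intron
#'
#' An intron enters survival screening when it has a valid IRratio (a
#' trusted value or a confident zero — anything but missing) in at least
#' 50% of patients, and at least 5% of those valid values exceed 0.1.
#'
#' @param row Numeric vector of IRratio cells (`NA` = missing).
#' @param min_valid Minimum valid fraction (default 0.50).
#' @param min_above Minimum fraction of valid values above `threshold`
#'   (default 0.05).
#' @param threshold Retention threshold (default 0.1, strict).
#' @return Logical.
#' @export
prognostic_eligibility <- function(row, min_valid = 0.50,
                                   min_above = 0.05, threshold = 0.1) {
  valid <- !is.na(row)
  if (mean(valid) < min_valid) return(FALSE)
  sum(row[valid] > threshold) / sum(valid) >= min_above
}

#' Median-split univariate Cox regression on one intron
#'
#' Restricts to patients with IRratio strictly above 0, splits them at the
#' median of that restricted set into IR-high (strictly above the median)
#' and IR-low (at or below — ties go low), and fits a univariate Cox
#' proportional-hazards model (Efron tie handling) of survival on the
#' group indicator.
#'
#' @param row Named numeric vector of IRratios (names = patient ids).
#' @param surv data frame with `patient_id`, `time`, `event`.
#' @return List with `hr` (hazard ratio high vs low), `p` (Wald),
#'   `n_high`, `n_low`, `n_events`.
#' @export
median_split_cox <- function(row, surv) {
  if (is.null(names(row))) stop_fmt("row must be named by patient_id")
  common <- intersect(names(row)[!is.na(row) & row > 0], surv$patient_id)
  x <- row[common]
  if (length(x) < 4L) stop_fmt("fewer than 4 patients with IRratio > 0")
  grp <- median_split(x)
  if (min(table(grp)) < 2L) {
    stop_fmt("degenerate median split: a group has < 2 patients")
  }
  s <- surv[match(common, surv$patient_id), ]
  if (sum(s$event) == 0L) stop_fmt("no events among eligible patients")
  fit <- survival::coxph(survival::Surv(time, event) ~ grp,
                         data = data.frame(time = s$time, event = s$event,
                                           grp = grp),
                         ties = "efron")
  sm <- summary(fit)
  list(hr = unname(sm$coefficients[1L, "exp(coef)"]),
       p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
       n_high = sum(grp == "high"), n_low = sum(grp == "low"),
       n_events = sum(s$event))
}

#' Median-split Cox regression on gene expression
#'
#' The gene-expression analog of [median_split_cox()]: genes whose median
#' expression is at or below 1 TPM are skipped (returns `NULL`); otherwise
#' patients are split at the median expression (ties low) and a univariate
#' Cox model is fitted.
#'
#' @param tpm Named numeric vector of TPM values (names = patient ids).
#' @param surv data frame with `patient_id`, `time`, `event`.
#' @param min_median_tpm Expression floor (default 1, strict).
#' @return `NULL` when skipped, else a list as in [median_split_cox()].
#' @export
expression_survival <- function(tpm, surv, min_median_tpm = 1) {
  if (is.null(names(tpm))) stop_fmt("tpm must be named by patient_id")
  tpm <- tpm[!is.na(tpm)]
  if (stats::median(tpm) <= min_median_tpm) return(NULL)
  if (stats::sd(tpm) == 0) stop_fmt("constant expression vector")
  common <- intersect(names(tpm), surv$patient_id)
  x <- tpm[common]
  grp <- median_split(x)
  if (min(table(grp)) < 2L) stop_fmt("degenerate median split")
  s <- surv[match(common, surv$patient_id), ]
  if (sum(s$event) == 0L) stop_fmt("no events among eligible patients")
  fit <- survival::coxph(survival::Surv(time, event) ~ grp,
                         data = data.frame(time = s$time, event = s$event,
                                           grp = grp),
                         ties = "efron")
  sm <- summary(fit)
  list(hr = unname(sm$coefficients[1L, "exp(coef)"]),
       p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
       n_high = sum(grp == "high"), n_low = sum(grp == "low"))
}

#' Fit the LASSO-Cox intron-retention risk (IRR) model
#'
#' Candidate introns are those with a missing rate below 20% (strict);
#' remaining missing cells are mean-imputed. A cross-validated penalized
#' Cox path (LASSO) is fitted over patients, coefficients taken at the
#' lambda minimizing the CV error (`"min"`, default) or at one standard
#' error (`"1se"`). Each patient's IRR score is the sum of their IRratios
#' weighted by the selected coefficients; the cohort median IRR splits
#' patients into high- and low-risk groups (ties go low). Features are
#' standardized inside the penalized fit; coefficients are reported on the
#' original IRratio scale.
#'
#' @param mat An `ir_matrix` or numeric matrix (introns x patients,
#'   `NA` = missing).
#' @param surv data frame with `patient_id`, `time`, `event` covering the
#'   matrix columns.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param max_missing Candidate missing-rate threshold (default 0.20).
#' @param nfolds CV folds for the penalized path (default 10, seeded).
#' @param seed Integer seed (controls CV fold assignment).
#' @return An `irr_model`: list with `intron_ids`, `coefficients`
#'   (nonzero, original scale), `lambda_rule`, `lambda`, `irr` (named
#'   score per patient), `cutoff` (median IRR) and `groups` (factor
#'   low/high).
#' @export
fit_irr <- function(mat, surv, lambda_rule = c("min", "1se"),
                    max_missing = 0.20, nfolds = 10L, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  m <- if (inherits(mat, "ir_matrix")) mat$ir else mat
  m <- m[rowMeans(is.na(m)) < max_missing, , drop = FALSE]
  if (nrow(m) < 2L) stop_fmt("fewer than 2 candidate introns")
  m <- matrix_prep(m, max_missing = 1)  # impute only; rows already filtered
  patients <- intersect(colnames(m), surv$patient_id)
  if (length(patients) < 10L) stop_fmt("fewer than 10 patients with survival")
  s <- surv[match(patients, surv$patient_id), ]
  if (sum(s$event) < 2L) stop_fmt("fewer than 2 events")
  x <- t(m[, patients, drop = FALSE])
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    warning("all features constant: empty model")
    keep[] <- TRUE
  }
  y <- survival::Surv(s$time, s$event)
  cv <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), length(patients)))
    glmnet::cv.glmnet(x[, keep, drop = FALSE], y, family = "cox",
                      alpha = 1, standardize = TRUE, foldid = foldid)
  })
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(stats::coef(cv, s = lam))[, 1L]
  nz <- beta[beta != 0]
  if (length(nz) == 0L) warning("no introns selected: empty model")
  irr <- as.vector(x[, names(nz), drop = FALSE] %*% nz)
  names(irr) <- patients
  cutoff <- stats::median(irr)
  structure(list(intron_ids = names(nz), coefficients = unname(nz),
                 lambda_rule = lambda_rule, lambda = lam,
                 irr = irr, cutoff = cutoff,
                 groups = median_split(irr), cv = cv),
            class = "irr_model")
}

#' @export
print.irr_model <- function(x, ...) {
  cat(sprintf(
    "irr_model: %d introns selected (lambda.%s = %.4g)\n  IRR cutoff (median) %.4g; %d high / %d low risk\n",
    length(x$intron_ids), x$lambda_rule, x$lambda, x$cutoff,
    sum(x$groups == "high"), sum(x$groups == "low")))
  invisible(x)
}

#' @export
coef.irr_model <- function(object, ...) {
  stats::setNames(object$coefficients, object$intron_ids)
}

#' Score new patients with a fitted IRR model
#'
#' @param object An `irr_model`.
#' @param newdata Numeric matrix, introns x patients (must contain the
#'   model's introns; missing cells mean-imputed per intron).
#' @param ... Unused.
#' @return data frame with `patient_id`, `irr` and `group` (split at the
#'   training cutoff).
#' @export
predict.irr_model <- function(object, newdata, ...) {
  miss <- setdiff(object$intron_ids, rownames(newdata))
  if (length(miss)) stop_fmt("newdata lacks intron %s", miss[1L])
  m <- newdata[object$intron_ids, , drop = FALSE]
  m <- t(apply(m, 1L, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  irr <- as.vector(t(m) %*% object$coefficients)
  data.frame(patient_id = colnames(newdata), irr = irr,
             group = factor(ifelse(irr > object$cutoff, "high", "low"),
                            levels = c("low", "high")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and log-rank test for risk groups
#'
#' Product-limit survival estimates per group, a two-sided log-rank test,
#' and the hazard ratio of high vs low risk from a univariate Cox model.
#'
#' @param groups Factor (levels low/high) named by patient id, e.g.
#'   `irr_model$groups`.
#' @param surv data frame with `patient_id`, `time`, `event`.
#' @return List with `fit` (a `survfit` object), `logrank_p`, `hr` and
#'   `n` per group.
#' @export
km_logrank <- function(groups, surv) {
  if (is.null(names(groups))) stop_fmt("groups must be named by patient_id")
  if (nlevels(droplevels(as.factor(groups))) < 2L) {
    stop_fmt("a risk group is empty")
  }
  common <- intersect(names(groups), surv$patient_id)
  s <- surv[match(common, surv$patient_id), ]
  d <- data.frame(time = s$time, event = s$event,
                  group = factor(groups[common], levels = c("low", "high")))
  if (any(table(d$group) == 0L)) stop_fmt("a risk group is empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  cox <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  list(fit = fit, logrank_p = p,
       hr = unname(exp(stats::coef(cox))), n = table(d$group))
}
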