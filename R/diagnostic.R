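#' Cross-validated Random-Forest tumor/normal classifier
#'
#' Repeated stratified 4-fold cross-validation of a Random Forest
#' (default 500 trees, mtry 3) on a dense IRratio feature matrix. Folds are
#' assigned at the patient-pair level so a tumor sample and its paired
#' normal can never straddle the train/test boundary (which would leak the
#' patient's IR profile). Out-of-fold class probabilities from all folds
#' and repeats are pooled into a single AUC; per-repeat AUCs, the ROC of a
#' designated repeat and its 0.5-threshold confusion matrix are also
#' reported, along with a final forest trained on all samples (used by
#' [evaluate_holdout()]).
#'
#' @param x Dense numeric matrix, samples x features (see
#'   [matrix_prep()]; transpose if needed).
#' @param labels Factor or character of class labels ("tumor"/"normal").
#' @param pairs Pair id per sample; `NA` samples are folded individually.
#' @param n_trees,mtry Forest size and variables per split (defaults 500
#'   and 3).
#' @param repeats,folds Cross-validation design (defaults 100 and 4).
#' @param seed Integer seed controlling both fold assignment and forest
#'   construction.
#' @return A `diagnostic_run`: list with `pooled_auc`, `repeat_aucs`,
#'   `roc` (pROC object for repeat 1), `confusion` (2x2 table at
#'   probability 0.5), `importance` (mean decrease in Gini from the final
#'   forest), `forest`, `oof` (pooled out-of-fold probabilities) and the
#'   design parameters.
#' @export
train_eval_cv <- function(x, labels, pairs = NULL, n_trees = 500L,
                          mtry = 3L, repeats = 100L, folds = 4L,
                          seed = 1L) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2L) stop_fmt("need two classes, got %d",
                                     nlevels(labels))
  if (nrow(x) != length(labels)) stop_fmt("labels do not match rows of x")
  if (is.null(pairs)) pairs <- rep(NA_character_, nrow(x))
  units <- ifelse(is.na(pairs), paste0(".solo", seq_len(nrow(x))), pairs)
  pos <- levels(labels)[2L]

  with_seed(seed, {
    oof <- matrix(NA_real_, nrow(x), repeats)
    for (r in seq_len(repeats)) {
      fold <- assign_pair_folds(units, labels, folds)
      stopifnot(all(tapply(fold, units, function(f)
        length(unique(f))) == 1L))  # no pair straddles folds
      for (f in seq_len(folds)) {
        test <- fold == f
        fit <- randomForest::randomForest(
          x[!test, , drop = FALSE], labels[!test],
          ntree = n_trees, mtry = min(mtry, ncol(x)))
        oof[test, r] <- stats::predict(fit, x[test, , drop = FALSE],
                                       type = "prob")[, pos]
      }
    }
    pooled_resp <- rep(labels, repeats)
    pooled_prob <- as.vector(oof)
    pooled_auc <- as.numeric(pROC::auc(pooled_resp, pooled_prob,
                                       levels = levels(labels),
                                       direction = "<", quiet = TRUE))
    repeat_aucs <- apply(oof, 2L, function(p)
      as.numeric(pROC::auc(labels, p, levels = levels(labels),
                           direction = "<", quiet = TRUE)))
    roc1 <- pROC::roc(labels, oof[, 1L], levels = levels(labels),
                      direction = "<", quiet = TRUE)
    pred1 <- factor(ifelse(oof[, 1L] > 0.5, pos, levels(labels)[1L]),
                    levels = levels(labels))
    confusion <- table(truth = labels, predicted = pred1)
    final <- randomForest::randomForest(x, labels, ntree = n_trees,
                                        mtry = min(mtry, ncol(x)),
                                        importance = TRUE)
    structure(list(pooled_auc = pooled_auc, repeat_aucs = repeat_aucs,
                   roc = roc1, confusion = confusion,
                   importance = randomForest::importance(final)[,
                     "MeanDecreaseGini"],
                   forest = final, oof = oof, labels = labels,
                   positive = pos,
                   params = list(n_trees = n_trees, mtry = mtry,
                                 repeats = repeats, folds = folds,
                                 seed = seed)),
              class = "diagnostic_run")
  })
}

# Balanced random fold assignment at the unit (pair) level.
assign_pair_folds <- function(units, labels, folds) {
  uu <- unique(units)
  fu <- sample(rep_len(seq_len(folds), length(uu)))
  names(fu) <- uu
  unname(fu[units])
}

#' @export
print.diagnostic_run <- function(x, ...) {
  cat(sprintf(
    "diagnostic_run: %dx%d-fold CV, %d trees, mtry %d\n  pooled AUC %.3f (per-repeat %.3f-%.3f)\n",
    x$params$repeats, x$params$folds, x$params$n_trees, x$params$mtry,
    x$pooled_auc, min(x$repeat_aucs), max(x$repeat_aucs)))
  invisible(x)
}

#' Feature-reduction curve
#'
#' Ranks features once by importance (mean decrease in Gini from a forest
#' on all data), then estimates 5-fold cross-validated misclassification
#' error on geometrically shrinking feature subsets: the size sequence is
#' `n, ceil(step * n), ...` (always decreasing by at least one) down to 2
#' features.
#'
#' @inheritParams train_eval_cv
#' @param cv_folds Folds for the error estimate (default 5).
#' @param step Geometric reduction factor (default 0.9).
#' @return data frame: `n_features`, `cv_error`.
#' @export
feature_reduction_curve <- function(x, labels, pairs = NULL,
                                    cv_folds = 5L, step = 0.9,
                                    n_trees = 500L, mtry = 3L, seed = 1L) {
  labels <- as.factor(as.character(labels))
  if (is.null(pairs)) pairs <- rep(NA_character_, nrow(x))
  units <- ifelse(is.na(pairs), paste0(".solo", seq_len(nrow(x))), pairs)
  with_seed(seed, {
    full <- randomForest::randomForest(x, labels, ntree = n_trees,
                                       mtry = min(mtry, ncol(x)),
                                       importance = TRUE)
    rank <- order(randomForest::importance(full)[, "MeanDecreaseGini"],
                  decreasing = TRUE)
    sizes <- reduction_sizes(ncol(x), step)
    fold <- assign_pair_folds(units, labels, cv_folds)
    err <- vapply(sizes, function(k) {
      sel <- rank[seq_len(k)]
      wrong <- 0L
      for (f in seq_len(cv_folds)) {
        test <- fold == f
        fit <- randomForest::randomForest(
          x[!test, sel, drop = FALSE], labels[!test],
          ntree = n_trees, mtry = min(mtry, k))
        pr <- stats::predict(fit, x[test, sel, drop = FALSE])
        wrong <- wrong + sum(pr != labels[test])
      }
      wrong / nrow(x)
    }, numeric(1))
    data.frame(n_features = sizes, cv_error = err)
  })
}

# n, ceil(step*n), ... decreasing by at least 1, down to 2.
reduction_sizes <- function(n, step) {
  sizes <- n
  while (n > 2L) {
    n <- min(as.integer(ceiling(step * n)), n - 1L)
    sizes <- c(sizes, n)
  }
  sizes
}

#' Evaluate a trained diagnostic model on a holdout set
#'
#' @param run A `diagnostic_run` from [train_eval_cv()].
#' @param x_new Feature matrix of the holdout samples (same columns).
#' @param labels_new Their class labels.
#' @return List with `auc`, `roc` and `confusion` (0.5 threshold).
#' @export
evaluate_holdout <- function(run, x_new, labels_new) {
  stopifnot(inherits(run, "diagnostic_run"))
  if (is.null(dim(x_new)) || nrow(x_new) == 0L) stop_fmt("empty holdout")
  labels_new <- factor(as.character(labels_new),
                       levels = levels(run$labels))
  if (length(unique(stats::na.omit(labels_new))) < 2L) {
    stop_fmt("holdout AUC undefined: a single class present")
  }
  prob <- stats::predict(run$forest, x_new, type = "prob")[, run$positive]
  roc <- pROC::roc(labels_new, prob, levels = levels(run$labels),
                   direction = "<", quiet = TRUE)
  pred <- factor(ifelse(prob > 0.5, run$positive,
                        levels(run$labels)[1L]),
                 levels = levels(run$labels))
  list(auc = as.numeric(pROC::auc(roc)), roc = roc,
       confusion = table(truth = labels_new, predicted = pred))
}
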