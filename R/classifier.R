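#' Balanced classification accuracy
#'
#' The mean of the per-class correct-classification rates,
#' `(TP / all positives + TN / all negatives) / 2`. For two classes its chance
#' level is 0.5 regardless of class imbalance, which is why it scores the
#' outcome classifiers: positive outcomes outnumber negative ones roughly
#' 5.6 : 1.
#'
#' @param predictions,truth Vectors (or factors) of predicted and true labels
#'   of equal length; `truth` must contain both classes.
#' @param positive The label counted as "positive"; defaults to the last
#'   factor level of `truth`. The score is symmetric in the two roles.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, truth, positive = NULL) {
  if (length(predictions) != length(truth) || length(truth) < 1L) {
    stopf("predictions and truth must be non-empty and of equal length")
  }
  truth <- as.factor(truth)
  classes <- unique(as.character(truth))
  if (length(classes) != 2L) {
    stopf("balanced accuracy requires both classes in truth (found %d)", length(classes))
  }
  if (is.null(positive)) positive <- levels(droplevels(truth))[2L]
  pred <- as.character(predictions)
  tru <- as.character(truth)
  pos <- tru == positive
  sens <- mean(pred[pos] == positive)
  spec <- mean(pred[!pos] != positive)
  (sens + spec) / 2
}

#' Fit a lasso-regularised logistic classifier
#'
#' Minimises the mean logistic negative log-likelihood plus
#' `lambda * ||weights||_1` (intercept unpenalised) over channel weights, the
#' model used for all outcome classifiers. The fit is deterministic given the
#' inputs. Predictors are not standardised: channels share a physical scale.
#'
#' @param X Numeric matrix, epochs x channels.
#' @param y Two-level factor (or coercible) of epoch labels; the fitted
#'   probability refers to the second level.
#' @param lambda Non-negative L1 penalty weight.
#' @param train_bin,contrast,permutation_id Optional bookkeeping stored in the
#'   model (training time-bin index, contrast name, label-permutation index).
#' @return An object of class `classifier_model`: `weights` (one per
#'   channel), `intercept`, `lambda`, `classes` (negative, positive),
#'   `train_bin`, `contrast`, `permutation_id`.
#' @export
train_l1_logistic <- function(X, y, lambda, train_bin = NA_integer_,
                              contrast = NA_character_, permutation_id = NA_integer_) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("y must have exactly two classes")
  if (min(table(y)) < 2L) stopf("need at least 2 exemplars per class")
  if (!all(is.finite(X))) stopf("X must be finite")
  if (lambda < 0) stopf("lambda must be non-negative")

  padded <- ncol(X) == 1L # glmnet requires >= 2 columns
  Xfit <- if (padded) cbind(X, 0) else X
  lseq <- sort(unique(lambda * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  if (lambda == 0) lseq <- c(0.1, 0.05, 0.01, 0)
  fit <- glmnet::glmnet(Xfit, y, family = "binomial", alpha = 1, lambda = lseq,
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  w <- cf[-1L]
  if (padded) w <- w[1L]
  structure(
    list(weights = w, intercept = cf[1L], lambda = lambda,
         classes = levels(y), train_bin = train_bin, contrast = contrast,
         permutation_id = permutation_id),
    class = "classifier_model"
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model %s> %d channels (%d nonzero), lambda=%g, bin=%s\n",
              ifelse(is.na(x$contrast), "", x$contrast), length(x$weights),
              sum(x$weights != 0), x$lambda,
              ifelse(is.na(x$train_bin), "-", x$train_bin)))
  invisible(x)
}

#' Predicted class probabilities of a classifier model
#'
#' @param object A `classifier_model`.
#' @param X Epochs x channels matrix with the model's channel count.
#' @param ... Unused.
#' @return Probability of the positive (second) class per row, via the
#'   logistic sigmoid of the linear score.
#' @export
predict.classifier_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$weights)) {
    stopf("channel mismatch: model has %d weights, data %d channels",
          length(object$weights), ncol(X))
  }
  logistic(drop(X %*% object$weights) + object$intercept)
}

classify <- function(model, X) {
  p <- predict.classifier_model(model, X)
  ifelse(p > 0.5, model$classes[2L], model$classes[1L])
}

cv_predict_bin <- function(X, y, lambda, folds_id) {
  pred <- character(length(y))
  for (f in sort(unique(folds_id))) {
    te <- folds_id == f
    m <- train_l1_logistic(X[!te, , drop = FALSE], y[!te], lambda)
    pred[te] <- classify(m, X[te, , drop = FALSE])
  }
  pred
}

#' Cross-validated balanced-accuracy time course
#'
#' Trains a separate lasso-logistic classifier for every 10-ms time bin of an
#' epoch set and scores it by stratified k-fold cross-validated balanced
#' accuracy (held-out predictions pooled across folds before scoring). With
#' the default 0-750 ms outcome window this yields a 75-value curve whose
#' argmax identifies the peak-discrimination bin.
#'
#' @param epochs An `epoch_set` (typically of kind `"outcome"`).
#' @param labels Epoch labels; default `epochs$meta$outcome`.
#' @param lambda L1 penalty (default 0.025, the fixed value used for bin
#'   selection before per-participant optimisation).
#' @param folds Number of stratified folds (default 5); reduced with a
#'   warning when the rarer class has fewer members.
#' @param seed Seed for the fold assignment.
#' @return An object of class `accuracy_curve`: `accuracy` (one value per
#'   bin), `bin_width`, `window`, `lambda`, `folds`, `n_epochs`, `classes`.
#' @export
accuracy_timecourse <- function(epochs, labels = NULL, lambda = 0.025,
                                folds = 5L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(labels)) labels <- epochs$meta$outcome
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stopf("labels must have exactly two classes")
  n_rare <- min(table(y))
  if (n_rare < 2L) stopf("rarer class has fewer than 2 exemplars")
  if (n_rare < folds) {
    warnf("rarer class has %d exemplars; reducing folds from %d to %d",
          n_rare, folds, n_rare)
    folds <- n_rare
  }
  n_bins <- dim(epochs$data)[3L]
  folds_id <- with_rng_seed(seed, stratified_folds(y, folds))
  acc <- vapply(seq_len(n_bins), function(b) {
    pred <- cv_predict_bin(epochs$data[, , b, drop = TRUE], y, lambda, folds_id)
    balanced_accuracy(pred, y)
  }, numeric(1))
  structure(
    list(accuracy = acc, bin_width = epochs$bin_width, window = epochs$window,
         lambda = lambda, folds = folds, n_epochs = length(y), classes = levels(y)),
    class = "accuracy_curve"
  )
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d bins, peak %.3f at bin %d (%g ms), lambda=%g\n",
              length(x$accuracy), max(x$accuracy), which.max(x$accuracy),
              x$window[1] + (which.max(x$accuracy) - 1) * x$bin_width, x$lambda))
  invisible(x)
}

#' Select the peak time bin and per-participant penalty
#'
#' The peak bin is the argmax of the group-mean accuracy curve (computed with
#' the fixed penalty). The penalty is then freed: for each participant the
#' cross-validated balanced accuracy at the peak bin is evaluated over a
#' lambda grid (a second, independent cross-validation) and the best value is
#' kept, ties resolved towards the larger penalty (sparser model).
#'
#' @param curves List of per-participant [accuracy_timecourse()] results.
#' @param epochs_list List of the matching outcome `epoch_set`s.
#' @param labels_list Optional list of label vectors; default each
#'   `meta$outcome`.
#' @param lambda_grid Candidate penalties; default 20 log-spaced values in
#'   `[1e-4, 1]`.
#' @param folds,seed Cross-validation folds and seed.
#' @return A list: `bin_star` (peak bin index), `group_curve`, `lambda_star`
#'   (one per participant), `cv_accuracy` (participants x grid matrix).
#' @export
select_peak_and_lambda <- function(curves, epochs_list, labels_list = NULL,
                                   lambda_grid = exp(seq(log(1e-4), log(1), length.out = 20)),
                                   folds = 5L, seed = 1L) {
  if (length(curves) < 1L) stopf("at least one participant curve is required")
  if (length(lambda_grid) < 1L) stopf("lambda_grid must be non-empty")
  lambda_grid <- sort(lambda_grid)
  group_curve <- colMeans(do.call(rbind, lapply(curves, `[[`, "accuracy")))
  bin_star <- which.max(group_curve)

  cv_acc <- matrix(NA_real_, length(epochs_list), length(lambda_grid))
  lambda_star <- numeric(length(epochs_list))
  for (s in seq_along(epochs_list)) {
    ep <- epochs_list[[s]]
    y <- droplevels(as.factor(
      if (is.null(labels_list)) ep$meta$outcome else labels_list[[s]]
    ))
    k <- min(folds, min(table(y)))
    folds_id <- with_rng_seed(seed + s, stratified_folds(y, k))
    X <- ep$data[, , bin_star, drop = TRUE]
    for (j in seq_along(lambda_grid)) {
      pred <- cv_predict_bin(X, y, lambda_grid[j], folds_id)
      cv_acc[s, j] <- balanced_accuracy(pred, y)
    }
    best <- which(cv_acc[s, ] == max(cv_acc[s, ]))
    lambda_star[s] <- lambda_grid[max(best)] # ties -> larger penalty, sparser fit
  }
  list(bin_star = bin_star, group_curve = group_curve,
       lambda_star = lambda_star, cv_accuracy = cv_acc,
       lambda_grid = lambda_grid)
}

suite_contrast <- function(X, y, lambda, bin_star, contrast, n_perm) {
  main <- train_l1_logistic(X, y, lambda, train_bin = bin_star, contrast = contrast)
  permuted <- lapply(seq_len(n_perm), function(k) {
    train_l1_logistic(X, sample(y), lambda, train_bin = bin_star,
                      contrast = contrast, permutation_id = k)
  })
  list(model = main, permuted = permuted)
}

#' Build the three outcome classifiers and their permuted null ensembles
#'
#' Trains, at the selected peak bin and penalty, the three contrasts used for
#' decoding — P vs N, P vs baseline, N vs baseline — plus `n_perm` additional
#' classifiers per contrast obtained after random permutation of the labels
#' (the permuted classifiers that furnish null distributions downstream).
#'
#' @param epochs Outcome `epoch_set` with P/N labels.
#' @param baseline Baseline `epoch_set` from [extract_baseline()].
#' @param bin_star Training time-bin index within the outcome window.
#' @param lambda The optimised penalty for this participant.
#' @param n_perm Size of each permuted ensemble (default 100).
#' @param seed Seed controlling the label permutations.
#' @return An object of class `classifier_suite`: `models` (named list of the
#'   three `classifier_model`s), `permuted` (named list of lists), `bin_star`,
#'   `lambda`, `n_labels` (P/N counts, used later for `p_chance`).
#' @export
build_classifier_suite <- function(epochs, baseline, bin_star, lambda,
                                   n_perm = 100L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(baseline, "epoch_set"))
  y_out <- epochs$meta$outcome
  if (!all(c("P", "N") %in% y_out)) stopf("outcome epochs must contain both P and N")
  X_out <- epochs$data[, , bin_star, drop = TRUE]
  X_base <- baseline$data[, , 1L, drop = TRUE]
  if (ncol(X_out) != ncol(X_base)) stopf("outcome and baseline channel counts differ")

  with_rng_seed(seed, {
    res <- list(
      P_vs_N = suite_contrast(
        X_out, factor(y_out, levels = c("N", "P")), lambda, bin_star, "P_vs_N", n_perm),
      P_vs_base = suite_contrast(
        rbind(X_base, X_out[y_out == "P", , drop = FALSE]),
        factor(rep(c("baseline", "P"), c(nrow(X_base), sum(y_out == "P"))),
               levels = c("baseline", "P")),
        lambda, bin_star, "P_vs_base", n_perm),
      N_vs_base = suite_contrast(
        rbind(X_base, X_out[y_out == "N", , drop = FALSE]),
        factor(rep(c("baseline", "N"), c(nrow(X_base), sum(y_out == "N"))),
               levels = c("baseline", "N")),
        lambda, bin_star, "N_vs_base", n_perm)
    )
    structure(
      list(models = lapply(res, `[[`, "model"),
           permuted = lapply(res, `[[`, "permuted"),
           bin_star = bin_star, lambda = lambda,
           n_labels = c(P = sum(y_out == "P"), N = sum(y_out == "N"))),
      class = "classifier_suite"
    )
  })
}

#' @export
print.classifier_suite <- function(x, ...) {
  cat(sprintf("<classifier_suite> bin %d, lambda=%g, %d permuted per contrast; P=%d N=%d\n",
              x$bin_star, x$lambda, length(x$permuted$P_vs_N),
              x$n_labels["P"], x$n_labels["N"]))
  invisible(x)
}

#' Leave-one-condition-out cross-classification
#'
#' Tests whether the outcome code generalises across task conditions: for
#' each level of loss probability (3) and loss magnitude (6), a classifier is
#' trained at the peak bin on all other levels and scored on the held-out
#' level, giving nine held-out balanced accuracies per participant.
#'
#' @param epochs Outcome `epoch_set`.
#' @param bin_star Training time-bin index.
#' @param lambda L1 penalty.
#' @param labels Optional labels; default `meta$outcome`.
#' @return Data frame with columns `condition` (`loss_prob`/`loss_mag`),
#'   `level`, `accuracy`, `n_test`; levels whose train or test role lacks a
#'   class are skipped with a warning and recorded with `NA` accuracy.
#' @seealso [cross_classification_test()] for the group-level Wilcoxon test.
#' @export
cross_classification <- function(epochs, bin_star, lambda, labels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  y <- if (is.null(labels)) epochs$meta$outcome else labels
  y <- factor(y, levels = c("N", "P"))
  X <- epochs$data[, , bin_star, drop = TRUE]
  specs <- rbind(
    data.frame(condition = "loss_prob", level = c("low", "medium", "high"),
               stringsAsFactors = FALSE),
    data.frame(condition = "loss_mag", level = as.character(0:5),
               stringsAsFactors = FALSE)
  )
  res <- specs
  res$accuracy <- NA_real_
  res$n_test <- 0L
  for (i in seq_len(nrow(specs))) {
    hold <- if (specs$condition[i] == "loss_prob") {
      epochs$meta$loss_prob_level == specs$level[i]
    } else {
      epochs$meta$loss_magnitude == as.integer(specs$level[i])
    }
    res$n_test[i] <- sum(hold)
    if (nlevels(droplevels(y[hold])) < 2L || nlevels(droplevels(y[!hold])) < 2L) {
      warnf("held-out level %s=%s lacks a class in train or test; skipped",
            specs$condition[i], specs$level[i])
      next
    }
    m <- train_l1_logistic(X[!hold, , drop = FALSE], y[!hold], lambda,
                           train_bin = bin_star)
    res$accuracy[i] <- balanced_accuracy(classify(m, X[hold, , drop = FALSE]), y[hold])
  }
  res
}

#' Group-level test of cross-classification accuracy
#'
#' One-sided Wilcoxon signed-rank test of the per-participant mean held-out
#' balanced accuracy against the 0.5 chance level, as appropriate for bounded
#' accuracy scores.
#'
#' @param acc_list List of per-participant [cross_classification()] tables.
#' @return A list: `participant_means`, `statistic`, `p_value`.
#' @export
cross_classification_test <- function(acc_list) {
  means <- vapply(acc_list, function(d) mean(d$accuracy, na.rm = TRUE), numeric(1))
  wt <- stats::wilcox.test(means, mu = 0.5, alternative = "greater", exact = FALSE)
  list(participant_means = means, statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Per-loss-probability accuracy time courses
#'
#' Splits the training set by loss-probability level, computes one
#' cross-validated accuracy curve per level at the fixed penalty, and
#' summarises each as its baseline-to-peak accuracy: accuracy at the peak bin
#' minus the mean accuracy over the first 100 ms after outcome onset. Levels
#' lacking either outcome class are omitted with a warning.
#'
#' @param epochs Outcome `epoch_set`.
#' @param bin_star Peak bin at which the summary is read out.
#' @param lambda L1 penalty (default 0.025).
#' @param folds,seed Cross-validation settings.
#' @return A list: `curves` (named list of `accuracy_curve`s),
#'   `baseline_to_peak` (named vector), `bin_star`.
#' @export
per_condition_timecourses <- function(epochs, bin_star, lambda = 0.025,
                                      folds = 5L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  curves <- list()
  for (lev in c("low", "medium", "high")) {
    sel <- epochs$meta$loss_prob_level == lev
    y <- epochs$meta$outcome[sel]
    if (length(unique(y)) < 2L || min(table(y)) < 2L) {
      warnf("level '%s' lacks exemplars of both outcomes; omitted", lev)
      next
    }
    sub <- epochs
    sub$data <- epochs$data[sel, , , drop = FALSE]
    sub$meta <- epochs$meta[sel, , drop = FALSE]
    curves[[lev]] <- accuracy_timecourse(sub, lambda = lambda, folds = folds, seed = seed)
  }
  base_bins <- seq_len(min(10L, dim(epochs$data)[3L])) # 0-100 ms post-outcome
  b2p <- vapply(curves, function(cv) {
    cv$accuracy[bin_star] - mean(cv$accuracy[base_bins])
  }, numeric(1))
  list(curves = curves, baseline_to_peak = b2p, bin_star = bin_star)
}
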