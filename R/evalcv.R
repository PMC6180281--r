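# Leave-one-subject-out cross-validation and performance metrics.
# All sessions of the held-out subject form the test fold; feature
# standardization and lambda selection see training rows only. Test
# metrics are computed on session-level predictions pooled across folds;
# AUC is likewise pooled because a 3-session fold is usually
# single-class.

#' Leave-one-subject-out folds
#'
#' @param groups Subject identifier per row.
#' @return List of folds ordered by subject id, each
#'   `list(subject, train, test)` with integer row indices; the test sets
#'   partition the rows.
#' @export
loso_folds <- function(groups) {
  subj <- sort(unique(groups))
  if (length(subj) < 2) stop_invalid("need at least 2 subjects")
  lapply(subj, function(s) {
    test <- which(groups == s)
    list(subject = s, train = which(groups != s), test = test)
  })
}

#' Confusion-matrix metrics
#'
#' Session-level counts and the derived proportions:
#' accuracy (TN+TP)/(TN+TP+FP+FN), sensitivity TP/(TP+FN) and
#' specificity TN/(TN+FP). The positive class is the more severe group
#' of the contrast.
#'
#' @param y_true,y_pred Label vectors (equal length).
#' @param positive The positive-class label.
#' @return Object of class `eeg_metrics`: TP, TN, FP, FN, sensitivity,
#'   specificity, accuracy.
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop_invalid("'y_true' and 'y_pred' must be non-empty, equal length")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y_true)),
            class = "eeg_metrics")
}

#' @export
print.eeg_metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics> acc %.3f, sens %.3f, spec %.3f (TP %d TN %d FP %d FN %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' Probability that a random positive scores above a random negative,
#' with ties contributing 1/2.
#'
#' @param y_true Labels.
#' @param scores Numeric scores (higher = more positive).
#' @param positive Positive-class label.
#' @return AUC in \[0, 1\], or `NA` (flagged with attribute `undefined`)
#'   when a class is absent.
#' @export
roc_auc <- function(y_true, scores, positive) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(structure(NA_real_, undefined = TRUE))
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the leave-one-subject-out classification pipeline
#'
#' For each subject: z-score features on the training rows, select lambda
#' by nested subject-grouped CV (skipped for `method = "lr"`, which fits
#' unpenalized), fit the penalized model, predict the held-out sessions,
#' and record the non-zero features. Reports pooled test metrics, pooled
#' AUC, and mean per-fold training accuracy.
#'
#' @param features A `feature_table`.
#' @param config An [analysis_config()]; its `contrast` selects the rows.
#' @param tol,max_iter Solver settings passed to [fit_penalized_lr()].
#' @return Object of class `loso_cv`: `folds` (per-subject records:
#'   subject, lambda, selected features, predicted probabilities, truth),
#'   `pooled` (data.frame of all test predictions), `metrics`, `auc`,
#'   `train_accuracy`, `config`.
#' @export
run_loso <- function(features, config = analysis_config(),
                     tol = 1e-7, max_iter = 200) {
  features <- as_feature_table(as.data.frame(features))
  neg <- config$contrast[1]; pos <- config$contrast[2]
  rows <- features$group %in% config$contrast
  if (!any(features$group == neg) || !any(features$group == pos))
    stop_invalid(sprintf("contrast groups %s and %s must both be present",
                         neg, pos))
  tab <- features[rows, , drop = FALSE]
  fc <- feature_cols(tab)
  Xall <- as.matrix(tab[, fc, drop = FALSE])
  keep_rows <- stats::complete.cases(Xall)
  if (!all(keep_rows)) {
    warning(sprintf("dropping %d session rows with missing features",
                    sum(!keep_rows)), call. = FALSE)
    tab <- tab[keep_rows, , drop = FALSE]
    Xall <- Xall[keep_rows, , drop = FALSE]
  }
  y <- as.numeric(tab$group == pos)
  subj <- tab$subject_id
  if (length(unique(subj)) < 3) stop_invalid("need at least 3 subjects")
  unpenalized <- config$method == "lr"
  alpha <- if (config$method == "enet") config$alpha
           else 1  # lasso; also used (inertly) for the lr fit at lambda 0
  folds <- loso_folds(subj)
  fold_out <- vector("list", length(folds))
  train_acc <- numeric(length(folds))
  for (i in seq_along(folds)) {
    fo <- folds[[i]]
    Xtr <- Xall[fo$train, , drop = FALSE]
    ytr <- y[fo$train]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- scale(Xall[fo$test, , drop = FALSE], mu, sdv)
    if (unpenalized) {
      lam <- 0
      fit <- suppressWarnings(
        fit_penalized_lr(Xtr, ytr, 0, 1, tol, max_iter))
    } else {
      sel <- select_lambda_nested(Xtr, ytr, subj[fo$train], alpha,
                                  inner_folds = config$inner_folds,
                                  K = config$lambda_grid_size,
                                  seed = .sub_seed(config$seed, i))
      lam <- sel$lambda
      fit <- fit_penalized_lr(Xtr, ytr, lam, alpha, tol, max_iter)
    }
    ptr <- predict_proba(fit, Xtr)
    train_acc[i] <- mean((ptr > 0.5) == (ytr == 1))
    pte <- predict_proba(fit, Xte)
    fold_out[[i]] <- list(
      subject = fo$subject, lambda = lam,
      selected = fc[abs(fit$beta) > 1e-8],
      prob = pte, truth = tab$group[fo$test],
      session = tab$session_id[fo$test],
      converged = fit$converged, kkt_residual = fit$kkt_residual)
  }
  pooled <- do.call(rbind, lapply(fold_out, function(f)
    data.frame(subject_id = f$subject, session_id = f$session,
               truth = f$truth, prob = f$prob,
               pred = ifelse(f$prob > 0.5, pos, neg),
               stringsAsFactors = FALSE)))
  structure(list(folds = fold_out, pooled = pooled,
                 metrics = confusion_metrics(pooled$truth, pooled$pred, pos),
                 auc = roc_auc(pooled$truth, pooled$prob, pos),
                 train_accuracy = mean(train_acc),
                 feature_names = fc, config = config),
            class = "loso_cv")
}

#' @export
print.loso_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<loso_cv> %s %s-vs-%s: test acc %.1f%%, sens %.1f%%, spec %.1f%%, train acc %.1f%%, AUC %.2f (%d folds)\n",
    x$config$method, x$config$contrast[1], x$config$contrast[2],
    100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity,
    100 * x$train_accuracy, x$auc, length(x$folds)))
  invisible(x)
}

#' Summarize a set of CV runs as a performance table
#'
#' @param ... `loso_cv` objects.
#' @return data.frame: method, contrast, sensitivity/specificity/test and
#'   train accuracy (percent), AUC.
#' @export
performance_table <- function(...) {
  runs <- list(...)
  do.call(rbind, lapply(runs, function(r) {
    m <- r$metrics
    data.frame(method = r$config$method,
               contrast = paste(r$config$contrast, collapse = " vs "),
               sensitivity_pct = 100 * m$sensitivity,
               specificity_pct = 100 * m$specificity,
               test_accuracy_pct = 100 * m$accuracy,
               train_accuracy_pct = 100 * r$train_accuracy,
               auc = r$auc, stringsAsFactors = FALSE)
  }))
}
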