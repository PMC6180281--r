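# Penalized logistic regression fitted natively by IRLS + coordinate
# descent (src/enet.cpp). Maximization objective:
#   sum_i [ y_i eta_i - log(1 + exp(eta_i)) ]
#     - lambda * sum_j [ (1 - alpha) beta_j^2 + alpha |beta_j| ]
# alpha = 1 is the LASSO; the intercept is never penalized. Columns are
# assumed standardized by the caller (run_loso z-scores on the training
# fold), which makes a single lambda meaningful across features.

#' Penalized logistic-regression objective
#'
#' Evaluates the maximization objective: Bernoulli log-likelihood minus
#' `lambda * sum((1 - alpha) * beta^2 + alpha * abs(beta))`. With
#' `alpha = 1` this is exactly the L1-penalized (LASSO) logistic
#' objective.
#'
#' @param beta0 Intercept.
#' @param beta Coefficient vector (length = `ncol(X)`).
#' @param X n x p numeric matrix.
#' @param y Binary labels in \{0, 1\}.
#' @param lambda Penalty weight, >= 0.
#' @param alpha Elastic-net trade-off in \[0, 1\].
#' @return Scalar objective value (to be maximized).
#' @export
penalized_objective <- function(beta0, beta, X, y, lambda, alpha) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop_invalid("length(beta) != ncol(X)")
  if (length(y) != nrow(X)) stop_invalid("length(y) != nrow(X)")
  if (!all(y %in% c(0, 1))) stop_invalid("'y' must be binary 0/1")
  if (lambda < 0 || alpha < 0 || alpha > 1)
    stop_invalid("need lambda >= 0 and alpha in [0, 1]")
  eta <- drop(beta0 + X %*% beta)
  ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                             log1p(exp(eta))))
  ll - lambda * sum((1 - alpha) * beta^2 + alpha * abs(beta))
}

#' Fit penalized logistic regression
#'
#' Solves the elastic-net logistic problem by iteratively reweighted
#' least squares with coordinate descent on each quadratic subproblem and
#' step-halving, so the objective never decreases. Convergence is
#' declared when the subgradient (KKT) residual of the exact problem
#' falls below `tol`. With `lambda = 0` on separable data (p > n) the
#' likelihood has no maximizer; the fit then stops at `max_iter` with
#' `converged = FALSE` and a warning.
#'
#' @param X n x p matrix (standardized columns recommended).
#' @param y Binary labels in \{0, 1\}; both classes must be present.
#' @param lambda Penalty weight >= 0.
#' @param alpha Elastic-net trade-off in \[0, 1\] (1 = LASSO).
#' @param tol KKT tolerance (default 1e-7).
#' @param max_iter IRLS iteration cap (default 200).
#' @param init Optional list(beta0, beta) warm start.
#' @return Object of class `penalized_lr`: `beta0`, `beta` (named by
#'   columns of X), `lambda`, `alpha`, `objective`, `converged`,
#'   `n_iter`, `kkt_residual`, `objective_trace`.
#' @export
fit_penalized_lr <- function(X, y, lambda, alpha = 1, tol = 1e-7,
                             max_iter = 200, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_invalid("'y' must be binary 0/1")
  if (length(unique(y)) < 2)
    stop_invalid("'y' must contain both classes")
  if (nrow(X) < 2) stop_invalid("need at least 2 samples")
  if (lambda < 0 || alpha < 0 || alpha > 1)
    stop_invalid("need lambda >= 0 and alpha in [0, 1]")
  p <- ncol(X)
  beta0 <- if (is.null(init)) 0 else init$beta0
  beta <- if (is.null(init)) numeric(p) else init$beta
  fit <- enet_irls(X, y, lambda, alpha, tol, as.integer(max_iter),
                   beta0, beta)
  if (!fit$converged && lambda > 0)
    warning("fit_penalized_lr: IRLS did not reach the KKT tolerance",
            call. = FALSE)
  structure(list(beta0 = fit$beta0,
                 beta = stats::setNames(drop(fit$beta), colnames(X)),
                 lambda = lambda, alpha = alpha,
                 objective = fit$objective, converged = fit$converged,
                 n_iter = fit$n_iter, kkt_residual = fit$kkt_residual,
                 objective_trace = fit$objective_trace),
            class = "penalized_lr")
}

#' @export
print.penalized_lr <- function(x, ...) {
  cat(sprintf(
    "<penalized_lr> lambda = %.4g, alpha = %.2f, %d/%d nonzero, %sconverged (%d it)\n",
    x$lambda, x$alpha, sum(x$beta != 0), length(x$beta),
    if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Penalty path for the elastic net
#'
#' `lambda_max = max_j |sum_i x_ij (y_i - mean(y))| / alpha` is the
#' smallest penalty at which the all-zero coefficient vector (with the
#' null intercept) satisfies the KKT conditions; the grid is log-spaced
#' over `[1e-3 * lambda_max, lambda_max]`, decreasing.
#'
#' @param X n x p matrix.
#' @param y Binary labels.
#' @param alpha Trade-off, must be > 0 (the ridge path has no finite
#'   `lambda_max`).
#' @param K Grid size (default 50).
#' @return Decreasing numeric vector of length `K`.
#' @export
lambda_path <- function(X, y, alpha = 1, K = 50) {
  if (alpha <= 0)
    stop_invalid("'alpha' must be > 0; supply a manual grid for ridge")
  X <- as.matrix(X)
  # the relative 1e-9 inflation keeps the all-zero solution strictly
  # inside the null region despite float rounding of the score
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / alpha * (1 + 1e-9)
  exp(seq(log(lam_max), log(1e-3 * lam_max), length.out = K))
}

#' Select lambda by nested subject-grouped cross-validation
#'
#' Splits the training subjects into `inner_folds` groups (all sessions
#' of a subject stay together), fits the full [lambda_path()] with warm
#' starts on each inner training set, and returns the lambda minimizing
#' the mean held-out binomial deviance.
#'
#' @param X n x p matrix (rows = sessions).
#' @param y Binary labels.
#' @param groups Subject identifier per row.
#' @param alpha Elastic-net trade-off (> 0).
#' @param inner_folds Number of inner folds (default 5).
#' @param K Grid size (default 50).
#' @param seed Seed for the subject shuffle; results are deterministic
#'   given it.
#' @return List: `lambda` (the selected value), `grid`, `mean_deviance`,
#'   `fold_assignment` (named subject -> inner fold).
#' @export
select_lambda_nested <- function(X, y, groups, alpha = 1, inner_folds = 5,
                                 K = 50, seed = 1L) {
  X <- as.matrix(X)
  subj <- unique(groups)
  cls_per_subj <- tapply(y, groups, function(v) v[1])
  if (min(table(cls_per_subj)) < inner_folds)
    stop_invalid(sprintf(
      "need at least %d subjects per class for %d inner folds",
      inner_folds, inner_folds))
  grid <- lambda_path(X, y, alpha, K)
  set.seed(seed)
  # round-robin assignment within class keeps folds class-balanced
  fold_of <- integer(length(subj))
  names(fold_of) <- subj
  for (cl in unique(cls_per_subj)) {
    s <- sample(subj[cls_per_subj[subj] == cl])
    fold_of[s] <- rep_len(seq_len(inner_folds), length(s))
  }
  dev <- matrix(NA_real_, inner_folds, K)
  for (f in seq_len(inner_folds)) {
    test <- groups %in% names(fold_of)[fold_of == f]
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- scale(X[test, , drop = FALSE], mu, sdv)
    init <- NULL
    for (k in seq_len(K)) {
      # inner-CV fits only feed deviance estimates; a looser KKT
      # tolerance than the final fit is ample and much faster
      fit <- fit_penalized_lr(Xtr, ytr, grid[k], alpha,
                              tol = 1e-4, max_iter = 100, init = init)
      init <- list(beta0 = fit$beta0, beta = fit$beta)
      pr <- predict_proba(fit, Xte)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      dev[f, k] <- -2 * mean(y[test] * log(pr) + (1 - y[test]) * log(1 - pr))
    }
  }
  md <- colMeans(dev)
  list(lambda = grid[which.min(md)], grid = grid, mean_deviance = md,
       fold_assignment = fold_of)
}

#' Predicted class-1 probabilities
#'
#' @param model A `penalized_lr`.
#' @param X Matrix with `length(model$beta)` columns.
#' @return Vector of probabilities `1 / (1 + exp(-(beta0 + X beta)))`,
#'   strictly inside (0, 1) for finite inputs.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta))
    stop_invalid(sprintf("X has %d columns, model expects %d",
                         ncol(X), length(model$beta)))
  drop(1 / (1 + exp(-(model$beta0 + X %*% model$beta))))
}
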