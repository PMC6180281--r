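# Canonical correlation analysis between the entropy feature set and the
# 12 symptom scores, solved by SVD of the whitened cross-covariance with
# pseudo-inverse whitening so rank-deficient (p > n) feature blocks are
# handled without regularization. In that regime the centered feature
# matrix spans the whole sample space and the leading canonical
# correlations are exactly 1 — the expected degenerate geometry, not an
# error.

#' Fit canonical correlation analysis
#'
#' Centers both blocks, whitens each by its thin SVD (dropping singular
#' values below a rank tolerance), and takes the SVD of the whitened
#' cross-product. Returns `k = min(rank(Xc), rank(Yc), ncol(Y))`
#' canonical pairs with non-increasing correlations in \[0, 1\];
#' successive canonical variates are uncorrelated within each block.
#'
#' @param X n x p numeric matrix (feature block).
#' @param Y n x q numeric matrix (symptom block); constant columns are
#'   dropped with a warning.
#' @return Object of class `cca_model`: `u_weights` (p x k), `v_weights`
#'   (q x k), `correlations` (length k), `x_center`, `y_center`,
#'   `x_structure`, `y_structure` (filled by
#'   [structure_coefficients()]), `kept_y` (Y columns used).
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y need equal row counts")
  n <- nrow(X)
  if (n < 3) stop_invalid("need at least 3 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  const_y <- apply(Y, 2, function(v) stats::var(v) == 0 || is.na(stats::var(v)))
  if (all(const_y)) stop_invalid("all Y columns are constant")
  if (any(const_y)) {
    warning(sprintf("dropping %d constant Y column(s): %s",
                    sum(const_y),
                    paste(colnames(Y)[const_y], collapse = ", ")),
            call. = FALSE)
    Y <- Y[, !const_y, drop = FALSE]
  }
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  sx <- svd(Xc); sy <- svd(Yc)
  rtol <- function(s) max(dim(Xc)) * .Machine$double.eps * s$d[1]
  rx <- sum(sx$d > rtol(sx)); ry <- sum(sy$d > rtol(sy))
  if (rx == 0 || ry == 0) stop_invalid("a block has rank 0 after centering")
  Qx <- sx$u[, seq_len(rx), drop = FALSE]
  Qy <- sy$u[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  k <- min(rx, ry, ncol(Y))
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  # back-transform whitened directions to variable weights
  u_w <- sx$v[, seq_len(rx), drop = FALSE] %*%
    (sv$u[, seq_len(k), drop = FALSE] / sx$d[seq_len(rx)])
  v_w <- sy$v[, seq_len(ry), drop = FALSE] %*%
    (sv$v[, seq_len(k), drop = FALSE] / sy$d[seq_len(ry)])
  dimnames(u_w) <- list(colnames(X), paste0("cv", seq_len(k)))
  dimnames(v_w) <- list(colnames(Y), paste0("cv", seq_len(k)))
  model <- structure(list(u_weights = u_w, v_weights = v_w,
                          correlations = rho, k = k,
                          x_center = xc, y_center = yc,
                          kept_y = colnames(Y),
                          x_structure = NULL, y_structure = NULL),
                     class = "cca_model")
  sc <- structure_coefficients(model, X, Y)
  model$x_structure <- sc$x
  model$y_structure <- sc$y
  model
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> %d canonical pairs; correlations: %s\n",
              x$k, paste(sprintf("%.3f", x$correlations), collapse = " ")))
  invisible(x)
}

#' Canonical variates (scores) of a fitted model
#'
#' @param model A `cca_model`.
#' @param X,Y Data blocks on the model's variables.
#' @return List with n x k matrices `U` and `V`.
#' @export
canonical_variates <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  Y <- Y[, model$kept_y, drop = FALSE]
  if (ncol(X) != nrow(model$u_weights))
    stop_invalid("X column count does not match the fitted model")
  list(U = sweep(X, 2, model$x_center) %*% model$u_weights,
       V = sweep(Y, 2, model$y_center) %*% model$v_weights)
}

#' Structure coefficients of a fitted CCA
#'
#' Correlation of every original variable with the canonical variates of
#' its own block — the loadings of the variables in canonical space.
#' Constant columns yield `NA` entries.
#'
#' @param model A `cca_model`.
#' @param X,Y The data the model was fitted on.
#' @return List of matrices `x` (p x k) and `y` (q x k), entries in
#'   \[-1, 1\] or `NA`.
#' @export
structure_coefficients <- function(model, X, Y) {
  sc <- canonical_variates(model, X, Y)
  safe_cor <- function(M, V) {
    out <- suppressWarnings(stats::cor(M, V))
    out[!is.finite(out)] <- NA_real_
    out
  }
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  list(x = safe_cor(as.matrix(X), sc$U),
       y = safe_cor(Y[, model$kept_y, drop = FALSE], sc$V))
}

#' Rank canonical pairs by feature-side loading strength
#'
#' Orders the canonical pairs by the maximum absolute feature-side
#' structure coefficient, the criterion used to decide which pairs carry
#' interpretable entropy signal.
#'
#' @param model A fitted `cca_model` (with structure coefficients).
#' @return List: `ranking` (data.frame pair, max_abs_x_loading, rank) and
#'   `long` (data.frame pair, variable, side, coefficient) suitable for
#'   CSV export.
#' @export
rank_canonical_pairs <- function(model) {
  if (is.null(model$x_structure))
    stop_invalid("model lacks structure coefficients")
  strength <- apply(abs(model$x_structure), 2, max, na.rm = TRUE)
  ranking <- data.frame(pair = seq_len(model$k),
                        max_abs_x_loading = as.numeric(strength),
                        rank = rank(-strength, ties.method = "first"))
  melt <- function(M, side) {
    data.frame(pair = rep(seq_len(ncol(M)), each = nrow(M)),
               variable = rep(rownames(M), ncol(M)),
               side = side, coefficient = as.vector(M),
               stringsAsFactors = FALSE)
  }
  rownames(model$x_structure) <- rownames(model$u_weights)
  rownames(model$y_structure) <- rownames(model$v_weights)
  list(ranking = ranking,
       long = rbind(melt(model$x_structure, "mse"),
                    melt(model$y_structure, "npi")))
}

#' Subject-averaged feature matrix for CCA
#'
#' Averages each subject's session rows so one row per subject pairs
#' with one symptom-score row, avoiding pseudo-replication of identical
#' score rows.
#'
#' @param features A `feature_table`.
#' @return List: `X` (subjects x features matrix), `subject_id`, `group`.
#' @export
subject_average_features <- function(features) {
  features <- as_feature_table(as.data.frame(features))
  fc <- feature_cols(features)
  subj <- sort(unique(features$subject_id))
  X <- t(vapply(subj, function(s) {
    colMeans(as.matrix(features[features$subject_id == s, fc, drop = FALSE]))
  }, numeric(length(fc))))
  rownames(X) <- subj
  grp <- features$group[match(subj, features$subject_id)]
  list(X = X, subject_id = subj, group = grp)
}
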