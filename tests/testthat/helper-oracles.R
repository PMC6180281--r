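# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# naive O(M^2) sample-entropy counter, straight from the definition
sampen_naive <- function(y, m, r) {
  M <- length(y)
  n_tpl <- M - m
  nm <- 0L
  nm1 <- 0L
  for (k in 1:(n_tpl - 1)) {
    for (l in (k + 1):n_tpl) {
      if (max(abs(y[k:(k + m - 1)] - y[l:(l + m - 1)])) < r) {
        nm <- nm + 1L
        if (abs(y[k + m] - y[l + m]) < r) nm1 <- nm1 + 1L
      }
    }
  }
  if (nm == 0L || nm1 == 0L) NA_real_ else -log(nm1 / nm)
}

# all-pairs AUC counter
auc_naive <- function(y_true, scores, positive) {
  sp <- scores[y_true == positive]
  sn <- scores[y_true != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# direct term-by-term transcription of the penalized logistic objective
objective_naive <- function(beta0, beta, X, y, lambda, alpha) {
  s <- 0
  for (i in seq_len(nrow(X))) {
    eta <- beta0 + sum(beta * X[i, ])
    s <- s + y[i] * eta - log(1 + exp(eta))
  }
  pen <- 0
  for (b in beta) pen <- pen + (1 - alpha) * b^2 + alpha * abs(b)
  s - lambda * pen
}
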