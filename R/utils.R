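`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Mann-Whitney AUC with 0.5 credit for ties; hot-loop primitive shared by the
# ROC surface, the combination benchmark and the exhaustive search.
.fast_auc <- function(scores, labels) {
  r <- rank(scores)
  m <- sum(labels == 1L)
  n <- length(labels) - m
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# Ridge-penalized logistic IRLS. Used as the fallback when the unpenalized
# fit separates (common for 20-predictor models on small cohorts); the
# intercept is never penalized.
.irls_ridge <- function(Xd, y, lambda, maxit = 200L, tol = 1e-10) {
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1L))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + diag(pen, p)
    beta_new <- tryCatch(drop(solve(H, crossprod(Xd, w * z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  prob <- stats::plogis(drop(Xd %*% beta))
  list(coefficients = beta, prob = prob, converged = converged)
}

# Predicted probabilities for a gene submatrix: unpenalized ML first, ridge
# fallback on separation or non-convergence.
.logit_prob <- function(Xi, y, ridge = 1e-2) {
  Xd <- cbind(1, Xi)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  p <- fit$fitted.values
  if (!fit$converged || any(p < 1e-8) || any(p > 1 - 1e-8)) {
    p <- .irls_ridge(Xd, y, ridge)$prob
  }
  p
}

# Uppercase-normalize gene symbols (trimmed); applied at every ingestion
# point so matrices, GMT pools and annotations agree on identity.
.norm_symbols <- function(x) toupper(trimws(as.character(x)))

.check_binary <- function(y, what = "y") {
  .assert(all(y %in% c(0, 1)), what, " must contain only 0/1 values")
  .assert(length(unique(y)) == 2L, what, " must contain both classes")
}
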