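#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, computed with
#' [survival::survfit()] and returned in a compact form keyed to the event
#' times (the points where the curve actually steps).
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return An object of class `km_curve` with fields `event_times`,
#'   `survival_prob`, `n_at_risk` (all aligned, one entry per distinct event
#'   time) and `n` (sample size). Censored-only input yields a flat curve at 1
#'   (no event times).
#' @seealso [km_survival_at()], [logrank_test()]
#' @export
km_estimate <- function(times, events) {
  .assert(length(times) > 0L, "empty survival input")
  .assert(length(times) == length(events), "times and events differ in length")
  .assert(all(is.finite(times)) && all(times >= 0), "times must be finite and non-negative")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- sf$n.event > 0
  structure(list(
    event_times = sf$time[keep],
    survival_prob = sf$surv[keep],
    n_at_risk = sf$n.risk[keep],
    n = length(times),
    n_events = sum(events)
  ), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the (right-continuous) step function.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  f <- stats::stepfun(curve$event_times, c(1, curve$survival_prob))
  f(t)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' First event time at which the survival probability drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#' @param curve A `km_curve`.
#' @return A single time or `NA`.
#' @export
km_median <- function(curve) {
  i <- which(curve$survival_prob <= 0.5)
  if (length(i) == 0L) return(NA_real_)
  curve$event_times[min(i)]
}

# Restricted mean survival up to tmax (area under the KM step function);
# direction fallback when medians are undefined.
.km_rmean <- function(curve, tmax) {
  ts <- c(0, curve$event_times[curve$event_times < tmax], tmax)
  ss <- c(1, curve$survival_prob[curve$event_times < tmax])
  sum(diff(ts) * ss)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$n_events, "\n")
  if (length(x$event_times)) {
    cat("  last event time:", max(x$event_times),
        " S =", signif(min(x$survival_prob), 4), "\n")
  } else {
    cat("  no events (flat curve at 1)\n")
  }
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Two or more groups are compared with the (k-sample) log-rank chi-square
#' statistic via [survival::survdiff()]; the p-value is the upper tail of the
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Group labels (any type coercible to factor); every level must
#'   be non-empty.
#' @return An object of class `logrank_result` with `statistic`, `df`,
#'   `p_value` and per-group observed/expected counts.
#' @export
logrank_test <- function(times, events, group) {
  .assert(length(times) == length(events) && length(times) == length(group),
          "times, events and group must have equal length")
  g <- factor(group)
  .assert(nlevels(g) >= 2L, "need at least two groups")
  .assert(all(table(g) > 0L), "every group must be non-empty")
  .assert(sum(events) > 0, "log-rank test undefined with no events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  stat <- unname(sd$chisq)
  structure(list(
    statistic = stat,
    df = df,
    p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
    observed = sd$obs,
    expected = sd$exp,
    groups = levels(g)
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Wilcoxon test for differential expression
#'
#' Two-sided Wilcoxon test: signed-rank when `paired = TRUE` (tumor vs
#' matched adjacent normal), rank-sum otherwise.
#'
#' @param x,y Numeric value vectors (equal length required when paired).
#' @param paired Use the signed-rank test on paired differences.
#' @return Two-sided p-value.
#' @export
wilcoxon_de_test <- function(x, y, paired = FALSE) {
  if (paired) {
    .assert(length(x) == length(y), "paired mode requires equal lengths")
    .assert(any(x - y != 0), "all paired differences are zero")
  }
  suppressWarnings(stats::wilcox.test(x, y, paired = paired)$p.value)
}

#' Logistic regression with separation-safe fallback
#'
#' Maximum-likelihood logistic fit of a binary outcome (vital status: 1 =
#' dead) on gene expression columns. When the ML fit does not converge or the
#' data are separable (fitted probabilities pinned to 0/1), the model is
#' refitted with a small fixed ridge penalty on the gene coefficients and the
#' `converged` flag is set to `FALSE` so downstream consumers know the fit is
#' penalized.
#'
#' @param X Sample-by-gene numeric matrix.
#' @param y 0/1 outcome containing both classes.
#' @param ridge Non-negative ridge penalty used only by the fallback.
#' @return An object of class `logit_fit` with `gene_names`, `intercept`,
#'   `coefficients`, `converged`, `penalized`, `aic`, `loglik` and
#'   `predicted_prob`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .assert(all(is.finite(X)), "X must be finite")
  .assert(nrow(X) == length(y), "nrow(X) must equal length(y)")
  .check_binary(y)
  .assert(ridge >= 0, "ridge must be non-negative")
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  prob <- fit$fitted.values
  separated <- any(prob < 1e-8) || any(prob > 1 - 1e-8)
  penalized <- FALSE
  if (!fit$converged || separated) {
    pf <- .irls_ridge(Xd, y, ridge)
    coefs <- pf$coefficients
    prob <- pf$prob
    penalized <- TRUE
    converged <- FALSE
    k <- ncol(Xd)
  } else {
    coefs <- fit$coefficients
    converged <- TRUE
    k <- fit$rank
  }
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(prob) + (1 - y) * log(1 - prob))
  structure(list(
    gene_names = nm,
    intercept = unname(coefs[1]),
    coefficients = stats::setNames(coefs[-1], nm),
    converged = converged,
    penalized = penalized,
    aic = 2 * k - 2 * ll,
    loglik = ll,
    predicted_prob = unname(prob)
  ), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic model on", length(x$gene_names), "genes;",
      if (x$penalized) "ridge-penalized (separation fallback)" else "ML fit",
      "\n  AIC:", signif(x$aic, 6), "\n")
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

# DeLong placement values: V10 per positive, V01 per negative.
.delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg))
  V10 <- (r_all[seq_len(m)] - rank(pos)) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
}

#' Area under the ROC curve with DeLong variance
#'
#' AUC computed as the Mann-Whitney statistic (ties receive 0.5 credit), with
#' the DeLong structural-components variance estimate.
#'
#' @param scores Numeric classifier scores (higher = more likely positive).
#' @param labels 0/1 class labels containing both classes.
#' @return An object of class `roc_result` with `auc`, `variance`, `n_pos`,
#'   `n_neg`.
#' @export
auc <- function(scores, labels) {
  .assert(length(scores) == length(labels), "scores and labels differ in length")
  .assert(all(is.finite(scores)), "scores must be finite")
  .check_binary(labels, "labels")
  pl <- .delong_placements(scores, labels)
  v <- stats::var(pl$V10) / pl$m + stats::var(pl$V01) / pl$n
  structure(list(auc = pl$auc, variance = v, n_pos = pl$m, n_neg = pl$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (DeLong SE %.4f; %d pos / %d neg)\n",
              x$auc, sqrt(x$variance), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of two classifiers scored on the same samples, using the
#' DeLong covariance of placement values and a two-sided normal
#' approximation on the AUC difference.
#'
#' @param scores_a,scores_b Score vectors for the two classifiers (same
#'   samples, same order).
#' @param labels Shared 0/1 labels.
#' @return An object of class `delong_test` with `auc_a`, `auc_b`, `delta`,
#'   `z` and `p_value`. Identical (or rank-identical) scores give `p_value`
#'   1; degenerate variance with unequal AUCs is an error.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  .assert(length(scores_a) == length(scores_b), "score vectors differ in length")
  .assert(length(scores_a) == length(labels), "scores and labels differ in length")
  .check_binary(labels, "labels")
  pa <- .delong_placements(scores_a, labels)
  pb <- .delong_placements(scores_b, labels)
  delta <- pa$auc - pb$auc
  v <- stats::var(pa$V10 - pb$V10) / pa$m + stats::var(pa$V01 - pb$V01) / pa$n
  if (v < 1e-16) {
    .assert(abs(delta) < 1e-12,
            "degenerate DeLong variance with unequal AUCs; ",
            "scores may be constant or perfectly anti-correlated")
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
                 p_value = p), class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.4f vs %.4f, delta = %.4f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$p_value))
  invisible(x)
}
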