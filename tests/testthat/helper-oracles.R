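# From-definition oracles, independent of the implementation paths they
# check. All are deliberately naive (brute force / O(n^2) / enumeration).

# Product-limit estimator straight from the definition.
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(times >= ts[i])
    d_i <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(event_times = ts, survival_prob = surv)
}

# Two-group log-rank statistic by brute-force accumulation of the 2x2
# hypergeometric moments at each event time.
logrank_oracle <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d_t <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n_t - d_t) / (n_t - 1) * (n1 / n_t) * (1 - n1 / n_t)
    }
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# AUC by O(n^2) counting over all positive/negative pairs, half credit for
# ties.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (tie-free differences assumed).
signed_rank_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  min(1, p)
}

# Prefix standard deviations recomputed one prefix at a time.
prefix_sd_oracle <- function(values, decreasing = TRUE) {
  sorted <- values[order(values, decreasing = decreasing)]
  vapply(3:length(sorted), function(k) sd(sorted[1:k]), numeric(1))
}

# Independent exhaustive best-subset search using the public model-fitting
# surface (fit_logistic + auc), not the internal fast path.
exhaustive_oracle <- function(genes, X, y) {
  m <- length(genes)
  best_auc <- -Inf
  best <- NULL
  for (s in 1:(2^m - 1)) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0L)
    fit <- fit_logistic(X[, genes[idx], drop = FALSE], y)
    a <- auc(fit$predicted_prob, y)$auc
    if (a > best_auc + 1e-12) {
      best_auc <- a
      best <- sort(genes[idx])
    }
  }
  list(best_subset = best, best_auc = best_auc)
}
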