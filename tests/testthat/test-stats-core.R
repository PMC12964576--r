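test_that("Kaplan-Meier estimate matches hand results and the product-limit definition", {
  # no events: flat at 1
  flat <- km_estimate(c(5, 8), c(0, 0))
  expect_length(flat$event_times, 0)
  expect_equal(km_survival_at(flat, c(0, 10, 100)), c(1, 1, 1))

  # two events by hand: S = 0.5 on [1,2), 0 at 2
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$event_times, c(1, 2))
  expect_equal(km$survival_prob, c(0.5, 0))
  expect_equal(km_survival_at(km, c(0.5, 1, 1.5, 2)), c(1, 0.5, 0.5, 0))

  # from-definition oracle on random instances (with ties)
  for (seed in 1:25) {
    d <- random_survival(30, seed)
    km <- km_estimate(d$times, d$events)
    or <- km_oracle(d$times, d$events)
    expect_equal(km$event_times, or$event_times)
    expect_equal(km$survival_prob, or$survival_prob, tolerance = 1e-12)
  }
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches the hypergeometric-moment oracle and is label-symmetric", {
  # duplicated groups: O = E, statistic 0, p 1
  tm <- c(3, 5, 7, 9, 11, 13)
  ev <- c(1, 0, 1, 1, 0, 1)
  r0 <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  for (seed in 1:25) {
    d <- random_survival(12, seed)
    if (length(unique(d$group)) < 2 || sum(d$events) == 0) next
    r <- logrank_test(d$times, d$events, d$group)
    or <- logrank_oracle(d$times, d$events, d$group)
    expect_equal(r$statistic, or$statistic, tolerance = 1e-8)
    expect_equal(r$p_value, or$p_value, tolerance = 1e-8)
    # swapping labels leaves the result unchanged
    r2 <- logrank_test(d$times, d$events, 1 - d$group)
    expect_equal(r$statistic, r2$statistic, tolerance = 1e-12)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "two groups")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(0, 1)), "no events")
})

test_that("log-rank p-value agrees with a permutation null at small n", {
  d <- random_survival(12, 42)
  obs <- logrank_test(d$times, d$events, d$group)$statistic
  set.seed(7)
  n_perm <- 4000
  perm <- replicate(n_perm, {
    logrank_test(d$times, d$events, sample(d$group))$statistic
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_asym <- logrank_test(d$times, d$events, d$group)$p_value
  # Monte-Carlo + chi-square approximation slack at n = 12
  expect_lt(abs(p_perm - p_asym), 0.08)
})

test_that("Wilcoxon wrapper: exact enumeration agreement, shift power, degenerate input", {
  expect_error(wilcoxon_de_test(1:5, 1:5, paired = TRUE), "zero")

  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(8)
    y <- rnorm(8)
    expect_equal(wilcoxon_de_test(x, y, paired = TRUE),
                 signed_rank_enum_oracle(x, y), tolerance = 1e-12)
  }

  # 2-pooled-SD shift is detected at n = 50
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- rnorm(50)
    wilcoxon_de_test(x + 2, rnorm(50)) < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("logistic MLE reduces to the 2x2 log-odds-ratio closed form", {
  for (seed in 1:20) {
    set.seed(seed)
    cells <- rmultinom(1, 200, c(0.3, 0.2, 0.25, 0.25)) + 1  # a, b, c, d > 0
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    x <- c(rep(1, a + b), rep(0, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    fit <- fit_logistic(matrix(x, ncol = 1), y)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients), log(a * d / (b * c_)),
                 tolerance = 1e-6)
    expect_equal(fit$intercept, log(c_ / d), tolerance = 1e-6)
  }
})

test_that("logistic fit: null behavior, AIC bookkeeping and separation fallback", {
  set.seed(3)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("A", "B", "C")))
  y <- rbinom(500, 1, 0.5)
  fit <- fit_logistic(X, y)
  expect_true(all(abs(fit$coefficients) < 0.5))
  expect_lt(abs(auc(fit$predicted_prob, y)$auc - 0.5), 0.08)
  expect_equal(fit$aic, 2 * 4 - 2 * fit$loglik, tolerance = 1e-9)
  expect_true(all(fit$predicted_prob > 0 & fit$predicted_prob < 1))

  # perfectly separable toy flags the penalized fallback
  xs <- c(-(5:1), 1:5)
  sep <- fit_logistic(matrix(xs, ncol = 1), as.integer(xs > 0))
  expect_false(sep$converged)
  expect_true(sep$penalized)
  expect_true(all(sep$predicted_prob > 0 & sep$predicted_prob < 1))

  expect_error(fit_logistic(matrix(1:4, 2), c(1, 1)), "both classes")
})

test_that("AIC drops when a truly predictive gene joins a null model", {
  better <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 150
    g <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * g))
    noise <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("n1", "n2")))
    with_gene <- fit_logistic(cbind(noise, sig = g), y)$aic
    without <- fit_logistic(noise, y)$aic
    with_gene < without
  }, logical(1))
  expect_gte(mean(better), 0.75)
})

test_that("AUC: separation, ties, pair-counting oracle and rank invariance", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)

  for (seed in 1:20) {
    set.seed(seed)
    s <- sample(1:15, 40, replace = TRUE)  # heavy ties
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- auc(s, l)
    expect_equal(r$auc, auc_pair_oracle(s, l), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc(exp(s / 3), l)$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    set.seed(seed)
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- auc(s, l)
    pr <- pROC::roc(l, s, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$variance, as.numeric(pROC::var(pr)), tolerance = 1e-9)
  }
})

test_that("DeLong comparison: identity, rank invariance, pROC agreement", {
  set.seed(5)
  s <- rnorm(80)
  l <- rbinom(80, 1, 0.5)
  expect_equal(delong_compare(s, s, l)$p_value, 1)
  expect_equal(delong_compare(s, qlogis(plogis(s)), l)$p_value, 1, tolerance = 1e-9)
  expect_equal(delong_compare(s, 2 * s + 7, l)$p_value, 1)

  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(100)
    b <- a + rnorm(100)
    l <- rbinom(100, 1, 0.5)
    r <- delong_compare(a, b, l)
    pr <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE, direction = "<"),
                         pROC::roc(l, b, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
    expect_equal(r$p_value, pr$p.value, tolerance = 1e-9)
  }
})

test_that("DeLong test type-I error is calibrated under the null", {
  rejections <- vapply(1:400, function(seed) {
    set.seed(seed)
    n <- 200
    latent <- rnorm(n)
    y <- rbinom(n, 1, plogis(latent))
    a <- latent + rnorm(n)
    b <- latent + rnorm(n)  # same information, correlated scores
    delong_compare(a, b, y)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})
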