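test_that("differential expression: null identity, planted recovery, direction filter", {
  set.seed(6)
  expr <- matrix(rlnorm(40 * 10), 40, 10, dimnames = list(gene_ids(40), NULL))
  expect_length(differential_upregulated(expr, expr), 0)

  g <- gene_ids(400)
  cfg <- cohort_config(n_patients = 38, n_genes = 400,
                       de_spec = data.frame(gene = g[1:30], fold_change = 4),
                       seed = 51)
  co <- generate_cohort(cfg)
  de <- differential_upregulated(co$tumor, co$normal)
  recall <- mean(g[1:30] %in% de)
  fpr <- mean(g[101:400] %in% de)
  expect_gte(recall, 0.9)
  expect_lt(fpr, 0.12)

  # a strongly downregulated gene is excluded despite a tiny p-value
  tum <- co$tumor
  tum[g[50], ] <- tum[g[50], ] / 10
  de2 <- differential_upregulated(tum, co$normal)
  expect_false(g[50] %in% de2)
})

test_that("cell-type expression filter keeps matching genes and reports drops", {
  genes <- paste0("GENE", 1:10)
  ann <- celltype_annotation(
    setNames(c(rep(list("macrophage"), 6), rep(list("bcell"), 2)),
             genes[1:8]),
    vocabulary = c("macrophage", "bcell"))
  kept <- filter_by_celltype_expression(genes, ann, "macrophage")
  expect_equal(as.character(kept), genes[1:6])
  expect_equal(attr(kept, "dropped_unannotated"), genes[9:10])
  expect_equal(attr(kept, "dropped_nonmatching"), genes[7:8])

  expect_equal(
    as.character(filter_by_celltype_expression(genes[1:6], ann, c("macrophage", "bcell"))),
    genes[1:6])
  none <- filter_by_celltype_expression(genes[9:10], ann, "macrophage")
  expect_length(none, 0)
  expect_error(filter_by_celltype_expression(genes, ann, character(0)), "empty")
  expect_error(filter_by_celltype_expression(genes, ann, "tcell"), "vocabulary")
})

test_that("stepwise selection recovers a planted gene and behaves under the null", {
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 300
    X <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, c("SIG1", paste0("N", 1:20))))
    y <- rbinom(n, 1, plogis(1.2 * X[, "SIG1"]))
    "SIG1" %in% stepwise_select(X, y)
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  set.seed(10)
  n <- 200
  X0 <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("N", 1:10)))
  y0 <- rbinom(n, 1, 0.5)
  sel0 <- stepwise_select(X0, y0)
  expect_lte(length(sel0), 4)
  null_aic <- AIC(glm(y0 ~ 1, family = binomial()))
  expect_lte(attr(sel0, "aic"), null_aic + 1e-6)

  # a duplicated gene is selected at most once
  set.seed(11)
  Xd <- cbind(X0[, 1:3], DUP = X0[, 1])
  colnames(Xd) <- c("A", "B", "C", "A2")
  yd <- rbinom(n, 1, plogis(2 * X0[, 1]))
  seld <- stepwise_select(Xd, yd)
  expect_lte(sum(seld %in% c("A", "A2")), 1)

  # p-value mode also finds the signal
  set.seed(12)
  Xp <- matrix(rnorm(300 * 6), 300, 6,
               dimnames = list(NULL, c("SIG", paste0("N", 1:5))))
  yp <- rbinom(300, 1, plogis(1.5 * Xp[, "SIG"]))
  expect_true("SIG" %in% stepwise_select(Xp, yp, criterion = "pvalue"))
})

test_that("combination benchmark: determinism, degenerate pool, pool ordering", {
  co <- planted_cohort(seed = 61, n_patients = 200, n_genes = 60,
                       n_de = 10, n_signal = 5, effect = 0.8)
  d <- design_from_cohort(co)
  sig <- co$truth$signal_genes
  noise <- setdiff(colnames(d$X), gene_ids(10))[1:20]

  b1 <- benchmark_random_combinations(c(sig, noise[1:5]), k = 4,
                                      n_draws = 300, X = d$X, y = d$y, seed = 5)
  b2 <- benchmark_random_combinations(c(sig, noise[1:5]), k = 4,
                                      n_draws = 300, X = d$X, y = d$y, seed = 5)
  expect_identical(b1$auc_values, b2$auc_values)
  expect_identical(b1$combos, b2$combos)
  expect_true(all(b1$auc_values >= 0 & b1$auc_values <= 1))
  # every draw holds k distinct pool genes
  expect_true(all(apply(b1$combos, 1, function(r) length(unique(r)) == 4)))

  # pool size == k: every draw is the same combination, variance 0
  bfix <- benchmark_random_combinations(sig[1:4], k = 4, n_draws = 50,
                                        X = d$X, y = d$y, seed = 1)
  expect_equal(sd(bfix$auc_values), 0)

  # signal pool beats a pure-noise pool
  bs <- benchmark_random_combinations(sig, k = 3, n_draws = 400,
                                      X = d$X, y = d$y, seed = 2)
  bn <- benchmark_random_combinations(noise, k = 3, n_draws = 400,
                                      X = d$X, y = d$y, seed = 2)
  expect_gt(mean(bs$auc_values), mean(bn$auc_values))

  expect_error(benchmark_random_combinations(sig[1:3], k = 5, n_draws = 10,
                                             X = d$X, y = d$y), "smaller")
})

test_that("frequency profile: hypergeometric baseline, errors, enrichment", {
  co <- planted_cohort(seed = 71, n_patients = 200, n_genes = 80,
                       n_de = 10, n_signal = 5, effect = 0.8)
  d <- design_from_cohort(co)
  pool <- c(co$truth$signal_genes,
            setdiff(colnames(d$X), gene_ids(10))[1:25])
  b <- benchmark_random_combinations(pool, k = 6, n_draws = 1500,
                                     X = d$X, y = d$y, seed = 3)

  # vacuous threshold: per-gene counts match the uniform-draw expectation
  fp0 <- frequency_profile(b, threshold = -1, top_m = 10)
  expected <- 1500 * 6 / 30
  sd_count <- sqrt(1500 * (6 / 30) * (1 - 6 / 30))
  expect_true(all(abs(fp0$table$count - expected) < 3 * sd_count))
  expect_equal(sum(fp0$table$count), 1500 * 6)

  expect_error(frequency_profile(b, threshold = 2), "threshold")

  # planted signal genes are enriched among high-AUC combinations
  fp <- frequency_profile(b, threshold = quantile(b$auc_values, 0.85),
                          top_m = 10)
  expect_gte(sum(co$truth$signal_genes %in% fp$top), 4)
})

test_that("exhaustive search matches independent brute force and its max property", {
  co <- planted_cohort(seed = 81, n_patients = 100, n_genes = 30,
                       n_de = 5, n_signal = 3, effect = 1)
  d <- design_from_cohort(co)
  genes <- c(co$truth$signal_genes, gene_ids(30)[20:24])[1:7]

  ps <- exhaustive_panel_search(genes, d$X, d$y)
  or <- exhaustive_oracle(genes, d$X, d$y)
  expect_equal(ps$best_auc, or$best_auc, tolerance = 1e-9)
  expect_equal(ps$best_subset, or$best_subset)
  expect_equal(ps$n_subsets_evaluated, 2^7 - 1)

  # max property: no leave-one-out AUC exceeds the exhaustive optimum
  if (!is.null(ps$leave_one_out)) {
    expect_true(all(ps$leave_one_out$auc_without <= ps$best_auc + 1e-9))
  }
  # superset property: best >= best single gene
  singles <- vapply(genes, function(g) auc(d$X[, g], d$y)$auc, numeric(1))
  expect_gte(ps$best_auc, max(singles) - 1e-9)

  # a perfect predictor forces AUC 1
  Xp <- cbind(d$X[, genes], PERF = d$y + rnorm(length(d$y), sd = 1e-4))
  ps2 <- exhaustive_panel_search(c(genes[1:2], "PERF"), Xp, d$y)
  expect_equal(ps2$best_auc, 1)

  expect_error(exhaustive_panel_search(gene_ids(21), d$X, d$y), "capped")
})

test_that("leave-one-out attribution: dominant gene, redundant duplicate", {
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 250
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("DOM", "W1", "W2", "W3")))
    y <- rbinom(n, 1, plogis(2 * X[, "DOM"] + 0.2 * X[, "W1"]))
    loo <- leave_one_out(colnames(X), X, y)
    loo$gene[1] == "DOM"
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  set.seed(9)
  n <- 200
  g <- rnorm(n)
  X2 <- cbind(A = g, B = g)
  y2 <- rbinom(n, 1, plogis(g))
  loo2 <- leave_one_out(c("A", "B"), X2, y2)
  expect_lt(max(abs(loo2$delta)), 0.02)
})
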