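#' Gene set constructor
#'
#' @param name Set name.
#' @param symbols Gene symbols; uppercase-normalized and deduplicated.
#' @return An object of class `gene_set` with `name` and `symbols`.
#' @export
gene_set <- function(name, symbols) {
  symbols <- unique(.norm_symbols(symbols))
  symbols <- symbols[nzchar(symbols)]
  .assert(length(symbols) > 0L, "gene set '", name, "' is empty")
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$symbols), " symbols\n", sep = "")
  invisible(x)
}

#' Restrict an expression matrix to a gene set
#'
#' @param expr Gene-by-sample expression matrix.
#' @param genes A `gene_set` (or character vector of symbols).
#' @return The row-subset matrix; symbols requested but absent from the
#'   matrix are reported in the `missing_genes` attribute.
#' @export
subset_to_gene_set <- function(expr, genes) {
  symbols <- if (inherits(genes, "gene_set")) genes$symbols else
    unique(.norm_symbols(genes))
  present <- intersect(symbols, rownames(expr))
  .assert(length(present) > 0L,
          "gene set has no overlap with the expression matrix")
  out <- expr[present, , drop = FALSE]
  attr(out, "missing_genes") <- setdiff(symbols, present)
  out
}

#' Cluster patients on gene expression
#'
#' Standardizes each gene (z-score across samples; zero-variance genes are
#' dropped with a warning), optionally reduces to the leading principal
#' components when the gene space is high-dimensional, and fits a Gaussian
#' mixture over samples with [fit_gmm()].
#'
#' @param expr Gene-by-sample expression matrix (>= 2 genes).
#' @param k_range Candidate component counts.
#' @param seed Seed passed through to [fit_gmm()].
#' @param n_init Initializations passed through to [fit_gmm()].
#' @param n_pc Number of principal components to keep when the number of
#'   genes exceeds `n_pc` (GMMs are ill-posed in raw thousand-dimensional
#'   expression space); set to `Inf` to disable reduction.
#' @return A `gmm_fit` over samples.
#' @export
cluster_by_expression <- function(expr, k_range = 2:8, seed = 1L,
                                  n_init = 1L, n_pc = 10L) {
  expr <- as.matrix(expr)
  .assert(nrow(expr) >= 2L, "need at least two genes")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    .assert(nrow(expr) >= 2L, "fewer than two variable genes")
  }
  z <- (expr - rowMeans(expr)) / sds
  feats <- t(z)
  if (is.finite(n_pc) && ncol(feats) > n_pc) {
    pc <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
    feats <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]
  }
  fit_gmm(feats, k_range = k_range, n_init = n_init, seed = seed)
}

# Poor strata of one clustering: clusters with median survival below the
# whole-cohort median whose pairwise log-rank against the best-surviving
# cluster is significant at alpha. Undefined medians (curve never reaches
# 0.5) count as infinite, i.e. good survival.
.poor_clusters <- function(assignment, clinical, alpha) {
  cl <- .clinical_for(clinical, names(assignment))
  clusters <- sort(unique(assignment))
  med <- vapply(clusters, function(g) {
    sel <- assignment == g
    m <- km_median(km_estimate(cl$os_time_days[sel], cl$os_event[sel]))
    if (is.na(m)) Inf else m
  }, numeric(1))
  cohort_med <- km_median(km_estimate(cl$os_time_days, cl$os_event))
  if (is.na(cohort_med)) cohort_med <- Inf
  best <- clusters[which.max(med)]
  poor <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    g <- clusters[i]
    if (g == best || med[i] >= cohort_med) next
    sel <- assignment %in% c(g, best)
    p <- tryCatch(
      logrank_test(cl$os_time_days[sel], cl$os_event[sel],
                   assignment[sel])$p_value,
      error = function(e) 1)
    poor[i] <- p < alpha
  }
  clusters[poor]
}

#' Define the poor-survival cohort from two stratifications
#'
#' Identifies the poor-prognosis clusters of the immune-fraction view and of
#' the gene-expression view independently (median survival below the cohort
#' median and pairwise log-rank against the best-surviving cluster below
#' `alpha`), and intersects their sample sets. The result is invariant to
#' cluster relabeling in either fit.
#'
#' @param immune_fit `gmm_fit` on immune fractions.
#' @param gene_fit `gmm_fit` on immune-regulatory gene expression (same
#'   sample universe).
#' @param clinical Clinical table covering the samples.
#' @param alpha Log-rank significance threshold (default 0.05).
#' @return An object of class `cohort_definition` with `sample_ids`,
#'   `immune_poor_clusters`, `gene_poor_clusters`, `rule` and an `empty`
#'   flag. An empty intersection is a valid, flagged result.
#' @export
define_poor_survival_cohort <- function(immune_fit, gene_fit, clinical,
                                        alpha = 0.05) {
  a1 <- immune_fit$assignment
  a2 <- gene_fit$assignment
  .assert(setequal(names(a1), names(a2)),
          "the two clusterings cover different sample universes")
  p1 <- .poor_clusters(a1, clinical, alpha)
  p2 <- .poor_clusters(a2, clinical, alpha)
  s1 <- names(a1)[a1 %in% p1]
  s2 <- names(a2)[a2 %in% p2]
  ids <- intersect(s1, s2)
  structure(list(
    sample_ids = sort(ids),
    immune_poor_clusters = p1,
    gene_poor_clusters = p2,
    n_immune_poor = length(s1),
    n_gene_poor = length(s2),
    rule = "intersection",
    alpha = alpha,
    empty = length(ids) == 0L
  ), class = "cohort_definition")
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat("Poor-survival cohort:", length(x$sample_ids), "samples",
      "(immune poor clusters:", paste(x$immune_poor_clusters, collapse = ","),
      "; gene poor clusters:", paste(x$gene_poor_clusters, collapse = ","),
      ")\n")
  if (x$empty) cat("  WARNING: empty intersection\n")
  invisible(x)
}
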