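#' Tumor/normal fold change per gene
#'
#' Linear-scale fold change of group means with a pseudocount guard:
#' `(mean tumor + pseudocount) / (mean normal + pseudocount)`.
#'
#' @param tumor,normal Gene-by-sample expression matrices sharing a gene
#'   universe.
#' @param pairing Optional `data.frame(tumor, normal)` of matched sample
#'   columns; when given, only the matched pairs are used.
#' @param pseudocount Small positive constant keeping ratios finite for
#'   all-zero genes.
#' @return Named numeric vector of fold changes over the shared genes, with
#'   the per-gene tumor and normal means in the `mean_tumor` /
#'   `mean_normal` attributes.
#' @export
fold_change <- function(tumor, normal, pairing = NULL, pseudocount = 0.01) {
  shared <- intersect(rownames(tumor), rownames(normal))
  .assert(length(shared) > 0L, "no shared genes between tumor and normal")
  .assert(pseudocount > 0, "pseudocount must be positive")
  if (!is.null(pairing)) {
    .assert(all(pairing$tumor %in% colnames(tumor)) &&
              all(pairing$normal %in% colnames(normal)),
            "pairing names samples absent from the matrices")
    .assert(nrow(pairing) >= 1L, "need at least one matched pair")
    tumor <- tumor[, pairing$tumor, drop = FALSE]
    normal <- normal[, pairing$normal, drop = FALSE]
  }
  mt <- rowMeans(tumor[shared, , drop = FALSE])
  mn <- rowMeans(normal[shared, , drop = FALSE])
  fc <- (mt + pseudocount) / (mn + pseudocount)
  attr(fc, "mean_tumor") <- mt
  attr(fc, "mean_normal") <- mn
  fc
}

#' Immune gene index
#'
#' Per-gene prioritization score: mean tumor expression multiplied by the
#' tumor/normal fold change. The exact product is returned; tabular output
#' rounds to two decimals for display.
#'
#' @param mean_expr Non-negative mean tumor expression (FPKM scale).
#' @param fc Non-negative fold change.
#' @return Numeric index values (exact products).
#' @export
immune_gene_index <- function(mean_expr, fc) {
  .assert(length(mean_expr) == length(fc), "inputs differ in length")
  .assert(all(is.finite(mean_expr)) && all(is.finite(fc)), "inputs must be finite")
  .assert(all(mean_expr >= 0) && all(fc >= 0), "inputs must be non-negative")
  mean_expr * fc
}

#' Build and rank an immune gene index table
#'
#' @param genes Gene symbols.
#' @param mean_expr Mean tumor expression per gene.
#' @param fc Fold change per gene.
#' @return A ranked `data.frame` (see [rank_by_index()]) with columns
#'   `gene`, `mean_tumor_expr`, `fold_change`, `index` (rounded to 2
#'   decimals for display) and `rank`.
#' @export
gene_index_table <- function(genes, mean_expr, fc) {
  tab <- data.frame(
    gene = .norm_symbols(genes),
    mean_tumor_expr = mean_expr,
    fold_change = fc,
    index = round(immune_gene_index(mean_expr, fc), 2),
    stringsAsFactors = FALSE
  )
  rank_by_index(tab)
}

#' Rank a gene index table in descending index order
#'
#' Stable descending sort by index with alphabetical tie-break on the gene
#' symbol; idempotent.
#'
#' @param table Data frame with at least `gene` and `index` columns.
#' @return The table reordered, with a 1-based `rank` column.
#' @export
rank_by_index <- function(table) {
  .assert(is.data.frame(table) && nrow(table) > 0L, "table must be non-empty")
  .assert(all(c("gene", "index") %in% names(table)),
          "table must have 'gene' and 'index' columns")
  out <- table[order(-table$index, table$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the head of a ranked index table at the last significant drop
#'
#' Scans the ratio of consecutive index values within the top `max_k` ranks
#' and keeps the top `k` genes, where `k` is the deepest rank whose drop to
#' the next gene is at least `drop_ratio` (i.e. `index[k]/index[k+1] >=
#' drop_ratio`). A ranked list typically falls steeply away from its head;
#' cutting at the last qualifying drop keeps the whole high-index head
#' rather than only the single top gene. Falls back to `max_k` when no drop
#' qualifies.
#'
#' @param table Ranked gene index table (re-ranked defensively).
#' @param max_k Deepest rank considered.
#' @param drop_ratio Minimum consecutive-index ratio counting as a drop
#'   (> 1).
#' @return An object of class `top_drop` with `genes`, `k`, `ratios` and the
#'   rule parameters.
#' @export
select_top_by_drop <- function(table, max_k = 10L, drop_ratio = 1.3) {
  .assert(drop_ratio > 1, "drop_ratio must exceed 1")
  .assert(nrow(table) >= max_k, "table has fewer than max_k rows")
  tab <- rank_by_index(table)
  kk <- min(max_k, nrow(tab) - 1L)
  ratios <- tab$index[seq_len(kk)] / tab$index[seq_len(kk) + 1L]
  qual <- which(is.finite(ratios) & ratios >= drop_ratio)
  k <- if (length(qual)) max(qual) else max_k
  structure(list(
    genes = tab$gene[seq_len(k)], k = k, ratios = ratios,
    max_k = max_k, drop_ratio = drop_ratio,
    fallback = length(qual) == 0L
  ), class = "top_drop")
}

#' @export
print.top_drop <- function(x, ...) {
  cat("Top-by-drop selection: k =", x$k,
      if (x$fallback) "(fallback: no qualifying drop)" else "", "\n  genes:",
      paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Tertile expression stratification with survival and ROC screen
#'
#' Splits samples into a high-expression top third and a low-expression
#' bottom third (middle third excluded; tertile boundaries at the
#' `ceiling(n/3)` order statistics, boundary ties resolved by sort
#' stability), compares the two groups by log-rank test, and computes the
#' ROC of the raw expression values against vital status over all samples.
#'
#' @param expr_values Named per-sample expression values (names = sample
#'   ids).
#' @param clinical Clinical table covering the samples.
#' @return A list with `groups` (named factor high/middle/low), `logrank`
#'   (a `logrank_result`) and `roc` (a `roc_result`).
#' @export
tertile_screen <- function(expr_values, clinical) {
  n <- length(expr_values)
  .assert(n >= 9L, "need at least 9 samples for tertiles")
  ids <- names(expr_values) %||% paste0("S", seq_len(n))
  cl <- .clinical_for(clinical, ids)
  t3 <- ceiling(n / 3)
  ord <- order(expr_values, decreasing = TRUE)
  .assert(expr_values[ord[t3]] != expr_values[ord[n - t3 + 1L]],
          "tied values span from the high tertile into the low tertile; ",
          "stratification is not meaningful")
  grp <- rep("middle", n)
  grp[ord[seq_len(t3)]] <- "high"
  grp[ord[(n - t3 + 1L):n]] <- "low"
  grp <- stats::setNames(factor(grp, levels = c("high", "middle", "low")), ids)
  sel <- grp != "middle"
  lr <- logrank_test(cl$os_time_days[sel], cl$os_event[sel], droplevels(grp[sel]))
  roc <- auc(unname(expr_values), cl$os_event)
  list(groups = grp, logrank = lr, roc = roc)
}
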