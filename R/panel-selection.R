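#' Upregulated differentially expressed genes
#'
#' Per-gene two-sided Wilcoxon test between tumor and matched adjacent
#' normal tissue (signed-rank on pairs by default), keeping genes with
#' `p < alpha` that are also upregulated (tumor mean above normal mean).
#' Raw p-values are used by default, mirroring a screening step without
#' multiplicity correction; set `fdr = TRUE` for Benjamini-Hochberg
#' adjustment.
#'
#' @param tumor,normal Gene-by-sample matrices sharing a gene universe.
#' @param pairing Optional `data.frame(tumor, normal)` of matched columns;
#'   required when column orders do not already correspond.
#' @param alpha Significance threshold.
#' @param paired Use the paired signed-rank test (>= 6 pairs required).
#' @param fdr Apply BH correction before thresholding.
#' @return Character vector of upregulated significant genes; the full
#'   per-gene table (gene, mean_tumor, mean_normal, p_value) is attached as
#'   the `table` attribute.
#' @export
differential_upregulated <- function(tumor, normal, pairing = NULL,
                                     alpha = 0.05, paired = TRUE,
                                     fdr = FALSE) {
  shared <- intersect(rownames(tumor), rownames(normal))
  .assert(length(shared) > 0L, "no shared genes")
  if (!is.null(pairing)) {
    tumor <- tumor[, pairing$tumor, drop = FALSE]
    normal <- normal[, pairing$normal, drop = FALSE]
  }
  if (paired) {
    .assert(ncol(tumor) == ncol(normal),
            "paired mode requires equal numbers of tumor and normal samples")
    .assert(ncol(tumor) >= 6L, "paired mode requires at least 6 matched pairs")
  }
  tumor <- tumor[shared, , drop = FALSE]
  normal <- normal[shared, , drop = FALSE]
  p <- vapply(seq_along(shared), function(i) {
    tryCatch(wilcoxon_de_test(tumor[i, ], normal[i, ], paired = paired),
             error = function(e) 1)
  }, numeric(1))
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  mt <- rowMeans(tumor)
  mn <- rowMeans(normal)
  keep <- p < alpha & mt > mn
  out <- shared[keep]
  attr(out, "table") <- data.frame(gene = shared, mean_tumor = unname(mt),
                                   mean_normal = unname(mn),
                                   p_value = p, stringsAsFactors = FALSE)
  out
}

#' Cell-type expression annotation
#'
#' Validates a gene -> cell-type annotation mapping (the packaged stand-in
#' for an immune-cell expression atlas).
#'
#' @param x Named list: gene symbol -> character vector of cell types in
#'   which the gene is expressed.
#' @param vocabulary Optional declared cell-type vocabulary; annotations
#'   outside it are an error.
#' @return The normalized annotation (class `celltype_annotation`).
#' @export
celltype_annotation <- function(x, vocabulary = NULL) {
  .assert(is.list(x) && !is.null(names(x)), "annotation must be a named list")
  names(x) <- .norm_symbols(names(x))
  x <- lapply(x, function(v) unique(as.character(v)))
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(unlist(x)), vocabulary)
    .assert(length(bad) == 0L, "annotation uses cell types outside the ",
            "declared vocabulary: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(x, class = "celltype_annotation", vocabulary = vocabulary)
}

#' Filter genes by immune cell-type expression
#'
#' Keeps genes annotated as expressed in at least one of the required cell
#' types; genes without any annotation are dropped and reported.
#'
#' @param genes Candidate gene symbols.
#' @param annotation A `celltype_annotation` (or plain named list).
#' @param required_celltypes Non-empty set of cell types of interest.
#' @return Character vector of retained genes with attributes
#'   `dropped_unannotated` and `dropped_nonmatching`.
#' @export
filter_by_celltype_expression <- function(genes, annotation,
                                          required_celltypes) {
  .assert(length(required_celltypes) > 0L, "required cell-type set is empty")
  vocab <- attr(annotation, "vocabulary")
  if (!is.null(vocab)) {
    .assert(all(required_celltypes %in% vocab),
            "required cell types outside the annotation vocabulary")
  }
  genes <- .norm_symbols(genes)
  annotated <- genes %in% names(annotation)
  hit <- vapply(genes, function(g) {
    types <- annotation[[g]]
    !is.null(types) && length(intersect(types, required_celltypes)) > 0L
  }, logical(1))
  out <- genes[hit]
  attr(out, "dropped_unannotated") <- genes[!annotated]
  attr(out, "dropped_nonmatching") <- genes[annotated & !hit]
  out
}

#' Stepwise logistic gene selection
#'
#' Bidirectional stepwise selection of genes predicting a binary outcome,
#' started from the null (intercept-only) model. In `"aic"` mode each step
#' applies the single add/remove move that most improves AIC (via
#' [stats::step()]); in `"pvalue"` mode variables enter at the smallest Wald
#' p-value below `p_enter` and leave at the largest above `p_exit`. The
#' search stops when no move improves the criterion or after `max_steps`
#' moves. Candidates are considered in alphabetical order, so ties are
#' deterministic.
#'
#' @param X Sample-by-gene matrix with gene column names.
#' @param y 0/1 outcome with both classes.
#' @param criterion `"aic"` (default) or `"pvalue"`.
#' @param max_steps Maximum number of moves.
#' @param p_enter,p_exit Entry/exit thresholds for `"pvalue"` mode.
#' @return Character vector of selected gene names (original symbols); the
#'   final model AIC is attached as the `aic` attribute.
#' @export
stepwise_select <- function(X, y, criterion = c("aic", "pvalue"),
                            max_steps = 200L, p_enter = 0.05, p_exit = 0.10) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  .check_binary(y)
  .assert(!is.null(colnames(X)) && ncol(X) >= 1L, "X needs gene column names")
  ord <- order(colnames(X))
  X <- X[, ord, drop = FALSE]
  orig <- colnames(X)
  safe <- make.names(orig, unique = TRUE)
  df <- as.data.frame(X)
  names(df) <- safe
  df$.y <- y

  if (criterion == "aic") {
    null_fit <- stats::glm(.y ~ 1, data = df, family = stats::binomial())
    upper <- stats::reformulate(safe, response = ".y")
    sel <- suppressWarnings(stats::step(
      null_fit, scope = list(lower = ~1, upper = upper),
      direction = "both", trace = 0, steps = max_steps))
    chosen_safe <- setdiff(names(stats::coef(sel)), "(Intercept)")
    final_aic <- stats::AIC(sel)
  } else {
    current <- character(0)
    for (step_i in seq_len(max_steps)) {
      changed <- FALSE
      cand <- setdiff(safe, current)
      if (length(cand)) {
        ps <- vapply(cand, function(v) {
          f <- stats::reformulate(c(current, v), response = ".y")
          fit <- suppressWarnings(stats::glm(f, data = df,
                                             family = stats::binomial()))
          cf <- summary(fit)$coefficients
          if (v %in% rownames(cf)) cf[v, 4] else 1
        }, numeric(1))
        if (min(ps) < p_enter) {
          current <- c(current, cand[which.min(ps)])
          changed <- TRUE
        }
      }
      if (length(current)) {
        f <- stats::reformulate(current, response = ".y")
        fit <- suppressWarnings(stats::glm(f, data = df,
                                           family = stats::binomial()))
        cf <- summary(fit)$coefficients
        ps <- vapply(current, function(v)
          if (v %in% rownames(cf)) cf[v, 4] else 1, numeric(1))
        if (max(ps) > p_exit) {
          current <- setdiff(current, current[which.max(ps)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    chosen_safe <- current
    final_aic <- if (length(current)) {
      stats::AIC(suppressWarnings(stats::glm(
        stats::reformulate(current, response = ".y"), data = df,
        family = stats::binomial())))
    } else {
      stats::AIC(stats::glm(.y ~ 1, data = df, family = stats::binomial()))
    }
  }
  out <- orig[match(chosen_safe, safe)]
  attr(out, "aic") <- final_aic
  out
}

#' Random gene-combination AUC benchmark
#'
#' Draws `n_draws` uniform `k`-subsets from a gene pool (distinct genes
#' within a draw; repeats across draws allowed), fits an in-sample logistic
#' model on each subset and records the AUC of its predicted probabilities
#' against the outcome. Used to compare a candidate pool against positive
#' and negative control pools.
#'
#' @param pool Gene symbols to draw from (all must be columns of `X`).
#' @param k Combination size.
#' @param n_draws Number of random combinations.
#' @param X Sample-by-gene expression matrix.
#' @param y 0/1 outcome.
#' @param seed Seed making the draws reproducible.
#' @param pool_name Label carried into the result.
#' @param ridge Ridge penalty for the separation fallback.
#' @return An object of class `combo_benchmark` with `auc_values`, `combos`
#'   (draw-by-k matrix of pool indices), `pool_genes`, `k`, `n_draws`,
#'   `seed`, `pool_name`.
#' @export
benchmark_random_combinations <- function(pool, k = 20L, n_draws = 10000L,
                                          X, y, seed = 1L,
                                          pool_name = "pool", ridge = 1e-2) {
  pool <- .norm_symbols(pool)
  .assert(all(pool %in% colnames(X)), "pool genes missing from X")
  p <- length(pool)
  .assert(p >= k, "pool smaller than combination size k")
  .check_binary(y)
  Xp <- as.matrix(X[, pool, drop = FALSE])
  storage.mode(Xp) <- "double"
  set.seed(seed)
  combos <- t(vapply(seq_len(n_draws), function(i) sample.int(p, k),
                     integer(k)))
  yl <- as.integer(y)
  aucs <- vapply(seq_len(n_draws), function(i) {
    prob <- .logit_prob(Xp[, combos[i, ], drop = FALSE], yl, ridge)
    .fast_auc(prob, yl)
  }, numeric(1))
  structure(list(pool_name = pool_name, pool_genes = pool, k = as.integer(k),
                 n_draws = as.integer(n_draws), auc_values = aucs,
                 combos = combos, seed = as.integer(seed)),
            class = "combo_benchmark")
}

#' @export
print.combo_benchmark <- function(x, ...) {
  cat(sprintf(
    "Combination benchmark '%s': %d draws of %d from %d genes; mean AUC %.4f (sd %.4f)\n",
    x$pool_name, x$n_draws, x$k, length(x$pool_genes),
    mean(x$auc_values), stats::sd(x$auc_values)))
  invisible(x)
}

#' Gene frequency profile among high-performing combinations
#'
#' Counts, for every pool gene, its appearances in benchmark combinations
#' whose AUC exceeds a threshold, and ranks genes by count (ties broken by
#' the mean AUC of the qualifying combinations containing the gene, then
#' alphabetically).
#'
#' @param bench A `combo_benchmark`.
#' @param threshold AUC bound defining high-performing combinations.
#' @param top_m Number of top genes to report.
#' @return An object of class `frequency_profile` with `table` (gene,
#'   count, mean_auc ordered by rank), `top` (the top `top_m` genes),
#'   `threshold` and `n_qualifying`.
#' @export
frequency_profile <- function(bench, threshold, top_m = 20L) {
  .assert(inherits(bench, "combo_benchmark"), "bench must be a combo_benchmark")
  qual <- bench$auc_values > threshold
  .assert(any(qual), "no combination exceeds the threshold (max AUC ",
          signif(max(bench$auc_values), 4), "); lower the threshold")
  p <- length(bench$pool_genes)
  cm <- bench$combos[qual, , drop = FALSE]
  idx <- as.vector(cm)
  counts <- tabulate(idx, nbins = p)
  a <- rep(bench$auc_values[qual], times = ncol(cm))
  sums <- numeric(p)
  agg <- tapply(a, idx, sum)
  sums[as.integer(names(agg))] <- agg
  mean_auc <- ifelse(counts > 0, sums / counts, NA_real_)
  tab <- data.frame(gene = bench$pool_genes, count = counts,
                    mean_auc = mean_auc, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, -tab$mean_auc, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top = utils::head(tab$gene, top_m),
                 threshold = threshold,
                 top_m = as.integer(top_m),
                 n_qualifying = sum(qual)),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("Frequency profile:", x$n_qualifying, "combinations above AUC",
      signif(x$threshold, 4), "\n  top genes:",
      paste(utils::head(x$top, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive best-subset panel search
#'
#' Evaluates every non-empty subset of up to 20 genes by in-sample logistic
#' AUC and returns the best panel (ties resolved toward the smaller subset,
#' then alphabetically), together with its fitted model and a
#' leave-one-gene-out attribution.
#'
#' @param genes Candidate genes (1 to 20; the subset count is `2^m - 1`).
#' @param X Sample-by-gene expression matrix.
#' @param y 0/1 outcome.
#' @param ridge Ridge penalty for the separation fallback.
#' @return An object of class `panel_search` with `best_subset` (sorted),
#'   `best_auc`, `n_subsets_evaluated`, `model` (a `logit_fit`) and
#'   `leave_one_out` (data frame from [leave_one_out()], `NULL` for a
#'   single-gene panel).
#' @export
exhaustive_panel_search <- function(genes, X, y, ridge = 1e-2) {
  genes <- .norm_symbols(genes)
  m <- length(genes)
  .assert(m >= 1L && m <= 20L,
          "exhaustive search is capped at 20 genes (got ", m, ")")
  .assert(all(genes %in% colnames(X)), "genes missing from X")
  .check_binary(y)
  Xg <- as.matrix(X[, genes, drop = FALSE])
  storage.mode(Xg) <- "double"
  yl <- as.integer(y)
  bits <- bitwShiftL(1L, 0:(m - 1L))
  n_subsets <- 2L^m - 1L
  best_auc <- -Inf
  best_idx <- NULL
  best_key <- ""
  for (s in seq_len(n_subsets)) {
    idx <- which(bitwAnd(s, bits) != 0L)
    prob <- .logit_prob(Xg[, idx, drop = FALSE], yl, ridge)
    a <- .fast_auc(prob, yl)
    if (a > best_auc + 1e-12) {
      best_auc <- a
      best_idx <- idx
      best_key <- paste(sort(genes[idx]), collapse = "|")
    } else if (abs(a - best_auc) <= 1e-12 && !is.null(best_idx)) {
      key <- paste(sort(genes[idx]), collapse = "|")
      if (length(idx) < length(best_idx) ||
          (length(idx) == length(best_idx) && key < best_key)) {
        best_idx <- idx
        best_key <- key
      }
    }
  }
  best_subset <- sort(genes[best_idx])
  model <- fit_logistic(Xg[, best_subset, drop = FALSE], yl, ridge = ridge)
  loo <- if (length(best_subset) >= 2L) {
    leave_one_out(best_subset, X, y, ridge = ridge)
  }
  structure(list(best_subset = best_subset, best_auc = best_auc,
                 n_subsets_evaluated = n_subsets, model = model,
                 leave_one_out = loo),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("Exhaustive panel search: best %d-gene panel, AUC = %.4f (%d subsets)\n",
              length(x$best_subset), x$best_auc, x$n_subsets_evaluated))
  cat("  panel:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-gene-out AUC attribution
#'
#' Refits the panel logistic model without each gene in turn and reports the
#' AUC without that gene and the drop relative to the full panel, ranked by
#' drop.
#'
#' @param panel Gene panel (>= 2 genes, columns of `X`).
#' @param X Sample-by-gene expression matrix.
#' @param y 0/1 outcome.
#' @param ridge Ridge penalty for the separation fallback.
#' @return Data frame with columns `gene`, `auc_without`, `delta`
#'   (panel AUC minus AUC without the gene), ordered by decreasing `delta`;
#'   the full-panel AUC is attached as the `panel_auc` attribute.
#' @export
leave_one_out <- function(panel, X, y, ridge = 1e-2) {
  panel <- .norm_symbols(panel)
  .assert(length(panel) >= 2L, "leave-one-out needs at least 2 genes")
  .assert(all(panel %in% colnames(X)), "panel genes missing from X")
  .check_binary(y)
  Xg <- as.matrix(X[, panel, drop = FALSE])
  storage.mode(Xg) <- "double"
  yl <- as.integer(y)
  full_auc <- .fast_auc(.logit_prob(Xg, yl, ridge), yl)
  auc_wo <- vapply(seq_along(panel), function(i) {
    tryCatch(
      .fast_auc(.logit_prob(Xg[, -i, drop = FALSE], yl, ridge), yl),
      error = function(e) {
        warning("leave-one-out fit failed for ", panel[i], ": ",
                conditionMessage(e))
        NA_real_
      })
  }, numeric(1))
  out <- data.frame(gene = panel, auc_without = auc_wo,
                    delta = full_auc - auc_wo, stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel_auc") <- full_auc
  out
}
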