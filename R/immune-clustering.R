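#' Gaussian mixture model fit with BIC model selection
#'
#' Fits Gaussian mixtures over a range of component counts with
#' [mclust::Mclust()] and returns the best fit by BIC. Initialization is
#' model-based hierarchical clustering (deterministic); additional random
#' subset-initialized restarts can be requested with `n_init`, and the best
#' fit across restarts is kept. Covariances are regularized through mclust's
#' conjugate prior when the unregularized fit fails (e.g. on compositional
#' input whose rows sum to one).
#'
#' @param features Sample-by-dimension numeric matrix (row names = sample
#'   ids).
#' @param k_range Candidate numbers of mixture components.
#' @param n_init Number of initializations (1 = deterministic hierarchical
#'   only).
#' @param seed Integer seed controlling the random restarts.
#' @return An object of class `gmm_fit` with `k`, `weights`, `means`
#'   (k x dim), `covariances` (dim x dim x k when available),
#'   `responsibilities` (n x k, rows sum to 1), `assignment` (named argmax
#'   labels), `bic` (lower is better), `bic_by_k`, `loglik`, `model_name`
#'   and `seed`.
#' @importFrom mclust mclustBIC
#' @export
fit_gmm <- function(features, k_range = 2:8, n_init = 1L, seed = 1L) {
  features <- as.matrix(features)
  .assert(all(is.finite(features)), "features must be finite")
  n <- nrow(features)
  .assert(n > max(k_range), "k_range must be below the sample count")
  ids <- rownames(features) %||% paste0("S", seq_len(n))
  set.seed(seed)

  run_one <- function(init) {
    fit <- tryCatch(
      mclust::Mclust(features, G = k_range, verbose = FALSE,
                     initialization = init),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        mclust::Mclust(features, G = k_range, verbose = FALSE,
                       prior = mclust::priorControl(),
                       initialization = init),
        error = function(e) NULL)
    }
    fit
  }
  best <- run_one(NULL)
  if (n_init > 1L) {
    for (i in seq_len(n_init - 1L)) {
      sub <- sample.int(n, min(n, max(50L, n %/% 2L)))
      cand <- run_one(list(subset = sub))
      if (!is.null(cand) &&
          (is.null(best) || cand$bic > best$bic)) best <- cand
    }
  }
  .assert(!is.null(best), "GMM estimation failed for every model/initialization")

  bic_by_k <- -apply(best$BIC[, , drop = FALSE], 1, max, na.rm = TRUE)
  z <- best$z
  if (is.null(z)) z <- matrix(1, n, 1)
  rownames(z) <- ids
  covs <- best$parameters$variance$sigma
  structure(list(
    k = best$G,
    weights = best$parameters$pro,
    means = t(best$parameters$mean),
    covariances = covs,
    responsibilities = z,
    assignment = stats::setNames(best$classification, ids),
    bic = -unname(best$bic),
    bic_by_k = bic_by_k,
    loglik = best$loglik,
    model_name = best$modelName,
    seed = seed
  ), class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit:", x$k, "components (model", x$model_name,
      "), BIC =", signif(x$bic, 6), "\n")
  cat("  sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative-SD cutoff for long-tailed variables
#'
#' Splits samples into high and low groups on one variable by sorting the
#' values (descending by default, so the accumulating prefix starts in the
#' long right tail), computing the standard deviation of each growing prefix
#' (first three samples, then four, ...), and cutting at the prefix size
#' where the SD is maximal. The SD trace is computed for prefixes of size 3
#' through n, but the cut is restricted to sizes 3 through n-3 so both
#' groups keep at least three samples; ties take the first maximum.
#'
#' When the trace is still rising at the end of the eligible range (the SD
#' maximum is censored, as happens when the two underlying groups are of
#' comparable size so dilution never overtakes between-group spread), the
#' cut falls back to the largest single-step SD increase: the prefix is
#' grown until just before the sample whose inclusion inflates the
#' dispersion most, which marks the entry point of the second group.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param decreasing Sort direction; with the default `TRUE` the prefix
#'   group is the high-value tail.
#' @param variable_name Label carried through to outputs.
#' @return An object of class `sd_cutoff`: `variable_name`, `sorted_order`
#'   (permutation of the input), `cutoff_rank`, `cutoff_value`, `group`
#'   (named factor high/low), `sd_trace` and `prefix_sizes` (3..n, for
#'   audit).
#' @export
cumulative_sd_cutoff <- function(values, decreasing = TRUE,
                                 variable_name = "value") {
  n <- length(values)
  .assert(n >= 6L, "need at least 6 samples")
  .assert(all(is.finite(values)), "values must be finite")
  .assert(stats::sd(values) > 0, "values are constant; no cutoff exists")
  ids <- names(values) %||% paste0("S", seq_len(n))
  ord <- order(values, decreasing = decreasing)
  sorted <- values[ord]
  ks <- 3:n
  s1 <- cumsum(sorted)
  s2 <- cumsum(sorted^2)
  sd_trace <- sqrt(pmax(0, (s2[ks] - s1[ks]^2 / ks) / (ks - 1)))
  eligible <- ks <= n - 3L
  cutoff_rank <- ks[eligible][which.max(sd_trace[eligible])]
  if (cutoff_rank == n - 3L) {
    # SD maximum censored at the range edge: cut before the largest jump.
    jumps <- diff(sd_trace[eligible])  # step k -> k+1 for k = 3..n-4
    if (any(jumps > 0)) cutoff_rank <- ks[eligible][which.max(jumps)]
  }
  prefix_label <- if (decreasing) "high" else "low"
  other_label <- if (decreasing) "low" else "high"
  grp <- rep(other_label, n)
  grp[ord[seq_len(cutoff_rank)]] <- prefix_label
  structure(list(
    variable_name = variable_name,
    sorted_order = ord,
    cutoff_rank = cutoff_rank,
    cutoff_value = unname(sorted[cutoff_rank]),
    group = stats::setNames(factor(grp, levels = c("high", "low")), ids),
    sd_trace = unname(sd_trace),
    prefix_sizes = ks
  ), class = "sd_cutoff")
}

#' @export
print.sd_cutoff <- function(x, ...) {
  cat(sprintf(
    "Cumulative-SD cutoff on '%s': rank %d of %d (value %.4g); high = %d, low = %d\n",
    x$variable_name, x$cutoff_rank, length(x$group), x$cutoff_value,
    sum(x$group == "high"), sum(x$group == "low")))
  invisible(x)
}

# Match clinical rows to sample ids; error if any is missing.
.clinical_for <- function(clinical, sample_ids) {
  .assert(all(c("sample_id", "os_time_days", "os_event") %in% names(clinical)),
          "clinical table must have sample_id, os_time_days, os_event")
  idx <- match(sample_ids, clinical$sample_id)
  .assert(!anyNA(idx), "clinical table does not cover all samples")
  clinical[idx, , drop = FALSE]
}

#' Survival screen across immune cell types
#'
#' For each cell type, stratifies patients into high/low infiltration with
#' the cumulative-SD cutoff and compares the groups by log-rank test. Cell
#' types with insufficient data (over 90% of fractions below 1e-4, a
#' stratum smaller than `min_group`, or a constant fraction vector) are
#' reported as excluded rather than tested.
#'
#' @param fractions Sample-by-cell-type fraction matrix (rows sum to 1).
#' @param clinical Clinical table covering all fraction rows.
#' @param min_group Minimum per-stratum size to test.
#' @return An object of class `celltype_screen` with a `summary` data frame
#'   (celltype, status, statistic, p_value, direction, n_high, n_low) and a
#'   `results` list holding the per-cell-type `sd_cutoff` and
#'   `logrank_result` objects. `direction` is the sign of (median survival
#'   of the high group minus the low group); restricted mean survival is
#'   used when a median is undefined.
#' @export
celltype_survival_screen <- function(fractions, clinical, min_group = 10L) {
  fractions <- as.matrix(fractions)
  ids <- rownames(fractions)
  .assert(!is.null(ids) && !anyDuplicated(ids), "fractions need unique row names")
  cl <- .clinical_for(clinical, ids)
  celltypes <- colnames(fractions) %||% paste0("celltype_", seq_len(ncol(fractions)))
  results <- list()
  rows <- vector("list", length(celltypes))
  for (j in seq_along(celltypes)) {
    ct <- celltypes[j]
    vals <- stats::setNames(fractions[, j], ids)
    status <- "tested"
    cut <- lr <- NULL
    direction <- NA_real_
    n_high <- n_low <- NA_integer_
    if (mean(vals < 1e-4) > 0.9) {
      status <- "excluded: insufficient data (>90% near-zero fractions)"
    } else {
      cut <- tryCatch(cumulative_sd_cutoff(vals, variable_name = ct),
                      error = function(e) conditionMessage(e))
      if (is.character(cut)) {
        status <- paste0("excluded: ", cut)
        cut <- NULL
      } else {
        n_high <- sum(cut$group == "high")
        n_low <- sum(cut$group == "low")
        if (min(n_high, n_low) < min_group) {
          status <- "excluded: stratum below min_group"
        } else {
          lr <- tryCatch(
            logrank_test(cl$os_time_days, cl$os_event, cut$group),
            error = function(e) conditionMessage(e))
          if (is.character(lr)) {
            status <- paste0("excluded: ", lr)
            lr <- NULL
          } else {
            hi <- cut$group == "high"
            km_h <- km_estimate(cl$os_time_days[hi], cl$os_event[hi])
            km_l <- km_estimate(cl$os_time_days[!hi], cl$os_event[!hi])
            mh <- km_median(km_h)
            ml <- km_median(km_l)
            if (is.na(mh) || is.na(ml)) {
              tmax <- max(cl$os_time_days)
              direction <- sign(.km_rmean(km_h, tmax) - .km_rmean(km_l, tmax))
            } else {
              direction <- sign(mh - ml)
            }
          }
        }
      }
    }
    results[[ct]] <- list(cutoff = cut, logrank = lr)
    rows[[j]] <- data.frame(
      celltype = ct, status = status,
      statistic = if (is.null(lr)) NA_real_ else lr$statistic,
      p_value = if (is.null(lr)) NA_real_ else lr$p_value,
      direction = direction, n_high = n_high, n_low = n_low,
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), results = results,
                 min_group = min_group),
            class = "celltype_screen")
}

#' @export
print.celltype_screen <- function(x, ...) {
  s <- x$summary
  tested <- s$status == "tested"
  cat("Cell-type survival screen:", sum(tested), "tested,",
      sum(!tested), "excluded\n")
  sig <- tested & !is.na(s$p_value) & s$p_value < 0.05
  if (any(sig)) {
    cat("  significant at p < 0.05:",
        paste(sprintf("%s (p=%.3g, dir %+d)", s$celltype[sig],
                      s$p_value[sig], s$direction[sig]), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Survival comparison across mixture clusters
#'
#' k-sample log-rank test across the clusters of a fitted mixture, plus a
#' Kaplan-Meier curve per cluster. Clusters left empty by the argmax
#' assignment are dropped with a warning.
#'
#' @param fit A `gmm_fit` whose assignment names are sample ids.
#' @param clinical Clinical table covering every assigned sample.
#' @return A list with `logrank` (a `logrank_result`), `curves` (named list
#'   of `km_curve`) and `n_per_cluster`.
#' @export
cluster_survival <- function(fit, clinical) {
  .assert(inherits(fit, "gmm_fit"), "fit must be a gmm_fit")
  .assert(fit$k >= 2L, "need at least two clusters to compare")
  assn <- fit$assignment
  present <- sort(unique(assn))
  if (length(present) < fit$k) {
    warning("dropping empty cluster(s): ",
            paste(setdiff(seq_len(fit$k), present), collapse = ", "))
  }
  .assert(length(present) >= 2L, "fewer than two non-empty clusters")
  cl <- .clinical_for(clinical, names(assn))
  lr <- logrank_test(cl$os_time_days, cl$os_event, assn)
  curves <- lapply(present, function(g) {
    sel <- assn == g
    km_estimate(cl$os_time_days[sel], cl$os_event[sel])
  })
  names(curves) <- paste0("cluster_", present)
  list(logrank = lr, curves = curves,
       n_per_cluster = table(factor(assn, levels = present)))
}
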