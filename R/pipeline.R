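#' Pipeline configuration
#'
#' Validates input paths and stage parameters for [run_pipeline()]. All
#' randomness downstream derives from `seed`.
#'
#' @param tumor_expression,normal_expression Paths to gene-by-sample
#'   expression TSVs (matched by patient via the clinical table).
#' @param fractions Path to the sample-by-cell-type immune fraction TSV.
#' @param clinical Path to the clinical TSV.
#' @param gene_sets Path to a GMT file containing the immune-regulation
#'   gene set and the positive/negative control pools.
#' @param celltype_annotation Path to the gene -> cell-type annotation TSV.
#' @param out_dir Output directory.
#' @param immune_set,pc_set,nc_set Names of the three sets inside the GMT.
#' @param k_range GMM component range for both clusterings.
#' @param n_init GMM initializations.
#' @param alpha Significance threshold used by the survival screens, cohort
#'   rule and differential expression.
#' @param min_group Minimum stratum size in the cell-type screen.
#' @param pseudocount Fold-change pseudocount.
#' @param max_k_index,drop_ratio Top-gene selection rule on the index table.
#' @param combo_k Genes per random combination (reduced to the candidate
#'   pool size when the stepwise pool is smaller).
#' @param n_draws Random combinations per pool.
#' @param threshold AUC threshold for frequency profiling; `NULL` uses the
#'   mean of the positive-control pool's AUC distribution.
#' @param top_m Genes kept from the frequency profile for the exhaustive
#'   search (capped at 20).
#' @param required_celltypes Optional override of the cell types required
#'   by the annotation filter; by default the cell types significant in the
#'   survival screen are used.
#' @param seed Master seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(tumor_expression, normal_expression, fractions,
                            clinical, gene_sets, celltype_annotation,
                            out_dir,
                            immune_set = "immune_regulation",
                            pc_set = "positive_control",
                            nc_set = "negative_control",
                            k_range = 2:8, n_init = 1L, alpha = 0.05,
                            min_group = 10L, pseudocount = 0.01,
                            max_k_index = 10L, drop_ratio = 1.3,
                            combo_k = 10L, n_draws = 10000L,
                            threshold = NULL, top_m = 12L,
                            required_celltypes = NULL, seed = 1L) {
  paths <- c(tumor_expression = tumor_expression,
             normal_expression = normal_expression,
             fractions = fractions, clinical = clinical,
             gene_sets = gene_sets,
             celltype_annotation = celltype_annotation)
  missing <- paths[!file.exists(paths)]
  .assert(length(missing) == 0L, "input file(s) not found: ",
          paste(missing, collapse = ", "))
  .assert(top_m <= 20L, "top_m is capped at 20 (exhaustive search bound)")
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 immune_set = immune_set, pc_set = pc_set, nc_set = nc_set,
                 k_range = k_range, n_init = n_init, alpha = alpha,
                 min_group = min_group, pseudocount = pseudocount,
                 max_k_index = max_k_index, drop_ratio = drop_ratio,
                 combo_k = as.integer(combo_k), n_draws = as.integer(n_draws),
                 threshold = threshold, top_m = as.integer(top_m),
                 required_celltypes = required_celltypes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  .assert(requireNamespace("yaml", quietly = TRUE),
          "the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("tumor_expression", "normal_expression", "fractions",
                "clinical", "gene_sets", "celltype_annotation")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  do.call(pipeline_config, cfg)
}

#' Run the full discovery pipeline
#'
#' Executes the stages in discovery order on the configured inputs:
#' immune-fraction clustering, cluster survival comparison, per-cell-type
#' cumulative-SD survival screen, immune-gene expression clustering,
#' poor-survival cohort intersection, gene index ranking with top-drop
#' selection, paired differential expression, cell-type annotation filter,
#' stepwise logistic selection, random-combination benchmarking of the
#' candidate pool against the positive and negative control pools,
#' frequency profiling above the benchmark threshold, and exhaustive panel
#' search with leave-one-gene-out attribution. Every output file embeds the
#' seed and stage parameters; a manifest JSON lists all stage outputs. A
#' stage failure aborts with the stage name after persisting the outputs of
#' completed stages. When no cell type reaches `alpha` in the survival
#' screen, the annotation filter falls back to the six best-ranked tested
#' cell types and records the fallback in the manifest.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("immunosig")),
                   parameters = config[setdiff(names(config), "paths")],
                   inputs = config$paths,
                   stages = list())
  meta <- c(seed = config$seed)
  outpath <- function(f) file.path(config$out_dir, f)
  write_manifest <- function() {
    jsonlite::write_json(manifest, outpath("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- res
    res
  }

  tumor <- read_expression(config$paths$tumor_expression)
  normal <- read_expression(config$paths$normal_expression)
  fractions <- read_fractions(config$paths$fractions)
  clinical <- read_clinical(config$paths$clinical)
  sets <- read_gmt(config$paths$gene_sets)
  .assert(all(c(config$immune_set, config$pc_set, config$nc_set) %in% names(sets)),
          "GMT must contain the immune, PC and NC sets")
  annotation <- read_celltype_annotation(config$paths$celltype_annotation)

  tumor_cl <- clinical[clinical$tissue == "tumor", , drop = FALSE]
  pairing <- data.frame(
    tumor = tumor_cl$sample_id,
    normal = clinical$sample_id[match(paste0(tumor_cl$patient_id, "normal"),
                                      paste0(clinical$patient_id, clinical$tissue))],
    stringsAsFactors = FALSE)
  pairing <- pairing[!is.na(pairing$normal) & pairing$tumor %in% colnames(tumor) &
                       pairing$normal %in% colnames(normal), , drop = FALSE]

  # 1. GMM on immune fractions
  immune_fit <- NULL
  stage("cluster-immune", function() {
    immune_fit <<- fit_gmm(fractions, k_range = config$k_range,
                           n_init = config$n_init, seed = config$seed)
    f <- outpath("immune_clusters.tsv")
    .write_meta_tsv(data.frame(sample_id = names(immune_fit$assignment),
                               cluster = unname(immune_fit$assignment)),
                    f, c(meta, k = immune_fit$k, bic = immune_fit$bic))
    list(outputs = f, k = immune_fit$k, model = immune_fit$model_name)
  })

  # 2. Survival across immune clusters
  stage("immune-cluster-survival", function() {
    cs <- cluster_survival(immune_fit, clinical)
    f <- outpath("immune_cluster_survival.tsv")
    .write_meta_tsv(data.frame(statistic = cs$logrank$statistic,
                               df = cs$logrank$df,
                               p_value = cs$logrank$p_value), f, meta)
    list(outputs = f, p_value = cs$logrank$p_value)
  })

  # 3. Cell-type cumulative-SD survival screen
  screen <- NULL
  stage("screen-celltypes", function() {
    screen <<- celltype_survival_screen(fractions, clinical,
                                        min_group = config$min_group)
    f <- outpath("celltype_screen.tsv")
    .write_meta_tsv(screen$summary, f, meta)
    traces <- do.call(rbind, lapply(names(screen$results), function(ct) {
      cut <- screen$results[[ct]]$cutoff
      if (is.null(cut)) return(NULL)
      data.frame(celltype = ct, prefix_size = cut$prefix_sizes,
                 sd = cut$sd_trace, stringsAsFactors = FALSE)
    }))
    f2 <- outpath("celltype_sd_traces.tsv")
    .write_meta_tsv(traces, f2, meta)
    list(outputs = c(f, f2),
         n_significant = sum(screen$summary$p_value < config$alpha,
                             na.rm = TRUE))
  })

  # 4. GMM on immune-regulatory gene expression
  gene_fit <- NULL
  stage("cluster-genes", function() {
    sub <- subset_to_gene_set(tumor, sets[[config$immune_set]])
    gene_fit <<- cluster_by_expression(sub, k_range = config$k_range,
                                       n_init = config$n_init,
                                       seed = config$seed)
    f <- outpath("gene_clusters.tsv")
    .write_meta_tsv(data.frame(sample_id = names(gene_fit$assignment),
                               cluster = unname(gene_fit$assignment)),
                    f, c(meta, k = gene_fit$k))
    list(outputs = f, k = gene_fit$k,
         n_genes_missing = length(attr(sub, "missing_genes")))
  })

  # 5. Poor-survival cohort (intersection of the two poor strata)
  cohort <- NULL
  stage("cohort", function() {
    cohort <<- define_poor_survival_cohort(immune_fit, gene_fit, clinical,
                                           alpha = config$alpha)
    .assert(!cohort$empty, "poor-survival cohort is empty")
    f <- outpath("poor_survival_cohort.tsv")
    .write_meta_tsv(data.frame(sample_id = cohort$sample_ids), f,
                    c(meta, alpha = config$alpha))
    list(outputs = f, n = length(cohort$sample_ids))
  })

  cohort_pairs <- pairing[pairing$tumor %in% cohort$sample_ids, , drop = FALSE]

  # 6. Immune gene index on the poor cohort's matched pairs
  top <- NULL
  stage("index", function() {
    imm <- sets[[config$immune_set]]$symbols
    tg <- intersect(imm, rownames(tumor))
    fc <- fold_change(tumor[tg, , drop = FALSE], normal[tg, , drop = FALSE],
                      pairing = cohort_pairs, pseudocount = config$pseudocount)
    tab <- gene_index_table(names(fc), attr(fc, "mean_tumor"), unname(fc))
    top <<- select_top_by_drop(tab, max_k = config$max_k_index,
                               drop_ratio = config$drop_ratio)
    f <- outpath("gene_index.tsv")
    .write_meta_tsv(tab, f, c(meta, drop_ratio = config$drop_ratio))
    list(outputs = f, top_genes = top$genes, k = top$k)
  })

  # 7. Differential expression on the poor cohort
  de <- NULL
  stage("de", function() {
    de <<- differential_upregulated(tumor, normal, pairing = cohort_pairs,
                                    alpha = config$alpha, paired = TRUE)
    f <- outpath("de_genes.tsv")
    .write_meta_tsv(attr(de, "table"), f, c(meta, alpha = config$alpha))
    list(outputs = f, n_upregulated = length(de))
  })

  # 8. Cell-type expression filter
  filtered <- NULL
  stage("filter", function() {
    req <- config$required_celltypes
    fallback <- FALSE
    if (is.null(req)) {
      s <- screen$summary[!is.na(screen$summary$p_value), , drop = FALSE]
      req <- s$celltype[s$p_value < config$alpha]
      if (length(req) == 0L) {
        # no cell type reaches alpha: fall back to the six best-ranked ones
        req <- s$celltype[order(s$p_value)][seq_len(min(6L, nrow(s)))]
        fallback <- TRUE
      }
    }
    .assert(length(req) > 0L, "no survival-associated cell types to filter on")
    filtered <<- filter_by_celltype_expression(de, annotation, req)
    f <- outpath("filtered_genes.tsv")
    .write_meta_tsv(data.frame(gene = as.character(filtered)), f,
                    c(meta, required = paste(req, collapse = ",")))
    list(outputs = f, n = length(filtered),
         required_celltypes = req, alpha_fallback = fallback)
  })

  X <- t(tumor[, tumor_cl$sample_id, drop = FALSE])
  y <- tumor_cl$os_event

  # 9. Stepwise logistic refinement
  candidates <- NULL
  stage("stepwise", function() {
    .assert(length(filtered) >= 1L, "no genes left after filtering")
    candidates <<- stepwise_select(X[, filtered, drop = FALSE], y)
    f <- outpath("stepwise_genes.tsv")
    .write_meta_tsv(data.frame(gene = as.character(candidates)), f,
                    c(meta, aic = attr(candidates, "aic")))
    list(outputs = f, n = length(candidates), aic = attr(candidates, "aic"))
  })

  # 10. Random-combination benchmark: candidate vs PC vs NC pools
  benches <- NULL
  stage("benchmark", function() {
    pools <- list(candidate = as.character(candidates),
                  positive_control = intersect(sets[[config$pc_set]]$symbols,
                                               colnames(X)),
                  negative_control = intersect(sets[[config$nc_set]]$symbols,
                                               colnames(X)))
    k_eff <- min(config$combo_k, vapply(pools, length, integer(1)))
    .assert(k_eff >= 2L, "candidate pool too small for combinations")
    benches <<- lapply(seq_along(pools), function(i) {
      benchmark_random_combinations(pools[[i]], k = k_eff,
                                    n_draws = config$n_draws, X = X, y = y,
                                    seed = config$seed + i,
                                    pool_name = names(pools)[i])
    })
    names(benches) <<- names(pools)
    f <- outpath("benchmark_auc.tsv")
    .write_meta_tsv(do.call(rbind, lapply(benches, function(b) {
      data.frame(pool = b$pool_name, draw = seq_len(b$n_draws),
                 auc = b$auc_values, stringsAsFactors = FALSE)
    })), f, c(meta, k = k_eff, n_draws = config$n_draws))
    list(outputs = f, k = k_eff,
         mean_auc = vapply(benches, function(b) mean(b$auc_values), numeric(1)))
  })

  # 11. Frequency profile above the PC benchmark
  freq <- NULL
  stage("frequency", function() {
    thr <- config$threshold %||% mean(benches$positive_control$auc_values)
    freq <<- frequency_profile(benches$candidate, threshold = thr,
                               top_m = config$top_m)
    f <- outpath("frequency_profile.tsv")
    .write_meta_tsv(freq$table, f, c(meta, threshold = thr))
    list(outputs = f, threshold = thr, top = freq$top)
  })

  # 12. Exhaustive panel search + leave-one-gene-out
  stage("search-panel", function() {
    ps <- exhaustive_panel_search(freq$top, X, y)
    f <- outpath("panel_result.json")
    jsonlite::write_json(list(
      seed = config$seed,
      best_subset = ps$best_subset,
      best_auc = ps$best_auc,
      n_subsets_evaluated = ps$n_subsets_evaluated,
      coefficients = as.list(coef(ps$model)),
      auc_label = "in-sample",
      leave_one_out = ps$leave_one_out
    ), f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(outputs = f, best_auc = ps$best_auc,
         panel = ps$best_subset)
  })

  write_manifest()
  manifest$outputs <- outpath("manifest.json")
  invisible(manifest)
}
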