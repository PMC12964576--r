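#' Configuration for a synthetic tumor cohort
#'
#' Bundles and validates every knob of the cohort generator: latent immune
#' clusters with Dirichlet-distributed cell-type fractions, log-normal
#' matched tumor/normal expression with planted fold changes, exponential
#' survival whose hazard depends on cluster membership and on planted signal
#' genes, and independent exponential censoring.
#'
#' Defaults emulate a mid-sized renal-cancer cohort: 22 immune cell types,
#' five latent infiltration clusters (one dominant cluster, two high-hazard
#' minority clusters), FPKM-like log-normal expression, a baseline hazard
#' giving roughly one-third mortality over ten years of follow-up and 30%
#' censoring.
#'
#' @param n_patients Number of patients (>= 10).
#' @param n_celltypes Number of immune cell types (fraction dimensions).
#' @param n_clusters Number of latent immune clusters.
#' @param cluster_weights Mixing probabilities (sum to 1).
#' @param cluster_profiles `n_clusters x n_celltypes` matrix of mean fraction
#'   profiles, rows on the simplex. `NULL` builds block-separated profiles at
#'   separation 0.6 (see [plant_separable_clusters()]).
#' @param fraction_concentration Dirichlet concentration around each profile;
#'   larger = tighter clusters.
#' @param n_genes Gene universe size.
#' @param immune_reg_fraction Fraction of genes flagged immune-regulatory
#'   (these form the packaged gene-set analogue of an immune-regulation GO
#'   term).
#' @param de_spec `data.frame(gene, fold_change)` of planted tumor/normal
#'   effects; all fold changes must be >= 1 (upregulated in tumor).
#' @param signal_spec `data.frame(gene, effect)` of per-gene log-hazard
#'   effects on death, applied to the standardized log tumor expression.
#' @param cluster_hazard Per-cluster hazard multipliers.
#' @param baseline_hazard Baseline death hazard per day.
#' @param follow_up_days Administrative end of follow-up.
#' @param censor_rate Target probability that a death is censored before it
#'   is observed (independent exponential censoring).
#' @param noise_sd Log-scale expression noise SD.
#' @param cluster_expr_shift SD of cluster-specific multiplicative log-shifts
#'   applied to immune-regulatory genes in tumors; 0 disables cluster
#'   structure in expression space.
#' @param annotation_coverage Probability that a gene carries a cell-type
#'   expression annotation (planted signal genes are always annotated to all
#'   cell types so that annotation filtering cannot silently remove the
#'   ground truth).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300L,
                          n_celltypes = 22L,
                          n_clusters = 5L,
                          cluster_weights = c(0.20, 0.35, 0.15, 0.15, 0.15),
                          cluster_profiles = NULL,
                          fraction_concentration = 120,
                          n_genes = 2000L,
                          immune_reg_fraction = 0.15,
                          de_spec = NULL,
                          signal_spec = NULL,
                          cluster_hazard = c(1, 1, 1, 2.5, 3.5),
                          baseline_hazard = 1.2e-4,
                          follow_up_days = 3650,
                          censor_rate = 0.3,
                          noise_sd = 0.5,
                          cluster_expr_shift = 0,
                          annotation_coverage = 0.9,
                          seed = 1L) {
  .assert(n_patients >= 10, "n_patients must be >= 10")
  .assert(n_celltypes >= 2, "n_celltypes must be >= 2")
  .assert(n_clusters >= 1, "n_clusters must be >= 1")
  .assert(length(cluster_weights) == n_clusters,
          "cluster_weights must have one entry per cluster")
  .assert(all(cluster_weights > 0) && abs(sum(cluster_weights) - 1) < 1e-8,
          "cluster_weights must be positive and sum to 1")
  cfg <- list(
    n_patients = as.integer(n_patients), n_celltypes = as.integer(n_celltypes),
    n_clusters = as.integer(n_clusters), cluster_weights = cluster_weights,
    cluster_profiles = cluster_profiles,
    fraction_concentration = fraction_concentration,
    n_genes = as.integer(n_genes), immune_reg_fraction = immune_reg_fraction,
    de_spec = de_spec, signal_spec = signal_spec,
    cluster_hazard = cluster_hazard, baseline_hazard = baseline_hazard,
    follow_up_days = follow_up_days, censor_rate = censor_rate,
    noise_sd = noise_sd, cluster_expr_shift = cluster_expr_shift,
    annotation_coverage = annotation_coverage, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  if (is.null(cfg$cluster_profiles)) {
    cfg <- plant_separable_clusters(cfg, separation = 0.6)
  }
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  pr <- cfg$cluster_profiles
  .assert(is.matrix(pr) && nrow(pr) == cfg$n_clusters &&
            ncol(pr) == cfg$n_celltypes,
          "cluster_profiles must be n_clusters x n_celltypes")
  .assert(all(pr >= 0) && all(abs(rowSums(pr) - 1) < 1e-8),
          "each cluster profile must be non-negative and sum to 1")
  .assert(cfg$fraction_concentration > 0, "fraction_concentration must be positive")
  .assert(length(cfg$cluster_hazard) == cfg$n_clusters &&
            all(cfg$cluster_hazard > 0),
          "cluster_hazard must be positive, one per cluster")
  .assert(cfg$baseline_hazard > 0, "baseline_hazard must be positive")
  .assert(cfg$censor_rate >= 0 && cfg$censor_rate < 1,
          "censor_rate must be in [0, 1)")
  .assert(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  .assert(cfg$follow_up_days > 0, "follow_up_days must be positive")
  gene_names <- .gene_names(cfg$n_genes)
  for (spec in list(cfg$de_spec, cfg$signal_spec)) {
    if (!is.null(spec)) {
      .assert(is.data.frame(spec) && "gene" %in% names(spec),
              "de_spec/signal_spec must be data frames with a 'gene' column")
      .assert(all(spec$gene %in% gene_names),
              "planted spec names genes outside the gene universe")
    }
  }
  if (!is.null(cfg$de_spec)) {
    .assert(all(cfg$de_spec$fold_change >= 1),
            "all planted fold changes must be >= 1 (upregulated in tumor)")
  }
  invisible(cfg)
}

.gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Build well-separated cluster profiles on the simplex
#'
#' Replaces `cluster_profiles` with block-structured profiles: each cluster
#' concentrates a `separation` share of its mass uniformly on a disjoint
#' block of cell types and spreads the remainder uniformly over all cell
#' types. The pairwise L1 distance between any two profiles is exactly
#' `2 * separation`, so Gaussian-mixture recovery is expected for moderate
#' concentration; `separation = 1` gives profiles with disjoint support
#' (orthogonal on the simplex).
#'
#' @param config A `cohort_config`.
#' @param separation Requested separation in (0, 1].
#' @return The config with `cluster_profiles` replaced; the separation and
#'   the guaranteed minimum pairwise L1 distance are recorded as attributes
#'   of the profile matrix.
#' @export
plant_separable_clusters <- function(config, separation = 0.6) {
  .assert(inherits(config, "cohort_config"), "config must be a cohort_config")
  .assert(separation > 0 && separation <= 1, "separation must be in (0, 1]")
  k <- config$n_clusters
  d <- config$n_celltypes
  .assert(k <= d,
          "cannot build ", k, " disjoint cluster blocks from ", d,
          " cell types")
  bs <- d %/% k
  prof <- matrix((1 - separation) / d, k, d)
  for (i in seq_len(k)) {
    block <- ((i - 1L) * bs + 1L):(i * bs)
    prof[i, block] <- prof[i, block] + separation / bs
  }
  attr(prof, "separation") <- separation
  attr(prof, "min_pairwise_l1") <- 2 * separation
  config$cluster_profiles <- prof
  .validate_config(config)
  config
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full cohort under the configured model: cluster labels, Dirichlet
#' immune fractions, matched log-normal tumor/normal expression with planted
#' fold changes, exponential survival with per-patient hazard
#' `baseline * cluster_multiplier * exp(sum(effect * z))` (z = standardized
#' log tumor expression of each signal gene), independent exponential
#' censoring calibrated to `censor_rate`, and administrative censoring at the
#' end of follow-up.
#'
#' @param config A validated `cohort_config`.
#' @return An object of class `synthetic_cohort`: `tumor` and `normal`
#'   gene-by-sample matrices (columns `<patient>-T` / `<patient>-N`),
#'   `fractions` (patients x cell types, rows summing to 1), `clinical`
#'   (one row per sample: `sample_id`, `patient_id`, `tissue`,
#'   `os_time_days`, `os_event`), `annotation` (gene -> cell types),
#'   `gene_sets` (immune-regulation set plus positive/negative control
#'   pools), `truth` (cluster labels, DE genes, signal genes, per-patient
#'   latent death probability) and the `config`.
#' @export
generate_cohort <- function(config) {
  .validate_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  d <- cfg$n_celltypes
  k <- cfg$n_clusters
  patients <- sprintf("P%04d", seq_len(n))
  genes <- .gene_names(cfg$n_genes)
  celltypes <- sprintf("celltype_%02d", seq_len(d))

  cluster <- sample.int(k, n, replace = TRUE, prob = cfg$cluster_weights)

  # Dirichlet draw around each cluster profile.
  alpha <- cfg$fraction_concentration * cfg$cluster_profiles
  fr <- matrix(stats::rgamma(n * d, shape = alpha[cluster, , drop = FALSE]),
               n, d)
  fr <- fr / rowSums(fr)
  dimnames(fr) <- list(paste0(patients, "-T"), celltypes)

  # Immune-regulatory gene flags and per-gene baselines (FPKM-like).
  # Planted DE and signal genes are immune-regulatory by construction: the
  # discovery procedure screens immune-regulation candidates, so planted
  # ground truth must live inside that set to be recoverable.
  planted <- unique(c(
    if (!is.null(cfg$de_spec)) cfg$de_spec$gene,
    if (!is.null(cfg$signal_spec)) cfg$signal_spec$gene))
  n_imm <- max(2L, round(cfg$immune_reg_fraction * cfg$n_genes))
  immune_reg <- sort(union(planted,
                           sample(genes, max(0L, n_imm - length(planted)))))
  baseline <- stats::rlnorm(cfg$n_genes, meanlog = log(8), sdlog = 1.5)
  names(baseline) <- genes

  fc <- stats::setNames(rep(1, cfg$n_genes), genes)
  de_genes <- character(0)
  if (!is.null(cfg$de_spec)) {
    fc[cfg$de_spec$gene] <- cfg$de_spec$fold_change
    de_genes <- cfg$de_spec$gene[cfg$de_spec$fold_change > 1]
  }

  # Cluster-specific multiplicative log-shifts on immune-regulatory genes
  # give the expression view the same latent structure as the fractions.
  shift <- matrix(0, k, cfg$n_genes, dimnames = list(NULL, genes))
  if (cfg$cluster_expr_shift > 0) {
    shift[, immune_reg] <- stats::rnorm(k * length(immune_reg),
                                        sd = cfg$cluster_expr_shift)
  }

  # Mean-calibrated log-normal noise: E[X] equals the target mean exactly,
  # so empirical fold changes recover planted ones as noise_sd -> 0.
  lnoise <- function() {
    matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd), cfg$n_genes, n)
  }
  adj <- cfg$noise_sd^2 / 2
  normal <- baseline * exp(lnoise() - adj)
  tumor_mean <- (baseline * fc) * exp(t(shift[cluster, , drop = FALSE]))
  tumor <- tumor_mean * exp(lnoise() - adj)
  dimnames(tumor) <- list(genes, paste0(patients, "-T"))
  dimnames(normal) <- list(genes, paste0(patients, "-N"))

  # Survival: per-patient hazard from cluster and signal-gene burden.
  log_rel <- rep(0, n)
  signal_genes <- character(0)
  if (!is.null(cfg$signal_spec) && nrow(cfg$signal_spec) > 0) {
    signal_genes <- cfg$signal_spec$gene
    z <- scale(t(log(tumor[signal_genes, , drop = FALSE] + 1e-9)))
    z[is.nan(z)] <- 0
    log_rel <- drop(z %*% cfg$signal_spec$effect)
  }
  hazard <- cfg$baseline_hazard * cfg$cluster_hazard[cluster] * exp(log_rel)
  t_death <- stats::rexp(n, rate = hazard)
  if (cfg$censor_rate > 0) {
    h_cens <- hazard * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(n, rate = h_cens)
  } else {
    h_cens <- rep(0, n)
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_death, t_cens, cfg$follow_up_days)
  os_event <- as.integer(t_death <= pmin(t_cens, cfg$follow_up_days))

  # P(death observed before censoring and end of follow-up).
  tot <- hazard + h_cens
  death_prob <- hazard / tot * (1 - exp(-tot * cfg$follow_up_days))

  clinical <- rbind(
    data.frame(sample_id = paste0(patients, "-T"), patient_id = patients,
               tissue = "tumor", os_time_days = os_time, os_event = os_event,
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(patients, "-N"), patient_id = patients,
               tissue = "normal", os_time_days = os_time, os_event = os_event,
               stringsAsFactors = FALSE)
  )

  # Cell-type expression annotation (stand-in for an immune-cell expression
  # atlas). Signal genes are annotated to every cell type by construction.
  annotation <- vector("list", cfg$n_genes)
  names(annotation) <- genes
  annotated <- stats::runif(cfg$n_genes) < cfg$annotation_coverage
  n_types <- sample(1:4, cfg$n_genes, replace = TRUE)
  for (i in which(annotated)) {
    annotation[[i]] <- sort(sample(celltypes, n_types[i]))
  }
  annotation[signal_genes] <- list(celltypes)
  annotation <- annotation[!vapply(annotation, is.null, logical(1))]

  # Control pools: a mixed-quality positive pool (signal + planted DE +
  # other immune genes) and a pure-noise negative pool.
  null_genes <- setdiff(genes, union(union(de_genes, signal_genes), immune_reg))
  pc_extra <- setdiff(union(de_genes, immune_reg), signal_genes)
  pc <- union(signal_genes,
              sample(pc_extra, min(length(pc_extra),
                                   max(0L, 63L - length(signal_genes)))))
  nc <- sample(null_genes, min(365L, length(null_genes)))
  gene_sets <- list(
    immune_regulation = gene_set("immune_regulation", immune_reg),
    positive_control = gene_set("positive_control", pc),
    negative_control = gene_set("negative_control", nc)
  )

  structure(list(
    tumor = tumor, normal = normal, fractions = fr, clinical = clinical,
    annotation = annotation, gene_sets = gene_sets,
    truth = list(cluster_label = stats::setNames(cluster, patients),
                 de_genes = de_genes, signal_genes = signal_genes,
                 death_prob = stats::setNames(death_prob, patients),
                 hazard = stats::setNames(hazard, patients)),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_patients, "patients,",
      x$config$n_genes, "genes,", x$config$n_celltypes, "cell types,",
      x$config$n_clusters, "latent clusters\n")
  cat("  planted DE genes:", length(x$truth$de_genes),
      "; signal genes:", length(x$truth$signal_genes),
      "; observed death rate:",
      round(mean(x$clinical$os_event[x$clinical$tissue == "tumor"]), 3), "\n")
  invisible(x)
}

#' Write a synthetic cohort to standard pipeline input files
#'
#' Emits the canonical TSV/GMT/JSON inputs consumed by [run_pipeline()]:
#' tumor and normal expression, immune fractions, clinical table, cell-type
#' annotation, the three gene-set pools and the ground truth.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "synthetic_cohort"), "not a synthetic_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(seed = cohort$config$seed)
  paths <- c(
    tumor_expression = file.path(dir, "tumor_expression.tsv"),
    normal_expression = file.path(dir, "normal_expression.tsv"),
    fractions = file.path(dir, "immune_fractions.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    annotation = file.path(dir, "celltype_annotation.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(cohort$tumor, paths["tumor_expression"], meta = meta)
  write_expression(cohort$normal, paths["normal_expression"], meta = meta)
  write_fractions(cohort$fractions, paths["fractions"], meta = meta)
  write_clinical(cohort$clinical, paths["clinical"], meta = meta)
  write_celltype_annotation(cohort$annotation, paths["annotation"], meta = meta)
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         cluster_label = as.list(cohort$truth$cluster_label),
         de_genes = cohort$truth$de_genes,
         signal_genes = cohort$truth$signal_genes,
         death_prob = as.list(cohort$truth$death_prob)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
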