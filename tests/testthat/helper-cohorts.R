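# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# Small cohort with planted DE genes, signal genes and cluster-aligned
# expression shifts: the standard fixture for recovery tests.
planted_cohort <- function(seed = 1, n_patients = 150, n_genes = 500,
                           n_de = 25, n_signal = 5, fc = 4,
                           effect = 0.5, shift = 1, ...) {
  g <- gene_ids(n_genes)
  cfg <- cohort_config(
    n_patients = n_patients, n_genes = n_genes,
    de_spec = if (n_de > 0)
      data.frame(gene = g[seq_len(n_de)], fold_change = fc),
    signal_spec = if (n_signal > 0)
      data.frame(gene = g[seq_len(n_signal)], effect = effect),
    cluster_expr_shift = shift, seed = seed, ...)
  generate_cohort(cfg)
}

# Survival-neutral cohort: equal hazards, no signal genes.
neutral_cohort <- function(seed = 1, n_patients = 200, n_genes = 100, ...) {
  cfg <- cohort_config(n_patients = n_patients, n_genes = n_genes,
                       cluster_hazard = rep(1, 5), seed = seed, ...)
  generate_cohort(cfg)
}

# Expression design matrix (samples x genes) and vital-status labels for
# logistic/ROC stages.
design_from_cohort <- function(cohort) {
  X <- t(cohort$tumor)
  cl <- cohort$clinical[cohort$clinical$tissue == "tumor", ]
  y <- cl$os_event[match(rownames(X), cl$sample_id)]
  list(X = X, y = y, clinical = cohort$clinical)
}

# Random small survival dataset for oracle agreement loops.
random_survival <- function(n, seed) {
  set.seed(seed)
  list(times = round(rexp(n, 0.1), 1) + 0.1,
       events = rbinom(n, 1, 0.7),
       group = rbinom(n, 1, 0.5))
}

table1_fixture <- function() {
  path <- system.file("extdata", "kirc_poor_survival_index_top20.tsv",
                      package = "immunosig")
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
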