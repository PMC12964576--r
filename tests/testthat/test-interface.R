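test_that("expression I/O round-trips losslessly and validates input", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  mat <- matrix(rlnorm(20 * 6), 20, 6,
                dimnames = list(gene_ids(20), paste0("S", 1:6)))
  f <- file.path(tmp, "expr.tsv")
  write_expression(mat, f, meta = c(seed = 42))
  back <- read_expression(f)
  expect_equal(back, mat, tolerance = 1e-12)
  # metadata header is embedded
  expect_match(readLines(f, n = 1), "seed=42")

  # duplicate gene rows collapse by mean with a warning
  dup <- rbind(mat, mat[1, , drop = FALSE])
  rownames(dup) <- c(rownames(mat), rownames(mat)[1])
  f2 <- file.path(tmp, "dup.tsv")
  write_expression(dup, f2)
  expect_warning(coll <- read_expression(f2), "duplicated")
  expect_equal(nrow(coll), 20)
  expect_equal(coll[1, ], mat[1, ], tolerance = 1e-12)

  # negative cell is an error naming the cell
  bad <- mat
  bad[3, 2] <- -1
  f3 <- file.path(tmp, "neg.tsv")
  write_expression(bad, f3)
  expect_error(read_expression(f3), "G00003.*S2")

  # non-numeric cell is an error
  writeLines(c("gene\tS1\tS2", "G1\t1.5\toops"), file.path(tmp, "txt.tsv"))
  expect_error(read_expression(file.path(tmp, "txt.tsv")), "non-numeric")
})

test_that("fractions, clinical and annotation I/O round-trip and validate", {
  tmp <- withr::local_tempdir()
  co <- planted_cohort(seed = 2, n_patients = 30, n_genes = 40)

  f <- file.path(tmp, "fr.tsv")
  write_fractions(co$fractions, f)
  expect_equal(read_fractions(f), co$fractions, tolerance = 1e-12)
  bad <- co$fractions * 1.2
  write_fractions(bad, f)
  expect_error(read_fractions(f), "sum to 1")

  fc <- file.path(tmp, "cl.tsv")
  write_clinical(co$clinical, fc)
  back <- read_clinical(fc)
  expect_equal(back$os_time_days, co$clinical$os_time_days, tolerance = 1e-12)
  expect_identical(back$sample_id, co$clinical$sample_id)
  write_clinical(co$clinical[, -5], fc)
  expect_error(read_clinical(fc), "os_event")

  fa <- file.path(tmp, "ann.tsv")
  write_celltype_annotation(co$annotation, fa)
  back_ann <- read_celltype_annotation(fa)
  expect_identical(unclass(back_ann)[order(names(back_ann))],
                   co$annotation[order(names(co$annotation))],
                   ignore_attr = TRUE)
})

test_that("GMT parsing: normalization, dedup, empty file, malformed line", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "sets.gmt")
  writeLines("myset\tdesc\ta\tB\tc\td\te", f)
  sets <- read_gmt(f)
  expect_length(sets, 1)
  expect_equal(sets$myset$symbols, c("A", "B", "C", "D", "E"))

  writeLines("dupset\tdesc\tA\tB\tA\tC\tB", f)
  expect_length(read_gmt(f)$dupset$symbols, 3)

  writeLines(character(0), f)
  expect_length(read_gmt(f), 0)

  writeLines("short\tonly2fields", f)
  expect_error(read_gmt(f), "fewer than 3")

  # write/read round trip
  write_gmt(list(gene_set("s1", c("X", "Y")), gene_set("s2", "Z")), f)
  rt <- read_gmt(f)
  expect_equal(names(rt), c("s1", "s2"))
  expect_equal(rt$s2$symbols, "Z")
})

test_that("pipeline config validates inputs before any computation", {
  tmp <- withr::local_tempdir()
  expect_error(
    pipeline_config(
      tumor_expression = file.path(tmp, "missing.tsv"),
      normal_expression = file.path(tmp, "missing.tsv"),
      fractions = file.path(tmp, "missing.tsv"),
      clinical = file.path(tmp, "missing.tsv"),
      gene_sets = file.path(tmp, "missing.gmt"),
      celltype_annotation = file.path(tmp, "missing.tsv"),
      out_dir = tmp),
    "not found")
})

test_that("pipeline runs end-to-end at small scale and is rerun-deterministic", {
  tmp <- withr::local_tempdir()
  g <- gene_ids(400)
  set.seed(123)
  cfg <- cohort_config(
    n_patients = 150, n_genes = 400,
    de_spec = data.frame(gene = g[1:30], fold_change = runif(30, 2, 6)),
    signal_spec = data.frame(gene = g[1:4], effect = 0.6),
    cluster_expr_shift = 1, seed = 19)
  co <- generate_cohort(cfg)
  paths <- write_cohort(co, file.path(tmp, "in"))
  mk_config <- function(out) {
    pipeline_config(
      tumor_expression = paths[["tumor_expression"]],
      normal_expression = paths[["normal_expression"]],
      fractions = paths[["fractions"]],
      clinical = paths[["clinical"]],
      gene_sets = paths[["gene_sets"]],
      celltype_annotation = paths[["annotation"]],
      out_dir = out, k_range = 4:6, n_draws = 400, combo_k = 6,
      top_m = 8, seed = 3)
  }
  m <- run_pipeline(mk_config(file.path(tmp, "out1")))
  expect_length(m$stages, 12)
  expect_true(file.exists(file.path(tmp, "out1", "manifest.json")))
  for (s in m$stages) expect_true(all(file.exists(s$outputs)))
  expect_true(m$stages$`search-panel`$best_auc > 0.5)

  # rerun with the same config: byte-identical numeric outputs
  run_pipeline(mk_config(file.path(tmp, "out2")))
  for (f in c("gene_index.tsv", "benchmark_auc.tsv", "frequency_profile.tsv",
              "panel_result.json")) {
    expect_identical(readLines(file.path(tmp, "out1", f)),
                     readLines(file.path(tmp, "out2", f)))
  }
})
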