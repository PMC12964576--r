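# Canonical table dialect: TSV, UTF-8, Unix newlines, uppercase gene
# symbols. Writers embed the seed/parameter metadata as '# key=value' header
# lines; readers skip '#' comments, so write-then-read round-trips.

.write_meta_tsv <- function(df, path, meta = NULL, row_label = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con, sep = "\n")
  }
  if (!is.null(row_label)) {
    rn <- rownames(df)  # may hold duplicates; kept verbatim
    rownames(df) <- NULL
    df <- as.data.frame(df, check.names = FALSE)
    df <- cbind(stats::setNames(data.frame(rn, stringsAsFactors = FALSE),
                                row_label), df)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a gene-symbol first column and a sample-ID header row. Gene
#' symbols are uppercase-normalized; duplicate symbols are collapsed by
#' their mean with a warning; negative or non-numeric cells are an error
#' naming the offending cell.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  .assert(ncol(df) >= 2L, "expression file needs a gene column plus samples: ", path)
  genes <- .norm_symbols(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric expression value at gene ", genes[bad[1, 1]],
           ", sample ", colnames(mat)[bad[1, 2]], call. = FALSE)
    }
    storage.mode(mat) <- "double"
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative expression value at gene ", genes[neg[1, 1]],
         ", sample ", colnames(mat)[neg[1, 2]], call. = FALSE)
  }
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene symbol(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "))
    rs <- rowsum(mat, group = genes)
    mat <- rs / as.vector(table(genes)[rownames(rs)])
    mat <- mat[unique(genes), , drop = FALSE]
  }
  mat
}

#' Write an expression matrix to TSV
#' @param mat Gene-by-sample matrix.
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key=value`
#'   header lines.
#' @export
write_expression <- function(mat, path, meta = NULL) {
  .write_meta_tsv(mat, path, meta, row_label = "gene")
}

#' Read a sample-by-cell-type immune fraction matrix from TSV
#'
#' @param path TSV path (sample-ID first column).
#' @param tol Row-sum tolerance around 1.
#' @return Numeric matrix, samples in rows.
#' @export
read_fractions <- function(path, tol = 1e-6) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  .assert(!anyDuplicated(ids), "duplicate sample ids in ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  .assert(all(is.finite(mat)) && all(mat >= 0),
          "fractions must be finite and non-negative: ", path)
  .assert(all(abs(rowSums(mat) - 1) < tol),
          "fraction rows must sum to 1 within ", tol, ": ", path)
  rownames(mat) <- ids
  mat
}

#' @rdname read_fractions
#' @param mat Sample-by-cell-type matrix.
#' @param meta Metadata header entries.
#' @export
write_fractions <- function(mat, path, meta = NULL) {
  .write_meta_tsv(mat, path, meta, row_label = "sample_id")
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `patient_id`, `tissue`, `os_time_days`,
#' `os_event`.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "patient_id", "tissue", "os_time_days", "os_event")
  missing <- setdiff(need, names(df))
  .assert(length(missing) == 0L, "clinical table missing column(s): ",
          paste(missing, collapse = ", "))
  .assert(all(df$os_event %in% c(0, 1)), "os_event must be 0/1")
  .assert(all(df$os_time_days >= 0), "os_time_days must be non-negative")
  df
}

#' @rdname read_clinical
#' @param df Clinical data frame.
#' @param meta Metadata header entries.
#' @export
write_clinical <- function(df, path, meta = NULL) {
  .write_meta_tsv(df, path, meta)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then symbols. Symbols are uppercase-normalized and deduplicated.
#'
#' @param path GMT path.
#' @return Named list of `gene_set` objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .assert(length(fields) >= 3L,
            "malformed GMT line ", i, " in ", path, ": fewer than 3 fields")
    gs <- gene_set(fields[1], fields[-(1:2)])
    sets[[gs$name]] <- gs
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(gs) {
    paste(c(gs$name, "na", gs$symbols), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
}

#' Read a cell-type expression annotation from TSV
#'
#' Two columns: `gene` and `celltypes` (comma-separated list).
#' @param path TSV path.
#' @return A `celltype_annotation`.
#' @export
read_celltype_annotation <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("gene", "celltypes") %in% names(df)),
          "annotation table needs 'gene' and 'celltypes' columns")
  ann <- strsplit(as.character(df$celltypes), ",", fixed = TRUE)
  ann <- lapply(ann, trimws)
  names(ann) <- df$gene
  celltype_annotation(ann)
}

#' @rdname read_celltype_annotation
#' @param ann Named list / `celltype_annotation`.
#' @param meta Metadata header entries.
#' @export
write_celltype_annotation <- function(ann, path, meta = NULL) {
  df <- data.frame(gene = names(ann),
                   celltypes = vapply(ann, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  .write_meta_tsv(df, path, meta)
}
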