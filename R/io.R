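# Plain-text table I/O: TSV for every pipeline artifact, MatrixMarket with
# sidecar name files for counts. Write -> read round-trips are identities.

#' Write / read a counts matrix as TSV
#'
#' Genes in rows, samples in columns, first column `probe_id`.
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param path Output path.
#' @return `write_counts_tsv` the path (invisibly); `read_counts_tsv` a
#'   numeric matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  values <- if (inherits(counts, "count_matrix")) counts$values else counts
  df <- data.frame(probe_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.numeric(m)) stop("non-numeric count entries in ", path)
  m
}

#' Write / read a counts matrix as MatrixMarket + name sidecars
#'
#' `<path>.mtx` holds the sparse matrix; `<path>.rownames.txt` and
#' `<path>.colnames.txt` the probe and sample ids (one per line).
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param path Base path (without extension).
#' @return `write_counts_mtx` the base path (invisibly); `read_counts_mtx`
#'   a dense numeric matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, path) {
  values <- if (inherits(counts, "count_matrix")) counts$values else counts
  Matrix::writeMM(Matrix::Matrix(values, sparse = TRUE), paste0(path, ".mtx"))
  writeLines(rownames(values), paste0(path, ".rownames.txt"))
  writeLines(colnames(values), paste0(path, ".colnames.txt"))
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  rownames(m) <- readLines(paste0(path, ".rownames.txt"))
  colnames(m) <- readLines(paste0(path, ".colnames.txt"))
  m
}

#' Write / read a study design (sample metadata) TSV
#'
#' @param design A `study_design`.
#' @param path File path.
#' @return The design (on read), classed `study_design`.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$vehicle_of[d$vehicle_of == "NA"] <- NA_character_
  rownames(d) <- d$sample_id
  class(d) <- c("study_design", "data.frame")
  d
}

#' Write / read a log2FC matrix (values + padj TSVs)
#'
#' `<path>.logfc.tsv`, `<path>.padj.tsv` (conditions in rows, first column
#' `condition_id`) and `<path>.conditions.tsv`.
#'
#' @param lfc A [logfc_matrix()].
#' @param path Base path.
#' @return On read, a `logfc_matrix`.
#' @export
write_logfc_tsv <- function(lfc, path) {
  wr <- function(m, p) {
    df <- data.frame(condition_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(lfc$values, paste0(path, ".logfc.tsv"))
  wr(lfc$padj, paste0(path, ".padj.tsv"))
  write.table(lfc$conditions, paste0(path, ".conditions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_logfc_tsv
#' @export
read_logfc_tsv <- function(path) {
  rd <- function(p) {
    df <- read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  conds <- read.delim(paste0(path, ".conditions.tsv"), stringsAsFactors = FALSE)
  rownames(conds) <- conds$condition_id
  logfc_matrix(rd(paste0(path, ".logfc.tsv")), rd(paste0(path, ".padj.tsv")), conds)
}

#' Write a generic data-frame artifact as TSV
#'
#' @param df Data frame (trait tables, RNAi tables, module assignments,
#'   correlation records, ...).
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
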