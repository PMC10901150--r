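#' Raw count matrix with sample metadata
#'
#' Entry-point container of the pipeline: a probes x samples matrix of raw
#' (non-negative integer) counts together with the `study_design` describing
#' each sample.
#'
#' @param values Non-negative numeric matrix, probes in rows (unique
#'   rownames), samples in columns.
#' @param design A `study_design` covering every column of `values`.
#' @return A `count_matrix` object (list with elements `values`, `design`).
#' @export
count_matrix <- function(values, design) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("count matrix contains negative entries")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("probe ids (rownames) must be present and unique")
  }
  if (is.null(colnames(values))) stop("sample ids (colnames) must be present")
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing)) {
    stop("samples absent from design metadata: ", paste(head(missing, 5), collapse = ", "))
  }
  obj <- list(values = values,
              design = design[match(colnames(values), design$sample_id), , drop = FALSE])
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d probes x %d samples (%d compounds, %d batches)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$compound)), length(unique(x$design$batch))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Condition x gene log2 fold-change matrix
#'
#' Carries log2FC values against matched vehicle controls, aligned adjusted
#' p-values, and per-condition metadata (compound, dose level, concentration,
#' time point, replicate counts).
#'
#' @param values Numeric matrix, conditions x genes; rownames are condition
#'   ids, colnames gene/probe ids.
#' @param padj Matrix of adjusted p-values, same dimensions and dimnames as
#'   `values` (entries in \[0, 1\]).
#' @param conditions Data frame with one row per condition (rownames matching
#'   `rownames(values)`), typically from [design_conditions()] plus replicate
#'   counts.
#' @return A `logfc_matrix` object.
#' @export
logfc_matrix <- function(values, padj, conditions) {
  stopifnot(is.matrix(values), is.matrix(padj))
  if (!identical(dim(values), dim(padj))) stop("values and padj dimensions differ")
  if (any(is.infinite(values))) stop("log2FC values must be finite (NA allowed for missing entries)")
  pr <- range(padj, na.rm = TRUE)
  if (pr[1] < 0 || pr[2] > 1) stop("padj entries must lie in [0, 1]")
  if (!all(rownames(values) %in% rownames(conditions))) {
    stop("every condition must appear in the conditions table")
  }
  obj <- list(values = values, padj = padj,
              conditions = conditions[rownames(values), , drop = FALSE])
  class(obj) <- "logfc_matrix"
  obj
}

#' @export
print.logfc_matrix <- function(x, ...) {
  cat(sprintf("logfc_matrix: %d conditions x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.logfc_matrix <- function(x) dim(x$values)
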