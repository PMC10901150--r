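# Shared fixture builders: small designs/specs used across test files.

tiny_design <- function(seed = 1, n_dili = 2, doses = 3, reps = 3, batches = 1) {
  generate_design(c(DILI = n_dili), n_dose_levels = doses,
                  time_points = c(4, 8, 24), n_replicates = reps,
                  n_batches = batches, seed = seed)
}

tiny_spec <- function(design, seed = 1, n_genes = 200, n_modules = 2,
                      module_size = 20, ...) {
  module_spec(design, n_genes = n_genes, n_modules = n_modules,
              module_size = module_size, seed = seed, ...)
}

# A logfc_matrix wrapper for a bare conditions x genes matrix.
as_lfc <- function(m, time_h = NULL, padj = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  conds <- data.frame(condition_id = rownames(m),
                      compound = "CPD", dose_level = seq_len(nrow(m)),
                      concentration = seq_len(nrow(m)),
                      time_h = time_h %||% rep(24, nrow(m)),
                      row.names = rownames(m), stringsAsFactors = FALSE)
  if (is.null(padj)) padj <- matrix(1, nrow(m), ncol(m))
  dimnames(padj) <- dimnames(m)
  logfc_matrix(m, padj, conds)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Block-structured random matrix: `blocks` named list module -> gene count,
# shared latent factor per block plus iid noise.
block_matrix <- function(n_cond, blocks, noise = 0.2, n_background = 0, seed = 1) {
  set.seed(seed)
  cols <- list()
  labels <- integer(0)
  for (b in seq_along(blocks)) {
    f <- rnorm(n_cond)
    for (j in seq_len(blocks[[b]])) {
      cols[[length(cols) + 1L]] <- f + rnorm(n_cond, 0, noise)
      labels <- c(labels, b)
    }
  }
  for (j in seq_len(n_background)) {
    cols[[length(cols) + 1L]] <- rnorm(n_cond)
    labels <- c(labels, 0L)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  attr(m, "labels") <- setNames(labels, colnames(m))
  m
}
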