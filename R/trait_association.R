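#' Align module scores and cell-death outcomes on shared conditions
#'
#' Pairs eigengene scores with cell-death fractions over the exposure
#' conditions (same compound and concentration) present in both tables:
#' every transcriptomic time point of a shared (compound, concentration)
#' pairs with every death measurement record for it.
#'
#' @param module_set A `module_set` whose `conditions` carry `compound`,
#'   `concentration`, `time_h`.
#' @param trait A `trait_table` (see [generate_cell_death()]): columns
#'   `compound`, `concentration`, `death_time_h`, `death_type`, `fraction`.
#' @return A `paired` data frame (`compound`, `concentration`,
#'   `condition_id`, `time_h`, `death_time_h`, `death_type`, `fraction`);
#'   unmatched (compound, concentration) keys of either side in
#'   `attr(, "unmatched")`.
#' @export
align_conditions <- function(module_set, trait) {
  conds <- module_set$conditions
  if (is.null(conds) || !nrow(conds) || !nrow(trait)) {
    stop("both module conditions and trait table must be nonempty")
  }
  key_eg <- paste(conds$compound, conds$concentration)
  key_tr <- paste(trait$compound, trait$concentration)
  shared <- intersect(key_eg, key_tr)
  unmatched <- list(module_only = setdiff(key_eg, key_tr),
                    trait_only = setdiff(key_tr, key_eg))
  if (!length(shared)) {
    stop("no shared (compound, concentration) conditions between module scores and trait table")
  }
  eg_side <- conds[key_eg %in% shared,
                   c("condition_id", "compound", "concentration", "time_h")]
  tr_side <- trait[key_tr %in% shared, , drop = FALSE]
  paired <- merge(eg_side, tr_side, by = c("compound", "concentration"))
  paired <- paired[order(paired$compound, paired$concentration,
                         paired$time_h, paired$death_time_h, paired$death_type), ]
  rownames(paired) <- NULL
  attr(paired, "unmatched") <- unmatched
  paired
}

#' Per-compound correlation of module activity with cell death
#'
#' For each (module, compound, death type, death time), computes the Pearson
#' correlation between the module's eigengene scores and the death fraction
#' over the paired observations (all shared concentrations x transcriptomic
#' time points), with a two-sided t-distribution p-value, BH-adjusted within
#' each (death type, death time) family across all module x compound
#' records. Records with fewer than `min_points` pairs or zero variance on
#' either side are skipped (and noted). The module's maximum eigengene
#' score over the compound's shared data points is recorded for the
#' activation criterion of [select_hit_modules()].
#'
#' @param module_set A `module_set`.
#' @param paired Paired observations from [align_conditions()].
#' @param min_points Minimum paired points for a correlation (default 3).
#' @return Data frame of correlation records: `module`, `compound`,
#'   `death_type`, `death_time_h`, `r`, `p`, `padj`, `n`, `max_eg`;
#'   skipped records in `attr(, "skipped")`.
#' @export
correlate_modules_death <- function(module_set, paired, min_points = 3) {
  egs <- module_set$eigengenes
  modules <- colnames(egs)
  grp <- interaction(paired$compound, paired$death_type, paired$death_time_h,
                     drop = TRUE)
  parts <- split(paired, grp)
  recs <- list(); skipped <- list()
  for (d in parts) {
    x_idx <- d$condition_id
    for (m in modules) {
      x <- egs[x_idx, m]
      y <- d$fraction
      key <- data.frame(module = m, compound = d$compound[1],
                        death_type = d$death_type[1],
                        death_time_h = d$death_time_h[1],
                        stringsAsFactors = FALSE)
      if (length(x) < min_points || sd(x) == 0 || sd(y) == 0) {
        skipped[[length(skipped) + 1L]] <- cbind(key, n = length(x))
        next
      }
      r <- cor(x, y)
      recs[[length(recs) + 1L]] <- cbind(
        key, r = r, p = cor_pvalue(r, length(x)), n = length(x),
        max_eg = max(x))
    }
  }
  if (!length(recs)) stop("no correlation record could be computed")
  out <- do.call(rbind, recs)
  out$padj <- NA_real_
  fam <- interaction(out$death_type, out$death_time_h, drop = TRUE)
  for (f in levels(fam)) {
    idx <- fam == f
    out$padj[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  out <- out[, c("module", "compound", "death_type", "death_time_h",
                 "r", "p", "padj", "n", "max_eg")]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Select cell-death-associated hit modules (four-part criteria)
#'
#' A (module, compound) pair passes iff the correlation record satisfies
#' `padj < padj_max`, `r > min_r`, and the module's eigengene exceeds
#' `min_eg` in at least one shared data point for that compound. A module
#' is a hit for a death type iff the number of distinct passing
#' DILI-category compounds is strictly greater than `min_dili_compounds`.
#'
#' @param records Correlation records from [correlate_modules_death()].
#' @param compound_categories Named character vector compound -> category
#'   (criterion counts `"DILI"` compounds only).
#' @param death_time Death measurement time point(s) to screen (default 58
#'   h, the late readout; `NULL` = all present).
#' @param padj_max,min_r,min_eg Pair-level thresholds (defaults .1, 0.5,
#'   2).
#' @param min_dili_compounds Strict lower bound on passing DILI compounds
#'   (default 4, i.e. at least 5 must pass).
#' @return A `trait_hits` data frame: one row per (module, death type) hit
#'   with `n_dili_passing` and the supporting compounds;
#'   `attr(, "passing_pairs")` holds all passing (module, compound) pairs.
#' @export
select_hit_modules <- function(records, compound_categories,
                               death_time = 58,
                               padj_max = 0.1, min_r = 0.5, min_eg = 2,
                               min_dili_compounds = 4) {
  if (!is.null(death_time)) {
    records <- records[records$death_time_h %in% death_time, , drop = FALSE]
  }
  pass <- records[!is.na(records$padj) & records$padj < padj_max &
                    records$r > min_r & records$max_eg > min_eg, , drop = FALSE]
  pass$is_dili <- compound_categories[pass$compound] == "DILI"
  hits <- list()
  if (nrow(pass)) {
    key <- interaction(pass$module, pass$death_type, drop = TRUE)
    for (d in split(pass, key)) {
      dili_cpds <- unique(d$compound[d$is_dili])
      if (length(dili_cpds) > min_dili_compounds) {
        hits[[length(hits) + 1L]] <- data.frame(
          module = d$module[1], death_type = d$death_type[1],
          n_dili_passing = length(dili_cpds),
          compounds = paste(sort(dili_cpds), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(module = character(0), death_type = character(0),
               n_dili_passing = integer(0), compounds = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$module, out$death_type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_hits", "data.frame")
  attr(out, "passing_pairs") <- pass
  out
}

#' Select candidate genes within hit modules
#'
#' A gene is a candidate iff it belongs to a hit module and is strongly
#' upregulated somewhere: some condition with `padj < padj_max` and
#' `log2FC > min_lfc` (strict; defaults .1 and 2).
#'
#' @param hits A `trait_hits` data frame (or character vector of module
#'   ids `"M<k>"`).
#' @param assignment Named integer vector gene -> module.
#' @param lfc The [logfc_matrix()] the modules were built from.
#' @param padj_max,min_lfc Selection thresholds.
#' @return Data frame `gene`, `module`, `max_lfc`, `min_padj` (empty if no
#'   gene qualifies).
#' @export
select_candidate_genes <- function(hits, assignment, lfc,
                                   padj_max = 0.1, min_lfc = 2) {
  mods <- if (is.character(hits)) unique(hits) else unique(hits$module)
  empty <- data.frame(gene = character(0), module = character(0),
                      max_lfc = numeric(0), min_padj = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(mods)) return(empty)
  mod_ids <- as.integer(sub("^M", "", mods))
  genes <- names(assignment)[assignment %in% mod_ids]
  genes <- intersect(genes, colnames(lfc$values))
  if (!length(genes)) return(empty)
  qual <- lfc$padj[, genes, drop = FALSE] < padj_max &
    lfc$values[, genes, drop = FALSE] > min_lfc
  sel <- genes[colSums(qual, na.rm = TRUE) > 0]
  if (!length(sel)) return(empty)
  out <- data.frame(
    gene = sel,
    module = paste0("M", assignment[sel]),
    max_lfc = apply(lfc$values[, sel, drop = FALSE], 2, max, na.rm = TRUE),
    min_padj = apply(lfc$padj[, sel, drop = FALSE], 2, min, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$module, out$gene), ]
}
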