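#' Remove samples with low library size
#'
#' Excludes samples whose total raw count (library size) is strictly lower
#' than `min_total`; the default reproduces the 500,000-read cut used for
#' targeted RNA-seq sample QC.
#'
#' @param counts A [count_matrix()].
#' @param min_total Minimum library size to retain a sample (default 5e5).
#' @return The filtered `count_matrix`; `attr(, "removed")` is a data frame
#'   of excluded samples with their totals.
#' @export
filter_library_size <- function(counts, min_total = 5e5) {
  stopifnot(min_total > 0)
  totals <- colSums(counts$values)
  keep <- totals >= min_total
  if (!any(keep)) {
    stop("library-size filter removed every sample (threshold ", min_total, ")")
  }
  out <- count_matrix(counts$values[, keep, drop = FALSE], counts$design)
  attr(out, "removed") <- data.frame(
    sample_id = colnames(counts$values)[!keep],
    library_size = unname(totals[!keep]),
    reason = rep("library_size", sum(!keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- attr(counts, "truth")
  out
}

#' Counts-per-million normalization
#'
#' Scales each sample's counts to a library size of one million. Every
#' retained column must have a positive total (run [filter_library_size()]
#' first).
#'
#' @param counts A [count_matrix()] or plain counts matrix.
#' @return Numeric matrix of CPM values, same dimnames as the input; every
#'   column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  values <- if (inherits(counts, "count_matrix")) counts$values else counts
  totals <- colSums(values)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(head(colnames(values)[totals <= 0], 5), collapse = ", "),
         " -- remove them with filter_library_size() first")
  }
  sweep(values, 2, totals, "/") * 1e6
}

#' Remove replicates that decorrelate from their condition mean
#'
#' For each replicate group (compound, dose level, time point, batch) with at
#' least two samples, computes each sample's Pearson correlation to the
#' group's mean profile on log2(CPM + 1) over the most variable probes, and
#' removes samples below `min_r` (default 0.95). Groups with a single sample
#' cannot be checked and are passed through with a warning.
#'
#' @param cpm CPM matrix (probes x samples) from [cpm_normalize()].
#' @param design A `study_design` covering the samples.
#' @param min_r Minimum Pearson correlation to the group mean.
#' @param top_n Number of most-variable probes used as the correlation
#'   feature space (all probes if fewer).
#' @param leave_one_out If `TRUE`, the group mean excludes the candidate
#'   sample; the default includes it (correlation "toward the mean of the
#'   same conditions").
#' @return The filtered CPM matrix; `attr(, "removed")` lists removed
#'   samples with their correlation, `attr(, "flagged_conditions")` lists
#'   groups left with fewer than two replicates.
#' @export
filter_replicate_correlation <- function(cpm, design, min_r = 0.95,
                                         top_n = 5000, leave_one_out = FALSE) {
  design <- design[match(colnames(cpm), design$sample_id), , drop = FALSE]
  y <- log2(cpm + 1)
  if (nrow(y) > top_n) {
    vars <- apply(y, 1, var)
    y <- y[order(vars, decreasing = TRUE)[seq_len(top_n)], , drop = FALSE]
  }
  grp <- paste(design$compound, design$dose_level, design$time_h, design$batch, sep = "|")
  removed <- data.frame(sample_id = character(0), r = numeric(0),
                        stringsAsFactors = FALSE)
  singletons <- character(0)
  keep <- rep(TRUE, ncol(cpm))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) {
      singletons <- c(singletons, g)
      next
    }
    for (i in idx) {
      ref_idx <- if (leave_one_out) setdiff(idx, i) else idx
      r <- cor(y[, i], rowMeans(y[, ref_idx, drop = FALSE]))
      if (is.na(r) || r < min_r) {
        keep[i] <- FALSE
        removed <- rbind(removed, data.frame(sample_id = colnames(cpm)[i],
                                             r = r, stringsAsFactors = FALSE))
      }
    }
  }
  if (length(singletons)) {
    warning(length(singletons),
            " condition(s) have a single replicate and cannot be checked")
  }
  if (!any(keep)) stop("replicate-correlation filter removed every sample")
  out <- cpm[, keep, drop = FALSE]
  # Groups that lost replicates below two are flagged for downstream care.
  grp_left <- table(grp[keep])
  flagged <- names(grp_left)[grp_left < 2]
  attr(out, "removed") <- removed
  attr(out, "flagged_conditions") <- union(flagged, singletons)
  out
}

# Vectorized two-sided Welch t-test between two sample groups, per gene.
# Returns p-values; degenerate zero-variance cases: equal means -> p = 1,
# different means -> p = 0.
welch_p <- function(y_treated, y_vehicle) {
  n1 <- ncol(y_treated); n2 <- ncol(y_vehicle)
  m1 <- rowMeans(y_treated); m2 <- rowMeans(y_vehicle)
  v1 <- apply(y_treated, 1, var); v2 <- apply(y_vehicle, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Log2 fold changes against matched vehicle controls
#'
#' For every treated condition (compound, dose level, time point), computes
#' `log2((mean treated CPM + pseudocount) / (mean vehicle CPM +
#' pseudocount))` per probe, where the vehicle samples are the matched
#' controls at the same time point from the same batch(es). Per-probe
#' p-values come from a two-sided Welch t-test on log2(CPM + 1) replicate
#' values, BH-adjusted within each time point across all conditions and
#' probes.
#'
#' @param cpm CPM matrix (probes x samples) after QC filtering.
#' @param design A `study_design` covering the samples.
#' @param pseudocount Pseudocount added inside the log ratio (default 1 CPM).
#' @return A [logfc_matrix()] (conditions x probes) with `padj` and condition
#'   metadata including replicate counts.
#' @export
compute_log2fc <- function(cpm, design, pseudocount = 1) {
  design <- design[match(colnames(cpm), design$sample_id), , drop = FALSE]
  conds <- design_conditions(design)
  is_veh <- design$category == "vehicle"
  y <- log2(cpm + 1)

  values <- matrix(NA_real_, nrow(conds), nrow(cpm),
                   dimnames = list(conds$condition_id, rownames(cpm)))
  pmat <- values
  n_treated <- n_vehicle <- integer(nrow(conds))
  orphans <- character(0)
  for (i in seq_len(nrow(conds))) {
    tr <- which(design$compound == conds$compound[i] &
                  design$dose_level == conds$dose_level[i] &
                  design$time_h == conds$time_h[i])
    veh_cpd <- design$vehicle_of[tr[1]]
    veh <- which(is_veh & design$compound == veh_cpd &
                   design$time_h == conds$time_h[i] &
                   design$batch %in% design$batch[tr])
    if (!length(veh)) {
      orphans <- c(orphans, conds$condition_id[i])
      next
    }
    mt <- rowMeans(cpm[, tr, drop = FALSE])
    mv <- rowMeans(cpm[, veh, drop = FALSE])
    values[i, ] <- log2((mt + pseudocount) / (mv + pseudocount))
    pmat[i, ] <- if (length(tr) >= 2 && length(veh) >= 2) {
      welch_p(y[, tr, drop = FALSE], y[, veh, drop = FALSE])
    } else {
      1   # no replication: uninformative p
    }
    n_treated[i] <- length(tr)
    n_vehicle[i] <- length(veh)
  }
  if (length(orphans)) {
    stop("no matched vehicle control for condition(s): ",
         paste(head(orphans, 10), collapse = ", "))
  }
  padj <- pmat
  for (t in unique(conds$time_h)) {
    rows <- which(conds$time_h == t)
    padj[rows, ] <- matrix(p.adjust(pmat[rows, , drop = FALSE], method = "BH"),
                           nrow = length(rows))
  }
  conds$n_treated <- n_treated
  conds$n_vehicle <- n_vehicle
  logfc_matrix(values, padj, conds)
}

#' Collapse probes to one measurement per gene
#'
#' For genes measured by several probes, keeps the probe whose minimum
#' adjusted p-value across conditions is smallest (the most significant
#' probe). Exact ties are broken by the larger mean raw count when
#' `probe_stats` is supplied, then by probe id (lexicographic), so the
#' result is deterministic.
#'
#' @param lfc A [logfc_matrix()] with probe columns.
#' @param probe_to_gene Named character vector mapping probe id -> gene id;
#'   must cover every probe column.
#' @param probe_stats Optional named numeric vector of per-probe mean raw
#'   counts used as the tie-break.
#' @return A `logfc_matrix` with one column per gene (gene ids as colnames);
#'   `attr(, "probe_used")` records the chosen probe per gene.
#' @export
collapse_probes <- function(lfc, probe_to_gene, probe_stats = NULL) {
  probes <- colnames(lfc$values)
  if (!all(probes %in% names(probe_to_gene))) {
    stop("probe_to_gene must cover every probe of the log2FC matrix")
  }
  gene <- probe_to_gene[probes]
  min_padj <- apply(lfc$padj, 2, min)
  stat <- if (is.null(probe_stats)) setNames(numeric(length(probes)), probes) else probe_stats[probes]
  ord <- order(gene, min_padj, -stat, probes)
  first <- ord[!duplicated(gene[ord])]
  first <- first[order(match(probes[first], probes))]   # preserve input probe order
  out <- logfc_matrix(lfc$values[, first, drop = FALSE],
                      lfc$padj[, first, drop = FALSE],
                      lfc$conditions)
  chosen <- probes[first]
  colnames(out$values) <- colnames(out$padj) <- unname(gene[first])
  attr(out, "probe_used") <- setNames(chosen, gene[first])
  out
}

#' Remove genes with non-meaningful log2FC profiles
#'
#' Drops genes whose profile is mostly missing or (near-)constant across
#' conditions, the standard "good genes" screen before network construction.
#'
#' @param lfc A [logfc_matrix()].
#' @param max_missing_frac Maximum tolerated fraction of missing entries per
#'   gene.
#' @param min_variance Minimum variance across conditions.
#' @return The filtered `logfc_matrix`; `attr(, "removed")` names the
#'   dropped genes.
#' @export
filter_good_genes <- function(lfc, max_missing_frac = 0.5, min_variance = 1e-8) {
  stopifnot(max_missing_frac >= 0, max_missing_frac < 1, min_variance >= 0)
  miss <- colMeans(is.na(lfc$values))
  vars <- apply(lfc$values, 2, var, na.rm = TRUE)
  keep <- miss <= max_missing_frac & !is.na(vars) & vars >= min_variance
  if (!any(keep)) stop("good-genes filter removed every gene")
  out <- logfc_matrix(lfc$values[, keep, drop = FALSE],
                      lfc$padj[, keep, drop = FALSE], lfc$conditions)
  attr(out, "removed") <- colnames(lfc$values)[!keep]
  out
}

#' Call differentially expressed genes per condition
#'
#' A gene is an up-DEG in a condition iff `padj < padj_max` and `log2FC >
#' min_abs_lfc`, and a down-DEG iff `padj < padj_max` and `log2FC <
#' -min_abs_lfc` (strict inequalities; defaults adj-p < .01, |log2FC| > 0.1).
#'
#' @param lfc A [logfc_matrix()].
#' @param padj_max Adjusted p-value threshold.
#' @param min_abs_lfc Absolute log2FC threshold.
#' @return A `deg_table`: data frame of records `condition_id`, `compound`,
#'   `dose_level`, `time_h`, `gene`, `direction` ("up"/"down").
#' @export
call_degs <- function(lfc, padj_max = 0.01, min_abs_lfc = 0.1) {
  stopifnot(padj_max > 0, min_abs_lfc > 0)
  sig <- lfc$padj < padj_max
  up <- which(sig & lfc$values > min_abs_lfc, arr.ind = TRUE)
  down <- which(sig & lfc$values < -min_abs_lfc, arr.ind = TRUE)
  build <- function(idx, dir) {
    if (!nrow(idx)) {
      return(data.frame(condition_id = character(0), gene = character(0),
                        direction = character(0), stringsAsFactors = FALSE))
    }
    data.frame(condition_id = rownames(lfc$values)[idx[, 1]],
               gene = colnames(lfc$values)[idx[, 2]],
               direction = dir, stringsAsFactors = FALSE)
  }
  recs <- rbind(build(up, "up"), build(down, "down"))
  meta <- lfc$conditions[recs$condition_id, c("compound", "dose_level", "time_h")]
  recs <- cbind(recs["condition_id"], meta, recs[c("gene", "direction")])
  rownames(recs) <- NULL
  class(recs) <- c("deg_table", "data.frame")
  recs
}

#' Aggregate unique DEGs per compound and time point
#'
#' Counts, for each compound, time point and direction, the number of unique
#' DEG gene ids pooled over all dose levels (set-union semantics, so a gene
#' differential at several doses counts once).
#'
#' @param degs A `deg_table` from [call_degs()].
#' @return Data frame with columns `compound`, `time_h`, `direction`,
#'   `n_unique_degs`.
#' @export
aggregate_degs <- function(degs) {
  if (!nrow(degs)) {
    return(data.frame(compound = character(0), time_h = numeric(0),
                      direction = character(0), n_unique_degs = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(degs$compound, degs$time_h, degs$direction, drop = TRUE)
  parts <- split(degs, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(compound = d$compound[1], time_h = d$time_h[1],
               direction = d$direction[1],
               n_unique_degs = length(unique(d$gene)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound, out$time_h, out$direction), ]
  rownames(out) <- NULL
  out
}
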