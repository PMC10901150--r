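#' Z-scores of siRNA screen cell-death values
#'
#' `z = (x - mu) / sigma`, where `mu` and `sigma` are the mean and standard
#' deviation of all cell-death values sharing the same (compound, time
#' point, death type) population. By default sigma is the sample SD (n - 1
#' denominator) and control records (mock, scrambled) are part of the
#' population; both choices are configurable. Populations with fewer than
#' two records or zero SD are flagged and their z-scores reported missing.
#'
#' @param table An `rnai_table` (see [generate_rnai_dataset()]): columns
#'   `target`, `is_control`, `compound`, `time_h`, `death_type`,
#'   `replicate`, `value`.
#' @param sd_type `"sample"` (n - 1) or `"population"` (n) denominator.
#' @param include_controls Include control records in mu/sigma.
#' @return The input with a `z` column appended; per-population statistics
#'   in `attr(, "population_stats")` (mu, sigma, n, flagged).
#' @export
zscore_cell_death <- function(table, sd_type = c("sample", "population"),
                              include_controls = TRUE) {
  sd_type <- match.arg(sd_type)
  strat <- interaction(table$compound, table$time_h, table$death_type, drop = TRUE)
  table$z <- NA_real_
  stats <- list()
  for (s in levels(strat)) {
    idx <- which(strat == s)
    pop <- if (include_controls) idx else idx[!table$is_control[idx]]
    v <- table$value[pop]
    n <- length(v)
    mu <- mean(v)
    sigma <- if (n >= 2) {
      if (sd_type == "sample") sd(v) else sqrt(mean((v - mu)^2))
    } else {
      NA_real_
    }
    flagged <- is.na(sigma) || sigma == 0
    if (!flagged) table$z[idx] <- (table$value[idx] - mu) / sigma
    d <- table[idx[1], c("compound", "time_h", "death_type")]
    stats[[length(stats) + 1L]] <- cbind(d, mu = mu, sigma = sigma, n = n,
                                         flagged = flagged)
  }
  attr(table, "population_stats") <- do.call(rbind, stats)
  table
}

#' Log2 fold change of cell death versus the scrambled control
#'
#' Per (target, compound, time, death type):
#' `log2((mean target value + eps) / (mean scrambled value + eps))`, with a
#' small `eps` guarding zero death fractions. A stratum without scrambled
#' control records is an error.
#'
#' @param table An `rnai_table`.
#' @param eps Zero-guard added to both means (default 1e-3).
#' @return Data frame `target`, `compound`, `time_h`, `death_type`,
#'   `log2fc`.
#' @export
log2fc_vs_control <- function(table, eps = 1e-3) {
  strat <- interaction(table$compound, table$time_h, table$death_type, drop = TRUE)
  out <- list()
  for (s in levels(strat)) {
    d <- table[strat == s, , drop = FALSE]
    ctrl <- d$value[d$target == "scrambled"]
    if (!length(ctrl)) {
      stop("no scrambled control in stratum ", s)
    }
    mc <- mean(ctrl)
    for (tg in setdiff(unique(d$target), "scrambled")) {
      mt <- mean(d$value[d$target == tg])
      out[[length(out) + 1L]] <- data.frame(
        target = tg, compound = d$compound[1], time_h = d$time_h[1],
        death_type = d$death_type[1],
        log2fc = log2((mt + eps) / (mc + eps)), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify siRNA targets as protective or enhancing
#'
#' Threshold rule on per-(gene, stratum) mean z-scores: a gene is
#' protective if its mean z is at or below `-z_min` in at least `k` strata
#' (knockdown lowers cell death), enhancing if at or above `+z_min` in at
#' least `k`; a gene meeting both is classed `"none"` with a conflict flag.
#' Controls are excluded. An optional clustering mode (Ward linkage on
#' per-gene log2FC-vs-control profiles, two groups, the controls' side
#' labelled `"none"`) mirrors heatmap-based grouping.
#'
#' @param ztab Output of [zscore_cell_death()].
#' @param z_min Z-score magnitude threshold (default 1).
#' @param k Minimum number of qualifying strata (default 4: with triplicate
#'   wells the per-stratum mean z of a null gene has SD near 0.6, so
#'   demanding four concordant strata of the twelve in a two-compound
#'   screen keeps the null clean while planted effects of 2-3 noise SDs
#'   still qualify in nearly every stratum).
#' @param mode `"threshold"` (default) or `"cluster"`.
#' @return Data frame `target`, `class`, `n_protective_strata`,
#'   `n_enhancing_strata`, `conflict`.
#' @export
classify_rnai_hits <- function(ztab, z_min = 1, k = 4,
                               mode = c("threshold", "cluster")) {
  mode <- match.arg(mode)
  d <- ztab[!ztab$is_control, , drop = FALSE]
  stratum <- interaction(d$compound, d$time_h, d$death_type, drop = TRUE)
  mz <- tapply(d$z, list(factor(d$target), stratum), mean, na.rm = TRUE)
  genes <- rownames(mz)
  n_strata <- rowSums(!is.na(mz))
  if (k > max(n_strata)) {
    warning("k exceeds the number of informative strata for every gene: no hits possible")
  }
  n_prot <- rowSums(mz <= -z_min, na.rm = TRUE)
  n_enh <- rowSums(mz >= z_min, na.rm = TRUE)
  prot <- n_prot >= k
  enh <- n_enh >= k
  cls <- ifelse(prot & !enh, "protective", ifelse(enh & !prot, "enhancing", "none"))

  if (mode == "cluster") {
    lfc <- log2fc_vs_control(ztab)
    prof <- tapply(lfc$log2fc,
                   list(lfc$target,
                        interaction(lfc$compound, lfc$time_h, lfc$death_type)),
                   mean)
    prof <- prof[complete.cases(prof), , drop = FALSE]
    hcw <- hclust(dist(prof), method = "ward.D2")
    grp <- cutree(hcw, k = 2)
    ctrl_grp <- grp["mock"]
    mean_by_grp <- tapply(rowMeans(prof), grp, mean)
    for (g in intersect(genes, names(grp))) {
      if (grp[g] == ctrl_grp) {
        cls[match(g, genes)] <- "none"
      } else {
        cls[match(g, genes)] <- if (mean_by_grp[as.character(grp[g])] <
                                      mean_by_grp[as.character(ctrl_grp)])
          "protective" else "enhancing"
      }
    }
  }

  data.frame(target = genes, class = unname(cls),
             n_protective_strata = as.integer(n_prot),
             n_enhancing_strata = as.integer(n_enh),
             conflict = unname(prot & enh), stringsAsFactors = FALSE)
}
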