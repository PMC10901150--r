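#' Classify module preservation from a Zsummary score
#'
#' Zsummary below 2 is nonpreserved, 2 up to (excluding) 10 moderately
#' preserved, 10 and above highly preserved.
#'
#' @param zsummary Numeric vector of Zsummary scores (finite).
#' @return Character vector in `c("nonpreserved", "moderate", "high")`.
#' @export
classify_preservation <- function(zsummary) {
  if (any(!is.finite(zsummary))) stop("Zsummary must be finite")
  ifelse(zsummary < 2, "nonpreserved", ifelse(zsummary < 10, "moderate", "high"))
}

# Observed preservation statistics of a gene set S: density (mean
# within-set test adjacency) and two connectivity statistics (correlation
# of intramodular connectivity ref vs test; correlation of the vectorized
# within-set gene-gene correlation matrices ref vs test).
preservation_observed <- function(S, ref_cor, test_cor, ref_adj, test_adj) {
  c(mean_adj = mean_offdiag(test_adj[S, S]),
    cor_kIM = cor(rowSums(ref_adj[S, S]) - 1, rowSums(test_adj[S, S]) - 1),
    cor_cor = cor(lower_tri(ref_cor[S, S]), lower_tri(test_cor[S, S])))
}

#' Permutation Zsummary / medianRank module preservation statistics
#'
#' Quantifies whether reference-system modules retain their density and
#' connectivity structure in a test system sharing gene identifiers. Per
#' module, observed statistics (mean within-module test adjacency;
#' correlation of intramodular connectivities ref vs test; correlation of
#' the within-module gene-gene correlation matrices ref vs test) are
#' compared against a null of `n_perm` random same-size gene sets drawn
#' from the shared genes: `Z = (observed - null mean) / null SD`.
#' `Zdensity` is the density Z, `Zconnectivity` the mean of the two
#' connectivity Zs, and `Zsummary = (Zdensity + Zconnectivity) / 2`.
#' `medianRank` is the median, over the three statistics, of the module's
#' observed-value rank (rank 1 = strongest); lower median rank = higher
#' preservation. A statistic whose permutation null has (numerically) zero
#' spread -- e.g. the connectivity correlations when the test data are the
#' reference data themselves -- is uninformative and dropped from the
#' composite for that module. Modules with fewer than `min_shared` shared
#' genes are skipped with a note.
#'
#' @param ref_lfc Reference-system [logfc_matrix()] (or matrix) on which
#'   `ref_assignment` was derived.
#' @param ref_assignment Named integer vector gene -> module of the
#'   reference system.
#' @param test_lfc Test-system [logfc_matrix()] (or matrix) sharing gene
#'   ids.
#' @param beta Soft power for both systems' adjacencies (default 6).
#' @param n_perm Number of permutation draws (default 200; below 50 a
#'   warning is issued).
#' @param seed Integer RNG seed; results are deterministic given the seed.
#' @param min_shared Minimum shared genes for a module to be evaluated
#'   (default 5).
#' @return A `preservation_result` data frame: per module the observed
#'   statistics, `Zdensity`, `Zconnectivity`, `Zsummary`, `medianRank` and
#'   `class`; skipped modules in `attr(, "skipped")`, run parameters in
#'   `attr(, "params")`.
#' @export
preservation_stats <- function(ref_lfc, ref_assignment, test_lfc,
                               beta = 6, n_perm = 200, seed = 1,
                               min_shared = 5) {
  if (n_perm < 50) warning("n_perm below 50: permutation null will be unstable")
  ref_x <- values_of(ref_lfc)
  test_x <- values_of(test_lfc)
  shared <- intersect(colnames(ref_x), colnames(test_x))
  if (length(shared) < 3) stop("fewer than 3 genes shared between systems")
  ref_x <- ref_x[, shared, drop = FALSE]
  test_x <- test_x[, shared, drop = FALSE]

  ref_cor <- cor(ref_x, use = "pairwise.complete.obs")
  test_cor <- cor(test_x, use = "pairwise.complete.obs")
  ref_adj <- abs(ref_cor)^beta; diag(ref_adj) <- 1
  test_adj <- abs(test_cor)^beta; diag(test_adj) <- 1

  mods <- sort(setdiff(unique(ref_assignment), 0L))
  members <- lapply(mods, function(m)
    intersect(names(ref_assignment)[ref_assignment == m], shared))
  eval_ok <- lengths(members) >= min_shared
  skipped <- data.frame(module = paste0("M", mods[!eval_ok], recycle0 = TRUE),
                        n_shared = lengths(members)[!eval_ok],
                        stringsAsFactors = FALSE)
  mods <- mods[eval_ok]; members <- members[eval_ok]
  if (!length(mods)) stop("no module has at least ", min_shared, " shared genes")

  obs <- t(vapply(members, preservation_observed, numeric(3),
                  ref_cor, test_cor, ref_adj, test_adj))

  zmat <- with_seed(seed, {
    out <- matrix(NA_real_, length(mods), 3,
                  dimnames = list(NULL, colnames(obs)))
    for (j in seq_along(mods)) {
      k <- length(members[[j]])
      null <- t(vapply(seq_len(n_perm), function(i) {
        preservation_observed(sample(shared, k), ref_cor, test_cor,
                              ref_adj, test_adj)
      }, numeric(3)))
      mu <- colMeans(null, na.rm = TRUE)
      sdv <- apply(null, 2, sd, na.rm = TRUE)
      z <- (obs[j, ] - mu) / sdv
      # A degenerate null (no spread, e.g. test data identical to the
      # reference so every random set scores cor = 1) makes the statistic
      # uninformative: drop it from the composite rather than divide by ~0.
      z[!is.finite(obs[j, ]) | !is.finite(sdv) | sdv < 1e-12] <- NA_real_
      out[j, ] <- z
    }
    out
  })

  Zdensity <- zmat[, "mean_adj"]
  Zconnectivity <- rowMeans(zmat[, c("cor_kIM", "cor_cor"), drop = FALSE],
                            na.rm = TRUE)
  Zconnectivity[is.nan(Zconnectivity)] <- NA_real_
  Zsummary <- ifelse(is.na(Zconnectivity), Zdensity,
                     ifelse(is.na(Zdensity), Zconnectivity,
                            (Zdensity + Zconnectivity) / 2))
  # Observed-value ranks per statistic: rank 1 = strongest preservation.
  ranks <- apply(-obs, 2, rank, ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  medianRank <- apply(ranks, 1, median)

  res <- data.frame(
    module = paste0("M", mods), n_shared = lengths(members),
    mean_adj = obs[, "mean_adj"], cor_kIM = obs[, "cor_kIM"],
    cor_cor = obs[, "cor_cor"],
    Zdensity = Zdensity, Zconnectivity = Zconnectivity, Zsummary = Zsummary,
    medianRank = medianRank,
    class = classify_preservation(Zsummary),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("preservation_result", "data.frame")
  attr(res, "skipped") <- skipped
  attr(res, "params") <- list(beta = beta, n_perm = n_perm, seed = seed,
                              n_shared_genes = length(shared))
  res
}
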