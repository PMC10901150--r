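# Unsigned weighted co-expression network construction: soft-power
# selection, |cor|^beta adjacency, topological overlap, tree-cut module
# detection, eigengene scoring/merging, corEG/hub genes, and gene-set
# annotation.

values_of <- function(x) if (inherits(x, "logfc_matrix")) x$values else x

# Scale-free topology fit of a connectivity distribution: frequencies over
# `n_bins` equal-width connectivity bins, linear fit of log10 p(k) on
# log10 k, signed R^2 = -sign(slope) * R^2 (power-law plotting convention:
# a decreasing relationship is required).
scale_free_fit <- function(k, n_bins = 10) {
  if (length(k) < n_bins) stop("fewer genes than connectivity bins")
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  k_mean <- tapply(k, bin, mean)
  ok <- !is.na(p_k) & p_k > 0 & k_mean > 0
  if (sum(ok) < 3) return(list(signed_r2 = -Inf, slope = NA_real_))
  fit <- lm(log10(p_k[ok]) ~ log10(k_mean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2]
  list(signed_r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Select the soft-threshold power for approximate scale-free topology
#'
#' Evaluates candidate powers beta on the unsigned adjacency `|cor|^beta`:
#' for each, the connectivity distribution is binned (equal-width bins) and
#' the signed R^2 of the log10 p(k) versus log10 k regression computed.
#' Returns the smallest power reaching `target_r2`; if none does, the
#' argmax power with a warning flag.
#'
#' @param lfc A [logfc_matrix()] or plain conditions x genes matrix (at
#'   least 20 conditions recommended).
#' @param candidates Candidate integer powers (default 1..20).
#' @param target_r2 Signed scale-free fit R^2 to reach (default 0.85).
#' @param n_bins Number of connectivity bins.
#' @return List with `beta`, `fits` (data frame power / signed_r2 /
#'   mean_k), and `reached_target` (logical).
#' @export
pick_soft_power <- function(lfc, candidates = 1:20, target_r2 = 0.85, n_bins = 10) {
  x <- values_of(lfc)
  if (nrow(x) < 20) warning("fewer than 20 conditions: scale-free fit may be unreliable")
  cr <- abs(cor(x, use = "pairwise.complete.obs"))
  fits <- data.frame(power = candidates, signed_r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    a <- cr^candidates[i]
    k <- colSums(a) - 1
    sf <- scale_free_fit(k, n_bins)
    fits$signed_r2[i] <- sf$signed_r2
    fits$mean_k[i] <- mean(k)
  }
  # target_r2 = 0 disables the fit requirement entirely
  pass <- if (target_r2 <= 0) seq_along(candidates) else
    which(fits$signed_r2 >= target_r2)
  if (length(pass)) {
    list(beta = candidates[pass[1]], fits = fits, reached_target = TRUE)
  } else {
    warning("no candidate power reached the scale-free fit target; returning the best fit")
    list(beta = candidates[which.max(fits$signed_r2)], fits = fits,
         reached_target = FALSE)
  }
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` over conditions (unsigned: co-induced and
#' co-repressed genes are equally connected). Pairwise-complete
#' correlations; constant genes are an error (remove them with
#' [filter_good_genes()]).
#'
#' @param lfc A [logfc_matrix()] or conditions x genes matrix.
#' @param beta Soft power (>= 1).
#' @return Symmetric adjacency matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
adjacency_matrix <- function(lfc, beta) {
  stopifnot(beta >= 1)
  x <- values_of(lfc)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stop("constant gene(s): ",
         paste(head(colnames(x)[sds == 0 | is.na(sds)], 5), collapse = ", "))
  }
  a <- abs(cor(x, use = "pairwise.complete.obs"))^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over u outside \{i, j\} and `k_i = sum_{u != i} a_iu`: genes are
#' similar when they share neighbours, not only when directly connected.
#'
#' @param adj Adjacency matrix from [adjacency_matrix()].
#' @return Symmetric TOM matrix, entries in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(adj) {
  k <- colSums(adj) - 1
  cross <- adj %*% adj            # includes u = i and u = j terms
  numer <- cross - adj            # = sum_{u not in {i,j}} a_iu a_uj + a_ij  (diag 1)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- numer / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}

#' Detect modules by tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' height; branches smaller than `min_module_size` fall into module 0
#' (unassigned). When `pam_stage` is enabled (and `lfc` supplied),
#' unassigned genes are re-assigned to the module whose eigengene their
#' profile correlates with best, if that |correlation| reaches
#' `pam_min_cor` -- a hybrid cut that rescues borderline branch members.
#' Module ids are ordered by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size Minimum genes per module (>= 3; default 20).
#' @param cut_height Dendrogram cut height on the 1 - TOM scale (default
#'   0.98).
#' @param pam_stage Re-assign unassigned genes by eigengene correlation.
#' @param pam_min_cor Minimum |cor| to an eigengene for re-assignment.
#' @param lfc The [logfc_matrix()] behind the TOM (needed for the PAM
#'   stage).
#' @return Named integer vector: gene -> module id (0 = unassigned).
#' @export
cluster_modules <- function(tom, min_module_size = 20, cut_height = 0.98,
                            pam_stage = TRUE, pam_min_cor = 0.3, lfc = NULL) {
  stopifnot(min_module_size >= 3)
  genes <- colnames(tom)
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: all genes unassigned")
    return(setNames(integer(n), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  assignment <- integer(n)
  for (m in keep) assignment[raw == m] <- m

  if (pam_stage && !is.null(lfc) && length(keep)) {
    egs <- compute_eigengenes(lfc, setNames(assignment, genes))
    z <- scale(values_of(lfc))
    un <- which(assignment == 0)
    if (length(un)) {
      cc <- abs(cor(z[, un, drop = FALSE], egs$eigengenes))
      best <- max.col(cc, ties.method = "first")
      ok <- cc[cbind(seq_along(un), best)] >= pam_min_cor
      mod_ids <- as.integer(sub("^M", "", colnames(egs$eigengenes)))
      assignment[un[ok]] <- mod_ids[best[ok]]
    }
  }
  # Renumber by decreasing size (ties by first appearance), module 0 kept.
  ids <- setdiff(unique(assignment), 0L)
  if (length(ids)) {
    sz <- sapply(ids, function(m) sum(assignment == m))
    new_id <- setNames(seq_along(ids), ids[order(-sz, seq_along(ids))])
    assignment <- ifelse(assignment == 0L, 0L,
                         new_id[as.character(assignment)])
  }
  setNames(as.integer(assignment), genes)
}

#' Module eigengene scores
#'
#' Per module: z-score each member gene's log2FC profile across conditions,
#' take the first principal component over conditions (first left singular
#' vector), orient its sign so it correlates non-negatively with the
#' module's mean z-scored profile, then normalize the score vector to unit
#' standard deviation across the whole condition set -- the module activity
#' score comparable across modules and treatments.
#'
#' @param lfc A [logfc_matrix()] or conditions x genes matrix.
#' @param assignment Named integer vector gene -> module (0 ignored).
#' @return List with `eigengenes` (conditions x modules matrix, columns
#'   `M<id>`, each column SD 1), `var_explained` (per module), and
#'   `flagged` (single-gene modules, degenerate PCA).
#' @export
compute_eigengenes <- function(lfc, assignment) {
  x <- values_of(lfc)
  z <- scale(x)
  mods <- sort(setdiff(unique(assignment), 0L))
  if (!length(mods)) stop("no modules to compute eigengenes for")
  egs <- matrix(NA_real_, nrow(x), length(mods),
                dimnames = list(rownames(x), paste0("M", mods)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  flagged <- character(0)
  for (j in seq_along(mods)) {
    members <- names(assignment)[assignment == mods[j]]
    zm <- z[, members, drop = FALSE]
    if (length(members) == 1L) {
      eg <- zm[, 1]
      ve[j] <- 1
      flagged <- c(flagged, paste0("M", mods[j]))
    } else {
      sv <- svd(zm, nu = 1, nv = 0)
      eg <- sv$u[, 1]
      ve[j] <- sv$d[1]^2 / sum(sv$d^2)
    }
    mean_profile <- rowMeans(zm)
    s <- cor(eg, mean_profile)
    if (!is.na(s) && s < 0) eg <- -eg
    egs[, j] <- eg / sd(eg)
  }
  list(eigengenes = egs, var_explained = ve, flagged = flagged)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively: compute eigengenes, chain together (single linkage) module
#' groups whose eigengene Pearson correlation reaches `merge_threshold`
#' (signed by default; set `use_abs` for absolute), union their gene sets,
#' recompute -- until no pair correlates at or above the threshold. Module 0
#' never merges.
#'
#' @param lfc A [logfc_matrix()] or conditions x genes matrix.
#' @param assignment Named integer vector gene -> module.
#' @param merge_threshold Eigengene correlation at or above which modules
#'   merge (default 0.8).
#' @param use_abs Merge on |cor| instead of signed correlation.
#' @param max_iter Safety bound on merge iterations.
#' @return List with the merged `assignment` (renumbered by decreasing
#'   size), final `eigengenes`, `var_explained`, and `n_iter`.
#' @export
merge_modules <- function(lfc, assignment, merge_threshold = 0.8,
                          use_abs = FALSE, max_iter = 50) {
  stopifnot(merge_threshold > 0, merge_threshold <= 1)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eg <- compute_eigengenes(lfc, assignment)
    if (ncol(eg$eigengenes) == 1L) { converged <- TRUE; break }
    cc <- cor(eg$eigengenes)
    if (use_abs) cc <- abs(cc)
    link <- cc >= merge_threshold
    diag(link) <- FALSE
    if (!any(link)) { converged <- TRUE; break }
    comp <- connected_components(link | t(link))
    mod_ids <- as.integer(sub("^M", "", colnames(eg$eigengenes)))
    # map each old id to the representative (smallest id) of its component
    reps <- tapply(mod_ids, comp, min)
    new_of <- setNames(as.integer(reps[as.character(comp)]), mod_ids)
    changed <- assignment != 0L
    assignment[changed] <- new_of[as.character(assignment[changed])]
  }
  if (!converged) stop("module merging did not converge in ", max_iter, " iterations")
  # Renumber by decreasing size.
  ids <- setdiff(unique(assignment), 0L)
  sz <- sapply(ids, function(m) sum(assignment == m))
  new_id <- setNames(seq_along(ids), ids[order(-sz, seq_along(ids))])
  assignment[assignment != 0L] <- new_id[as.character(assignment[assignment != 0L])]
  assignment <- setNames(as.integer(assignment), names(assignment))
  eg <- compute_eigengenes(lfc, assignment)
  list(assignment = assignment, eigengenes = eg$eigengenes,
       var_explained = eg$var_explained, n_iter = iter)
}

#' Gene-eigengene correlation (corEG) and hub genes
#'
#' `corEG(g)` is the Pearson correlation between gene g's log2FC profile and
#' the eigengene of its parent module; the hub gene of a module is the
#' member maximizing corEG (ties broken by gene id, lexicographic).
#'
#' @param lfc A [logfc_matrix()] or conditions x genes matrix.
#' @param assignment Named integer vector gene -> module.
#' @param eigengenes Conditions x modules matrix from
#'   [compute_eigengenes()].
#' @return List with `corEG` (named numeric over assigned genes) and `hub`
#'   (named character, module -> gene).
#' @export
compute_coreg_hub <- function(lfc, assignment, eigengenes) {
  x <- values_of(lfc)
  mods <- sort(setdiff(unique(assignment), 0L))
  corEG <- setNames(rep(NA_real_, sum(assignment != 0L)),
                    names(assignment)[assignment != 0L])
  hub <- setNames(character(length(mods)), paste0("M", mods))
  for (m in mods) {
    members <- names(assignment)[assignment == m]
    cc <- as.vector(cor(x[, members, drop = FALSE], eigengenes[, paste0("M", m)]))
    corEG[members] <- cc
    ord <- order(-cc, members)
    hub[paste0("M", m)] <- members[ord[1]]
  }
  list(corEG = corEG, hub = hub)
}

#' Full unsigned co-expression module pipeline
#'
#' Orchestrates soft-power selection (unless `beta` is given), adjacency,
#' TOM, tree-cut module detection, eigengene merging, and corEG/hub
#' computation into a `module_set`.
#'
#' @param lfc A [logfc_matrix()] (post [filter_good_genes()]).
#' @param beta Soft power, or `"auto"` to select by scale-free fit.
#' @param min_module_size,cut_height,pam_stage,pam_min_cor Passed to
#'   [cluster_modules()].
#' @param merge_threshold Passed to [merge_modules()].
#' @param target_r2 Scale-free fit target for automatic power selection.
#' @return A `module_set`: list with `assignment`, `eigengenes`,
#'   `var_explained`, `corEG`, `hub`, `sizes`, `beta`, `conditions`,
#'   `power_fit` and (once annotated) `annotation`.
#' @export
wgcna_modules <- function(lfc, beta = "auto", min_module_size = 20,
                          cut_height = 0.98, pam_stage = TRUE,
                          pam_min_cor = 0.3, merge_threshold = 0.8,
                          target_r2 = 0.85) {
  power_fit <- NULL
  if (identical(beta, "auto")) {
    power_fit <- pick_soft_power(lfc, target_r2 = target_r2)
    beta <- power_fit$beta
  }
  adj <- adjacency_matrix(lfc, beta)
  tom <- tom_similarity(adj)
  assignment <- cluster_modules(tom, min_module_size = min_module_size,
                                cut_height = cut_height, pam_stage = pam_stage,
                                pam_min_cor = pam_min_cor, lfc = lfc)
  if (all(assignment == 0L)) {
    warning("no modules detected")
    return(structure(list(assignment = assignment, eigengenes = NULL,
                          var_explained = NULL, corEG = NULL, hub = NULL,
                          sizes = integer(0), beta = beta,
                          conditions = if (inherits(lfc, "logfc_matrix")) lfc$conditions else NULL,
                          power_fit = power_fit, annotation = NULL),
                     class = "module_set"))
  }
  merged <- merge_modules(lfc, assignment, merge_threshold = merge_threshold)
  ch <- compute_coreg_hub(lfc, merged$assignment, merged$eigengenes)
  sizes <- table(merged$assignment[merged$assignment != 0L])
  obj <- list(assignment = merged$assignment,
              eigengenes = merged$eigengenes,
              var_explained = merged$var_explained,
              corEG = ch$corEG, hub = ch$hub,
              sizes = setNames(as.integer(sizes), paste0("M", names(sizes))),
              beta = beta,
              conditions = if (inherits(lfc, "logfc_matrix")) lfc$conditions else NULL,
              power_fit = power_fit, annotation = NULL)
  class(obj) <- "module_set"
  obj
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules over %d genes (%d unassigned), beta = %s\n",
              length(x$sizes), length(x$assignment),
              sum(x$assignment == 0L), format(x$beta)))
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: set id, description, then member gene
#' ids. Lines with fewer than three fields and duplicated set ids are
#' errors (with line numbers).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(head(short, 5), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Annotate modules by gene-set over-representation
#'
#' Per (module, gene set): hypergeometric upper-tail p-value of the overlap
#' within `universe`, BH-adjusted across all pairs; each module is labelled
#' with its minimum-adjusted-p set (no label if no set overlaps).
#'
#' @param module_set A `module_set` (or a named assignment vector).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of all genes considered; must contain
#'   every module gene.
#' @return List with `pairs` (all tested module x set records: overlap, p,
#'   padj) and `annotation` (one row per module: best set, its padj, or NA).
#' @export
enrich_modules <- function(module_set, gene_sets, universe) {
  assignment <- if (inherits(module_set, "module_set")) module_set$assignment else module_set
  mods <- sort(setdiff(unique(assignment), 0L))
  if (!length(gene_sets)) {
    warning("empty gene-set collection: all annotations missing")
    return(list(pairs = data.frame(),
                annotation = data.frame(module = paste0("M", mods),
                                        set_id = NA_character_, padj = NA_real_,
                                        stringsAsFactors = FALSE)))
  }
  if (!all(names(assignment)[assignment != 0L] %in% universe)) {
    stop("universe must contain every module gene")
  }
  N <- length(unique(universe))
  sets <- lapply(gene_sets, intersect, universe)
  pairs <- do.call(rbind, lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    n <- length(members)
    ov <- vapply(sets, function(s) length(intersect(s, members)), 0L)
    K <- lengths(sets)
    p <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(module = paste0("M", m), set_id = names(sets),
               overlap = ov, set_size = K, module_size = n, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  pairs$padj <- p.adjust(pairs$p, method = "BH")
  annotation <- do.call(rbind, lapply(split(pairs, pairs$module), function(d) {
    d <- d[d$overlap > 0, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(module = NA_character_, set_id = NA_character_,
                        padj = NA_real_, stringsAsFactors = FALSE))
    }
    d <- d[order(d$padj, d$set_id), ]
    data.frame(module = d$module[1], set_id = d$set_id[1], padj = d$padj[1],
               stringsAsFactors = FALSE)
  }))
  miss <- is.na(annotation$module)
  annotation$module[miss] <- rownames(annotation)[miss]
  rownames(annotation) <- NULL
  annotation <- annotation[match(paste0("M", mods), annotation$module), ]
  rownames(annotation) <- NULL
  list(pairs = pairs, annotation = annotation)
}
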