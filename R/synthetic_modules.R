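#' Specify planted co-expression modules for the synthetic generator
#'
#' Defines the ground truth for synthetic transcriptomic data: which genes
#' belong to which module, each gene's loading on its module, and each
#' module's activation over the (compound, dose level, time point) grid. The
#' activation is a Hill function of dose level (per-module EC50 and slope)
#' scaled by a per-module time-profile multiplier and a per-compound effect
#' direction, so modules show the saturating dose-response and time
#' dependence typical of stress-pathway transcriptional programs.
#'
#' @param design A `study_design` whose compounds the activation functions
#'   refer to.
#' @param n_genes Total number of genes (module genes + background).
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module, recycled to `n_modules`; sizes must
#'   sum to at most `n_genes`.
#' @param amplitude Maximal module activation on the log2FC scale.
#' @param noise_sd Residual log2FC noise standard deviation.
#' @param prob_active Probability that a module responds to a given compound
#'   (ignored for modules with explicit `compound_effects`).
#' @param mixed_sign_frac Fraction of module 1's genes given negative
#'   loadings, so at least one module contains anti-correlated members (the
#'   case unsigned networks must handle).
#' @param compound_effects Optional list (length `n_modules`) of named
#'   numeric vectors in \[-1, 1\]: per-module, per-compound effect
#'   directions/scales overriding the random draw. Names must be compounds of
#'   `design`.
#' @param ec50_range,hill_range Ranges for the per-module dose-response EC50
#'   (in dose-level units) and Hill slope.
#' @param baseline_mean,baseline_sd Parameters of the per-gene baseline
#'   log2-expression distribution used by [generate_counts()].
#' @param module_baseline_offset,module_baseline_sd Module genes' baseline
#'   log2 expression is drawn from `N(baseline_mean + module_baseline_offset,
#'   module_baseline_sd)`: inducible stress-program genes sit low at rest,
#'   which also keeps the library composition (and hence CPM ratios) stable
#'   when modules activate.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene negative-binomial dispersion used by [generate_counts()].
#' @param seed Integer RNG seed.
#'
#' @return A `module_spec` object: list with `gene_ids`, `assignment`
#'   (0 = background), `loadings` (signed, magnitude in \[0.3, 1\]),
#'   `modules` (per-module activation parameters), `amplitude`, `noise_sd`,
#'   `baseline`, `dispersion`, and the `design`.
#' @export
module_spec <- function(design,
                        n_genes = 2000,
                        n_modules = 8,
                        module_size = 60,
                        amplitude = 4,
                        noise_sd = 0.3,
                        prob_active = 0.5,
                        mixed_sign_frac = 0.3,
                        compound_effects = NULL,
                        ec50_range = c(1.5, 4),
                        hill_range = c(1, 3),
                        baseline_mean = 4,
                        baseline_sd = 2,
                        module_baseline_offset = -4,
                        module_baseline_sd = 1,
                        dispersion_meanlog = log(0.02),
                        dispersion_sdlog = 0.5,
                        seed = 1) {
  sizes <- rep_len(module_size, n_modules)
  if (n_modules > 0 && sum(sizes) > n_genes) {
    stop("module sizes sum to more than n_genes")
  }
  compounds <- unique(design$compound[design$category != "vehicle"])
  if (!is.null(compound_effects)) {
    if (length(compound_effects) != n_modules) {
      stop("compound_effects must have one entry per module")
    }
    bad <- setdiff(unlist(lapply(compound_effects, names)), compounds)
    if (length(bad)) {
      stop("compound_effects reference compounds absent from the design: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  time_points <- sort(unique(design$time_h))

  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    assignment <- integer(n_genes)
    loadings <- numeric(n_genes)
    names(assignment) <- names(loadings) <- gene_ids

    pos <- 1L
    modules <- vector("list", n_modules)
    for (m in seq_len(n_modules)) {
      idx <- seq.int(pos, length.out = sizes[m])
      pos <- pos + sizes[m]
      assignment[idx] <- m
      l <- runif(sizes[m], 0.3, 1)
      if (m == 1L && mixed_sign_frac > 0) {
        nneg <- floor(mixed_sign_frac * sizes[m])
        if (nneg > 0) l[seq_len(nneg)] <- -l[seq_len(nneg)]
      }
      loadings[idx] <- l

      if (!is.null(compound_effects)) {
        eff <- setNames(numeric(length(compounds)), compounds)
        eff[names(compound_effects[[m]])] <- compound_effects[[m]]
      } else {
        active <- runif(length(compounds)) < prob_active
        if (!any(active)) active[sample(length(compounds), 1L)] <- TRUE
        eff <- setNames(ifelse(active, sample(c(1, -1), length(compounds),
                                              replace = TRUE, prob = c(0.8, 0.2)), 0),
                        compounds)
      }
      tm <- runif(length(time_points), 0.3, 1)
      tm[which.max(tm)] <- 1   # each module reaches full amplitude at some time
      modules[[m]] <- list(
        module = m,
        compound_effect = eff,
        ec50 = runif(1, ec50_range[1], ec50_range[2]),
        hill = runif(1, hill_range[1], hill_range[2]),
        time_mult = setNames(tm, as.character(time_points))
      )
    }

    baseline <- pmax(rnorm(n_genes, baseline_mean, baseline_sd), 0)
    in_module <- assignment > 0
    baseline[in_module] <- pmax(rnorm(sum(in_module),
                                      baseline_mean + module_baseline_offset,
                                      module_baseline_sd), 0)
    spec <- list(
      gene_ids = gene_ids,
      assignment = assignment,
      loadings = loadings,
      modules = modules,
      n_genes = n_genes,
      n_modules = n_modules,
      amplitude = amplitude,
      noise_sd = noise_sd,
      baseline = setNames(baseline, gene_ids),
      dispersion = setNames(rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog), gene_ids),
      design = design
    )
    class(spec) <- "module_spec"
    spec
  })
}

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf("module_spec: %d genes, %d planted modules (sizes %s), amplitude %.3g, noise sd %.3g\n",
              x$n_genes, x$n_modules,
              paste(tabulate(x$assignment, x$n_modules), collapse = "/"),
              x$amplitude, x$noise_sd))
  invisible(x)
}

#' True module activation over a set of conditions
#'
#' Evaluates each planted module's activation function on a grid of
#' (compound, dose level, time point) conditions: per-compound effect x Hill
#' dose response x time multiplier x amplitude. Compounds without an effect
#' entry (e.g. vehicles) score 0.
#'
#' @param spec A `module_spec`.
#' @param conditions Data frame with columns `compound`, `dose_level`,
#'   `time_h` (e.g. from [design_conditions()]).
#' @return Numeric matrix, `nrow(conditions)` x `n_modules`, columns named
#'   `M1..Mk`; rownames taken from `conditions$condition_id` when present.
#' @export
module_activation <- function(spec, conditions) {
  n <- nrow(conditions)
  act <- matrix(0, n, spec$n_modules,
                dimnames = list(conditions$condition_id %||% NULL,
                                paste0("M", seq_len(spec$n_modules), recycle0 = TRUE)))
  for (m in seq_len(spec$n_modules)) {
    mod <- spec$modules[[m]]
    eff <- mod$compound_effect[conditions$compound]
    eff[is.na(eff)] <- 0
    d <- conditions$dose_level
    hillv <- ifelse(d > 0, d^mod$hill / (mod$ec50^mod$hill + d^mod$hill), 0)
    tmult <- mod$time_mult[as.character(conditions$time_h)]
    tmult[is.na(tmult)] <- 1
    act[, m] <- spec$amplitude * eff * hillv * tmult
  }
  act
}

# Synthetic adjusted p-values for directly generated log2FC values: residual
# noise is Gaussian by construction, so the two-sided normal tail is the
# exact per-entry p-value; BH within each time point mirrors the count-based
# pipeline's adjustment family.
synthetic_padj <- function(values, noise_sd, time_h) {
  p <- 2 * pnorm(-abs(values) / noise_sd)
  padj <- p
  for (t in unique(time_h)) {
    rows <- which(time_h == t)
    padj[rows, ] <- matrix(p.adjust(p[rows, , drop = FALSE], method = "BH"),
                           nrow = length(rows))
  }
  padj
}

#' Generate a condition x gene log2FC matrix with planted modules
#'
#' Directly simulates the log2 fold-change matrix the network stage consumes:
#' for a gene g in module m, `logfc = loading_g * activation_m(condition) +
#' N(0, noise_sd)`; background genes are pure noise. Adjusted p-values are
#' exact two-sided Gaussian tails BH-corrected within each time point (the
#' residual noise is Gaussian by construction).
#'
#' @param design A `study_design`.
#' @param spec A `module_spec` built on the same design.
#' @param seed Integer RNG seed.
#' @return A [logfc_matrix()] over the treated conditions of `design`, with
#'   the planted `assignment` and activation matrix attached as
#'   `attr(, "truth")`.
#' @export
generate_logfc <- function(design, spec, seed = 1) {
  conds <- design_conditions(design)
  act <- module_activation(spec, conds)
  with_seed(seed, {
    values <- matrix(rnorm(nrow(conds) * spec$n_genes, 0, spec$noise_sd),
                     nrow(conds), spec$n_genes,
                     dimnames = list(conds$condition_id, spec$gene_ids))
    for (m in seq_len(spec$n_modules)) {
      g <- which(spec$assignment == m)
      if (length(g)) {
        values[, g] <- values[, g] + act[, m] %o% spec$loadings[g]
      }
    }
    padj <- synthetic_padj(values, spec$noise_sd, conds$time_h)
    dimnames(padj) <- dimnames(values)
    out <- logfc_matrix(values, padj, conds)
    attr(out, "truth") <- list(assignment = spec$assignment, activation = act)
    out
  })
}

#' Generate negative-binomial counts with planted modules and QC defects
#'
#' Simulates probe-level counts of a targeted RNA-seq screen: per-gene
#' baseline log2 expression, module activation shifting the log2 mean of
#' member genes by `loading x activation`, gene-specific negative-binomial
#' dispersion, and per-sample library sizes drawn from `library_size_range`.
#' A `qc_defect_rate` fraction of samples is deliberately corrupted to
#' exercise the QC filters: half get a library size below 500,000 reads
#' ("low_lib"), half have their gene profile scrambled so they decorrelate
#' from their replicates ("decorrelated"). At most one sample per replicate
#' group is corrupted, so the QC oracle is exact.
#'
#' @param design A `study_design`.
#' @param spec A `module_spec` built on a design containing the same
#'   compounds.
#' @param library_size_range Length-2 positive vector of target library
#'   sizes for intact samples.
#' @param qc_defect_rate Fraction of samples to corrupt, in \[0, 1).
#' @param seed Integer RNG seed.
#' @return A [count_matrix()]; `attr(, "truth")` records the corrupted
#'   samples (`sample_id`, `mode`), the gene-module `assignment` and the
#'   condition activation matrix.
#' @export
generate_counts <- function(design, spec,
                            library_size_range = c(8e5, 3e6),
                            qc_defect_rate = 0,
                            seed = 1) {
  if (any(library_size_range <= 0)) stop("library sizes must be positive")
  if (qc_defect_rate < 0 || qc_defect_rate >= 1) stop("qc_defect_rate must be in [0, 1)")
  spec_compounds <- unique(design$compound[design$category != "vehicle"])
  eff_compounds <- unique(unlist(lapply(spec$modules, function(m)
    names(m$compound_effect)[m$compound_effect != 0])))
  unknown <- setdiff(eff_compounds, spec_compounds)
  if (length(unknown)) {
    stop("module activation functions reference compounds unknown to the design: ",
         paste(unknown, collapse = ", "))
  }

  n_samp <- nrow(design)
  act_samp <- module_activation(spec, design)   # vehicles score 0

  with_seed(seed, {
    lib <- runif(n_samp, library_size_range[1], library_size_range[2])

    # Choose corrupted samples so that no two share a replicate group;
    # otherwise a surviving replicate's correlation to its group mean could
    # be dragged down and the QC oracle would no longer be exact.
    n_bad <- round(qc_defect_rate * n_samp)
    grp <- paste(design$compound, design$dose_level, design$time_h, design$batch, sep = "|")
    bad_idx <- integer(0)
    if (n_bad > 0) {
      cand <- sample(n_samp)
      taken <- character(0)
      for (i in cand) {
        if (length(bad_idx) >= n_bad) break
        if (!(grp[i] %in% taken)) {
          bad_idx <- c(bad_idx, i)
          taken <- c(taken, grp[i])
        }
      }
      if (length(bad_idx) < n_bad) {
        stop("cannot corrupt ", n_bad, " samples without touching a replicate group twice")
      }
    }
    mode <- rep(c("low_lib", "decorrelated"), length.out = length(bad_idx))
    lib[bad_idx[mode == "low_lib"]] <- runif(sum(mode == "low_lib"), 1e5, 4e5)

    size <- 1 / spec$dispersion
    b <- spec$baseline
    draw_sample <- function(s, decorrelated) {
      if (decorrelated) {
        # Partial profile scramble: correlation to the true baseline drops
        # to ~0.75, enough to fail the 0.95 replicate filter without
        # dragging the replicate-group mean down with it.
        rho <- 0.75
        bp <- sample(b)
        mu_log2 <- mean(b) + rho * (b - mean(b)) + sqrt(1 - rho^2) * (bp - mean(b))
      } else if (spec$n_modules > 0) {
        shift <- numeric(spec$n_genes)
        assigned <- spec$assignment > 0
        shift[assigned] <- spec$loadings[assigned] * act_samp[s, spec$assignment[assigned]]
        mu_log2 <- b + shift
      } else {
        mu_log2 <- b
      }
      rel <- 2^mu_log2
      mu <- lib[s] * rel / sum(rel)
      rnbinom(spec$n_genes, mu = mu, size = size)
    }

    counts <- matrix(0L, spec$n_genes, n_samp,
                     dimnames = list(spec$gene_ids, design$sample_id))
    for (s in seq_len(n_samp)) {
      counts[, s] <- draw_sample(s, s %in% bad_idx[mode == "decorrelated"])
    }

    # Post-hoc verification of the corruption contract: under the default
    # QC settings, exactly the low_lib samples fail the library-size filter
    # and exactly the decorrelated samples fail the replicate filter.
    # Borderline draws are redrawn (still deterministic given the seed).
    if (length(bad_idx)) {
      for (attempt in seq_len(20)) {
        cm <- count_matrix(counts, design)
        c1 <- filter_library_size(cm)
        lib_removed <- attr(c1, "removed")$sample_id
        cpm <- cpm_normalize(c1)
        cpm2 <- suppressWarnings(
          filter_replicate_correlation(cpm, c1$design))
        rep_removed <- attr(cpm2, "removed")$sample_id
        want_lib <- sort(design$sample_id[bad_idx[mode == "low_lib"]])
        want_rep <- sort(design$sample_id[bad_idx[mode == "decorrelated"]])
        if (identical(sort(lib_removed), want_lib) &&
            identical(sort(rep_removed), want_rep)) break
        if (attempt == 20) {
          stop("could not realise the requested QC defects cleanly after 20 draws")
        }
        redo <- union(bad_idx,
                      match(union(lib_removed, rep_removed), design$sample_id))
        for (s in redo) {
          counts[, s] <- draw_sample(s, s %in% bad_idx[mode == "decorrelated"])
        }
      }
    }

    out <- count_matrix(counts, design)
    attr(out, "truth") <- list(
      corrupted = data.frame(sample_id = design$sample_id[bad_idx],
                             mode = mode, stringsAsFactors = FALSE),
      assignment = spec$assignment,
      activation = module_activation(spec, design_conditions(design))
    )
    out
  })
}

#' Generate a second-system log2FC matrix with a preserved module subset
#'
#' Emulates a reference test system (e.g. primary hepatocytes profiled under
#' an independent condition set) sharing gene identifiers with the source
#' system. Conditions are resampled from the source activation grid.
#' Preserved modules keep their co-expression structure (loadings shared,
#' amplitude optionally attenuated); non-preserved modules are scrambled:
#' each member gene receives an independently resampled activation profile,
#' so within-module correlation collapses to background.
#'
#' @param spec A `module_spec` (carries the source design).
#' @param preserved_module_ids Integer ids of modules whose structure is
#'   retained; must be a subset of the spec's modules.
#' @param n_conditions Number of synthetic test-system conditions. Below 10
#'   a warning is issued (permutation preservation statistics are unstable).
#' @param seed Integer RNG seed.
#' @param attenuation Multiplier in (0, 1\] applied to preserved modules'
#'   activation amplitude.
#' @return A [logfc_matrix()] with conditions `REF_001..`; `attr(, "truth")`
#'   records the preserved set.
#' @export
generate_reference_logfc <- function(spec, preserved_module_ids,
                                     n_conditions = 60, seed = 1,
                                     attenuation = 1) {
  preserved_module_ids <- as.integer(preserved_module_ids)
  if (length(setdiff(preserved_module_ids, seq_len(spec$n_modules)))) {
    stop("preserved_module_ids must be a subset of the spec's module ids")
  }
  if (n_conditions < 10) {
    warning("fewer than 10 test-system conditions: preservation statistics will be unstable")
  }
  conds_src <- design_conditions(spec$design)
  act_src <- module_activation(spec, conds_src)

  with_seed(seed, {
    idx <- sample(nrow(act_src), n_conditions, replace = TRUE)
    cond_id <- sprintf("REF_%03d", seq_len(n_conditions))
    values <- matrix(rnorm(n_conditions * spec$n_genes, 0, spec$noise_sd),
                     n_conditions, spec$n_genes,
                     dimnames = list(cond_id, spec$gene_ids))
    for (m in seq_len(spec$n_modules)) {
      g <- which(spec$assignment == m)
      if (!length(g)) next
      if (m %in% preserved_module_ids) {
        values[, g] <- values[, g] +
          attenuation * act_src[idx, m] %o% spec$loadings[g]
      } else {
        for (j in g) {   # independent resample per gene: structure destroyed
          values[, j] <- values[, j] +
            spec$loadings[j] * act_src[sample(nrow(act_src), n_conditions, replace = TRUE), m]
        }
      }
    }
    conds <- data.frame(condition_id = cond_id, compound = "REF",
                        dose_level = NA_integer_, concentration = NA_real_,
                        time_h = NA_real_, row.names = cond_id,
                        stringsAsFactors = FALSE)
    padj <- matrix(p.adjust(2 * pnorm(-abs(values) / spec$noise_sd), "BH"),
                   n_conditions, spec$n_genes, dimnames = dimnames(values))
    out <- logfc_matrix(values, padj, conds)
    attr(out, "truth") <- list(preserved = preserved_module_ids)
    out
  })
}
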