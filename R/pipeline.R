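# One-call orchestration of the full analysis over a simulated study, with
# TSV/JSON artifacts and a run manifest.

#' Pipeline parameter defaults
#'
#' Central table of every stage default. The QC, DEG, network, preservation,
#' trait and gene-selection thresholds default to the values the analysis
#' protocol fixes (500,000-read library floor; 0.95 replicate correlation;
#' DEG adj-p < .01 and |log2FC| > 0.1; soft power selected by scale-free fit
#' with 9 as the documented full-scale reference value; eigengene merge at
#' 0.8; preservation classes at Zsummary 2 and 10; trait criteria adj-p
#' < .1, r > 0.5, eigengene > 2, more than 4 DILI compounds; candidate genes
#' at adj-p < .1 and log2FC > 2).
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    min_library_size = 5e5,
    min_replicate_r = 0.95,
    replicate_top_n = 5000,
    pseudocount = 1,
    deg_padj_max = 0.01,
    deg_min_abs_lfc = 0.1,
    beta = "auto",
    beta_reference = 9,
    min_module_size = 20,
    cut_height = 0.98,
    merge_threshold = 0.8,
    target_r2 = 0.85,
    preservation_moderate = 2,
    preservation_high = 10,
    n_perm = 200,
    trait_padj_max = 0.1,
    trait_min_r = 0.5,
    trait_min_eg = 2,
    trait_min_dili_compounds = 4,
    trait_death_time = 58,
    gene_padj_max = 0.1,
    gene_min_lfc = 2,
    rnai_z_min = 1,
    rnai_k = 4
  )
}

#' Run the full pipeline on a simulated study
#'
#' Executes the enabled stages in order -- simulate, qc, network, preserve,
#' trait, rnai -- each consuming the previous stage's outputs, writing
#' plain-text artifacts under `config$out` and a JSON manifest recording
#' parameters, seed and file checksums. Reruns with the same config and
#' seed reproduce identical artifacts.
#'
#' @param config A list, or path to a YAML file, with elements `out`
#'   (output directory), `seed`, optional `stages` (subset of the six, in
#'   order), optional `simulate` (arguments of the study generators) and
#'   optional `params` overriding [pipeline_defaults()].
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out)) stop("config$out (output directory) is required")
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("simulate", "qc", "network", "preserve", "trait", "rnai")
  known <- c("simulate", "qc", "network", "preserve", "trait", "rnai")
  if (length(setdiff(stages, known))) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  p <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  sim <- utils::modifyList(list(
    categories = c(DILI = 6, stress_reference = 2),
    n_dose_levels = 4, time_points = c(4, 8, 24), n_replicates = 3,
    n_batches = 1, n_genes = 600, n_modules = 6, module_size = 40,
    amplitude = 4, noise_sd = 0.3, qc_defect_rate = 0,
    preserved_modules = NULL, link_weights = c(M1 = 1.2),
    rnai_effect_size = 3
  ), config$simulate %||% list())

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  on.exit({
    if (!isTRUE(res$.complete)) {
      writeLines("pipeline failed before completing all stages",
                 file.path(config$out, "FAILED"))
    }
  })

  design <- generate_design(unlist(sim$categories), sim$n_dose_levels,
                            sim$time_points, sim$n_replicates, sim$n_batches,
                            seed = seed)
  spec <- module_spec(design, n_genes = sim$n_genes, n_modules = sim$n_modules,
                      module_size = sim$module_size, amplitude = sim$amplitude,
                      noise_sd = sim$noise_sd, seed = seed + 1)

  if ("simulate" %in% stages) {
    counts <- generate_counts(design, spec, qc_defect_rate = sim$qc_defect_rate,
                              seed = seed + 2)
    write_design_tsv(design, file.path(config$out, "metadata.tsv"))
    write_counts_tsv(counts, file.path(config$out, "counts.tsv"))
    truth <- attr(counts, "truth")
    jsonlite::write_json(
      list(assignment = as.list(truth$assignment),
           corrupted = truth$corrupted),
      file.path(config$out, "truth.json"), auto_unbox = TRUE)
    res$counts <- counts
  }

  if ("qc" %in% stages) {
    if (is.null(res$counts)) stop("qc stage needs the simulate stage (or preloaded counts)")
    c1 <- filter_library_size(res$counts, p$min_library_size)
    cpm <- cpm_normalize(c1)
    cpm <- filter_replicate_correlation(cpm, c1$design, p$min_replicate_r,
                                        top_n = p$replicate_top_n)
    lfc <- compute_log2fc(cpm, design, pseudocount = p$pseudocount)
    lfc <- filter_good_genes(lfc)
    degs <- call_degs(lfc, p$deg_padj_max, p$deg_min_abs_lfc)
    write_logfc_tsv(lfc, file.path(config$out, "logfc"))
    write_table_tsv(aggregate_degs(degs), file.path(config$out, "deg_summary.tsv"))
    jsonlite::write_json(
      list(removed_library_size = attr(c1, "removed"),
           removed_replicate_correlation = attr(cpm, "removed")),
      file.path(config$out, "qc_report.json"), auto_unbox = TRUE)
    res$logfc <- lfc
  }

  if ("network" %in% stages) {
    if (is.null(res$logfc)) stop("network stage needs the qc stage")
    ms <- wgcna_modules(res$logfc, beta = p$beta,
                        min_module_size = p$min_module_size,
                        cut_height = p$cut_height,
                        merge_threshold = p$merge_threshold,
                        target_r2 = p$target_r2)
    assign_df <- data.frame(gene = names(ms$assignment),
                            module_id = unname(ms$assignment),
                            corEG = unname(ms$corEG[names(ms$assignment)]),
                            is_hub = names(ms$assignment) %in% ms$hub,
                            stringsAsFactors = FALSE)
    write_table_tsv(assign_df, file.path(config$out, "modules.tsv"))
    if (!is.null(ms$eigengenes)) {
      eg_df <- data.frame(condition_id = rownames(ms$eigengenes), ms$eigengenes,
                          check.names = FALSE, stringsAsFactors = FALSE)
      write_table_tsv(eg_df, file.path(config$out, "eigengenes.tsv"))
    }
    if (!is.null(ms$power_fit)) {
      write_table_tsv(ms$power_fit$fits, file.path(config$out, "soft_power_fit.tsv"))
    }
    res$module_set <- ms
  }

  if ("preserve" %in% stages) {
    preserved <- sim$preserved_modules %||% seq_len(max(1, floor(sim$n_modules / 2)))
    test_lfc <- generate_reference_logfc(spec, preserved, n_conditions = 60,
                                         seed = seed + 3)
    ref_lfc <- res$logfc %||% generate_logfc(design, spec, seed = seed + 4)
    pres <- preservation_stats(ref_lfc, spec$assignment, test_lfc,
                               beta = if (identical(p$beta, "auto")) 6 else p$beta,
                               n_perm = p$n_perm, seed = seed + 5)
    write_table_tsv(pres, file.path(config$out, "preservation.tsv"))
    jsonlite::write_json(attr(pres, "params"),
                         file.path(config$out, "preservation_params.json"),
                         auto_unbox = TRUE)
    res$preservation <- pres
  }

  if ("trait" %in% stages) {
    lfc <- res$logfc %||% generate_logfc(design, spec, seed = seed + 4)
    eg <- compute_eigengenes(lfc, spec$assignment)
    ms <- structure(list(assignment = spec$assignment, eigengenes = eg$eigengenes,
                         conditions = lfc$conditions), class = "module_set")
    conds <- design_conditions(design)
    late <- conds[conds$time_h == max(conds$time_h), , drop = FALSE]
    lw <- unlist(sim$link_weights)
    trait <- trait_spec(linked_modules = lw)
    trait_table <- generate_cell_death(
      design, list(conditions = late, scores = module_activation(spec, late)),
      trait, seed = seed + 6)
    paired <- align_conditions(ms, trait_table)
    records <- correlate_modules_death(ms, paired)
    cats <- setNames(design$category, design$compound)
    hits <- select_hit_modules(records, cats, death_time = p$trait_death_time,
                               padj_max = p$trait_padj_max, min_r = p$trait_min_r,
                               min_eg = p$trait_min_eg,
                               min_dili_compounds = p$trait_min_dili_compounds)
    cands <- select_candidate_genes(hits, spec$assignment, lfc,
                                    padj_max = p$gene_padj_max,
                                    min_lfc = p$gene_min_lfc)
    write_table_tsv(trait_table, file.path(config$out, "trait_table.tsv"))
    write_table_tsv(records, file.path(config$out, "trait_correlations.tsv"))
    write_table_tsv(hits, file.path(config$out, "trait_hits.tsv"))
    write_table_tsv(cands, file.path(config$out, "candidate_genes.tsv"))
    res$trait <- list(records = records, hits = hits, candidates = cands)
  }

  if ("rnai" %in% stages) {
    screen <- standard_rnai_screen(seed = seed + 7, effect_size = sim$rnai_effect_size)
    ztab <- zscore_cell_death(screen$table)
    classes <- classify_rnai_hits(ztab, z_min = p$rnai_z_min, k = p$rnai_k)
    write_table_tsv(ztab, file.path(config$out, "rnai_zscores.tsv"))
    write_table_tsv(log2fc_vs_control(screen$table),
                    file.path(config$out, "rnai_log2fc.tsv"))
    write_table_tsv(classes, file.path(config$out, "rnai_classes.tsv"))
    res$rnai <- list(ztab = ztab, classes = classes)
  }

  files <- list.files(config$out, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|FAILED$", files)]
  manifest <- list(
    package = "toxmodnet",
    version = as.character(utils::packageVersion("toxmodnet")),
    r_version = R.version.string,
    seed = seed, stages = stages, params = p,
    simulate = sim[order(names(sim))],
    files = lapply(setNames(nm = basename(files)),
                   function(f) unname(tools::md5sum(file.path(config$out, f))))
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$.complete <- TRUE
  invisible(res)
}
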