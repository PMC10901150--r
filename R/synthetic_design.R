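#' Generate a synthetic exposure study design
#'
#' Builds a compound x dose-level x time-point x replicate design of the kind
#' used in targeted dose-time-response transcriptomic screens of hepatocyte
#' models: several compound categories (DILI compounds with a severity class,
#' stress-pathway reference compounds, cytokines/growth factors, negative
#' controls), up to six concentration levels per compound in a geometric
#' series, and matched vehicle controls per batch and time point.
#'
#' @param n_compounds_per_category Named integer vector of compound counts,
#'   names from `c("DILI", "stress_reference", "cytokine_growth_factor",
#'   "negative")`. At least one entry must be positive.
#' @param n_dose_levels Number of concentration levels per compound (1..6).
#' @param time_points Exposure durations in hours (default `c(4, 8, 24)`).
#' @param n_replicates Biological replicates per condition (>= 2; the
#'   replicate-correlation QC filter needs at least two).
#' @param n_batches Number of experimental batches; compounds are assigned to
#'   batches round-robin and every batch carries its own vehicle samples.
#' @param seed Integer RNG seed; the design is a pure function of its
#'   arguments.
#' @param vehicle Label of the vehicle control compound (default `"DMSO"`).
#'
#' @return A `study_design` data frame with one row per sample and columns
#'   `sample_id`, `compound`, `category`, `severity`, `dose_level`,
#'   `concentration`, `conc_unit`, `time_h`, `replicate`, `batch`,
#'   `vehicle_of`. Vehicle samples have `dose_level = 0`, `category =
#'   "vehicle"` and `vehicle_of = NA`.
#' @export
generate_design <- function(n_compounds_per_category,
                            n_dose_levels = 6,
                            time_points = c(4, 8, 24),
                            n_replicates = 3,
                            n_batches = 1,
                            seed = 1,
                            vehicle = "DMSO") {
  cats <- n_compounds_per_category
  if (length(cats) == 0L || sum(cats) == 0L) {
    stop("n_compounds_per_category is empty: at least one category must have a positive compound count")
  }
  allowed <- c("DILI", "stress_reference", "cytokine_growth_factor", "negative")
  if (is.null(names(cats)) || !all(names(cats) %in% allowed)) {
    stop("n_compounds_per_category must be named with categories among: ",
         paste(allowed, collapse = ", "))
  }
  if (n_dose_levels < 1 || n_dose_levels > 6) stop("n_dose_levels must be in 1..6")
  if (n_replicates < 2) stop("n_replicates must be >= 2 (replicate QC requires at least two replicates)")
  if (n_batches < 1) stop("n_batches must be >= 1")

  with_seed(seed, {
    compounds <- data.frame(
      compound = character(0), category = character(0),
      severity = integer(0), stringsAsFactors = FALSE
    )
    for (cat in names(cats)) {
      n <- cats[[cat]]
      if (n == 0) next
      lab <- sprintf("%s_%02d", toupper(substr(cat, 1, 4)), seq_len(n))
      sev <- if (cat == "DILI") sample(3:8, n, replace = TRUE) else rep(NA_integer_, n)
      compounds <- rbind(compounds, data.frame(
        compound = lab, category = cat, severity = sev, stringsAsFactors = FALSE
      ))
    }
    compounds$batch <- rep_len(seq_len(n_batches), nrow(compounds))
    # Geometric concentration series per compound: dose levels strictly
    # ordered by concentration.
    base_conc <- 10^runif(nrow(compounds), -1, 2)

    rows <- list()
    for (i in seq_len(nrow(compounds))) {
      grid <- expand.grid(
        dose_level = seq_len(n_dose_levels),
        time_h = time_points,
        replicate = seq_len(n_replicates),
        KEEP.OUT.ATTRS = FALSE
      )
      rows[[i]] <- data.frame(
        compound = compounds$compound[i],
        category = compounds$category[i],
        severity = compounds$severity[i],
        dose_level = grid$dose_level,
        concentration = base_conc[i] * 2^(grid$dose_level - 1),
        conc_unit = "uM",
        time_h = grid$time_h,
        replicate = grid$replicate,
        batch = compounds$batch[i],
        vehicle_of = vehicle,
        stringsAsFactors = FALSE
      )
    }
    treated <- do.call(rbind, rows)

    veh_grid <- expand.grid(
      batch = seq_len(n_batches),
      time_h = time_points,
      replicate = seq_len(n_replicates),
      KEEP.OUT.ATTRS = FALSE
    )
    veh <- data.frame(
      compound = vehicle, category = "vehicle", severity = NA_integer_,
      dose_level = 0L, concentration = 0, conc_unit = "uM",
      time_h = veh_grid$time_h, replicate = veh_grid$replicate,
      batch = veh_grid$batch, vehicle_of = NA_character_,
      stringsAsFactors = FALSE
    )

    design <- rbind(treated, veh)
    design <- design[order(design$batch, design$compound, design$dose_level,
                           design$time_h, design$replicate), , drop = FALSE]
    design$sample_id <- sprintf("S%04d", seq_len(nrow(design)))
    rownames(design) <- design$sample_id
    design <- design[, c("sample_id", "compound", "category", "severity",
                         "dose_level", "concentration", "conc_unit", "time_h",
                         "replicate", "batch", "vehicle_of")]
    class(design) <- c("study_design", "data.frame")
    design
  })
}

#' Treated (non-vehicle) experimental conditions of a design
#'
#' One row per unique (compound, dose_level, time_h) combination, carrying
#' compound metadata and a stable `condition_id`.
#'
#' @param design A `study_design`.
#' @return Data frame with columns `condition_id`, `compound`, `category`,
#'   `severity`, `dose_level`, `concentration`, `time_h`.
#' @export
design_conditions <- function(design) {
  tr <- design[design$category != "vehicle", , drop = FALSE]
  key <- paste(tr$compound, tr$dose_level, tr$time_h, sep = "|")
  tr <- tr[!duplicated(key), c("compound", "category", "severity",
                               "dose_level", "concentration", "time_h")]
  tr$condition_id <- paste(tr$compound, tr$dose_level, tr$time_h, sep = "|")
  rownames(tr) <- tr$condition_id
  tr[, c("condition_id", "compound", "category", "severity", "dose_level",
         "concentration", "time_h")]
}
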