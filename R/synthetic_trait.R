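#' Specify the coupling between module activity and cell death
#'
#' Defines how planted module activations drive the synthetic cell-death
#' readout: a weighted sum of linked-module activations is passed through a
#' saturating logistic link into a death fraction in \[0, 1\], scaled by a
#' monotone accumulation ramp over the death measurement time points
#' (apoptosis and necrosis accumulate; later measurements are never lower).
#'
#' @param linked_modules Named numeric vector of link weights; names are
#'   module columns (`"M1"`, ...). All-zero weights give a pure-noise
#'   negative control.
#' @param death_types Character vector of death readouts.
#' @param death_times Death measurement time points (hours), a subset of
#'   `c(8, 24, 48, 58)`.
#' @param time_ramp Named accumulation multipliers in (0, 1\] for each death
#'   time; must be non-decreasing with time.
#' @param slope Logistic link slope on the activation scale.
#' @param baseline Death fraction at zero activation.
#' @param noise_sd Gaussian noise SD added to fractions (then clipped and
#'   made monotone over death times).
#' @return A `trait_spec` object.
#' @export
trait_spec <- function(linked_modules,
                       death_types = c("apoptosis", "necrosis"),
                       death_times = c(8, 24, 48, 58),
                       time_ramp = c(`8` = 0.25, `24` = 0.5, `48` = 0.8, `58` = 1),
                       slope = 1,
                       baseline = 0,
                       noise_sd = 0.02) {
  if (!all(death_times %in% c(8, 24, 48, 58))) {
    stop("death_times must be a subset of {8, 24, 48, 58} h")
  }
  ramp <- time_ramp[as.character(death_times)]
  if (any(is.na(ramp))) stop("time_ramp must cover every death time point")
  if (is.unsorted(ramp)) stop("time_ramp must be non-decreasing in time (monotone accumulation)")
  if (baseline < 0 || baseline >= 1) stop("baseline must be in [0, 1)")
  obj <- list(linked_modules = linked_modules, death_types = death_types,
              death_times = sort(death_times), time_ramp = time_ramp,
              slope = slope, baseline = baseline, noise_sd = noise_sd)
  class(obj) <- "trait_spec"
  obj
}

#' Generate a synthetic cell-death trait table
#'
#' Produces per-(compound, concentration, death time, death type) dead-cell
#' fractions driven by the true activations of the linked modules:
#' `fraction = baseline + (1 - baseline) * ramp(t) * (2 * plogis(slope * eta) - 1)`
#' with `eta = max(0, sum(weights * activation))`, plus Gaussian noise,
#' clipped to \[0, 1\] and made monotone non-decreasing over death times
#' within each condition (death accumulates).
#'
#' @param design A `study_design` (supplies the compound x concentration
#'   grid).
#' @param egs_truth List with `conditions` (data frame with `compound`,
#'   `dose_level`, `concentration`) and `scores` (matrix, conditions x
#'   modules) of true module activations per (compound, concentration), e.g.
#'   evaluated at the latest transcriptomic time point. Must cover every
#'   treated (compound, concentration) pair of the design.
#' @param trait A [trait_spec()]; its `linked_modules` names must be columns
#'   of `egs_truth$scores`, and at least one module must remain unlinked.
#' @param seed Integer RNG seed.
#' @return A `trait_table` data frame with columns `compound`,
#'   `concentration`, `death_time_h`, `death_type`, `fraction`.
#' @export
generate_cell_death <- function(design, egs_truth, trait, seed = 1) {
  conds <- egs_truth$conditions
  scores <- egs_truth$scores
  stopifnot(nrow(conds) == nrow(scores))
  key_design <- unique(paste(design$compound[design$category != "vehicle"],
                             design$concentration[design$category != "vehicle"]))
  key_truth <- paste(conds$compound, conds$concentration)
  if (!all(key_design %in% key_truth)) {
    stop("egs_truth does not cover every treated (compound, concentration) pair of the design")
  }
  w <- setNames(numeric(ncol(scores)), colnames(scores))
  unknown <- setdiff(names(trait$linked_modules), colnames(scores))
  if (length(unknown)) stop("linked modules absent from egs_truth: ", paste(unknown, collapse = ", "))
  w[names(trait$linked_modules)] <- trait$linked_modules
  if (all(w != 0)) stop("at least one module must remain unlinked (negative-control structure)")

  eta <- pmax(as.vector(scores %*% w), 0)
  with_seed(seed, {
    recs <- vector("list", length(trait$death_times) * length(trait$death_types))
    i <- 0L
    base_resp <- trait$baseline +
      (1 - trait$baseline) * (2 * plogis(trait$slope * eta) - 1)
    for (dt in trait$death_types) {
      for (tt in trait$death_times) {
        i <- i + 1L
        frac <- trait$baseline +
          (base_resp - trait$baseline) * trait$time_ramp[[as.character(tt)]]
        if (trait$noise_sd > 0) frac <- frac + rnorm(length(frac), 0, trait$noise_sd)
        recs[[i]] <- data.frame(
          compound = conds$compound, concentration = conds$concentration,
          death_time_h = tt, death_type = dt,
          fraction = pmin(pmax(frac, 0), 1), stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, recs)
    # Enforce monotone accumulation: cumulative max over death times within
    # each (compound, concentration, death type).
    tab <- tab[order(tab$death_type, tab$compound, tab$concentration, tab$death_time_h), ]
    grp <- paste(tab$death_type, tab$compound, tab$concentration)
    tab$fraction <- unlist(lapply(split(tab$fraction, factor(grp, unique(grp))), cummax),
                           use.names = FALSE)
    rownames(tab) <- NULL
    class(tab) <- c("trait_table", "data.frame")
    tab
  })
}

#' Generate a synthetic siRNA cell-death screen
#'
#' Emulates an RNAi screen read out by live-cell imaging of apoptosis (AnV)
#' and necrosis (PI): per (compound, time, death type) stratum, every siRNA
#' target and the mock/scrambled controls get `n_replicates` death values
#' around a stratum baseline; planted protective knockdowns are shifted down
#' by `effect_size * noise_sd` and enhancing knockdowns up by the same
#' amount.
#'
#' @param target_genes Character vector of siRNA target gene ids.
#' @param protective_set,enhancing_set Disjoint subsets of `target_genes`
#'   with planted effects.
#' @param compounds Compounds applied after knockdown.
#' @param time_points Imaging times in hours (default `c(24, 48, 72)`).
#' @param effect_size Planted shift in units of `noise_sd` (>= 0).
#' @param seed Integer RNG seed.
#' @param death_types Readout channels (default `c("AnV", "PI")`).
#' @param n_replicates Replicates per (target, stratum).
#' @param noise_sd Replicate noise SD on the fraction scale.
#' @param baseline Death fraction of an unperturbed well at the first time
#'   point; rises with time.
#' @return An `rnai_table` data frame with columns `target`, `is_control`,
#'   `compound`, `time_h`, `death_type`, `replicate`, `value`;
#'   `attr(, "truth")` records the planted sets.
#' @export
generate_rnai_dataset <- function(target_genes,
                                  protective_set = character(0),
                                  enhancing_set = character(0),
                                  compounds,
                                  time_points = c(24, 48, 72),
                                  effect_size = 3,
                                  seed = 1,
                                  death_types = c("AnV", "PI"),
                                  n_replicates = 3,
                                  noise_sd = 0.02,
                                  baseline = 0.2) {
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (length(intersect(protective_set, enhancing_set))) {
    stop("protective_set and enhancing_set must be disjoint")
  }
  if (!all(c(protective_set, enhancing_set) %in% target_genes)) {
    stop("planted sets must be subsets of target_genes")
  }
  targets <- c(target_genes, "mock", "scrambled")
  shift <- setNames(numeric(length(targets)), targets)
  shift[protective_set] <- -effect_size * noise_sd
  shift[enhancing_set] <- effect_size * noise_sd

  with_seed(seed, {
    grid <- expand.grid(
      target = targets, compound = compounds, time_h = time_points,
      death_type = death_types, replicate = seq_len(n_replicates),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    # Stratum baseline: death accumulates with time, compounds differ a bit.
    cpd_off <- setNames(seq_along(compounds) * 0.03, compounds)
    strat_base <- baseline + 0.08 * (match(grid$time_h, sort(unique(time_points))) - 1) +
      cpd_off[grid$compound]
    value <- strat_base + shift[grid$target] + rnorm(nrow(grid), 0, noise_sd)
    grid$value <- pmin(pmax(value, 0), 1)
    grid$is_control <- grid$target %in% c("mock", "scrambled")
    tab <- grid[, c("target", "is_control", "compound", "time_h",
                    "death_type", "replicate", "value")]
    class(tab) <- c("rnai_table", "data.frame")
    attr(tab, "truth") <- list(protective = protective_set, enhancing = enhancing_set)
    tab
  })
}
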