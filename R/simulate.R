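#' Variant effect profile
#'
#' Describes how a single LDLR variant perturbs the quantities measured by the
#' functional assays. A reference benign variant has all factors at 1 and no
#' surface-negative subpopulation.
#'
#' @param variant_id Variant label (HGVS p. notation, e.g. `"p.(Ala391Thr)"`).
#' @param surface_factor Multiplier (>= 0) on the surface-label signal of a
#'   transfected cell relative to the reference variant.
#' @param binding_internalization_factor Multiplier in `[0, 1]` on the
#'   receptor-dependent component of LDL uptake (binding/internalization
#'   efficiency).
#' @param expression_factor Multiplier (>= 0) on total protein abundance.
#' @param surface_negative_fraction Probability in `[0, 1]` that a transfected
#'   cell expresses no receptor on the surface at all (bimodal phenotype).
#' @param mature_fraction Probability in `[0, 1]` that a receptor molecule is
#'   in the mature (160 kDa) rather than the precursor (120 kDa) form.
#' @param truncated Logical; `TRUE` for a truncated protein product detected
#'   as a single band of reduced molecular weight.
#' @return An object of class `"variant_effect_profile"` (a named list).
#' @examples
#' benign <- variant_effect_profile("p.(Ala391Thr)")
#' er_retained <- variant_effect_profile("classA", surface_factor = 0.03,
#'                                       mature_fraction = 0.05)
#' @export
variant_effect_profile <- function(variant_id,
                                   surface_factor = 1,
                                   binding_internalization_factor = 1,
                                   expression_factor = 1,
                                   surface_negative_fraction = 0,
                                   mature_fraction = 0.75,
                                   truncated = FALSE) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L, nzchar(variant_id))
  probs <- c(binding_internalization_factor, surface_negative_fraction, mature_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("binding_internalization_factor, surface_negative_fraction and mature_fraction must lie in [0, 1]")
  }
  if (surface_factor < 0 || expression_factor < 0) {
    stop("surface_factor and expression_factor must be >= 0")
  }
  structure(list(
    variant_id = variant_id,
    surface_factor = surface_factor,
    binding_internalization_factor = binding_internalization_factor,
    expression_factor = expression_factor,
    surface_negative_fraction = surface_negative_fraction,
    mature_fraction = mature_fraction,
    truncated = isTRUE(truncated)
  ), class = "variant_effect_profile")
}

#' Well specification
#'
#' Identifies one well of a transfection experiment: which variant it carries,
#' which assay it feeds, the experiment (day) it belongs to and its replicate
#' index.
#'
#' @param variant_id Variant label.
#' @param assay One of `"surface"`, `"internalization"`, `"fmo_no_antibody"`,
#'   `"fmo_no_reporter"`, `"ldlr_deficient"`.
#' @param experiment_id Integer day index.
#' @param replicate Integer well index (>= 1).
#' @param n_events Number of cytometer events recorded for the well.
#' @param seed Integer seed making this well's events reproducible.
#' @return An object of class `"well_spec"`.
#' @export
well_spec <- function(variant_id, assay, experiment_id = 1L, replicate = 1L,
                      n_events = 40000L, seed = 1L) {
  assays <- c("surface", "internalization", "fmo_no_antibody",
              "fmo_no_reporter", "ldlr_deficient")
  if (!is.character(assay) || length(assay) != 1L || !assay %in% assays) {
    stop(sprintf("unknown assay kind for well '%s/%s': must be one of %s",
                 variant_id, as.character(assay)[1],
                 paste(assays, collapse = ", ")))
  }
  stopifnot(n_events > 0, replicate >= 1)
  structure(list(variant_id = variant_id, assay = assay,
                 experiment_id = as.integer(experiment_id),
                 replicate = as.integer(replicate),
                 n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "well_spec")
}

#' Simulation configuration
#'
#' Statistical parameters of the event-level generator. All fluorescence
#' populations are log-normal; `*_meanlog`/`*_sdlog` are on the natural-log
#' scale. Scatter channels are in arbitrary units (a.u.).
#'
#' @param doublet_fraction Probability an event is a doublet (two aggregated
#'   cells; forward-scatter area about twice the height-matched singlet value).
#' @param dead_fraction Probability a cell is dead (high viability-dye signal).
#' @param transfected_fraction Probability a cell was transfected and expresses
#'   the reporter; default 0.15, the middle of the 10--25% efficiency range
#'   typical for PEI transfection of CHO cells.
#' @param reporter_neg_meanlog,reporter_neg_sdlog Autofluorescence of the
#'   reporter channel in untransfected cells.
#' @param reporter_pos_meanlog,reporter_pos_sdlog Reporter signal of
#'   transfected cells.
#' @param surface_bg_meanlog,surface_bg_sdlog Surface-channel background
#'   (autofluorescence; unstained or receptor-free cells).
#' @param surface_pos_meanlog,surface_pos_sdlog Surface-label signal of a
#'   reference-variant transfected cell.
#' @param surface_nonspecific_factor Multiplier on the surface background
#'   median for antibody-stained cells without surface receptor (nonspecific
#'   antibody binding).
#' @param uptake_bg_meanlog,uptake_bg_sdlog Uptake-channel autofluorescence
#'   (no labeled LDL added).
#' @param uptake_pos_meanlog,uptake_pos_sdlog Uptake signal of a reference
#'   transfected cell exposed to labeled LDL.
#' @param viability_live_meanlog,viability_live_sdlog,viability_dead_meanlog,viability_dead_sdlog
#'   Viability-dye populations for live and dead cells.
#' @param fsc_meanlog,fsc_sdlog Forward-scatter height distribution.
#' @param fsc_ratio_sd Spread of the singlet fsc_h/fsc_a ratio around 1.
#' @param uptake_background Receptor-independent LDL uptake as a fraction of
#'   the reference receptor-dependent signal.
#' @param uptake_saturation_k Saturation constant of the uptake response to
#'   surface receptor level.
#' @param experiment_scale_sd Log-scale SD of the multiplicative per-day
#'   (per-experiment) factor applied to stain intensities.
#' @param densitometry_base_volume Expected total LDLR band volume (a.u.) for
#'   a reference lane.
#' @param densitometry_total_sdlog Log-scale SD of the lane total volume
#'   (lysate amount, transfection efficiency).
#' @param densitometry_partition_sdlog Log-scale SD applied to each band's
#'   share of the lane total.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(doublet_fraction = 0.10,
                              dead_fraction = 0.10,
                              transfected_fraction = 0.15,
                              reporter_neg_meanlog = log(50), reporter_neg_sdlog = 0.5,
                              reporter_pos_meanlog = log(5000), reporter_pos_sdlog = 0.6,
                              surface_bg_meanlog = log(30), surface_bg_sdlog = 0.5,
                              surface_pos_meanlog = log(3000), surface_pos_sdlog = 1.0,
                              surface_nonspecific_factor = 1.3,
                              uptake_bg_meanlog = log(20), uptake_bg_sdlog = 0.5,
                              uptake_pos_meanlog = log(2000), uptake_pos_sdlog = 0.5,
                              viability_live_meanlog = log(50), viability_live_sdlog = 0.4,
                              viability_dead_meanlog = log(5000), viability_dead_sdlog = 0.4,
                              fsc_meanlog = log(1e5), fsc_sdlog = 0.15,
                              fsc_ratio_sd = 0.05,
                              uptake_background = 0.20,
                              uptake_saturation_k = 3.0,
                              experiment_scale_sd = 0.15,
                              densitometry_base_volume = 10000,
                              densitometry_total_sdlog = 0.25,
                              densitometry_partition_sdlog = 0.08) {
  cfg <- as.list(environment())
  fr <- c(cfg$doublet_fraction, cfg$dead_fraction, cfg$transfected_fraction,
          cfg$uptake_background)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  sds <- c(cfg$reporter_neg_sdlog, cfg$reporter_pos_sdlog, cfg$surface_bg_sdlog,
           cfg$surface_pos_sdlog, cfg$uptake_bg_sdlog, cfg$uptake_pos_sdlog,
           cfg$viability_live_sdlog, cfg$viability_dead_sdlog, cfg$fsc_sdlog,
           cfg$fsc_ratio_sd)
  if (any(sds <= 0)) stop("spread parameters must be > 0")
  structure(cfg, class = "simulation_config")
}

# Relative uptake response: receptor-independent background plus a saturating
# receptor-dependent term in the effective surface level s (s = 1 at reference).
uptake_response <- function(s, bif, config) {
  k <- config$uptake_saturation_k
  config$uptake_background +
    (1 - config$uptake_background) * bif * (1 - exp(-k * s)) / (1 - exp(-k))
}

#' Simulate the events of one cytometer well
#'
#' Draws `n_events` events as a mixture of singlets/doublets, live/dead and
#' transfected/untransfected cells with log-normal fluorescence channels.
#' Transfected live cells carry variant-dependent surface and uptake signals;
#' FMO wells omit the corresponding stain and receptor-deficient wells carry
#' no surface receptor at all. Deterministic given `spec$seed`.
#'
#' In addition to the canonical channel columns
#' (`fsc_a`, `fsc_h`, `viability_dye`, `reporter`, `surface_label`,
#' `uptake_label`) and the well metadata, the returned table carries the
#' simulation-truth flags `is_doublet`, `is_dead`, `is_transfected`,
#' `is_surface_negative`, which exist only to validate gating and are not part
#' of the on-disk event format (see [write_events()]).
#'
#' @param spec A [well_spec()].
#' @param profile A [variant_effect_profile()] for the well's variant.
#' @param config A [simulation_config()].
#' @param day_factor Multiplicative per-experiment scale applied to the stain
#'   channels (reporter, surface, uptake); 1 for a single isolated well.
#' @return A `data.frame` event table with one row per event.
#' @export
simulate_events <- function(spec, profile, config = simulation_config(),
                            day_factor = 1) {
  stopifnot(inherits(spec, "well_spec"), inherits(profile, "variant_effect_profile"),
            inherits(config, "simulation_config"), day_factor > 0)
  n <- spec$n_events
  set.seed(spec$seed)

  is_doublet <- stats::runif(n) < config$doublet_fraction
  is_dead <- stats::runif(n) < config$dead_fraction
  is_transfected <- stats::runif(n) < config$transfected_fraction
  is_surface_negative <- is_transfected &
    (stats::runif(n) < profile$surface_negative_fraction)

  # Scatter: singlet fsc_h/fsc_a ratio ~ N(1, fsc_ratio_sd); doublets have
  # about twice the area at the same height.
  fsc_h <- stats::rlnorm(n, config$fsc_meanlog, config$fsc_sdlog)
  ratio <- stats::rnorm(n, 1, config$fsc_ratio_sd)
  ratio[ratio < 0.5] <- 0.5   # keep ratios physical
  fsc_a <- fsc_h / ratio
  fsc_a[is_doublet] <- 2 * fsc_a[is_doublet]

  viability_dye <- ifelse(is_dead,
    stats::rlnorm(n, config$viability_dead_meanlog, config$viability_dead_sdlog),
    stats::rlnorm(n, config$viability_live_meanlog, config$viability_live_sdlog))

  ldf <- log(day_factor)
  reporter_on <- is_transfected & spec$assay != "fmo_no_reporter" &
    spec$assay != "ldlr_deficient"
  reporter <- ifelse(reporter_on,
    stats::rlnorm(n, config$reporter_pos_meanlog + ldf, config$reporter_pos_sdlog),
    stats::rlnorm(n, config$reporter_neg_meanlog, config$reporter_neg_sdlog))

  # Surface channel. Antibody staining is present in the surface assay, the
  # reporter-FMO well and the receptor-deficient control; it is omitted in the
  # antibody-FMO well and in internalization wells (cells are not stained).
  stained <- spec$assay %in% c("surface", "fmo_no_reporter", "ldlr_deficient")
  surface_level <- profile$expression_factor * profile$surface_factor
  if (spec$assay == "ldlr_deficient") surface_level <- 0
  has_surface <- stained & is_transfected & !is_surface_negative &
    surface_level > 0 & !profile$truncated
  bg_median <- config$surface_bg_meanlog +
    ifelse(stained, log(config$surface_nonspecific_factor), 0)
  pos_meanlog <- config$surface_pos_meanlog + log(max(surface_level, 1e-12)) + ldf
  surface_label <- ifelse(has_surface,
    stats::rlnorm(n, pos_meanlog, config$surface_pos_sdlog),
    stats::rlnorm(n, bg_median, config$surface_bg_sdlog))

  # Uptake channel. Labeled LDL is present only in internalization wells
  # (the uptake FMO is a surface-type well without the label).
  if (spec$assay == "internalization") {
    s <- rep(0, n)
    s[is_transfected & !is_surface_negative] <- surface_level
    if (profile$truncated) s[] <- 0
    rel <- uptake_response(s, profile$binding_internalization_factor, config)
    # receptor-independent background applies to every cell in the well
    rel[!is_transfected] <- config$uptake_background
    uptake_label <- stats::rlnorm(n, config$uptake_pos_meanlog + log(pmax(rel, 1e-12)) + ldf,
                                  config$uptake_pos_sdlog)
  } else {
    uptake_label <- stats::rlnorm(n, config$uptake_bg_meanlog, config$uptake_bg_sdlog)
  }

  data.frame(
    fsc_a = fsc_a, fsc_h = fsc_h, viability_dye = viability_dye,
    reporter = reporter, surface_label = surface_label,
    uptake_label = uptake_label,
    variant_id = spec$variant_id, assay = spec$assay,
    experiment_id = spec$experiment_id, replicate = spec$replicate,
    is_doublet = is_doublet, is_dead = is_dead,
    is_transfected = is_transfected, is_surface_negative = is_surface_negative,
    stringsAsFactors = FALSE
  )
}

#' Simulate densitometry replicates for one variant
#'
#' Total LDLR band volume scales with the variant's expression factor; the
#' mature (160 kDa) and precursor (120 kDa) bands split the total according to
#' `mature_fraction`, each with independent partition noise. A truncated
#' product appears as a single band of reduced molecular weight.
#'
#' @param profile A [variant_effect_profile()].
#' @param n_replicates Number of independent lanes.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `variant_id`, `replicate`,
#'   `volume_precursor`, `volume_mature`, `volume_truncated`,
#'   `loading_control_volume`.
#' @export
simulate_densitometry <- function(profile, n_replicates = 3,
                                  config = simulation_config(), seed = 1L) {
  stopifnot(inherits(profile, "variant_effect_profile"), n_replicates >= 1)
  set.seed(seed)
  total <- config$densitometry_base_volume * profile$expression_factor *
    stats::rlnorm(n_replicates, 0, config$densitometry_total_sdlog)
  part <- function(share) {
    total * share * stats::rlnorm(n_replicates, 0, config$densitometry_partition_sdlog)
  }
  if (profile$truncated) {
    mature <- precursor <- rep(0, n_replicates)
    truncated <- part(1)
  } else {
    mature <- part(profile$mature_fraction)
    precursor <- part(1 - profile$mature_fraction)
    truncated <- rep(0, n_replicates)
  }
  data.frame(
    variant_id = profile$variant_id,
    replicate = seq_len(n_replicates),
    volume_precursor = precursor,
    volume_mature = mature,
    volume_truncated = truncated,
    loading_control_volume = 5000 * stats::rlnorm(n_replicates, 0, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full multi-day experiment for a variant panel
#'
#' For each experiment (day) generates three surface wells and two
#' internalization wells per variant plus one FMO control well of each kind,
#' all sharing a log-normal day factor, and densitometry lanes per variant.
#' The reference benign variant must be part of the panel because every
#' experiment is normalized to it.
#'
#' @param profiles List of [variant_effect_profile()]s (the panel).
#' @param n_experiments Number of independent experiments (days), >= 1.
#' @param config A [simulation_config()].
#' @param seed Integer master seed; per-well seeds are derived from it.
#' @param reference_id Variant id of the benign reference that must be present.
#' @param n_events Events per well.
#' @param n_surface_wells,n_uptake_wells Replicate wells per variant and
#'   experiment for the two flow assays (triplicate / duplicate by default).
#' @param densitometry_replicates Lanes per variant over the whole experiment.
#' @return A list with elements `events` (list of per-well event tables),
#'   `densitometry` (one `data.frame`), and `day_factors`.
#' @export
simulate_experiment <- function(profiles, n_experiments = 3,
                                config = simulation_config(), seed = 1L,
                                reference_id = "p.(Ala391Thr)",
                                n_events = 40000L,
                                n_surface_wells = 3L, n_uptake_wells = 2L,
                                densitometry_replicates = 3L) {
  stopifnot(n_experiments >= 1)
  if (inherits(profiles, "variant_effect_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, `[[`, character(1), "variant_id")
  if (!reference_id %in% ids) {
    stop(sprintf("reference variant '%s' is missing from the panel", reference_id))
  }
  names(profiles) <- ids
  set.seed(seed)
  day_factors <- stats::rlnorm(n_experiments, 0, config$experiment_scale_sd)
  # independent integer seed stream for wells and lanes
  well_seeds <- sample.int(.Machine$integer.max - 1L,
                           n_experiments * (length(ids) * (n_surface_wells + n_uptake_wells) + 3L) +
                             length(ids))

  events <- list()
  k <- 0L
  for (e in seq_len(n_experiments)) {
    df <- day_factors[e]
    for (id in ids) {
      for (r in seq_len(n_surface_wells)) {
        k <- k + 1L
        sp <- well_spec(id, "surface", e, r, n_events, well_seeds[k])
        events[[length(events) + 1L]] <- simulate_events(sp, profiles[[id]], config, df)
      }
      for (r in seq_len(n_uptake_wells)) {
        k <- k + 1L
        sp <- well_spec(id, "internalization", e, r, n_events, well_seeds[k])
        events[[length(events) + 1L]] <- simulate_events(sp, profiles[[id]], config, df)
      }
    }
    ref <- profiles[[reference_id]]
    for (fmo in c("fmo_no_antibody", "fmo_no_reporter", "ldlr_deficient")) {
      k <- k + 1L
      prof <- if (fmo == "ldlr_deficient") {
        variant_effect_profile("ldlr_deficient", expression_factor = 0)
      } else ref
      sp <- well_spec(prof$variant_id, fmo, e, 1L, n_events, well_seeds[k])
      events[[length(events) + 1L]] <- simulate_events(sp, prof, config, df)
    }
  }
  dens <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    simulate_densitometry(profiles[[i]], densitometry_replicates, config,
                          seed = well_seeds[k + i])
  }))
  list(events = events, densitometry = dens, day_factors = day_factors)
}

#' Archetype effect profiles for the main LDLR variant classes
#'
#' Convenience constructors of representative profiles: `benign` (no defect),
#' `class1` (truncated product, no surface receptor), `class2a` (severe
#' transport defect: ~3% surface, precursor-only maturation), `class2b5`
#' (partial transport/recycling defect: ~40% surface, reduced maturation) and
#' `class3_4` (normal surface, binding/internalization efficiency ~0.55).
#'
#' @param class_archetype One of `"benign"`, `"class1"`, `"class2a"`,
#'   `"class2b5"`, `"class3_4"`.
#' @param variant_id Label for the profile.
#' @return A [variant_effect_profile()].
#' @export
archetype_profile <- function(class_archetype, variant_id = class_archetype) {
  switch(class_archetype,
    benign = variant_effect_profile(variant_id),
    class1 = variant_effect_profile(variant_id, surface_factor = 0,
                                    binding_internalization_factor = 0,
                                    truncated = TRUE),
    class2a = variant_effect_profile(variant_id, surface_factor = 0.03,
                                     mature_fraction = 0.02),
    class2b5 = variant_effect_profile(variant_id, surface_factor = 0.40,
                                      mature_fraction = 0.35),
    class3_4 = variant_effect_profile(variant_id,
                                      binding_internalization_factor = 0.55),
    stop(sprintf("unknown class archetype '%s'", class_archetype))
  )
}

event_table_columns <- c("fsc_a", "fsc_h", "viability_dye", "reporter",
                         "surface_label", "uptake_label", "variant_id",
                         "assay", "experiment_id", "replicate")

#' Write / read event tables as CSV
#'
#' The on-disk format is a plain CSV with the fixed header
#' `fsc_a,fsc_h,viability_dye,reporter,surface_label,uptake_label,variant_id,assay,experiment_id,replicate`.
#' Simulation-truth columns are dropped on write.
#'
#' @param events Event table (`data.frame`).
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the event `data.frame`.
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(event_table_columns, names(events))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(events[event_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(event_table_columns, names(ev))
  if (length(missing_cols)) {
    stop("event CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ev
}
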