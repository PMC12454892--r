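#' Run the full analysis chain on event-level data
#'
#' Reproduces the analysis of a multi-day transfection experiment: per-well
#' gating (singlets, viable cells, reporter positivity against the per-day FMO
#' threshold) and MFI extraction; averaging of replicate wells; conversion to
#' percent of the benign reference within each experiment; Dixon's Q outlier
#' screen on the per-experiment percentages; cross-experiment aggregation;
#' ANOVA with Dunnett's post hoc test against the statistical control; and,
#' when densitometry is supplied, maturation ratios, severity grading, variant
#' class inference and PS3/BS3 criterion assignment.
#'
#' @param events List of per-well event tables (see [simulate_events()]), or a
#'   single `data.frame` that is split by well.
#' @param densitometry Optional `data.frame` of band volumes (see
#'   [simulate_densitometry()]).
#' @param gating_config A [gating_config()].
#' @param thresholds A [classification_thresholds()].
#' @param reference_id Benign reference variant used for normalization.
#' @param control_id Statistical control group for Dunnett's test (the
#'   reference variant is exactly 100% in every experiment and carries no
#'   variance, so it cannot serve as the test control). Skipped if absent.
#' @param apply_dixon Screen per-experiment percentages for a single outlier
#'   per variant/assay before aggregation.
#' @return A list with `well_measurements`, `experiment_percents`, `results`
#'   (per variant/assay mean and SD), `dunnett`, `maturation`, `calls`,
#'   `assessments`, `summary`, `removed_outliers`, `fmo_thresholds`.
#' @export
pipeline_run <- function(events, densitometry = NULL,
                         gating_config = ldlrflow::gating_config(),
                         thresholds = classification_thresholds(),
                         reference_id = "p.(Ala391Thr)", control_id = "WT",
                         apply_dixon = TRUE) {
  if (is.data.frame(events)) {
    events <- split(events, interaction(events$experiment_id, events$assay,
                                        events$variant_id, events$replicate,
                                        drop = TRUE))
  }
  if (!length(events)) stop("empty input: no event tables supplied")
  meta <- do.call(rbind, lapply(events, function(e) {
    e[1, c("variant_id", "assay", "experiment_id", "replicate")]
  }))

  experiments <- sort(unique(meta$experiment_id))
  fmo_thresholds <- list()
  measurements <- list()
  for (e in experiments) {
    idx <- which(meta$experiment_id == e)
    find_well <- function(kind) {
      j <- idx[meta$assay[idx] == kind]
      if (!length(j)) stop(sprintf("experiment %s has no '%s' control well", e, kind))
      events[[j[1]]]
    }
    fmo_rep <- gate_viable(gate_singlets(find_well("fmo_no_reporter"), gating_config),
                           gating_config)
    fmo_ab <- gate_viable(gate_singlets(find_well("fmo_no_antibody"), gating_config),
                          gating_config)
    thr_reporter <- derive_fmo_threshold(fmo_rep, "reporter", gating_config)
    thr_surface <- derive_fmo_threshold(fmo_ab, "surface_label", gating_config)
    fmo_thresholds[[as.character(e)]] <- c(reporter = thr_reporter,
                                           surface_label = thr_surface)
    for (j in idx) {
      assay <- meta$assay[j]
      if (!assay %in% c("surface", "internalization")) next
      channel <- if (assay == "surface") "surface_label" else "uptake_label"
      alt <- if (assay == "surface") thr_surface else NULL
      measurements[[length(measurements) + 1L]] <-
        summarize_well(events[[j]], gating_config, channel,
                       gate_channel = "reporter", gate_threshold = thr_reporter,
                       alt_threshold = alt)
    }
  }
  wells <- do.call(rbind, measurements)
  usable <- wells[!wells$flagged, , drop = FALSE]

  # replicate-well averaging, then percent of reference within each experiment
  percents <- list()
  for (e in experiments) {
    for (assay in c("surface", "internalization")) {
      sub <- usable[usable$experiment_id == e & usable$assay == assay, , drop = FALSE]
      if (!nrow(sub)) next
      means <- tapply(sub$mfi, sub$variant_id, mean)
      pct <- percent_of_reference(means, reference_id)
      percents[[length(percents) + 1L]] <- data.frame(
        variant_id = names(pct), assay = assay, experiment_id = e,
        percent = as.numeric(pct), stringsAsFactors = FALSE)
    }
  }
  experiment_percents <- do.call(rbind, percents)

  removed <- list()
  results <- list()
  for (assay in unique(experiment_percents$assay)) {
    sub <- experiment_percents[experiment_percents$assay == assay, , drop = FALSE]
    for (v in unique(sub$variant_id)) {
      p <- sub$percent[sub$variant_id == v]
      if (apply_dixon && v != reference_id && length(p) >= 3 && length(p) <= 30) {
        dq <- dixon_q(p)
        if (!is.na(dq$outlier_index)) {
          removed[[length(removed) + 1L]] <- data.frame(
            variant_id = v, assay = assay, value = p[dq$outlier_index],
            statistic = dq$statistic, stringsAsFactors = FALSE)
          p <- p[-dq$outlier_index]
        }
      }
      results[[length(results) + 1L]] <- aggregate_experiments(p, v, assay)
    }
  }
  results <- do.call(rbind, results)
  removed_outliers <- if (length(removed)) do.call(rbind, removed) else NULL

  # many-to-one testing per assay against the statistical control
  dunnett <- list()
  for (assay in unique(results$assay)) {
    sub <- results[results$assay == assay, , drop = FALSE]
    groups <- stats::setNames(sub$per_experiment_percents, sub$variant_id)
    groups <- groups[names(groups) != reference_id]  # reference has zero variance
    groups <- groups[lengths(groups) >= 2]
    if (control_id %in% names(groups) && length(groups) >= 2) {
      dunnett[[assay]] <- anova_dunnett(groups, control_id)
    }
  }

  out <- list(well_measurements = wells,
              experiment_percents = experiment_percents,
              results = results, dunnett = dunnett,
              removed_outliers = removed_outliers,
              fmo_thresholds = fmo_thresholds)

  # densitometry, grading and classification
  maturation <- NULL
  if (!is.null(densitometry)) {
    ref_lanes <- densitometry[densitometry$variant_id == reference_id, , drop = FALSE]
    if (!nrow(ref_lanes)) {
      stop(sprintf("densitometry lacks reference variant '%s'", reference_id))
    }
    ref_total <- mean(ref_lanes$volume_mature + ref_lanes$volume_precursor +
                        ref_lanes$volume_truncated)
    maturation <- do.call(rbind, lapply(split(densitometry, densitometry$variant_id),
      function(s) maturation_result(s, ref_total)))
  }

  surf <- results[results$assay == "surface", , drop = FALSE]
  intr <- results[results$assay == "internalization", , drop = FALSE]
  ids <- union(surf$variant_id, intr$variant_id)
  ids <- setdiff(ids, c(reference_id))
  get1 <- function(df, v, col) {
    x <- df[[col]][df$variant_id == v]
    if (length(x)) x[1] else NA
  }
  calls <- lapply(ids, function(v) {
    sp <- get1(surf, v, "mean_percent")
    ip <- get1(intr, v, "mean_percent")
    ratio <- NA_real_
    expr <- "NORMAL"
    if (!is.null(maturation) && v %in% maturation$variant_id) {
      mrow <- maturation[maturation$variant_id == v, ]
      ratio <- mrow$ratio_mean
      expr <- mrow$expression_call
    }
    infer_classes(grade_surface(sp, thresholds),
                  grade_internalization(ip, thresholds),
                  grade_ratio(ratio, thresholds),
                  expr, variant_id = v)
  })
  assessments <- lapply(ids, function(v) {
    assign_ps3_bs3(get1(surf, v, "mean_percent"), get1(intr, v, "mean_percent"),
                   thresholds, variant_id = v)
  })
  out$maturation <- maturation
  out$calls <- calls
  out$assessments <- assessments
  out$summary <- summarize_panel(calls, assessments)
  out
}

#' Compare reporter-based and surface-based gating for a bimodal variant
#'
#' Simulates, in one experimental run, surface-assay wells for a benign
#' reference and a variant with a surface-negative subpopulation, then
#' extracts the surface MFI under the two alternative gates: positivity on the
#' transfection reporter (captures all transfected cells, including the
#' surface-negative ones) versus positivity on the surface label itself
#' (captures only cells with surface receptor, hiding the negative
#' subpopulation).
#'
#' @param surface_negative_fraction Fraction of transfected cells with no
#'   surface receptor for the bimodal variant.
#' @param config A [simulation_config()].
#' @param gating A [gating_config()].
#' @param n_events Events per well.
#' @param seed Integer seed.
#' @return A `data.frame` with one row per variant: MFI under the reporter
#'   gate, MFI under the surface gate, and the fraction of reporter-positive
#'   cells that are surface-positive.
#' @export
fig4_comparison <- function(surface_negative_fraction = 0.45,
                            config = simulation_config(),
                            gating = gating_config(),
                            n_events = 40000L, seed = 1L) {
  benign <- variant_effect_profile("benign_reference")
  bimodal <- variant_effect_profile("bimodal_variant",
    surface_negative_fraction = surface_negative_fraction)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  fmo_rep <- simulate_events(well_spec("benign_reference", "fmo_no_reporter",
                                       1L, 1L, n_events, seeds[1]), benign, config)
  fmo_ab <- simulate_events(well_spec("benign_reference", "fmo_no_antibody",
                                      1L, 1L, n_events, seeds[2]), benign, config)
  gv <- function(e) gate_viable(gate_singlets(e, gating), gating)
  thr_reporter <- derive_fmo_threshold(gv(fmo_rep), "reporter", gating)
  thr_surface <- derive_fmo_threshold(gv(fmo_ab), "surface_label", gating)

  rows <- lapply(list(benign, bimodal), function(prof) {
    idx <- if (identical(prof$variant_id, "benign_reference")) 3L else 4L
    ev <- simulate_events(well_spec(prof$variant_id, "surface", 1L, 1L,
                                    n_events, seeds[idx]), prof, config)
    m <- summarize_well(ev, gating, "surface_label", "reporter",
                        thr_reporter, alt_threshold = thr_surface)
    data.frame(variant_id = prof$variant_id,
               mfi_reporter_gate = m$mfi,
               mfi_surface_gate = m$mfi_alt_gate,
               fraction_surface_positive = m$fraction_positive_in_alt_gate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write pipeline configuration as YAML
#'
#' The YAML file may contain the blocks `simulation`, `gating`, `thresholds`
#' (each a mapping of constructor arguments), plus the scalars `reference_id`,
#' `control_id` and `seed`. Missing blocks take their defaults.
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a list with elements `simulation`,
#'   `gating`, `thresholds`, `reference_id`, `control_id`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  list(
    simulation = build(simulation_config, raw$simulation),
    gating = build(gating_config, raw$gating),
    thresholds = build(classification_thresholds, raw$thresholds),
    reference_id = if (is.null(raw$reference_id)) "p.(Ala391Thr)" else raw$reference_id,
    control_id = if (is.null(raw$control_id)) "WT" else raw$control_id,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
}

#' @rdname read_pipeline_config
#' @param config A list as returned by [read_pipeline_config()], or any subset
#'   of its blocks.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Write a pipeline report as JSON
#'
#' Serializes the per-variant results, classification calls, criterion
#' assignments, panel summary, removed outliers and the thresholds in force.
#' Floats are written with six significant digits.
#'
#' @param run A [pipeline_run()] result.
#' @param path Output file.
#' @param thresholds The [classification_thresholds()] used (echoed in the
#'   report metadata).
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path, thresholds = classification_thresholds()) {
  results <- run$results
  results$per_experiment_percents <- NULL
  report <- list(
    results = results,
    calls = lapply(run$calls, unclass),
    assessments = lapply(run$assessments, unclass),
    summary = lapply(run$summary, function(x) {
      if (is.table(x)) as.data.frame(x) else x
    }),
    removed_outliers = run$removed_outliers,
    thresholds = unclass(thresholds)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 6, null = "null")
  invisible(path)
}
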