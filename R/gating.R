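#' Gating configuration
#'
#' Parameters of the gating chain applied to each well: the forward-scatter
#' singlet band, the live/dead split on the viability dye, and the quantile of
#' the fluorescence-minus-one (FMO) distribution used as the positivity
#' threshold for a stain.
#'
#' @param singlet_ratio_band Length-2 numeric: allowed interval of the
#'   `fsc_h / fsc_a` ratio around the singlet line (doublets fall near 0.5).
#' @param viability_threshold Optional manual cut on the viability dye; events
#'   strictly below it are kept. If `NULL` the threshold is derived from the
#'   dye distribution (valley between the live and dead modes, with a
#'   high-quantile fallback for unimodal wells).
#' @param fmo_quantile Quantile of the gated FMO distribution used as the
#'   positivity threshold (events strictly above the threshold are positive).
#' @return An object of class `"gating_config"`.
#' @export
gating_config <- function(singlet_ratio_band = c(0.75, 1.25),
                          viability_threshold = NULL,
                          fmo_quantile = 0.999) {
  stopifnot(length(singlet_ratio_band) == 2,
            singlet_ratio_band[1] < singlet_ratio_band[2],
            fmo_quantile > 0, fmo_quantile < 1)
  structure(list(singlet_ratio_band = as.numeric(singlet_ratio_band),
                 viability_threshold = viability_threshold,
                 fmo_quantile = fmo_quantile),
            class = "gating_config")
}

assert_events <- function(events, cols = c("fsc_a", "fsc_h")) {
  if (!is.data.frame(events) || nrow(events) == 0) {
    stop("empty event table")
  }
  missing_cols <- setdiff(cols, names(events))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  invisible(events)
}

#' Gate single cells on forward scatter
#'
#' Keeps events whose `fsc_h / fsc_a` ratio lies inside the singlet band.
#' Events with zero forward-scatter area have an undefined ratio and are
#' excluded.
#'
#' @param events Event table.
#' @param config A [gating_config()].
#' @return The filtered event table.
#' @export
gate_singlets <- function(events, config = gating_config()) {
  assert_events(events)
  ratio <- ifelse(events$fsc_a > 0, events$fsc_h / events$fsc_a, NA_real_)
  keep <- !is.na(ratio) & ratio >= config$singlet_ratio_band[1] &
    ratio <= config$singlet_ratio_band[2]
  events[keep, , drop = FALSE]
}

# Valley between the two largest density modes of log10(x + 1); NULL if the
# distribution is effectively unimodal.
find_viability_valley <- function(x) {
  lx <- log10(x + 1)
  if (length(unique(lx)) < 10) return(NULL)
  d <- stats::density(lx, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) return(NULL)
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  # require a genuine second mode, not a density ripple
  if (min(y[top2]) < 0.05 * max(y[top2])) return(NULL)
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  10^d$x[valley] - 1
}

#' Gate viable cells on the dead-cell dye
#'
#' Keeps events strictly below the viability threshold. With no manual
#' threshold, the cut is placed at the valley between the live and dead modes
#' of the dye distribution; if no second mode is detectable all events are
#' retained (no dead population present).
#'
#' @inheritParams gate_singlets
#' @return The filtered event table. An all-dead well returns an empty table
#'   with a warning.
#' @export
gate_viable <- function(events, config = gating_config()) {
  assert_events(events, c("viability_dye"))
  thr <- config$viability_threshold
  if (is.null(thr)) {
    thr <- find_viability_valley(events$viability_dye)
    if (is.null(thr)) return(events)
  }
  out <- events[events$viability_dye < thr, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("all events fall above the viability threshold (all-dead well)")
  }
  out
}

#' Derive a positivity threshold from an FMO control
#'
#' The threshold for a channel is the `fmo_quantile` quantile of that channel
#' among the gated (singlet, viable) events of the control well lacking the
#' corresponding stain.
#'
#' @param fmo_events Event table of the FMO well, already gated for singlets
#'   and viability.
#' @param channel Channel column name, e.g. `"reporter"` or `"surface_label"`.
#' @param config A [gating_config()].
#' @return Threshold in channel units.
#' @export
derive_fmo_threshold <- function(fmo_events, channel, config = gating_config()) {
  assert_events(fmo_events, channel)
  if (nrow(fmo_events) < 100) {
    stop(sprintf("too few gated FMO events (%d < 100) to derive a '%s' threshold",
                 nrow(fmo_events), channel))
  }
  unname(stats::quantile(fmo_events[[channel]], config$fmo_quantile, type = 7))
}

#' Gate positive events in a channel
#'
#' Keeps events whose channel value is strictly greater than the threshold
#' (ties at the threshold are negative).
#'
#' @param events Event table.
#' @param channel Channel column name.
#' @param threshold Positivity threshold.
#' @return The filtered event table.
#' @export
gate_positive <- function(events, channel, threshold) {
  assert_events(events, channel)
  events[events[[channel]] > threshold, , drop = FALSE]
}

#' Median fluorescence intensity of a channel
#'
#' @param events Event table.
#' @param channel Channel column name.
#' @return The exact median (mean of the central pair for an even count).
#' @export
median_intensity <- function(events, channel) {
  assert_events(events, channel)
  stats::median(events[[channel]])
}

#' Summarize one well: gating chain plus MFI extraction
#'
#' Applies singlets -> viable -> positivity on the gating channel, then takes
#' the median of the analysis channel. Also records, for surface wells, the
#' fraction of reporter-positive cells that are surface-label positive, and
#' the MFI under the alternate gate (positivity on the analysis channel
#' itself), which mirrors gating on the antibody signal instead of the
#' transfection reporter.
#'
#' @param events Event table for one well.
#' @param gating_config A [gating_config()].
#' @param analysis_channel Channel whose MFI is reported (e.g.
#'   `"surface_label"` or `"uptake_label"`).
#' @param gate_channel Channel used for the positivity gate (default the
#'   transfection reporter).
#' @param gate_threshold Positivity threshold for `gate_channel` (from
#'   [derive_fmo_threshold()]).
#' @param alt_threshold Optional positivity threshold for `analysis_channel`;
#'   when supplied, `fraction_positive_in_alt_gate` and `mfi_alt_gate` are
#'   computed.
#' @return A one-row `data.frame` (a well measurement) with columns
#'   `variant_id`, `assay`, `experiment_id`, `replicate`, `mfi`, `n_gated`,
#'   `fraction_positive_in_alt_gate`, `mfi_alt_gate`, `flagged`.
#' @export
summarize_well <- function(events, gating_config = ldlrflow::gating_config(),
                           analysis_channel, gate_channel = "reporter",
                           gate_threshold, alt_threshold = NULL) {
  assert_events(events, c("fsc_a", "fsc_h", "viability_dye",
                          analysis_channel, gate_channel))
  meta <- events[1, c("variant_id", "assay", "experiment_id", "replicate")]
  gated <- gate_viable(gate_singlets(events, gating_config), gating_config)
  pos <- gate_positive(gated, gate_channel, gate_threshold)

  frac_alt <- NA_real_
  mfi_alt <- NA_real_
  if (!is.null(alt_threshold)) {
    if (nrow(pos) > 0) {
      frac_alt <- mean(pos[[analysis_channel]] > alt_threshold)
    }
    alt <- gate_positive(gated, analysis_channel, alt_threshold)
    if (nrow(alt) > 0) mfi_alt <- median_intensity(alt, analysis_channel)
  }
  flagged <- nrow(pos) == 0
  if (flagged) {
    warning(sprintf("well %s/%s e%d r%d: zero gated events; measurement flagged",
                    meta$variant_id, meta$assay, meta$experiment_id, meta$replicate))
  }
  data.frame(
    meta,
    mfi = if (flagged) NA_real_ else median_intensity(pos, analysis_channel),
    n_gated = nrow(pos),
    fraction_positive_in_alt_gate = frac_alt,
    mfi_alt_gate = mfi_alt,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}
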