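#' Mature-to-precursor band ratio of one lane
#'
#' Relates the raw volume of the 160 kDa (mature, Golgi-glycosylated) LDLR
#' band to the 120 kDa (precursor, ER) band.
#'
#' @param volume_mature,volume_precursor Raw band volumes (a.u.).
#' @return The ratio; `NaN` with class note when the precursor band is zero
#'   but the mature band is not (undefined ratio), `NA` when both are zero
#'   (nothing to quantify).
#' @export
mature_precursor_ratio <- function(volume_mature, volume_precursor) {
  stopifnot(volume_mature >= 0, volume_precursor >= 0)
  if (volume_precursor == 0) {
    if (volume_mature == 0) return(NA_real_)
    return(NaN)  # mature band with no precursor: ratio undefined
  }
  volume_mature / volume_precursor
}

#' Semiquantitative protein-expression call from band volumes
#'
#' Transfection-efficiency variation prevents normalizing LDLR band volumes to
#' a loading control, so expression is judged semiquantitatively: the combined
#' LDLR band volume of a lane relative to the reference lane is mapped to
#' NORMAL / FAINT / NEARLY_ABSENT. A lane showing only a truncated band is
#' called TRUNCATED_ONLY.
#'
#' @param volume_mature,volume_precursor,volume_truncated Raw band volumes.
#' @param reference_total Combined LDLR band volume of the reference lane.
#' @param faint_fraction Totals below this fraction of the reference are FAINT.
#' @param absent_fraction Totals below this fraction are NEARLY_ABSENT.
#' @return One of `"NORMAL"`, `"FAINT"`, `"NEARLY_ABSENT"`, `"TRUNCATED_ONLY"`.
#' @export
call_expression <- function(volume_mature, volume_precursor,
                            volume_truncated = 0, reference_total,
                            faint_fraction = 0.15, absent_fraction = 0.02) {
  stopifnot(reference_total > 0, absent_fraction < faint_fraction)
  full_length <- volume_mature + volume_precursor
  if (volume_truncated > 0 && full_length == 0) return("TRUNCATED_ONLY")
  rel <- (full_length + volume_truncated) / reference_total
  if (rel < absent_fraction) "NEARLY_ABSENT"
  else if (rel < faint_fraction) "FAINT"
  else "NORMAL"
}

#' Summarize densitometry replicates for one variant
#'
#' Computes the per-replicate mature-to-precursor ratios, their mean and
#' sample SD, and the expression call. The ratio is reported as NOT_ANALYZED
#' for truncated-only products and for lanes too weak to quantify (both the
#' stricter of the two semiquantitative defect calls).
#'
#' @param samples `data.frame` of lanes for one variant with columns
#'   `volume_mature`, `volume_precursor`, `volume_truncated` (see
#'   [simulate_densitometry()]).
#' @param reference_total Mean combined LDLR volume of the reference lanes.
#' @param faint_fraction,absent_fraction Cutoffs passed to [call_expression()].
#' @return One-row `data.frame`: `variant_id`, `ratio_mean`, `ratio_sd`,
#'   `n_replicates`, `expression_call`, `ratio_analyzed`.
#' @export
maturation_result <- function(samples, reference_total,
                              faint_fraction = 0.15, absent_fraction = 0.02) {
  stopifnot(nrow(samples) >= 1)
  calls <- vapply(seq_len(nrow(samples)), function(i) {
    call_expression(samples$volume_mature[i], samples$volume_precursor[i],
                    samples$volume_truncated[i], reference_total,
                    faint_fraction, absent_fraction)
  }, character(1))
  # majority call across lanes; ties resolved toward the more severe call
  severity_order <- c("NORMAL", "FAINT", "NEARLY_ABSENT", "TRUNCATED_ONLY")
  tab <- table(factor(calls, levels = severity_order))
  top <- max(tab)
  call <- severity_order[max(which(tab == top))]

  # faint or weaker bands are too weak for a reliable ratio
  analyzed <- call == "NORMAL"
  if (analyzed) {
    ratios <- vapply(seq_len(nrow(samples)), function(i) {
      mature_precursor_ratio(samples$volume_mature[i], samples$volume_precursor[i])
    }, numeric(1))
    ratios <- ratios[is.finite(ratios)]
  } else {
    ratios <- numeric(0)
  }
  data.frame(
    variant_id = samples$variant_id[1],
    ratio_mean = if (length(ratios)) mean(ratios) else NA_real_,
    ratio_sd = if (length(ratios) > 1) stats::sd(ratios) else NA_real_,
    n_replicates = nrow(samples),
    expression_call = call,
    ratio_analyzed = analyzed && length(ratios) > 0,
    stringsAsFactors = FALSE
  )
}
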