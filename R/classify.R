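#' Severity and criterion thresholds
#'
#' Band edges for the four-level severity grading of each assay and the
#' functional-evidence cutoffs. Surface expression: >90% normal, 70--90% gray
#' zone, 10--69% slight/moderate defect, <10% severe. LDL internalization:
#' >95% normal, 80--95% gray, 40--79% moderate, <40% severe. Mature-to-
#' precursor ratio: >2.0 normal, 0.2--2.0 moderate, <0.2 severe. The
#' functional-evidence cutoffs (<70% defect, >90% normal) follow the
#' LDLR-specific ACMG/AMP specifications.
#'
#' Boundary conventions: a value exactly at 90% surface is GRAY (not normal);
#' exactly 70% does not qualify as a functional defect (the criterion is
#' "below 70%"); the internalization moderate band is closed at 40 and open
#' at 80.
#'
#' @param surface_normal_gt,surface_gray_ge,surface_severe_lt Surface band
#'   edges (percent).
#' @param internalization_normal_gt,internalization_gray_ge,internalization_severe_lt
#'   Internalization band edges (percent).
#' @param ratio_normal_gt,ratio_severe_lt Maturation-ratio band edges.
#' @param acmg_defect_lt,acmg_normal_gt Functional-evidence cutoffs (percent).
#' @return An object of class `"classification_thresholds"`.
#' @export
classification_thresholds <- function(surface_normal_gt = 90,
                                      surface_gray_ge = 70,
                                      surface_severe_lt = 10,
                                      internalization_normal_gt = 95,
                                      internalization_gray_ge = 80,
                                      internalization_severe_lt = 40,
                                      ratio_normal_gt = 2.0,
                                      ratio_severe_lt = 0.2,
                                      acmg_defect_lt = 70,
                                      acmg_normal_gt = 90) {
  th <- as.list(environment())
  stopifnot(th$surface_severe_lt < th$surface_gray_ge,
            th$surface_gray_ge < th$surface_normal_gt,
            th$internalization_severe_lt < th$internalization_gray_ge,
            th$internalization_gray_ge < th$internalization_normal_gt,
            th$ratio_severe_lt < th$ratio_normal_gt)
  structure(th, class = "classification_thresholds")
}

severity_levels <- c("NORMAL", "GRAY", "MODERATE", "SEVERE")

#' Ordinal rank of a severity level
#'
#' NORMAL = 0, GRAY = 0.5, MODERATE = 1, SEVERE = 2; `NA` for level `"NA"` or
#' missing. The half-rank for the gray zone keeps a gray-zone surface result
#' combined with normal internalization from triggering the
#' binding/internalization rule.
#'
#' @param level Character severity level(s).
#' @return Numeric rank(s).
#' @export
severity_rank <- function(level) {
  ranks <- c(NORMAL = 0, GRAY = 0.5, MODERATE = 1, SEVERE = 2)
  unname(ranks[as.character(level)])
}

grade_banded <- function(value, normal_gt, gray_ge, severe_lt) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v > normal_gt) "NORMAL"
    else if (v >= gray_ge) "GRAY"
    else if (v >= severe_lt) "MODERATE"
    else "SEVERE"
  }, character(1))
}

#' Grade assay results into severity levels
#'
#' `grade_surface()` and `grade_internalization()` grade percent-of-reference
#' values from the two flow-cytometry assays; `grade_ratio()` grades the
#' Western-blot mature-to-precursor ratio (which has no gray zone).
#'
#' @param percent Percent of the benign reference (surface or internalization).
#' @param thresholds A [classification_thresholds()].
#' @return Character severity level(s): `"NORMAL"`, `"GRAY"`, `"MODERATE"`,
#'   `"SEVERE"`, or `NA` for missing input.
#' @examples
#' grade_surface(90)  # "GRAY": exactly at the edge is ambiguous
#' grade_surface(3)   # "SEVERE"
#' grade_ratio(1.33)  # "MODERATE"
#' @export
grade_surface <- function(percent, thresholds = classification_thresholds()) {
  grade_banded(percent, thresholds$surface_normal_gt,
               thresholds$surface_gray_ge, thresholds$surface_severe_lt)
}

#' @rdname grade_surface
#' @export
grade_internalization <- function(percent, thresholds = classification_thresholds()) {
  grade_banded(percent, thresholds$internalization_normal_gt,
               thresholds$internalization_gray_ge,
               thresholds$internalization_severe_lt)
}

#' @rdname grade_surface
#' @param ratio Mature-to-precursor band-volume ratio.
#' @export
grade_ratio <- function(ratio, thresholds = classification_thresholds()) {
  vapply(ratio, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v > thresholds$ratio_normal_gt) "NORMAL"
    else if (v >= thresholds$ratio_severe_lt) "MODERATE"
    else "SEVERE"
  }, character(1))
}

#' Infer LDLR variant classes from assay severities
#'
#' Applies the decision rules combining the three assays, in order:
#' 1. a truncated-only product is class 1 (with a nonsense-mediated-decay
#'    caveat: the intron-less expression construct cannot trigger NMD);
#' 2. faint or nearly absent protein together with any surface defect points
#'    to reduced protein levels rather than a transport defect;
#' 3. a severe surface defect with normal protein expression is class 2a; a
#'    moderate surface defect is class 2b/5 (maturation and recycling defects
#'    are indistinguishable here);
#' 4. internalization at least one severity rank worse than surface adds a
#'    binding/internalization defect (class 3/4, not further separable);
#' 5. no moderate-or-worse defect anywhere is no defect, with a note when the
#'    surface result sits in the gray zone; a gray-zone internalization
#'    result alone leaves the call indeterminate;
#' 6. anything else is indeterminate.
#'
#' @param surface,internalization,maturation Severity levels (`"NORMAL"`,
#'   `"GRAY"`, `"MODERATE"`, `"SEVERE"` or `NA`).
#' @param expression_call Semiquantitative expression call (see
#'   [call_expression()]); `NA` is treated as normal expression with a note.
#' @param variant_id Optional label carried into the result.
#' @return A list of class `"functional_class_call"` with fields
#'   `variant_id`, `surface`, `internalization`, `maturation`,
#'   `expression_call`, `classes` (character vector), `notes`.
#' @export
infer_classes <- function(surface, internalization, maturation = NA,
                          expression_call = "NORMAL",
                          variant_id = NA_character_) {
  notes <- character(0)
  classes <- character(0)
  expr <- if (is.na(expression_call)) {
    notes <- c(notes, "expression not assessed; assuming normal protein levels")
    "NORMAL"
  } else expression_call

  result <- function(classes, notes) {
    structure(list(variant_id = variant_id, surface = surface,
                   internalization = internalization, maturation = maturation,
                   expression_call = expression_call,
                   classes = classes, notes = notes),
              class = "functional_class_call")
  }

  # (1) truncated product
  if (expr == "TRUNCATED_ONLY") {
    return(result("CLASS_1", c(notes,
      "truncated product; in vivo NMD would likely abolish expression (intron-less construct prevents NMD)")))
  }

  surf_rank <- severity_rank(surface)
  int_rank <- severity_rank(internalization)

  # (2) reduced protein levels
  if (expr %in% c("NEARLY_ABSENT", "FAINT") &&
      !is.na(surf_rank) && surf_rank >= 1) {
    return(result("REDUCED_PROTEIN", c(notes,
      "surface defect attributable to reduced total LDLR protein")))
  }

  # (3) transport defect classes from the surface assay
  if (!is.na(surf_rank)) {
    if (surface == "SEVERE" && expr == "NORMAL") classes <- c(classes, "CLASS_2A")
    if (surface == "MODERATE") classes <- c(classes, "CLASS_2B_5")
  } else {
    notes <- c(notes, "surface severity unavailable; transport-class rule skipped")
  }

  # (4) disproportionate internalization defect
  if (!is.na(surf_rank) && !is.na(int_rank)) {
    if (int_rank - surf_rank >= 1) classes <- c(classes, "CLASS_3_4")
  } else if (is.na(int_rank)) {
    notes <- c(notes, "internalization severity unavailable; binding/internalization rule skipped")
  }

  if (length(classes)) return(result(classes, notes))

  # (5) no defect
  defect_ranks <- c(surf_rank, int_rank, severity_rank(maturation))
  any_defect <- any(defect_ranks >= 1, na.rm = TRUE)
  if (!any_defect) {
    if (!is.na(int_rank) && internalization == "GRAY") {
      return(result("INDETERMINATE", c(notes,
        "gray-zone internalization with no other defect")))
    }
    if (!is.na(surf_rank) && surface == "GRAY") {
      notes <- c(notes, "gray-zone surface expression; otherwise normal")
    }
    return(result("NO_DEFECT", notes))
  }

  # (6)
  result("INDETERMINATE", c(notes, "assay pattern fits no single rule"))
}

#' Assign the PS3/BS3 functional-evidence criterion
#'
#' PS3 (strong pathogenic evidence) requires a functional defect: surface
#' expression or LDL internalization below the defect cutoff. BS3 (strong
#' benign evidence) requires both assays above the normal cutoff. Values
#' exactly at a cutoff qualify for neither. PS3 and BS3 are mutually
#' exclusive by construction. The final clinical classification is not
#' computed: it depends on evidence beyond the functional study, so the
#' result carries only an advisory.
#'
#' @param surface_percent,internalization_percent Percent-of-reference assay
#'   results.
#' @param thresholds A [classification_thresholds()].
#' @param prior Prior clinical classification, one of `"B"`, `"LB"`, `"VUS"`,
#'   `"LP"`, `"P"` (optional).
#' @param variant_id Optional label.
#' @return A list of class `"acmg_assessment"` with `variant_id`, `criterion`
#'   (`"PS3"`, `"BS3"` or `"NONE"`), `prior_classification`, `advisory`.
#' @export
assign_ps3_bs3 <- function(surface_percent, internalization_percent,
                           thresholds = classification_thresholds(),
                           prior = NA_character_, variant_id = NA_character_) {
  s <- surface_percent
  i <- internalization_percent
  criterion <- "NONE"
  if ((!is.na(s) && s < thresholds$acmg_defect_lt) ||
      (!is.na(i) && i < thresholds$acmg_defect_lt)) {
    criterion <- "PS3"
  } else if (!is.na(s) && !is.na(i) &&
             s > thresholds$acmg_normal_gt && i > thresholds$acmg_normal_gt) {
    criterion <- "BS3"
  }
  advisory <- switch(criterion,
    PS3 = if (identical(prior, "VUS")) {
      "VUS+PS3: eligible for upgrade toward likely pathogenic"
    } else "PS3 supports pathogenicity; combine with other criteria",
    BS3 = if (identical(prior, "VUS")) {
      "VUS+BS3: eligible for downgrade toward likely benign"
    } else "BS3 supports benignity; combine with other criteria",
    NONE = "functional results do not meet the PS3 or BS3 cutoffs"
  )
  structure(list(variant_id = variant_id, criterion = criterion,
                 prior_classification = prior, advisory = advisory),
            class = "acmg_assessment")
}

#' Tally a panel of classified variants
#'
#' @param calls List of [infer_classes()] results.
#' @param assessments Optional list of [assign_ps3_bs3()] results (parallel to
#'   `calls`).
#' @return A list of counts: `n_variants`, `n_no_defect`, `n_both_defect`
#'   (surface and internalization each moderate or worse), `n_class2`
#'   (class 2a or 2b/5), `n_class2_with_34` (class 3/4 flags within the
#'   class-2 group), `n_class34` (all class 3/4 flags), `n_deleterious` (at
#'   least one flow assay moderate or worse), `n_ps3`, `n_bs3`, `n_none`, and
#'   `criterion_by_prior` (criterion x prior classification table).
#' @export
summarize_panel <- function(calls, assessments = NULL) {
  get_rank <- function(call, field) severity_rank(call[[field]])
  has_class <- function(call, cls) any(cls %in% call$classes)

  surf <- vapply(calls, get_rank, numeric(1), "surface")
  intr <- vapply(calls, get_rank, numeric(1), "internalization")
  both <- !is.na(surf) & surf >= 1 & !is.na(intr) & intr >= 1
  any_flow <- (!is.na(surf) & surf >= 1) | (!is.na(intr) & intr >= 1)
  class2 <- vapply(calls, has_class, logical(1), c("CLASS_2A", "CLASS_2B_5"))
  class34 <- vapply(calls, has_class, logical(1), "CLASS_3_4")
  no_defect <- vapply(calls, has_class, logical(1), "NO_DEFECT")

  out <- list(
    n_variants = length(calls),
    n_no_defect = sum(no_defect),
    n_both_defect = sum(both),
    n_class2 = sum(class2),
    n_class2_with_34 = sum(class2 & class34),
    n_class34 = sum(class34),
    n_deleterious = sum(any_flow)
  )
  if (!is.null(assessments)) {
    crit <- vapply(assessments, `[[`, character(1), "criterion")
    prior <- vapply(assessments, function(a) {
      p <- a$prior_classification
      if (is.na(p)) "unknown" else p
    }, character(1))
    out$n_ps3 <- sum(crit == "PS3")
    out$n_bs3 <- sum(crit == "BS3")
    out$n_none <- sum(crit == "NONE")
    out$criterion_by_prior <- table(criterion = crit, prior = prior)
  }
  out
}

#' The built-in LDLR variant panel
#'
#' Loads the packaged panel of 26 LDLR variants: 16 variants studied in
#' heterologous CHO cells plus 10 class controls, with their assay outcomes
#' (percent of the benign reference where a value was printed; severity
#' levels; semiquantitative expression calls) and prior clinical
#' classifications. Percentages not individually reported are mid-band values
#' consistent with the reported severity, tagged `estimated` in the
#' source columns.
#'
#' @param role Optional filter: `"studied"` or `"control"`.
#' @return A `data.frame`, one row per variant.
#' @export
ldlr_panel <- function(role = NULL) {
  path <- system.file("extdata", "ldlr_variant_panel.tsv", package = "ldlrflow",
                      mustWork = TRUE)
  panel <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(role)) panel <- panel[panel$role == role, , drop = FALSE]
  panel
}

#' Classify a panel from recorded severities and percentages
#'
#' Fixture-values mode of the pipeline: skips the cytometry stages and feeds
#' recorded severity levels and percentages straight into class inference and
#' criterion assignment.
#'
#' @param panel A `data.frame` in the layout of [ldlr_panel()].
#' @param thresholds A [classification_thresholds()].
#' @return A list with `calls`, `assessments` (parallel lists) and `summary`
#'   (from [summarize_panel()]).
#' @export
classify_printed_panel <- function(panel, thresholds = classification_thresholds()) {
  calls <- lapply(seq_len(nrow(panel)), function(i) {
    infer_classes(panel$surface_severity[i], panel$internalization_severity[i],
                  panel$ratio_severity[i], panel$expression_call[i],
                  variant_id = panel$protein_change[i])
  })
  assessments <- lapply(seq_len(nrow(panel)), function(i) {
    assign_ps3_bs3(panel$surface_percent[i], panel$internalization_percent[i],
                   thresholds, prior = panel$prior_classification[i],
                   variant_id = panel$protein_change[i])
  })
  list(calls = calls, assessments = assessments,
       summary = summarize_panel(calls, assessments))
}
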