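test_that("severity grading honors the published band edges", {
  expect_equal(grade_surface(100), "NORMAL")
  expect_equal(grade_surface(90), "GRAY")   # exactly at the edge is ambiguous
  expect_equal(grade_surface(70), "GRAY")
  expect_equal(grade_surface(69.9), "MODERATE")
  expect_equal(grade_surface(10), "MODERATE")
  expect_equal(grade_surface(3), "SEVERE")

  expect_equal(grade_internalization(96), "NORMAL")
  expect_equal(grade_internalization(95), "GRAY")
  expect_equal(grade_internalization(80), "GRAY")
  expect_equal(grade_internalization(75), "MODERATE")
  expect_equal(grade_internalization(40), "MODERATE")
  expect_equal(grade_internalization(35), "SEVERE")

  expect_equal(grade_ratio(2.5), "NORMAL")
  expect_equal(grade_ratio(2.0), "MODERATE")
  expect_equal(grade_ratio(1.33), "MODERATE")
  expect_equal(grade_ratio(0.2), "MODERATE")
  expect_equal(grade_ratio(0.13), "SEVERE")
  expect_true(is.na(grade_ratio(NA)))
})

test_that("severity bands tile the axis and grading is monotone", {
  set.seed(5)
  pts <- c(runif(500, 0, 150), 0, 10, 40, 70, 80, 90, 95, 100)
  for (grader in list(grade_surface, grade_internalization)) {
    lv <- grader(pts)
    expect_true(all(lv %in% c("NORMAL", "GRAY", "MODERATE", "SEVERE")))
    ord <- order(pts)
    expect_true(all(diff(severity_rank(lv[ord])) <= 0 + 1e-12 |
                      diff(pts[ord]) == 0))
  }
  rv <- grade_ratio(c(runif(200, 0, 4), 0, 0.2, 2))
  expect_true(all(rv %in% c("NORMAL", "MODERATE", "SEVERE")))
})

test_that("class inference reproduces the canonical variant patterns", {
  # severe transport defect with normal protein: complete retention (2a)
  c2a <- infer_classes("SEVERE", "SEVERE", "SEVERE", "NORMAL")
  expect_equal(c2a$classes, "CLASS_2A")

  # normal surface with disproportionate internalization loss: binding defect
  c34 <- infer_classes("NORMAL", "MODERATE", "MODERATE", "NORMAL")
  expect_equal(c34$classes, "CLASS_3_4")

  # fully normal assays
  expect_equal(infer_classes("NORMAL", "NORMAL", "NORMAL", "NORMAL")$classes,
               "NO_DEFECT")

  # severe surface defect explained by missing protein, not retention
  red <- infer_classes("SEVERE", "SEVERE", NA, "NEARLY_ABSENT")
  expect_equal(red$classes, "REDUCED_PROTEIN")

  # truncated product
  c1 <- infer_classes("SEVERE", "SEVERE", NA, "TRUNCATED_ONLY")
  expect_equal(c1$classes, "CLASS_1")
  expect_match(paste(c1$notes, collapse = " "), "NMD")

  # moderate surface defect with a worse internalization defect
  both <- infer_classes("MODERATE", "SEVERE", "MODERATE", "NORMAL")
  expect_setequal(both$classes, c("CLASS_2B_5", "CLASS_3_4"))

  # gray-zone surface with otherwise normal assays stays benign-like
  gray <- infer_classes("GRAY", "NORMAL", "NORMAL", "NORMAL")
  expect_equal(gray$classes, "NO_DEFECT")
  expect_match(paste(gray$notes, collapse = " "), "gray")

  # gray-zone surface must not trigger the binding/internalization rule
  expect_false("CLASS_3_4" %in% infer_classes("GRAY", "NORMAL", NA, "NORMAL")$classes)

  # missing inputs skip rules with a note instead of failing
  na_int <- infer_classes("MODERATE", NA, NA, "NORMAL")
  expect_equal(na_int$classes, "CLASS_2B_5")
  expect_match(paste(na_int$notes, collapse = " "), "internalization")
})

test_that("PS3/BS3 assignment follows the threshold semantics", {
  expect_equal(assign_ps3_bs3(100, 75)$criterion, "NONE")   # 75 is not below 70
  expect_equal(assign_ps3_bs3(90, 97)$criterion, "NONE")    # 90 is not above 90
  expect_equal(assign_ps3_bs3(95, 98)$criterion, "BS3")
  expect_equal(assign_ps3_bs3(3, 35)$criterion, "PS3")
  expect_equal(assign_ps3_bs3(100, 60)$criterion, "PS3")    # either assay suffices
  expect_equal(assign_ps3_bs3(70, 70)$criterion, "NONE")    # boundary fails both

  # never both, over random inputs
  set.seed(11)
  for (i in 1:500) {
    a <- assign_ps3_bs3(runif(1, 0, 130), runif(1, 0, 130))
    expect_true(a$criterion %in% c("PS3", "BS3", "NONE"))
  }
  vus <- assign_ps3_bs3(3, 35, prior = "VUS")
  expect_match(vus$advisory, "likely pathogenic")
})

test_that("the built-in panel classifies to the published tallies", {
  panel <- ldlr_panel()
  expect_equal(nrow(panel), 26)
  expect_equal(sum(panel$role == "studied"), 16)
  expect_equal(sum(panel$role == "control"), 10)

  studied <- classify_printed_panel(ldlr_panel("studied"))
  s <- studied$summary
  expect_equal(s$n_no_defect, 2)
  expect_equal(s$n_both_defect, 13)
  expect_equal(s$n_class2, 11)
  expect_equal(s$n_class2_with_34, 4)
  expect_equal(s$n_class34, 5)
  expect_equal(s$n_deleterious, 14)
  expect_equal(s$n_ps3, 13)
  expect_equal(s$n_bs3, 1)
  expect_equal(s$n_none, 2)

  # benign controls carry no defect class
  controls <- classify_printed_panel(ldlr_panel("control"))
  benign_idx <- which(ldlr_panel("control")$control_class == "benign")
  for (i in benign_idx) {
    expect_equal(controls$calls[[i]]$classes, "NO_DEFECT")
  }
  # the truncating control is class 1
  trunc_idx <- which(ldlr_panel("control")$control_class == "class1")
  expect_equal(controls$calls[[trunc_idx]]$classes, "CLASS_1")

  # empty panel: all counts zero
  empty <- summarize_panel(list())
  expect_equal(empty$n_variants, 0)
  expect_equal(empty$n_deleterious, 0)
})
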