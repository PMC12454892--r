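test_that("profiles and well specs validate their inputs", {
  expect_error(variant_effect_profile("v", surface_negative_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(variant_effect_profile("v", surface_factor = -0.1), ">= 0")
  expect_error(well_spec("v", "no_such_assay"), "unknown assay")
  benign <- variant_effect_profile("ref")
  expect_equal(benign$surface_factor, 1)
  expect_equal(benign$surface_negative_fraction, 0)
})

test_that("the same seed reproduces an event table bit for bit", {
  sp <- well_spec("v", "surface", seed = 99, n_events = 2000)
  prof <- variant_effect_profile("v", surface_factor = 0.5)
  expect_identical(simulate_events(sp, prof), simulate_events(sp, prof))
  sp2 <- well_spec("v", "surface", seed = 100, n_events = 2000)
  expect_false(identical(simulate_events(sp, prof), simulate_events(sp2, prof)))
})

test_that("mixture fractions track their configured probabilities", {
  prof <- variant_effect_profile("ref")
  fracs <- vapply(1:5, function(s) {
    ev <- simulate_events(well_spec("ref", "surface", seed = s), prof)
    c(mean(ev$is_transfected), mean(ev$is_doublet), mean(ev$is_dead))
  }, numeric(3))
  # 40,000 events: binomial SE ~0.2%, spec band +/-2%
  expect_true(all(abs(fracs[1, ] - 0.15) < 0.02))
  expect_true(all(abs(fracs[2, ] - 0.10) < 0.02))
  expect_true(all(abs(fracs[3, ] - 0.10) < 0.02))
})

test_that("zero expression collapses the surface signal onto the FMO background", {
  cfg <- simulation_config()
  null_prof <- variant_effect_profile("null", expression_factor = 0)
  stained <- simulate_events(well_spec("null", "surface", seed = 5), null_prof, cfg)
  fmo <- simulate_events(well_spec("ref", "fmo_no_antibody", seed = 6),
                         variant_effect_profile("ref"), cfg)
  # same log-normal family; stained receptor-free cells carry only the
  # nonspecific-binding shift relative to the unstained FMO background
  expect_equal(median(log(stained$surface_label)) - median(log(fmo$surface_label)),
               log(cfg$surface_nonspecific_factor), tolerance = 0.05)
  expect_equal(sd(log(stained$surface_label)), sd(log(fmo$surface_label)),
               tolerance = 0.02)
})

test_that("zero surface level leaves only receptor-independent uptake", {
  cfg <- simulation_config()
  no_surface <- variant_effect_profile("v", surface_factor = 0)
  ref <- variant_effect_profile("ref")
  ev_v <- simulate_events(well_spec("v", "internalization", seed = 7), no_surface, cfg)
  ev_r <- simulate_events(well_spec("ref", "internalization", seed = 8), ref, cfg)
  rel <- median(ev_v$uptake_label[ev_v$is_transfected]) /
    median(ev_r$uptake_label[ev_r$is_transfected])
  expect_equal(rel, cfg$uptake_background, tolerance = 0.03)
})

test_that("expected signals are monotone in the effect factors", {
  cfg <- simulation_config()
  surf_medians <- vapply(c(0, 0.05, 0.2, 0.5, 1, 2), function(f) {
    prof <- variant_effect_profile("v", surface_factor = f)
    ev <- simulate_events(well_spec("v", "surface", seed = 21, n_events = 20000), prof, cfg)
    median(ev$surface_label[ev$is_transfected])
  }, numeric(1))
  expect_true(all(diff(surf_medians) >= 0))
  up_medians <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(b) {
    prof <- variant_effect_profile("v", binding_internalization_factor = b)
    ev <- simulate_events(well_spec("v", "internalization", seed = 22, n_events = 20000),
                          prof, cfg)
    median(ev$uptake_label[ev$is_transfected])
  }, numeric(1))
  expect_true(all(diff(up_medians) >= 0))
})

test_that("simulate_experiment lays out wells, controls and day factors", {
  sim <- small_panel_sim(n_experiments = 3, n_events = 500)
  meta <- do.call(rbind, lapply(sim$events, function(e) e[1, c("variant_id", "assay", "experiment_id")]))
  # 2 variants x (3 surface + 2 uptake) wells x 3 experiments + 3 controls/experiment
  expect_equal(sum(meta$assay == "surface"), 3 * 2 * 3)
  expect_equal(sum(meta$assay == "internalization"), 3 * 2 * 2)
  expect_equal(sum(meta$assay %in% c("fmo_no_antibody", "fmo_no_reporter", "ldlr_deficient")),
               3 * 3)
  expect_length(sim$day_factors, 3)
  expect_error(simulate_experiment(list(variant_effect_profile("WT")), 1),
               "reference variant")
})

test_that("densitometry volumes encode the maturation split and truncation", {
  prof <- variant_effect_profile("v", mature_fraction = 2 / 3)
  lanes <- simulate_densitometry(prof, n_replicates = 200, seed = 31)
  expect_equal(mean(lanes$volume_mature / lanes$volume_precursor), 2.0,
               tolerance = 0.05)
  trunc <- simulate_densitometry(variant_effect_profile("t", truncated = TRUE),
                                 n_replicates = 3, seed = 32)
  expect_true(all(trunc$volume_truncated > 0))
  expect_true(all(trunc$volume_mature == 0 & trunc$volume_precursor == 0))
})

test_that("event CSV round-trips through the fixed header", {
  ev <- simulate_events(well_spec("v", "surface", seed = 41, n_events = 200),
                        variant_effect_profile("v"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_named(back, c("fsc_a", "fsc_h", "viability_dye", "reporter",
                       "surface_label", "uptake_label", "variant_id", "assay",
                       "experiment_id", "replicate"))
  expect_equal(back$surface_label, ev$surface_label)
  expect_error(write_events(back[, -1], path), "missing columns")
})
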