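test_that("singlet gate recovers the simulated singlets", {
  ev <- simulate_events(well_spec("v", "surface", seed = 1), variant_effect_profile("v"))
  kept <- gate_singlets(ev)
  expect_equal(nrow(kept) / nrow(ev), 1 - 0.10, tolerance = 0.02)
  expect_true(mean(kept$is_doublet) < 0.005)

  pure <- ev[!ev$is_doublet, , drop = FALSE]
  expect_gt(nrow(gate_singlets(pure)) / nrow(pure), 0.995)

  degenerate <- pure
  degenerate$fsc_a[1:5] <- 0
  expect_false(any(gate_singlets(degenerate)$fsc_a == 0))
  expect_error(gate_singlets(ev[0, ]), "empty")
})

test_that("viability gate splits live from dead on the dye valley", {
  ev <- simulate_events(well_spec("v", "surface", seed = 2), variant_effect_profile("v"))
  kept <- gate_viable(ev)
  expect_equal(nrow(kept) / nrow(ev), 1 - 0.10, tolerance = 0.02)
  expect_true(mean(kept$is_dead) < 0.01)

  # unimodal dye distribution: nothing to cut
  all_live <- ev
  all_live$viability_dye <- 0
  expect_equal(nrow(gate_viable(all_live)), nrow(ev))

  # a manual threshold is honored exactly
  manual <- gating_config(viability_threshold = 100)
  expect_true(all(gate_viable(ev, manual)$viability_dye < 100))
})

test_that("FMO thresholds are the configured quantile of the gated control", {
  const <- data.frame(fsc_a = 1, fsc_h = 1, reporter = rep(7, 500))
  expect_equal(derive_fmo_threshold(const, "reporter"), 7)

  unif <- data.frame(fsc_a = 1, fsc_h = 1, reporter = seq(0, 1, length.out = 10001))
  expect_equal(derive_fmo_threshold(unif, "reporter"), 0.999, tolerance = 1e-4)

  expect_error(derive_fmo_threshold(const[1:50, ], "reporter"), "too few")
})

test_that("positivity gate uses a strict threshold and matches the simulator", {
  ev <- simulate_events(well_spec("v", "surface", seed = 3), variant_effect_profile("v"))
  expect_equal(nrow(gate_positive(ev, "reporter", -1)), nrow(ev))
  expect_equal(nrow(gate_positive(ev, "reporter", max(ev$reporter))), 0)
  expect_equal(nrow(gate_positive(ev, "reporter", max(ev$reporter) - 1e-9)), 1)

  fmo <- gate_chain(simulate_events(well_spec("r", "fmo_no_reporter", seed = 4),
                                    variant_effect_profile("r")))
  thr <- derive_fmo_threshold(fmo, "reporter")
  gated <- gate_chain(ev)
  pos <- gate_positive(gated, "reporter", thr)
  expect_equal(nrow(pos) / nrow(gated), 0.15, tolerance = 0.02)
  expect_gt(mean(pos$is_transfected), 0.99)
})

test_that("median intensity is the exact sample median", {
  tbl <- function(x) data.frame(fsc_a = 1, fsc_h = 1, ch = x)
  expect_equal(median_intensity(tbl(c(1, 2, 3)), "ch"), 2)
  expect_equal(median_intensity(tbl(c(1, 2, 3, 10)), "ch"), 2.5)
  set.seed(8)
  x <- rlnorm(10001, 5, 1)
  expect_equal(median_intensity(tbl(x), "ch"), sort(x)[5001])
})

test_that("gates compose like brute-force row filters and are idempotent", {
  cfg <- gating_config(viability_threshold = 500)
  ev <- simulate_events(well_spec("v", "surface", seed = 5, n_events = 1000),
                        variant_effect_profile("v"))
  chained <- gate_positive(gate_viable(gate_singlets(ev, cfg), cfg), "reporter", 300)
  ratio <- ev$fsc_h / ev$fsc_a
  brute <- ev[ev$fsc_a > 0 & ratio >= 0.75 & ratio <= 1.25 &
                ev$viability_dye < 500 & ev$reporter > 300, ]
  expect_equal(chained, brute)

  once <- gate_singlets(ev, cfg)
  expect_equal(gate_singlets(once, cfg), once)
  viable <- gate_viable(ev, cfg)
  expect_equal(gate_viable(viable, cfg), viable)
})

test_that("well summaries hit the generator's configured medians", {
  cfg <- simulation_config()
  gcfg <- gating_config()
  ref <- variant_effect_profile("ref")
  fmo <- gate_chain(simulate_events(well_spec("ref", "fmo_no_reporter", seed = 6),
                                    ref, cfg))
  thr <- derive_fmo_threshold(fmo, "reporter", gcfg)
  ev <- simulate_events(well_spec("ref", "surface", seed = 7), ref, cfg)
  m <- summarize_well(ev, gcfg, "surface_label", "reporter", thr)
  expect_equal(m$mfi, exp(cfg$surface_pos_meanlog), tolerance = 0.10)
  expect_lte(m$n_gated, nrow(ev))

  # an FMO well analyzed for its omitted channel sits at background
  fmo_ab <- simulate_events(well_spec("ref", "fmo_no_antibody", seed = 8), ref, cfg)
  m_bg <- summarize_well(fmo_ab, gcfg, "surface_label", "reporter", thr)
  expect_equal(m_bg$mfi, exp(cfg$surface_bg_meanlog), tolerance = 0.10)
})

test_that("surface-channel gating hides a surface-negative subpopulation", {
  # the two-gate comparison: reporter gating sees the bimodal dip, antibody
  # gating reproduces the benign-like distribution of the remaining cells
  cmp <- fig4_comparison(surface_negative_fraction = 0.45, n_events = 20000, seed = 9)
  benign <- cmp[cmp$variant_id == "benign_reference", ]
  bimodal <- cmp[cmp$variant_id == "bimodal_variant", ]
  expect_lt(bimodal$mfi_reporter_gate, 0.5 * benign$mfi_reporter_gate)
  expect_equal(bimodal$mfi_surface_gate, benign$mfi_surface_gate, tolerance = 0.2)
  expect_gte(bimodal$mfi_surface_gate, bimodal$mfi_reporter_gate)
  expect_equal(bimodal$fraction_surface_positive, 0.55, tolerance = 0.05)

  # without a negative subpopulation the two gates agree
  uni <- fig4_comparison(surface_negative_fraction = 0, n_events = 20000, seed = 10)
  expect_equal(uni$mfi_surface_gate / uni$mfi_reporter_gate,
               rep(1, 2), tolerance = 0.1)

  # a fully surface-negative variant sits at background under reporter gating
  all_neg <- fig4_comparison(surface_negative_fraction = 1, n_events = 20000, seed = 11)
  bg <- simulation_config()
  expect_lt(all_neg$mfi_reporter_gate[2],
            exp(bg$surface_bg_meanlog) * bg$surface_nonspecific_factor * 2)
})
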