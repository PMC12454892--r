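# Shared helpers: gating chain shorthand and a compact simulated panel.

gate_chain <- function(events, config = gating_config()) {
  gate_viable(gate_singlets(events, config), config)
}

# A small three-variant panel (reference, WT, one test profile) simulated at
# reduced event counts so pipeline-level tests stay fast.
small_panel_sim <- function(test_profile = NULL, n_experiments = 3,
                            n_events = 4000, seed = 11,
                            config = simulation_config()) {
  profiles <- list(variant_effect_profile("p.(Ala391Thr)"),
                   variant_effect_profile("WT"))
  if (!is.null(test_profile)) profiles <- c(profiles, list(test_profile))
  simulate_experiment(profiles, n_experiments = n_experiments, config = config,
                      seed = seed, n_events = n_events)
}
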