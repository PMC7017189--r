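# small, well-separated cohort shared across tests
small_cohort <- function(seed = 11, n_pairs = 8, n_unpaired = 40) {
  cfg <- sim_config(n_pairs = n_pairs, n_unpaired_tumors = n_unpaired,
                    seed = seed)
  simulate_cohort(cfg, tempfile("cohort"))
}
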