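# shared fixtures, built once per test run
ref_net <- reference_network()
panel_variants <- h1299_panel(ref_net)
full_grid <- c(0, 1, 5, 10, 30, 120, 360)

sim_panel_observables <- function(egf_dose = 10, times = full_grid,
                                  variants = panel_variants) {
  rows <- lapply(names(variants), function(nm) {
    tr <- simulate_pathway(variants[[nm]],
                           stimulus_protocol(egf_dose = egf_dose,
                                             t_outputs = times))
    ob <- observables(tr, which = c("pEGFR", "pShc", "pMEK", "pERK"))
    ob$cell_line <- nm
    ob
  })
  do.call(rbind, rows)
}

# tiny noiseless synthetic configuration used by estimation tests
tiny_synth_config <- function(sigma = 0, seed = 42) {
  synthetic_config(network = ref_net,
                   cell_types = c("WT", "EGFR_WT", "L858R_A"),
                   doses = 10, times = c(0, 1, 5, 10, 30),
                   replicates = if (sigma > 0) 2 else 1,
                   sigma = sigma, seed = seed)
}

recovery_bounds <- function(names, width = 10) {
  gt <- c(default_parameters(),
          `mult:L858R_A:k3` = 0.15, `mult:L858R_A:k8` = 0.15)
  b <- cbind(gt[names] / width, pmin(gt[names] * width,
                                     ifelse(grepl("^mult", names), 0.999,
                                            Inf)))
  rownames(b) <- names
  b
}
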