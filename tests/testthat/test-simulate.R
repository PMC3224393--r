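test_that("the unstimulated state is stationary and phospho-free", {
  tr <- simulate_pathway(panel_variants$EGFR_WT,
                         stimulus_protocol(egf_dose = 0))
  expect_equal(max(abs(sweep(tr$states, 2, tr$states[1, ]))), 0)
  ob <- observables(tr, which = c("pEGFR", "pShc", "pMEK", "pERK"))
  expect_true(all(ob$value == 0))
})

test_that("compiled and interpreted engines agree", {
  for (nm in c("WT", "L858R_A")) {
    t1 <- simulate_pathway(panel_variants[[nm]],
                           stimulus_protocol(egf_dose = 10,
                                             t_outputs = c(0, 1, 5, 30)))
    t2 <- simulate_pathway(panel_variants[[nm]],
                           stimulus_protocol(egf_dose = 10,
                                             t_outputs = c(0, 1, 5, 30)),
                           engine = "interpreted")
    expect_lt(max(abs(t1$states - t2$states)), 1e-6)
  }
})

test_that("finite differences of a dense trajectory match the RHS", {
  v <- panel_variants$EGFR_WT
  h <- 1e-3
  tt <- seq(0, 3, by = h)
  tr <- simulate_pathway(v, stimulus_protocol(egf_dose = 10,
                                              t_outputs = tt))
  rhs <- build_rhs(ref_net)
  eff <- egfrpath:::.variant_effective(v, egf_dose = 10)
  idx <- c(500, 1500, 2500)  # interior points
  for (i in idx) {
    fd <- (tr$states[i + 1, ] - tr$states[i - 1, ]) / (2 * h)
    an <- rhs(tt[i], tr$states[i, ], eff$params)[[1]]
    scale <- pmax(abs(an), 1e-3 * max(abs(an)))
    expect_lt(max(abs(fd - an) / scale), 1e-3)
  }
})

test_that("moiety pools and the receptor audit are conserved along trajectories", {
  pools <- conservation_pools(ref_net)
  for (nm in names(panel_variants)) {
    tr <- simulate_pathway(panel_variants[[nm]],
                           stimulus_protocol(egf_dose = 10,
                                             t_outputs = seq(0, 360, 30)))
    st <- tr$states
    for (pn in names(pools$closed)) {
      tot <- rowSums(st[, pools$closed[[pn]], drop = FALSE])
      expect_lt((max(tot) - min(tot)) / max(tot[1], 1e-12), 1e-6,
                label = paste(nm, pn))
    }
    w <- pools$receptor
    audit <- as.vector(st[, names(w), drop = FALSE] %*% w)
    expect_lt((max(audit) - min(audit)) / audit[1], 1e-6)
    expect_true(all(st > -1e-8))
  }
})

test_that("solutions are converged with respect to solver tolerance", {
  v <- panel_variants$EGFR_WT
  a <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)),
                        rtol = 1e-8, atol = 1e-10)
  b <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)),
                        rtol = 5e-9, atol = 5e-11)
  rel <- abs(a$states[2, "ERKPP"] - b$states[2, "ERKPP"]) /
    a$states[2, "ERKPP"]
  expect_lt(rel, 1e-4)
})

test_that("observable mappings implement the antibody sums", {
  st <- matrix(0, nrow = 2, ncol = 27,
               dimnames = list(NULL, egfrpath:::.egfr_species_order))
  st[2, "MEKP"] <- 0.2; st[2, "MEKPP"] <- 0.5; st[2, "ShcP"] <- 3
  traj <- structure(list(times = c(0, 5), states = st, variant = "WT",
                         protocol = stimulus_protocol()),
                    class = "egfr_trajectory")
  ob <- observables(traj, which = c("pMEK", "pShc", "pERK"))
  expect_equal(ob$value[ob$protein == "pMEK" & ob$time == 5], 0.7)
  expect_equal(ob$value[ob$protein == "pShc" & ob$time == 5], 3)
  expect_equal(ob$value[ob$protein == "pERK" & ob$time == 5], 0)
  expect_error(observables(traj, which = "pAKT"), "unknown observable")

  # complexed ShcP forms make total pShc dominate free ShcP
  tr <- simulate_pathway(panel_variants$EGFR_WT, stimulus_protocol())
  pshc <- observables(tr, which = "pShc")$value
  expect_true(all(pshc >= tr$states[, "ShcP"] - 1e-12))

  # dimer weighting convention is configurable
  m2 <- phospho_observable_map(dimer_weight = 2)
  ob1 <- observables(tr, which = "pEGFR")
  ob2 <- observables(tr, which = "pEGFR", map = m2)
  expect_equal(ob2$value, 2 * ob1$value)
})

test_that("panel normalisation matches the western-blot procedure", {
  pan <- data.frame(
    cell_line = rep(c("a", "b"), each = 3),
    protein = "pERK", time = rep(c(0, 5, 10), 2),
    value = c(0, 2, 4, 0, 1, 2))
  out <- normalize_panel(pan)
  expect_equal(out$value, c(0, 0.5, 1, 0, 0.25, 0.5))
  expect_true(all(out$normalized))

  zero <- data.frame(cell_line = "a", protein = "pERK",
                     time = c(0, 5), value = c(0, 0))
  expect_equal(normalize_panel(zero)$value, c(0, 0))
  expect_error(normalize_panel(pan[0, ]), "empty")

  # nonzero baseline is subtracted before scaling
  pan$value <- pan$value + 1
  out2 <- normalize_panel(pan)
  expect_equal(out2$value, c(0, 0.5, 1, 0, 0.25, 0.5))

  # simulated three-cell-line panel: exactly one series attains 1 per protein
  ob <- sim_panel_observables(variants = panel_variants[c("WT", "EGFR_WT",
                                                          "L858R_A")])
  norm <- normalize_panel(ob, series_cols = "cell_line")
  for (pr in c("pEGFR", "pShc")) {
    hits <- norm[norm$protein == pr & norm$value == 1, ]
    expect_equal(nrow(hits), 1, label = pr)
    expect_equal(hits$cell_line, "EGFR_WT")
  }
})

test_that("dose response is zero without ligand and increases with dose", {
  dr <- dose_response(panel_variants$EGFR_WT, doses = c(0, 0.1, 10))
  expect_true(all(dr$value[dr$dose == 0] == 0))
  pe <- dr$value[dr$protein == "pEGFR"]
  expect_gt(pe[3], pe[2])
  expect_error(dose_response(panel_variants$WT, doses = -1), "non-negative")
})

test_that("gefitinib is applied as a k3 factor for the whole run", {
  p1 <- stimulus_protocol(gefitinib_alpha = 0.1)
  tr <- simulate_pathway(panel_variants$EGFR_WT, p1)
  # identical to multiplying k3 directly
  tr2 <- simulate_pathway(panel_variants$EGFR_WT,
                          stimulus_protocol(),
                          extra_multipliers = c(k3 = 0.1))
  expect_equal(tr$states, tr2$states, tolerance = 1e-12)
  expect_error(stimulus_protocol(gefitinib_alpha = 0), "alpha")
  expect_error(stimulus_protocol(gefitinib_alpha = 1.2), "alpha")
})
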