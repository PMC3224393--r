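test_that("alpha scans are anchored at 1 and pEGFR responds monotonically", {
  sc <- alpha_scan(panel_variants$EGFR_WT,
                   alphas = c(1, 0.1, 0.01, 5e-4))
  expect_true(all(sc$value[sc$alpha == 1] == 1))
  pe <- sc$value[sc$protein == "pEGFR"]
  expect_true(all(diff(pe) <= 0))  # alphas listed in decreasing order
  expect_true(all(sc$value >= 0))
  expect_error(alpha_scan(panel_variants$WT, alphas = c(2, 1)), "alphas")
})

test_that("the R index is 1 at equal factors and errors on a zero reference", {
  v <- panel_variants$EGFR_WT
  expect_equal(r_index(v, "pShc", alpha_on = 0.3, alpha_off = 0.3), 1)
  expect_error(r_index(v, "pShc", egf_dose = 0), "zero")
})

test_that("the R index equals its recomputation from cached trajectories", {
  v <- panel_variants$EGFR_WT
  r1 <- r_index(v, "pShc")
  t_on <- simulate_pathway(v, stimulus_protocol(gefitinib_alpha = 5e-4,
                                                t_outputs = c(0, 5)))
  t_off <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)))
  num <- observables(t_on, "pShc"); den <- observables(t_off, "pShc")
  r2 <- num$value[num$time == 5] / den$value[den$time == 5]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("parameter multipliers commute and compose with variants", {
  v <- panel_variants$EGFR_WT
  t1 <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)),
                         extra_multipliers = c(k3 = 0.2, k8 = 0.4))
  t2 <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)),
                         extra_multipliers = c(k8 = 0.4, k3 = 0.2))
  expect_identical(t1$states, t2$states)
  expect_error(simulate_pathway(v, stimulus_protocol(),
                                extra_multipliers = c(zz = 0.5)),
               "unknown parameter")

  # applying the L858R_A factors to the EGFR_WT model reproduces L858R_A
  mults <- default_variant_settings()$L858R_A$parameter_multipliers
  t3 <- simulate_pathway(v, stimulus_protocol(t_outputs = c(0, 5)),
                         extra_multipliers = mults)
  t4 <- simulate_pathway(panel_variants$L858R_A,
                         stimulus_protocol(t_outputs = c(0, 5)))
  expect_equal(t3$states, t4$states, tolerance = 1e-10)
})

test_that("pairwise index grids cover the six Mig6 pairs with exact corners", {
  pairs <- mig6_parameter_pairs()
  expect_length(pairs, 6)
  expect_setequal(vapply(pairs, paste, character(1), collapse = "&"),
                  c("k3&k5", "k3&k7", "k3&k8", "k5&k7", "k5&k8", "k7&k8"))

  g <- pairwise_index_grid(c("k3", "k8"), grid1 = c(1, 0.15),
                           grid2 = c(1, 0.15))
  base_idx <- sensitivity_ratio(panel_variants$EGFR_WT)
  expect_equal(g$index["1", "1"], base_idx, tolerance = 1e-10)

  # the fitted corner with k5, k7 fixed at the L858R_A factors equals the
  # full L858R_A model's index
  g2 <- pairwise_index_grid(c("k3", "k8"), grid1 = c(1, 0.15),
                            grid2 = c(1, 0.15),
                            fixed = c(k5 = 0.5, k7 = 0.5))
  full_idx <- sensitivity_ratio(panel_variants$L858R_A)
  expect_equal(g2$index["0.15", "0.15"], full_idx, tolerance = 1e-8)

  expect_error(pairwise_index_grid(c("k3", "k3"), 1, 1), "distinct")
  expect_error(pairwise_index_grid(c("k3", "k8"), c(0.5), c(1)),
               "factor 1")
})

test_that("downstream amplification covers the six readouts with unit corners", {
  grids <- downstream_amplification(grid3 = c(1, 0.15),
                                    grid8 = c(1, 0.15))
  expect_setequal(names(grids),
                  c("RasGTP", "Raf1A", "MEKP", "MEKPP", "ERKP", "ERKPP"))
  # at (1, 1) numerator and denominator contexts coincide across readouts:
  # the index is the EGFR-WT baseline ratio-of-ratios, identical however
  # it is recomputed
  v <- panel_variants$EGFR_WT
  up <- r_index(v, "E11P_ShcP_GS")
  for (y in names(grids))
    expect_equal(grids[[y]]$index["1", "1"], up / r_index(v, y),
                 tolerance = 1e-8, label = y)
})

test_that("inhibition inversion round-trips within 0.1 percentage points", {
  base <- egfrpath:::.readout_at(panel_variants$EGFR_WT, "ERKPP")
  for (target in c(10, 40)) {
    for (par in c("k3", "k8")) {
      inv <- invert_inhibition(par, target)
      expect_lt(inv$factor, 1)
      v <- egfrpath:::.readout_at(panel_variants$EGFR_WT, "ERKPP",
                                  multipliers = setNames(inv$factor, par))
      achieved <- 100 * (1 - v / base)
      expect_lt(abs(achieved - target), 0.1,
                label = sprintf("%s at %d%%", par, target))
    }
  }
  expect_equal(invert_inhibition("k3", 0)$factor, 1)
  expect_error(invert_inhibition("k3", 120), "target inhibition")
})

test_that("combination classification is additive at X = 0 and stable in eps", {
  res <- classify_combination(X_grid = c(0, 20), eps = 0.5)
  expect_equal(res$class[res$X == 0], "additive")
  expect_equal(res$k3_factor[res$X == 0], 1)
  expect_equal(res$combined_inhibition[res$X == 0], 0)

  # classification of a clear case is unchanged across eps in [0.25, 1]
  cl <- vapply(c(0.25, 0.5, 1), function(e)
    classify_combination(X_grid = 20, eps = e)$class, character(1))
  expect_length(unique(cl), 1)
})
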