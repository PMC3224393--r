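test_that("reference network has the declared structure", {
  expect_length(ref_net$reactions, 27)
  expect_equal(nrow(ref_net$species), 29)
  expect_equal(sum(ref_net$species$is_dynamic), 27)
  mm <- vapply(ref_net$reactions, function(r)
    r$law == "michaelis_menten", logical(1))
  expect_setequal(which(mm), c(4, 11, 15:27))
  expect_silent(validate_network(ref_net))
})

test_that("reaction fluxes follow their rate laws", {
  st <- setNames(rep(0, 29), ref_net$species$id)
  p <- ref_net$parameters

  # Michaelis-Menten half-saturation and 90%-saturation identities
  r4 <- ref_net$reactions[[4]]
  st["E11P"] <- p$values[["Km4"]]
  expect_equal(reaction_rate(r4, st, p), p$values[["V4"]] / 2)
  st["E11P"] <- 9 * p$values[["Km4"]]
  expect_equal(reaction_rate(r4, st, p), 0.9 * p$values[["V4"]])

  # catalysed MM flux is proportional to the modifier concentration
  r20 <- ref_net$reactions[[20]]
  st["MEK"] <- 50; st["Raf1A"] <- 2
  expect_equal(reaction_rate(r20, st, p),
               p$values[["kcat20"]] * 2 * 50 / (p$values[["Km20"]] + 50))

  # mass action forward term vanishes with any reactant at zero
  r1 <- ref_net$reactions[[1]]
  st["EGF"] <- 0; st["EGFR"] <- 100; st["Ra"] <- 0
  expect_equal(reaction_rate(r1, st, p), 0)
  st["Ra"] <- 3  # reverse term only
  expect_equal(reaction_rate(r1, st, p), -p$values[["kr1"]] * 3)

  # dimerisation is second order in the monomer
  r2 <- ref_net$reactions[[2]]
  st["Ra"] <- 4; st["E11"] <- 0
  expect_equal(reaction_rate(r2, st, p), p$values[["kf2"]] * 16)

  expect_error(reaction_rate(r4, st, c(V4 = 1)), "Km|subscript")
})

test_that("a frozen system (all rate constants zero) has zero derivatives", {
  rhs <- build_rhs(ref_net)
  p0 <- ref_net$parameters$values
  p0[] <- 0
  p0[grep("^Km", names(p0))] <- 1  # keep MM denominators positive
  y <- setNames(runif(27, 0, 10), .egfr_species_order)
  expect_equal(rhs(0, y, p0)[[1]], rep(0, 27))
})

test_that("conservation pools annihilate the stoichiometry matrix", {
  S <- stoichiometry_matrix(ref_net)
  pools <- conservation_pools(ref_net)
  expect_setequal(pools$closed$MEK, c("MEK", "MEKP", "MEKPP"))
  expect_setequal(pools$closed$ERK, c("ERK", "ERKP", "ERKPP"))
  for (nm in names(pools$closed)) {
    ind <- rownames(S) %in% pools$closed[[nm]]
    expect_equal(max(abs(colSums(S[ind, , drop = FALSE]))), 0,
                 info = nm)
  }
  # the receptor pool closes only once the degradation sink is counted
  w <- setNames(rep(0, nrow(S)), rownames(S))
  w[names(pools$receptor)] <- pools$receptor
  expect_equal(max(abs(as.vector(w %*% S))), 0)
  no_sink <- w; no_sink["EGFRdeg"] <- 0
  expect_gt(max(abs(as.vector(no_sink %*% S))), 0)
})

test_that("variants validate their settings and never mutate the base", {
  expect_error(make_variant("L858R_C", ref_net), "unknown variant")
  expect_error(make_variant("L858R_A", ref_net,
    list(initial_overrides = c(EGFR = 100),
         parameter_multipliers = c(k3 = 1.5, k5 = 0.5, k7 = 0.5,
                                   k8 = 0.5))), "multipliers")
  expect_error(make_variant("EGFR_WT", ref_net,
    list(initial_overrides = c(EGFR = -5))), "negative")
  expect_error(make_variant("WT", ref_net,
    list(initial_overrides = c(EGFR = 50))), "no overrides")

  wt <- make_variant("WT", ref_net)
  expect_length(wt$initial_overrides, 0)
  a <- make_variant("L858R_A", ref_net)
  expect_setequal(names(a$parameter_multipliers),
                  c("k3", "k5", "k7", "k8"))

  before <- ref_net$parameters$values
  invisible(simulate_pathway(a, stimulus_protocol(egf_dose = 10,
                                                  t_outputs = c(0, 5))))
  expect_identical(ref_net$parameters$values, before)
})

test_that("parameter sets enforce positivity and bounds", {
  expect_error(parameter_set(c(a = -1)), "positive")
  b <- cbind(low = c(a = 1), high = c(a = 2))
  expect_error(parameter_set(c(a = 5), b), "outside")
  ps <- parameter_set(c(a = 1.5), b)
  expect_equal(unname(ps$bounds[, "high"]), 2)
})

test_that("Michaelis-Menten flux approaches first-order mass action as Km grows", {
  # V/Km held fixed at 1/min while Km -> Inf; compare at S <= Km/100
  for (Km in c(1e3, 1e5)) {
    r <- .reaction(1, "michaelis_menten", c(E11P = 1), c(E11 = 1),
                   c(V = "V", Km = "Km"))
    S <- Km / 100
    flux <- reaction_rate(r, c(E11P = S, E11 = 0), c(V = Km * 1, Km = Km))
    expect_lt(abs(flux - S) / S, 1e-2)
  }
  Km <- 1e6
  r <- .reaction(1, "michaelis_menten", c(E11P = 1), c(E11 = 1),
                 c(V = "V", Km = "Km"))
  S <- Km / 1000
  flux <- reaction_rate(r, c(E11P = S, E11 = 0), c(V = Km, Km = Km))
  expect_lt(abs(flux - S) / S, 1e-3)
})
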