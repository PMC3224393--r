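test_that("the ERR objective is self-consistent and audits against brute force", {
  ds <- generate_dataset(tiny_synth_config(sigma = 0))
  meas <- dataset_measurements(ds)
  free <- recovery_bounds(c("k3", "kcat24"))
  spec <- objective_spec(meas, free, doses = 10, network = ref_net)

  truth <- c(k3 = default_parameters()[["k3"]],
             kcat24 = default_parameters()[["kcat24"]])
  expect_lt(err_objective(truth, spec), 1e-10)

  # brute-force re-summation over an independent double loop
  cand <- truth * c(2, 0.5)
  err <- err_objective(cand, spec)
  res <- err_objective(cand, spec, return_residuals = TRUE)
  brute <- 0
  for (i in seq_len(nrow(res)))
    brute <- brute + (res$value[i] - res$simulated[i])^2
  expect_equal(err, brute)
  expect_gt(err, 0)

  # single-observation arithmetic: (0.4 - 0.1)^2 = 0.09
  one <- res[1, ]
  one$value <- 0.4; one$simulated <- 0.1
  expect_equal((one$value - one$simulated)^2, 0.09)
})

test_that("solver failure yields the configured finite penalty", {
  ds <- generate_dataset(tiny_synth_config(sigma = 0))
  spec <- objective_spec(dataset_measurements(ds),
                         recovery_bounds("k3"), doses = 10,
                         network = ref_net, penalty = 1e6)
  # a parameter set violating positivity cannot be simulated
  expect_equal(err_objective(c(k3 = NA_real_), spec), 1e6)
})

test_that("problem decomposition partitions the stages", {
  a_names <- stage_parameters(ref_net, "A")
  b_names <- stage_parameters(ref_net, "B")
  expect_length(intersect(a_names, b_names), 0)
  expect_true(all(c("k3", "k8", "V4", "kcat15") %in% a_names))
  expect_true(all(c("kcat18", "kcat24", "V19") %in% b_names))

  ds <- generate_dataset(tiny_synth_config(sigma = 0))
  free <- recovery_bounds(c("k3", "k8", "kcat18", "kcat24",
                            "mult:L858R_A:k3"))
  spec <- objective_spec(dataset_measurements(ds), free, doses = 10,
                         network = ref_net)
  parts <- decompose_objective(spec)
  expect_setequal(rownames(parts$A$free_parameters),
                  c("k3", "k8", "mult:L858R_A:k3"))
  expect_setequal(rownames(parts$B$free_parameters),
                  c("kcat18", "kcat24"))
  expect_setequal(parts$A$proteins, c("pEGFR", "pShc"))
  expect_setequal(parts$B$proteins, c("pMEK", "pERK"))
  # stage-B spec owns no stage-A free parameter
  expect_length(intersect(rownames(parts$B$free_parameters), a_names), 0)
})

test_that("the genetic algorithm minimises, is elitist and deterministic", {
  sphere <- function(p) sum(log10(p)^2)
  b <- cbind(rep(0.01, 5), rep(100, 5))
  rownames(b) <- paste0("x", 1:5)
  cfg <- ga_config(seed = 7)  # default budget
  fit <- ga_minimize(sphere, b, cfg)
  expect_lt(fit$value, 1e-3)
  expect_true(all(diff(fit$trace$best) <= 0))

  fit2 <- ga_minimize(sphere, b, cfg)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$value, fit2$value)
  expect_identical(fit$trace, fit2$trace)

  fit3 <- ga_minimize(sphere, b, ga_config(seed = 8))
  expect_false(identical(fit3$par, fit2$par))

  expect_error(ga_minimize(sphere, b[0, , drop = FALSE]), "empty")
  expect_error(ga_config(pop_size = 2), "budget")
})

test_that("the GA does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(ga_minimize(function(p) sum(p), cbind(a = 0.1, b = 10),
                        ga_config(pop_size = 8, generations = 2)))
  expect_identical(runif(1), before)
})

test_that("a small noiseless fit recovers the generating parameters", {
  ds <- generate_dataset(tiny_synth_config(sigma = 0))
  free <- recovery_bounds(c("k3", "k8", "kcat18"), width = 5)
  spec <- objective_spec(dataset_measurements(ds), free, doses = 10,
                         network = ref_net)
  fit <- fit_pathway(spec,
                     config = ga_config(pop_size = 16, generations = 6,
                                        local_steps = 30, seed = 11))
  expect_s3_class(fit, "egfr_fit_result")
  # the reported objective equals the ERR recomputed from the residuals
  expect_equal(fit$value, sum(fit$residuals$residual^2))
  gt <- default_parameters()
  for (nm in c("k3", "k8", "kcat18"))
    expect_lt(abs(log10(fit$par[[nm]] / gt[[nm]])), log10(1.1) + 0.05,
              label = nm)
})
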