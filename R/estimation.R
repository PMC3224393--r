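## Parameter estimation: squared-error objective over the normalised
## phospho panel, upstream/downstream problem decomposition, and a
## diversity-controlled genetic algorithm with local search.

#' Parameters belonging to an estimation stage
#'
#' Stage A covers reaction steps 1-17 (receptor module through Ras),
#' stage B steps 18-27 (Raf-MEK-ERK cascade).
#'
#' @param network an \code{egfr_network}.
#' @param stage \code{"A"} or \code{"B"}.
#' @return Character vector of parameter names.
#' @export
stage_parameters <- function(network, stage = c("A", "B")) {
  stage <- match.arg(stage)
  steps <- if (stage == "A") 1:17 else 18:27
  unique(unlist(lapply(network$reactions, function(r)
    if (r$step %in% steps) unname(r$params))))
}

#' Objective specification for parameter estimation
#'
#' @param data normalised measurement table: columns cell_line, protein,
#'   dose, time, value (the output of \code{generate_dataset} or
#'   \code{read_dataset}).
#' @param free_parameters two-column matrix (low, high) of positive search
#'   bounds, rownames naming the free quantities.  Plain names refer to
#'   shared rate constants; \code{"mult:VARIANT:param"} frees a
#'   variant-specific multiplier and \code{"init:VARIANT:species"} a
#'   variant-specific initial concentration.
#' @param cell_types subset of the variant names present in the data.
#' @param proteins subset of pEGFR, pShc, pMEK, pERK.
#' @param time_points minutes after stimulation entering the residuals
#'   (default 1, 5, 10, 30).
#' @param doses EGF doses entering the objective (default all in data).
#' @param network base network (default \code{reference_network()}).
#' @param variant_settings per-variant settings (default
#'   \code{default_variant_settings()}).
#' @param stage \code{"A"}, \code{"B"} or \code{"joint"} (bookkeeping tag).
#' @param penalty finite objective value substituted on solver failure.
#' @return An object of class \code{egfr_objective}.
#' @export
objective_spec <- function(data, free_parameters,
                           cell_types = intersect(
                             c("WT", "EGFR_WT", "L858R_A", "L858R_B"),
                             unique(data$cell_line)),
                           proteins = c("pEGFR", "pShc", "pMEK", "pERK"),
                           time_points = c(1, 5, 10, 30),
                           doses = sort(unique(data$dose)),
                           network = reference_network(),
                           variant_settings = default_variant_settings(),
                           stage = "joint", penalty = 1e6) {
  stopifnot(all(c("cell_line", "protein", "dose", "time", "value") %in%
                  names(data)))
  free_parameters <- as.matrix(free_parameters)
  colnames(free_parameters) <- c("low", "high")
  if (any(free_parameters <= 0) ||
      any(free_parameters[, 1] >= free_parameters[, 2]))
    stop("free parameter bounds must be positive with low < high")
  data <- data[data$cell_line %in% cell_types & data$protein %in% proteins &
                 data$dose %in% doses, ]
  if (!nrow(data)) stop("no data rows match the specification")
  structure(list(data = data, free_parameters = free_parameters,
                 cell_types = cell_types, proteins = proteins,
                 time_points = time_points, doses = doses,
                 network = network, variant_settings = variant_settings,
                 stage = stage, penalty = penalty),
            class = "egfr_objective")
}

# apply a named candidate vector to (parameter set, variant settings)
.apply_candidate <- function(par, network, variant_settings) {
  vals <- network$parameters$values
  vs <- variant_settings
  for (nm in names(par)) {
    if (startsWith(nm, "mult:")) {
      f <- strsplit(nm, ":", fixed = TRUE)[[1]]
      vs[[f[2]]]$parameter_multipliers[[f[3]]] <- par[[nm]]
    } else if (startsWith(nm, "init:")) {
      f <- strsplit(nm, ":", fixed = TRUE)[[1]]
      vs[[f[2]]]$initial_overrides[[f[3]]] <- par[[nm]]
    } else {
      if (!nm %in% names(vals)) stop("unknown free parameter: ", nm)
      vals[[nm]] <- par[[nm]]
    }
  }
  net2 <- network
  net2$parameters <- parameter_set(vals, bounds = NULL)
  list(network = net2, variant_settings = vs)
}

# simulate the panel for a candidate and return it normalised per
# (protein, dose) across cell lines, on the union time grid of the data
.simulated_panel <- function(par, spec, ...) {
  mdl <- .apply_candidate(par, spec$network, spec$variant_settings)
  tgrid <- sort(unique(c(0, spec$data$time)))
  rows <- list()
  for (ct in spec$cell_types) {
    v <- make_variant(ct, mdl$network, mdl$variant_settings[[ct]])
    for (d in spec$doses) {
      tr <- simulate_pathway(v, stimulus_protocol(egf_dose = d,
                                                  t_outputs = tgrid), ...)
      ob <- observables(tr, which = spec$proteins)
      ob$cell_line <- ct
      ob$dose <- d
      rows[[length(rows) + 1L]] <- ob
    }
  }
  panel <- do.call(rbind, rows)
  # normalise per protein jointly across cell lines, within each dose
  out <- lapply(split(panel, panel$dose), normalize_panel,
                series_cols = c("cell_line", "dose"))
  do.call(rbind, out)
}

#' Squared-error objective over the normalised phospho panel
#'
#' Sum over cell types, proteins and time points of the squared difference
#' between the normalised data and the normalised simulation produced by
#' the candidate parameters.  Solver failures yield the configured finite
#' penalty.
#'
#' @param par named positive candidate values (natural scale) for the free
#'   quantities of the spec.
#' @param spec an \code{egfr_objective}.
#' @param return_residuals if TRUE, return the per-observation residual
#'   table instead of the scalar.
#' @param ... passed to \code{simulate_pathway}.
#' @return Non-negative scalar (or residual data frame).
#' @export
err_objective <- function(par, spec, return_residuals = FALSE, ...) {
  sim <- tryCatch(.simulated_panel(par, spec, ...), error = function(e) e)
  if (inherits(sim, "error")) {
    if (return_residuals) stop(sim)
    return(spec$penalty)
  }
  dat <- spec$data[spec$data$time %in% spec$time_points, ]
  key <- function(d) paste(d$cell_line, d$protein, d$dose, d$time,
                           sep = "\r")
  m <- match(key(dat), key(sim))
  if (anyNA(m)) stop("data rows without matching simulated observable")
  res <- dat
  res$simulated <- sim$value[m]
  res$residual <- res$value - res$simulated
  if (return_residuals) return(res)
  sum(res$residual^2)
}

#' Decompose an estimation problem into upstream and downstream stages
#'
#' Stage A frees only quantities of reaction steps 1-17 (plus any
#' variant-level multipliers/initials, which act upstream) with targets
#' pEGFR and pShc; stage B frees only step 18-27 parameters with targets
#' pMEK and pERK.  The stages are solved in order, upstream first, and the
#' stage-B search never touches a stage-A parameter.
#'
#' @param spec an \code{egfr_objective} whose free parameters partition
#'   cleanly into the two stages.
#' @return List with elements \code{A} and \code{B} (both
#'   \code{egfr_objective}s).
#' @export
decompose_objective <- function(spec) {
  pa <- stage_parameters(spec$network, "A")
  pb <- stage_parameters(spec$network, "B")
  nm <- rownames(spec$free_parameters)
  plain <- nm[!grepl(":", nm)]
  bad <- setdiff(plain, c(pa, pb))
  if (length(bad)) stop("free parameter in neither stage: ",
                        paste(bad, collapse = ", "))
  in_a <- nm %in% c(pa) | grepl(":", nm)
  in_b <- nm %in% pb
  if (any(in_a & in_b)) stop("free parameter appears in both stages")
  mk <- function(idx, prot, tag) {
    s <- spec
    s$free_parameters <- spec$free_parameters[idx, , drop = FALSE]
    s$proteins <- intersect(spec$proteins, prot)
    s$data <- spec$data[spec$data$protein %in% s$proteins, ]
    s$stage <- tag
    s
  }
  list(A = mk(in_a, c("pEGFR", "pShc"), "A"),
       B = mk(in_b, c("pMEK", "pERK"), "B"))
}

#' Genetic-algorithm configuration
#'
#' Knobs of the real-coded, log-scale genetic search with elitism,
#' tournament selection, blend crossover, per-gene Gaussian mutation,
#' Nelder-Mead local polish of the incumbent, and archive-based diversity
#' rejection (offspring falling within the diversity radius of an archived
#' solution, in normalised log space, are resampled).
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param p_cross per-gene blend-crossover probability.
#' @param p_mut per-gene mutation probability.
#' @param sd_mut mutation standard deviation in normalised log space.
#' @param elite_frac fraction of the population copied unchanged.
#' @param local_steps Nelder-Mead iterations applied to the incumbent per
#'   generation (0 disables local search).
#' @param diversity_radius rejection radius in normalised log space.
#' @param seed RNG seed recorded in every result.
#' @return List of class \code{egfr_ga_config}.
#' @export
ga_config <- function(pop_size = 40, generations = 30, p_cross = 0.9,
                      p_mut = 0.2, sd_mut = 0.15, elite_frac = 0.1,
                      local_steps = 50, diversity_radius = 0.02,
                      seed = 1) {
  cfg <- list(pop_size = pop_size, generations = generations,
              p_cross = p_cross, p_mut = p_mut, sd_mut = sd_mut,
              elite_frac = elite_frac, local_steps = local_steps,
              diversity_radius = diversity_radius, seed = seed)
  if (any(vapply(cfg, function(x) !is.numeric(x) || x < 0, logical(1))))
    stop("all GA configuration values must be non-negative numbers")
  if (pop_size < 4 || generations < 1) stop("GA budget too small")
  class(cfg) <- "egfr_ga_config"
  cfg
}

#' Minimise an objective with the diversity-controlled genetic algorithm
#'
#' Real-coded search on log10-transformed parameters within finite bounds.
#' Deterministic for a fixed seed.
#'
#' @param objective function taking a named positive parameter vector.
#' @param bounds two-column matrix (low, high), positive, with rownames.
#' @param config an \code{egfr_ga_config}.
#' @return List of class \code{egfr_fit}: \code{par} (named, natural
#'   scale), \code{value}, \code{trace} (per-generation best/median),
#'   \code{evals}, \code{config}.
#' @export
#' @examples
#' sphere <- function(p) sum((log10(p) - 0)^2)
#' b <- cbind(rep(0.01, 3), rep(100, 3))
#' rownames(b) <- paste0("x", 1:3)
#' fit <- ga_minimize(sphere, b, ga_config(pop_size = 20, generations = 10))
ga_minimize <- function(objective, bounds, config = ga_config()) {
  bounds <- as.matrix(bounds)
  if (!nrow(bounds)) stop("empty bounds")
  if (any(bounds <= 0)) stop("bounds must be positive (log-scale search)")
  lo <- log10(bounds[, 1]); hi <- log10(bounds[, 2])
  d <- length(lo); nm <- rownames(bounds)
  to_nat <- function(u) setNames(10^(lo + u * (hi - lo)), nm)
  evals <- 0L
  f <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    evals <<- evals + 1L
    objective(to_nat(u))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- config$pop_size
  pop <- matrix(runif(n * d), n, d)
  fit <- apply(pop, 1, f)
  elite_n <- max(1L, floor(n * config$elite_frac))
  archive <- NULL
  trace <- data.frame(generation = integer(0), best = numeric(0),
                      median = numeric(0))
  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]; fit <- fit[ord]
    # local polish of the incumbent
    if (config$local_steps > 0) {
      ls <- if (d == 1) {
        stats::optim(pop[1, ], f, method = "Brent", lower = 0, upper = 1)
      } else {
        stats::optim(pop[1, ], f, method = "Nelder-Mead",
                     control = list(maxit = config$local_steps))
      }
      if (ls$value < fit[1]) {
        pop[1, ] <- pmin(pmax(ls$par, 0), 1)
        fit[1] <- ls$value
      }
    }
    archive <- rbind(archive, pop[seq_len(elite_n), , drop = FALSE])
    newpop <- pop[seq_len(elite_n), , drop = FALSE]
    while (nrow(newpop) < n) {
      cand <- NULL
      for (try in 1:10) {
        i <- min(sample.int(n, 2)); j <- min(sample.int(n, 2))
        p1 <- pop[i, ]; p2 <- pop[j, ]
        cross <- runif(d) < config$p_cross
        w <- runif(d, -0.5, 1.5)
        child <- ifelse(cross, p1 + w * (p2 - p1), p1)
        mut <- runif(d) < config$p_mut
        child[mut] <- child[mut] + rnorm(sum(mut), 0, config$sd_mut)
        child <- pmin(pmax(child, 0), 1)
        dist <- sqrt(rowSums((archive - matrix(child, nrow(archive), d,
                                               byrow = TRUE))^2) / d)
        if (all(dist > config$diversity_radius)) { cand <- child; break }
      }
      if (is.null(cand)) cand <- child  # accept after repeated rejection
      newpop <- rbind(newpop, cand)
    }
    newfit <- c(fit[seq_len(elite_n)],
                apply(newpop[-seq_len(elite_n), , drop = FALSE], 1, f))
    pop <- newpop; fit <- newfit
    trace <- rbind(trace, data.frame(generation = g, best = min(fit),
                                     median = stats::median(fit)))
  }
  best <- which.min(fit)
  structure(list(par = to_nat(pop[best, ]), value = fit[best],
                 trace = trace, evals = evals, config = config),
            class = "egfr_fit")
}

#' Two-stage fit of the pathway model to a normalised dataset
#'
#' Runs the upstream stage (A: steps 1-17, targets pEGFR/pShc) and then
#' the downstream stage (B: steps 18-27, targets pMEK/pERK) with stage-A
#' winners frozen, or a joint single-stage fit.
#'
#' @param spec an \code{egfr_objective} covering all free parameters.
#' @param config an \code{egfr_ga_config}.
#' @param stage \code{"both"} (decomposed, default) or \code{"joint"}.
#' @param ... passed to \code{simulate_pathway} via the objective.
#' @return List of class \code{egfr_fit_result}: \code{par} (all fitted
#'   quantities), \code{value} (full-spec ERR at the fitted parameters),
#'   \code{residuals}, \code{stages} (per-stage \code{egfr_fit}s),
#'   \code{config}.
#' @export
fit_pathway <- function(spec, config = ga_config(),
                        stage = c("both", "joint"), ...) {
  stage <- match.arg(stage)
  if (stage == "joint") {
    fit <- ga_minimize(function(p) err_objective(p, spec, ...),
                       spec$free_parameters, config)
    stages <- list(joint = fit)
    par <- fit$par
  } else {
    parts <- decompose_objective(spec)
    fitA <- ga_minimize(function(p) err_objective(p, parts$A, ...),
                        parts$A$free_parameters, config)
    # freeze stage-A winners into the network/settings for stage B
    specB <- parts$B
    frozen <- .apply_candidate(fitA$par, specB$network,
                               specB$variant_settings)
    specB$network <- frozen$network
    specB$variant_settings <- frozen$variant_settings
    fitB <- ga_minimize(function(p) err_objective(p, specB, ...),
                        specB$free_parameters, config)
    stages <- list(A = fitA, B = fitB)
    par <- c(fitA$par, fitB$par)
  }
  value <- err_objective(par, spec, ...)
  residuals <- err_objective(par, spec, return_residuals = TRUE, ...)
  structure(list(par = par, value = value, residuals = residuals,
                 stages = stages, config = config),
            class = "egfr_fit_result")
}

#' @export
print.egfr_fit_result <- function(x, ...) {
  cat(sprintf("Pathway fit: ERR = %.6g over %d observations, %d parameters\n",
              x$value, nrow(x$residuals), length(x$par)))
  invisible(x)
}
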