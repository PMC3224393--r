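## Stiff ODE simulation of a variant under a stimulus protocol, and
## experiment-comparable phospho observables.

#' Stimulus protocol
#'
#' @param egf_dose EGF bath concentration in nM applied at t = 0.
#' @param gefitinib_alpha multiplicative factor in (0, 1] on the receptor
#'   autophosphorylation rate constant k3 for the whole run; 1 means no
#'   gefitinib.
#' @param t_outputs ascending output time grid in minutes, starting at 0.
#' @param pre_equilibration minutes of unstimulated settling before the
#'   stimulus (the unstimulated state is stationary, so this is normally 0).
#' @return An object of class \code{egfr_protocol}.
#' @export
stimulus_protocol <- function(egf_dose = 10, gefitinib_alpha = 1,
                              t_outputs = c(0, 1, 5, 10, 30, 120, 360),
                              pre_equilibration = 0) {
  if (egf_dose < 0) stop("egf_dose must be non-negative")
  if (gefitinib_alpha <= 0 || gefitinib_alpha > 1)
    stop("gefitinib_alpha must lie in (0, 1]")
  if (t_outputs[1] != 0 || is.unsorted(t_outputs, strictly = TRUE))
    stop("t_outputs must be strictly ascending and start at 0")
  structure(list(egf_dose = egf_dose, gefitinib_alpha = gefitinib_alpha,
                 t_outputs = t_outputs,
                 pre_equilibration = pre_equilibration),
            class = "egfr_protocol")
}

#' Build an interpreted right-hand-side function for any network
#'
#' Generic rate-law interpreter used for declarative or imported networks
#' and as an independent cross-check of the compiled reference right-hand
#' side.  The EGF bath is clamped (zero derivative).
#'
#' @param network an \code{egfr_network}.
#' @return Function \code{(t, y, p)} in \code{deSolve} form.
#' @export
build_rhs <- function(network) {
  S <- stoichiometry_matrix(network)
  dyn <- rownames(S)
  const <- setNames(
    network$species$initial_concentration[!network$species$is_dynamic],
    network$species$id[!network$species$is_dynamic])
  rxs <- network$reactions
  # precompute index/closure data per reaction for speed
  compiled <- lapply(rxs, function(r) {
    list(law = r$law,
         ri = match(names(r$reactants), dyn),
         rs = unname(r$reactants),
         pi_ = match(names(r$products), dyn),
         ps = unname(r$products),
         prm = r$params,
         mod = r$modifier,
         mod_const = !is.null(r$modifier) && r$modifier %in% names(const))
  })
  function(t, y, p) {
    v <- numeric(length(compiled))
    for (j in seq_along(compiled)) {
      cj <- compiled[[j]]
      if (cj$law == "michaelis_menten") {
        s <- y[cj$ri[1]]
        V <- if (is.null(cj$mod)) p[[cj$prm[["V"]]]]
             else p[[cj$prm[["kcat"]]]] *
               (if (cj$mod_const) const[[cj$mod]]
                else y[[match(cj$mod, dyn)]])
        v[j] <- V * s / (p[[cj$prm[["Km"]]]] + s)
      } else {
        f <- p[[cj$prm[["kf"]]]] * prod(y[cj$ri]^cj$rs)
        if (cj$law == "mass_action_reversible")
          f <- f - p[[cj$prm[["kr"]]]] * prod(y[cj$pi_]^cj$ps)
        v[j] <- f
      }
    }
    list(as.vector(S %*% v))
  }
}

#' Simulate a variant under a stimulus protocol
#'
#' Integrates the 27-state system with a stiff-capable solver
#' (\code{deSolve::ode}, lsoda).  Gefitinib is applied as a constant
#' multiplicative factor on k3 for the whole run; EGF is set to the dose at
#' t = 0 and held (clamped bath).
#'
#' @param variant an \code{egfr_variant}.
#' @param protocol an \code{egfr_protocol}.
#' @param extra_multipliers optional named positive factors applied to
#'   parameters on top of the variant's own multipliers (used by the
#'   perturbation analyses).
#' @param engine \code{"compiled"} (C right-hand side, reference topology
#'   only), \code{"interpreted"} (generic R interpreter), or \code{"auto"}.
#' @param rtol,atol solver tolerances.
#' @param method \code{deSolve} integration method.
#' @return An object of class \code{egfr_trajectory}: list with
#'   \code{times}, \code{states} (time x species matrix), \code{variant},
#'   \code{protocol}.
#' @export
#' @examples
#' v <- make_variant("EGFR_WT", reference_network())
#' tr <- simulate_pathway(v, stimulus_protocol(egf_dose = 10))
#' tr$states[, "ERKPP"]
simulate_pathway <- function(variant, protocol = stimulus_protocol(),
                             extra_multipliers = NULL,
                             engine = c("auto", "compiled", "interpreted"),
                             rtol = 1e-10, atol = 1e-12, method = "lsoda") {
  engine <- match.arg(engine)
  stopifnot(inherits(variant, "egfr_variant"),
            inherits(protocol, "egfr_protocol"))
  eff <- .variant_effective(variant, egf_dose = protocol$egf_dose,
                            gefitinib_alpha = protocol$gefitinib_alpha,
                            extra_multipliers = extra_multipliers)
  is_ref <- isTRUE(attr(variant$network, "reference_topology"))
  if (engine == "auto") engine <- if (is_ref) "compiled" else "interpreted"
  if (engine == "compiled" && !is_ref)
    stop("compiled engine requires the reference topology")

  times <- protocol$t_outputs
  if (engine == "compiled") {
    pvec <- c(eff$params[.egfr_param_order],
              eff$constants[c("PP2A", "MKP3")])
    out <- deSolve::ode(y = eff$state, times = times, parms = pvec,
                        func = "egfr_derivs", dllname = "egfrpath",
                        initfunc = "egfr_initmod", method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    rhs <- build_rhs(variant$network)
    ids <- variant$network$species$id[variant$network$species$is_dynamic]
    out <- deSolve::ode(y = eff$state[ids], times = times, parms = eff$params,
                        func = rhs, method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("solver failure for variant '%s' (EGF=%g, alpha=%g)",
                 variant$name, protocol$egf_dose, protocol$gefitinib_alpha))
  st <- out[, -1, drop = FALSE]
  if (any(!is.finite(st)))
    stop("non-finite state encountered during integration")
  structure(list(times = out[, 1], states = st, variant = variant$name,
                 protocol = protocol),
            class = "egfr_trajectory")
}

#' Antibody-to-species observable mapping
#'
#' pEGFR sums all species containing a phosphorylated receptor dimer (a
#' dimer counts once, configurable via \code{dimer_weight}); pShc sums all
#' ShcP-containing species (free and complexed); pMEK is MEKP + MEKPP
#' (the Ser217/221 antibody detects both phosphoforms); pERK is ERKPP only
#' (doubly-phosphorylated p44/42 antibody).
#'
#' @param dimer_weight receptor equivalents counted per phosphorylated
#'   dimer in the pEGFR readout (default 1).
#' @return Named list of weight vectors over species ids.
#' @export
phospho_observable_map <- function(dimer_weight = 1) {
  pd <- c("E11P", "E11P_Cbl", "E11P_GAP", "E11P_Shc", "E11P_ShcP",
          "E11P_ShcP_GS")
  list(
    pEGFR = setNames(rep(dimer_weight, length(pd)), pd),
    pShc = c(ShcP = 1, E11P_ShcP = 1, E11P_ShcP_GS = 1, ShcP_GS = 1),
    pMEK = c(MEKP = 1, MEKPP = 1),
    pERK = c(ERKPP = 1))
}

.raw_readouts <- c("E11P_ShcP_GS", "RasGTP", "Raf1A", "MEKP", "MEKPP",
                   "ERKP", "ERKPP")

#' Extract raw observables from a trajectory
#'
#' Returns the four antibody-style phospho readouts plus raw species
#' readouts, as a tidy data frame.
#'
#' @param traj an \code{egfr_trajectory}.
#' @param which character vector of observable names (phospho readouts
#'   and/or raw species); defaults to all.
#' @param map observable mapping from \code{phospho_observable_map()}.
#' @return Data frame with columns \code{time}, \code{protein},
#'   \code{value}, \code{normalized} (FALSE).
#' @export
observables <- function(traj, which = NULL,
                        map = phospho_observable_map()) {
  st <- traj$states
  avail <- c(names(map), colnames(st))
  if (is.null(which)) which <- c(names(map), .raw_readouts)
  bad <- setdiff(which, avail)
  if (length(bad)) stop("unknown observable(s): ", paste(bad, collapse = ", "))
  rows <- lapply(which, function(nm) {
    val <- if (nm %in% names(map)) {
      w <- map[[nm]]
      as.vector(st[, names(w), drop = FALSE] %*% w)
    } else st[, nm]
    data.frame(time = traj$times, protein = nm, value = val,
               normalized = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalise a panel of observable series western-blot style
#'
#' Within each protein: subtract each series' own t = 0 value, then divide
#' all series jointly by the panel-wide maximum, so values lie in [0, 1],
#' are 0 at t = 0, and exactly one series attains 1 (the panel anchor).
#' An all-zero panel stays all zero.
#'
#' @param panel tidy data frame with columns \code{protein}, \code{time},
#'   \code{value} and one or more series-identifying columns (for example
#'   \code{cell_line}, \code{dose}).
#' @param series_cols names of the series-identifying columns; defaults to
#'   all columns other than protein/time/value/normalized.
#' @return The panel with \code{value} replaced by the normalised value and
#'   \code{normalized = TRUE}.
#' @export
#' @examples
#' pan <- data.frame(cell_line = "a", protein = "pERK",
#'                   time = c(0, 5, 10), value = c(0, 2, 4))
#' normalize_panel(pan)$value
normalize_panel <- function(panel, series_cols = NULL) {
  req <- c("protein", "time", "value")
  if (!all(req %in% names(panel))) stop("panel lacks protein/time/value")
  if (nrow(panel) == 0) stop("empty panel")
  if (is.null(series_cols))
    series_cols <- setdiff(names(panel),
                           c("protein", "time", "value", "normalized"))
  key <- do.call(paste, c(panel[c("protein", series_cols)], sep = "\r"))
  # subtract each series' own t = 0 value
  for (k in unique(key)) {
    i <- key == k
    t0 <- panel$value[i & panel$time == 0]
    if (length(t0) != 1)
      stop("each series must contain exactly one t = 0 row")
    panel$value[i] <- panel$value[i] - t0
  }
  # joint per-protein maximum
  for (pr in unique(panel$protein)) {
    i <- panel$protein == pr
    m <- max(panel$value[i])
    if (m > 0) panel$value[i] <- panel$value[i] / m
  }
  panel$normalized <- TRUE
  panel
}

#' EGF dose-response of the phospho readouts at a fixed read time
#'
#' One simulation per dose; values reported at \code{t_read} minutes.
#'
#' @param variant an \code{egfr_variant}.
#' @param doses EGF doses in nM.
#' @param t_read read time in minutes (default 5).
#' @param ... passed to \code{simulate_pathway}.
#' @return Tidy data frame with columns \code{dose}, \code{protein},
#'   \code{value}.
#' @export
dose_response <- function(variant, doses = c(0.1, 1, 10), t_read = 5, ...) {
  if (any(doses < 0)) stop("doses must be non-negative")
  rows <- lapply(doses, function(d) {
    tr <- simulate_pathway(variant,
                           stimulus_protocol(egf_dose = d,
                                             t_outputs = c(0, t_read)), ...)
    ob <- observables(tr, which = c("pEGFR", "pShc", "pMEK", "pERK"))
    ob <- ob[ob$time == t_read, c("protein", "value")]
    ob$dose <- d
    ob
  })
  do.call(rbind, rows)[, c("dose", "protein", "value")]
}

#' Tidy long-format table of a trajectory
#'
#' @param traj an \code{egfr_trajectory}.
#' @return Data frame with columns variant, egf_dose, gefitinib_alpha,
#'   time, name, value, normalized.
#' @export
trajectory_table <- function(traj) {
  st <- traj$states
  data.frame(variant = traj$variant,
             egf_dose = traj$protocol$egf_dose,
             gefitinib_alpha = traj$protocol$gefitinib_alpha,
             time = rep(traj$times, ncol(st)),
             name = rep(colnames(st), each = nrow(st)),
             value = as.vector(st),
             normalized = FALSE,
             stringsAsFactors = FALSE)
}

#' @export
print.egfr_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: variant %s, EGF %g nM, alpha %g, %d time points\n",
              x$variant, x$protocol$egf_dose, x$protocol$gefitinib_alpha,
              length(x$times)))
  invisible(x)
}
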