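## Reference EGFR-ERK reaction network: species, 27 reactions, rate laws,
## kinetic parameters with search bounds, conservation pools.

# canonical state ordering shared with the compiled right-hand side
.egfr_species_order <- c(
  "EGF", "EGFR", "Ra", "E11", "E11P", "Cbl", "E11P_Cbl", "GAP", "E11P_GAP",
  "Shc", "E11P_Shc", "E11P_ShcP", "ShcP", "GS", "E11P_ShcP_GS", "ShcP_GS",
  "RasGDP", "RasGTP", "Raf1", "Raf1A", "MEK", "MEKP", "MEKPP",
  "ERK", "ERKP", "ERKPP", "EGFRdeg")

# canonical parameter ordering shared with the compiled right-hand side
.egfr_param_order <- c(
  "kf1", "kr1", "kf2", "kr2", "k3", "V4", "Km4",
  "k5", "kr5", "k6", "k7", "kr7", "k8", "kr8", "k9",
  "kf10", "kr10", "V11", "Km11",
  "kf12", "kr12", "kf13", "kr13", "kf14", "kr14",
  "kcat15", "Km15", "V16", "Km16", "kcat17", "Km17",
  "kcat18", "Km18", "V19", "Km19",
  "kcat20", "Km20", "kcat21", "Km21", "kcat22", "Km22", "kcat23", "Km23",
  "kcat24", "Km24", "kcat25", "Km25", "kcat26", "Km26", "kcat27", "Km27")

#' Default kinetic parameters of the reference model
#'
#' Rate constants for the 27 reaction steps, in nM and minutes.  Bimolecular
#' constants are in 1/(nM min), unimolecular in 1/min, Michaelis-Menten
#' maximal rates in nM/min (or 1/min for catalysed steps, where the maximal
#' rate is \code{kcat * [enzyme]}), and Michaelis constants in nM.
#'
#' The values are fallback defaults in the magnitude range of the classical
#' receptor-module and MAPK-cascade models this network descends from,
#' calibrated once so that the four cell-line variants reproduce the
#' hallmark behaviours of the H1299 panel: the EGFR-overexpressing line
#' gives the panel-wide phosphorylation maxima; ERK output of the
#' EGFR-overexpressing line is almost insensitive to gefitinib while the
#' L858R+Mig6 variant is strongly inhibited; inhibition is amplified at the
#' MEK and ERK phosphorylation/dephosphorylation cycles; and combined
#' Mig6-type and gefitinib-type perturbation is synergistic.  See the
#' methods vignette for the calibration rationale.
#'
#' @return Named numeric vector of 51 rate constants in canonical order.
#' @export
#' @examples
#' p <- default_parameters()
#' p[["k3"]]
default_parameters <- function() {
  c(kf1 = 0.18, kr1 = 3.6,
    kf2 = 0.6, kr2 = 6,
    k3 = 60,
    V4 = 1800, Km4 = 200,
    k5 = 0.06, kr5 = 0.6,
    k6 = 0.15,
    k7 = 0.06, kr7 = 0.6,
    k8 = 0.006, kr8 = 0.6,
    k9 = 6,
    kf10 = 6, kr10 = 0.06,
    V11 = 6, Km11 = 30,
    kf12 = 0.06, kr12 = 0.6,
    kf13 = 3, kr13 = 0.01,
    kf14 = 3, kr14 = 0.01,
    kcat15 = 60, Km15 = 120,
    V16 = 6, Km16 = 120,
    kcat17 = 1.2, Km17 = 120,
    kcat18 = 6, Km18 = 200,
    V19 = 30, Km19 = 10,
    kcat20 = 240, Km20 = 15,
    kcat21 = 2.1, Km21 = 1,
    kcat22 = 240, Km22 = 15,
    kcat23 = 2.1, Km23 = 1,
    kcat24 = 30, Km24 = 15,
    kcat25 = 18.75, Km25 = 0.1,
    kcat26 = 30, Km26 = 15,
    kcat27 = 18.75, Km27 = 15)
}

#' Parameter set with values and search bounds
#'
#' @param values named numeric vector of positive rate constants.
#' @param bounds optional two-column matrix (low, high) with rownames
#'   matching \code{values}; defaults to two decades either side of each
#'   value.
#' @return An object of class \code{egfr_parameters}.
#' @export
parameter_set <- function(values = default_parameters(), bounds = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values <= 0)) stop("all rate constants must be positive")
  if (is.null(bounds)) {
    bounds <- cbind(low = values / 100, high = values * 100)
  }
  bounds <- as.matrix(bounds)
  if (!setequal(rownames(bounds), names(values)))
    stop("bounds must cover exactly the named parameters")
  bounds <- bounds[names(values), , drop = FALSE]
  colnames(bounds) <- c("low", "high")
  if (any(values < bounds[, "low"] | values > bounds[, "high"]))
    stop("parameter value outside its bounds")
  structure(list(values = values, bounds = bounds),
            class = "egfr_parameters")
}

.reaction <- function(step, law, reactants, products, params,
                      modifier = NULL) {
  stopifnot(law %in% c("mass_action_irreversible", "mass_action_reversible",
                       "michaelis_menten"))
  structure(list(step = step, law = law, reactants = reactants,
                 products = products, params = params, modifier = modifier),
            class = "egfr_reaction")
}

#' Build the reference EGFR-ERK reaction network
#'
#' Constructs the canonical 27-step network: EGF binding (1), receptor
#' dimerisation (2), autophosphorylation (3), receptor dephosphorylation
#' (4, MM), Cbl binding (5), internalisation/degradation into a counted
#' sink (6), GAP binding (7), Shc binding (8), Shc phosphorylation (9),
#' complex dissociations (10, 13, 14), ShcP dephosphorylation (11, MM),
#' Grb2/SOS recruitment (12), Ras GDP-to-GTP exchange catalysed by the
#' receptor-Shc-Grb2/SOS complex (15, MM), basal and receptor-GAP
#' accelerated Ras deactivation (16, 17, MM), Raf1 activation by RasGTP
#' (18) and deactivation (19), dual MEK phosphorylation by active Raf1
#' (20, 22) and dephosphorylation by PP2A (21, 23), and dual ERK
#' phosphorylation by active MEK (24, 26) and dephosphorylation by MKP3
#' (25, 27).  Steps 4, 11 and 15-27 use Michaelis-Menten kinetics, the
#' rest mass action.
#'
#' The model has 29 components: 27 integrated states (EGF is carried as a
#' clamped extracellular bath with zero net flux; degraded receptor dimers
#' are counted in a terminal sink so receptor mass is auditable) plus the
#' constant phosphatase pools PP2A and MKP3 that act through the
#' Michaelis-Menten maximal rates of steps 21/23 and 25/27.
#'
#' @param parameters an \code{egfr_parameters} object; defaults to
#'   \code{parameter_set()}.
#' @return An object of class \code{egfr_network} with elements
#'   \code{species} (data frame: id, display_name, initial_concentration,
#'   is_dynamic), \code{reactions} (list of 27 \code{egfr_reaction}s) and
#'   \code{parameters}.
#' @export
#' @examples
#' net <- reference_network()
#' length(net$reactions)
reference_network <- function(parameters = parameter_set()) {
  sp <- data.frame(
    id = c(.egfr_species_order, "PP2A", "MKP3"),
    display_name = c(
      "EGF", "EGFR", "EGF-EGFR", "EGFR homodimer",
      "phosphorylated EGFR homodimer", "Cbl", "E11P-Cbl", "GAP",
      "E11P-GAP", "Shc", "E11P-Shc", "E11P-ShcP", "phosphorylated Shc",
      "Grb2/SOS", "E11P/ShcP/Grb2/SOS", "ShcP/Grb2/SOS",
      "Ras-GDP", "Ras-GTP", "Raf1", "activated Raf1",
      "MEK", "singly phosphorylated MEK", "doubly phosphorylated MEK",
      "ERK", "singly phosphorylated ERK", "doubly phosphorylated ERK",
      "degraded receptor dimer", "PP2A", "MKP3"),
    initial_concentration = c(
      0, 10, 0, 0, 0, 20, 0, 12, 0, 150, 0, 0, 0, 34, 0, 0,
      120, 0, 100, 0, 120, 0, 0, 300, 0, 0, 0, 11.4, 2.4),
    is_dynamic = c(rep(TRUE, 27), FALSE, FALSE),
    stringsAsFactors = FALSE)

  rx <- list(
    .reaction(1, "mass_action_reversible", c(EGF = 1, EGFR = 1), c(Ra = 1),
              c(kf = "kf1", kr = "kr1")),
    .reaction(2, "mass_action_reversible", c(Ra = 2), c(E11 = 1),
              c(kf = "kf2", kr = "kr2")),
    .reaction(3, "mass_action_irreversible", c(E11 = 1), c(E11P = 1),
              c(kf = "k3")),
    .reaction(4, "michaelis_menten", c(E11P = 1), c(E11 = 1),
              c(V = "V4", Km = "Km4")),
    .reaction(5, "mass_action_reversible", c(E11P = 1, Cbl = 1),
              c(E11P_Cbl = 1), c(kf = "k5", kr = "kr5")),
    .reaction(6, "mass_action_irreversible", c(E11P_Cbl = 1),
              c(EGFRdeg = 1, Cbl = 1), c(kf = "k6")),
    .reaction(7, "mass_action_reversible", c(E11P = 1, GAP = 1),
              c(E11P_GAP = 1), c(kf = "k7", kr = "kr7")),
    .reaction(8, "mass_action_reversible", c(E11P = 1, Shc = 1),
              c(E11P_Shc = 1), c(kf = "k8", kr = "kr8")),
    .reaction(9, "mass_action_irreversible", c(E11P_Shc = 1),
              c(E11P_ShcP = 1), c(kf = "k9")),
    .reaction(10, "mass_action_reversible", c(E11P_ShcP = 1),
              c(E11P = 1, ShcP = 1), c(kf = "kf10", kr = "kr10")),
    .reaction(11, "michaelis_menten", c(ShcP = 1), c(Shc = 1),
              c(V = "V11", Km = "Km11")),
    .reaction(12, "mass_action_reversible", c(E11P_ShcP = 1, GS = 1),
              c(E11P_ShcP_GS = 1), c(kf = "kf12", kr = "kr12")),
    .reaction(13, "mass_action_reversible", c(E11P_ShcP_GS = 1),
              c(E11P = 1, ShcP_GS = 1), c(kf = "kf13", kr = "kr13")),
    .reaction(14, "mass_action_reversible", c(ShcP_GS = 1),
              c(ShcP = 1, GS = 1), c(kf = "kf14", kr = "kr14")),
    .reaction(15, "michaelis_menten", c(RasGDP = 1), c(RasGTP = 1),
              c(kcat = "kcat15", Km = "Km15"), modifier = "E11P_ShcP_GS"),
    .reaction(16, "michaelis_menten", c(RasGTP = 1), c(RasGDP = 1),
              c(V = "V16", Km = "Km16")),
    .reaction(17, "michaelis_menten", c(RasGTP = 1), c(RasGDP = 1),
              c(kcat = "kcat17", Km = "Km17"), modifier = "E11P_GAP"),
    .reaction(18, "michaelis_menten", c(Raf1 = 1), c(Raf1A = 1),
              c(kcat = "kcat18", Km = "Km18"), modifier = "RasGTP"),
    .reaction(19, "michaelis_menten", c(Raf1A = 1), c(Raf1 = 1),
              c(V = "V19", Km = "Km19")),
    .reaction(20, "michaelis_menten", c(MEK = 1), c(MEKP = 1),
              c(kcat = "kcat20", Km = "Km20"), modifier = "Raf1A"),
    .reaction(21, "michaelis_menten", c(MEKP = 1), c(MEK = 1),
              c(kcat = "kcat21", Km = "Km21"), modifier = "PP2A"),
    .reaction(22, "michaelis_menten", c(MEKP = 1), c(MEKPP = 1),
              c(kcat = "kcat22", Km = "Km22"), modifier = "Raf1A"),
    .reaction(23, "michaelis_menten", c(MEKPP = 1), c(MEKP = 1),
              c(kcat = "kcat23", Km = "Km23"), modifier = "PP2A"),
    .reaction(24, "michaelis_menten", c(ERK = 1), c(ERKP = 1),
              c(kcat = "kcat24", Km = "Km24"), modifier = "MEKPP"),
    .reaction(25, "michaelis_menten", c(ERKP = 1), c(ERK = 1),
              c(kcat = "kcat25", Km = "Km25"), modifier = "MKP3"),
    .reaction(26, "michaelis_menten", c(ERKP = 1), c(ERKPP = 1),
              c(kcat = "kcat26", Km = "Km26"), modifier = "MEKPP"),
    .reaction(27, "michaelis_menten", c(ERKPP = 1), c(ERKP = 1),
              c(kcat = "kcat27", Km = "Km27"), modifier = "MKP3"))

  net <- structure(list(species = sp, reactions = rx,
                        parameters = parameters),
                   class = "egfr_network")
  attr(net, "reference_topology") <- TRUE
  validate_network(net)
  net
}

#' Validate structural invariants of a network
#'
#' Checks species id uniqueness, non-negative initial concentrations,
#' contiguous step indices, parameter resolution, and the declared rate-law
#' assignment (Michaelis-Menten exactly on steps 4, 11 and 15-27 for the
#' reference topology).
#'
#' @param network an \code{egfr_network}.
#' @return The network, invisibly; stops on violation.
#' @export
validate_network <- function(network) {
  sp <- network$species
  if (anyDuplicated(sp$id)) stop("duplicate species ids")
  if (any(sp$initial_concentration < 0))
    stop("negative initial concentration")
  steps <- vapply(network$reactions, `[[`, numeric(1), "step")
  if (!identical(sort(steps), as.numeric(seq_along(steps))))
    stop("reaction step indices must cover 1..n without gaps")
  pnames <- names(network$parameters$values)
  for (r in network$reactions) {
    if (!all(r$params %in% pnames))
      stop(sprintf("step %d references unknown parameter(s): %s", r$step,
                   paste(setdiff(r$params, pnames), collapse = ", ")))
    ids <- c(names(r$reactants), names(r$products), r$modifier)
    if (!all(ids %in% sp$id))
      stop(sprintf("step %d references unknown species", r$step))
  }
  if (isTRUE(attr(network, "reference_topology"))) {
    mm <- steps[vapply(network$reactions, function(r)
      r$law == "michaelis_menten", logical(1))]
    if (!setequal(mm, c(4, 11, 15:27)))
      stop("reference topology must use Michaelis-Menten on steps 4, 11, 15-27")
    if (length(network$reactions) != 27L) stop("expected 27 reactions")
  }
  invisible(network)
}

#' Evaluate the flux of a single reaction
#'
#' Mass action: \code{kf * prod(reactants) - kr * prod(products)} (kr = 0
#' when irreversible).  Michaelis-Menten: \code{V * S / (Km + S)} with
#' \code{V = kcat * [modifier]} when a catalytic modifier is declared.
#'
#' @param reaction an \code{egfr_reaction}.
#' @param state named concentration vector (must cover all species the
#'   reaction touches).
#' @param parameters an \code{egfr_parameters} object or named vector.
#' @return Flux in nM/min.
#' @export
#' @examples
#' net <- reference_network()
#' st <- setNames(rep(1, 29), net$species$id)
#' reaction_rate(net$reactions[[4]], st, net$parameters)
reaction_rate <- function(reaction, state, parameters) {
  p <- if (inherits(parameters, "egfr_parameters")) parameters$values
       else parameters
  if (any(state[c(names(reaction$reactants), names(reaction$products))] < 0))
    stop("negative concentration")
  if (reaction$law == "michaelis_menten") {
    Km <- p[[reaction$params[["Km"]]]]
    if (Km <= 0) stop("Km must be positive")
    S <- state[[names(reaction$reactants)[1]]]
    V <- if (!is.null(reaction$modifier)) {
      p[[reaction$params[["kcat"]]]] * state[[reaction$modifier]]
    } else {
      p[[reaction$params[["V"]]]]
    }
    return(V * S / (Km + S))
  }
  fwd <- p[[reaction$params[["kf"]]]] *
    prod(state[names(reaction$reactants)]^reaction$reactants)
  bwd <- if (reaction$law == "mass_action_reversible") {
    p[[reaction$params[["kr"]]]] *
      prod(state[names(reaction$products)]^reaction$products)
  } else 0
  fwd - bwd
}

#' Net stoichiometry matrix of a network
#'
#' @param network an \code{egfr_network}.
#' @return Matrix (species x reactions) of net stoichiometric coefficients
#'   over the dynamic species.
#' @export
stoichiometry_matrix <- function(network) {
  ids <- network$species$id[network$species$is_dynamic]
  S <- matrix(0, nrow = length(ids), ncol = length(network$reactions),
              dimnames = list(ids, paste0("v", seq_along(network$reactions))))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (s in names(r$reactants)) S[s, j] <- S[s, j] - r$reactants[[s]]
    for (s in names(r$products)) S[s, j] <- S[s, j] + r$products[[s]]
  }
  # the EGF bath is clamped: its formal ODE is dEGF/dt = 0
  S["EGF", ] <- 0
  S
}

#' Conserved moiety pools of the reference network
#'
#' Returns the closed pools (each pool's weighted species sum is invariant
#' under the flow) and, separately, the receptor pool, which is not closed
#' under the reaction flow alone but is conserved once the degradation sink
#' is counted (dimers carry weight 2).
#'
#' @param network an \code{egfr_network} with the reference topology.
#' @return List with elements \code{closed} (named list of species-id
#'   vectors) and \code{receptor} (named weight vector over
#'   receptor-containing species plus the sink).
#' @export
#' @examples
#' conservation_pools(reference_network())$closed$MEK
conservation_pools <- function(network) {
  if (!isTRUE(attr(network, "reference_topology")))
    stop("conservation pools are defined for the reference topology")
  closed <- list(
    Shc = c("Shc", "E11P_Shc", "E11P_ShcP", "ShcP", "E11P_ShcP_GS",
            "ShcP_GS"),
    Grb2_SOS = c("GS", "E11P_ShcP_GS", "ShcP_GS"),
    Cbl = c("Cbl", "E11P_Cbl"),
    GAP = c("GAP", "E11P_GAP"),
    Ras = c("RasGDP", "RasGTP"),
    Raf1 = c("Raf1", "Raf1A"),
    MEK = c("MEK", "MEKP", "MEKPP"),
    ERK = c("ERK", "ERKP", "ERKPP"))
  receptor <- c(EGFR = 1, Ra = 1, E11 = 2, E11P = 2, E11P_Cbl = 2,
                E11P_GAP = 2, E11P_Shc = 2, E11P_ShcP = 2,
                E11P_ShcP_GS = 2, EGFRdeg = 2)
  list(closed = closed, receptor = receptor)
}

#' @export
print.egfr_network <- function(x, ...) {
  laws <- table(vapply(x$reactions, `[[`, character(1), "law"))
  cat(sprintf("EGFR-ERK reaction network: %d species (%d dynamic), %d reactions\n",
              nrow(x$species), sum(x$species$is_dynamic),
              length(x$reactions)))
  cat("  rate laws:", paste(sprintf("%s=%d", names(laws), laws),
                            collapse = ", "), "\n")
  invisible(x)
}
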