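## The four H1299 cell-line model variants.

#' Default variant settings for the H1299 panel
#'
#' The wild-type line carries a low endogenous receptor level; the
#' EGFR-overexpressing and both L858R lines share a raised EGFR initial
#' concentration.  The first L858R model represents endogenous Mig6
#' overexpression through multiplicative slow-downs of the forward rate
#' constants of receptor autophosphorylation (k3) and of phospho-receptor
#' binding to Cbl (k5), GAP (k7) and Shc (k8); the second represents
#' enhanced Cbl-mediated degradation through a raised Cbl initial
#' concentration with all rate constants untouched.
#'
#' @return Named list of per-variant settings.
#' @export
default_variant_settings <- function() {
  list(
    WT = list(),
    EGFR_WT = list(initial_overrides = c(EGFR = 100)),
    L858R_A = list(initial_overrides = c(EGFR = 100),
                   parameter_multipliers = c(k3 = 0.15, k5 = 0.5,
                                             k7 = 0.5, k8 = 0.15)),
    L858R_B = list(initial_overrides = c(EGFR = 100, Cbl = 80)))
}

#' Construct a cell-line model variant
#'
#' A variant never mutates the shared base network; it records initial
#' concentration overrides and parameter multipliers that are applied at
#' simulation time.
#'
#' @param name one of \code{"WT"}, \code{"EGFR_WT"}, \code{"L858R_A"},
#'   \code{"L858R_B"}.
#' @param network the shared base \code{egfr_network}.
#' @param settings list with optional elements \code{initial_overrides}
#'   (named species concentrations) and, for \code{L858R_A},
#'   \code{parameter_multipliers} (positive factors < 1 on exactly k3, k5,
#'   k7, k8).  Defaults to \code{default_variant_settings()[[name]]}.
#' @return An object of class \code{egfr_variant}.
#' @export
#' @examples
#' v <- make_variant("L858R_A", reference_network())
#' v$parameter_multipliers
make_variant <- function(name, network, settings = NULL) {
  valid <- c("WT", "EGFR_WT", "L858R_A", "L858R_B")
  if (!name %in% valid)
    stop("unknown variant name: ", name)
  if (is.null(settings)) settings <- default_variant_settings()[[name]]
  ov <- settings$initial_overrides %||% numeric(0)
  mu <- settings$parameter_multipliers %||% numeric(0)
  if (any(ov < 0)) stop("negative concentration override")
  if (!all(names(ov) %in% network$species$id))
    stop("override for unknown species")
  if (name == "WT" && (length(ov) || length(mu)))
    stop("WT variant takes no overrides")
  if (name == "EGFR_WT" && (!identical(names(ov), "EGFR") || length(mu)))
    stop("EGFR_WT overrides only the EGFR initial concentration")
  if (name == "L858R_A") {
    if (!setequal(names(mu), c("k3", "k5", "k7", "k8")))
      stop("L858R_A multiplies exactly k3, k5, k7, k8")
    if (any(mu <= 0) || any(mu >= 1))
      stop("L858R_A multipliers must lie in (0, 1)")
  }
  if (name == "L858R_B" && length(mu))
    stop("L858R_B has no parameter multipliers")
  structure(list(name = name, network = network,
                 initial_overrides = ov, parameter_multipliers = mu),
            class = "egfr_variant")
}

#' Build the full default four-variant H1299 panel
#'
#' @param network base network; defaults to \code{reference_network()}.
#' @param settings per-variant settings; defaults to
#'   \code{default_variant_settings()}.
#' @return Named list of four \code{egfr_variant} objects.
#' @export
h1299_panel <- function(network = reference_network(),
                        settings = default_variant_settings()) {
  lapply(setNames(nm = names(settings)), function(nm)
    make_variant(nm, network, settings[[nm]]))
}

# effective (parameter vector, initial state) for a variant under a protocol
.variant_effective <- function(variant, egf_dose = 0, gefitinib_alpha = 1,
                               extra_multipliers = NULL) {
  net <- variant$network
  p <- net$parameters$values
  mu <- variant$parameter_multipliers
  if (length(mu)) p[names(mu)] <- p[names(mu)] * mu
  if (!is.null(extra_multipliers)) {
    if (!all(names(extra_multipliers) %in% names(p)))
      stop("multiplier for unknown parameter")
    p[names(extra_multipliers)] <- p[names(extra_multipliers)] *
      extra_multipliers
  }
  p[["k3"]] <- p[["k3"]] * gefitinib_alpha
  sp <- net$species
  y <- setNames(sp$initial_concentration[match(.egfr_species_order, sp$id)],
                .egfr_species_order)
  ov <- variant$initial_overrides
  if (length(ov)) y[names(ov)] <- ov
  y[["EGF"]] <- egf_dose
  const <- setNames(sp$initial_concentration[!sp$is_dynamic],
                    sp$id[!sp$is_dynamic])
  list(params = p, state = y, constants = const)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.egfr_variant <- function(x, ...) {
  cat(sprintf("H1299 model variant '%s'\n", x$name))
  if (length(x$initial_overrides))
    cat("  initial overrides:",
        paste(sprintf("%s=%g", names(x$initial_overrides),
                      x$initial_overrides), collapse = ", "), "\n")
  if (length(x$parameter_multipliers))
    cat("  parameter multipliers:",
        paste(sprintf("%s=%g", names(x$parameter_multipliers),
                      x$parameter_multipliers), collapse = ", "), "\n")
  invisible(x)
}
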