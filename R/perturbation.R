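## Gefitinib dose scans, sensitivity-ratio indices over the Mig6-affected
## parameters, and additive/antagonistic/synergistic classification of the
## combined Mig6 + gefitinib perturbation.

.readout_at <- function(variant, readout, alpha = 1, multipliers = NULL,
                        egf_dose = 10, t_read = 5, ...) {
  tr <- simulate_pathway(
    variant,
    stimulus_protocol(egf_dose = egf_dose, gefitinib_alpha = alpha,
                      t_outputs = c(0, t_read)),
    extra_multipliers = multipliers, ...)
  ob <- observables(tr, which = readout)
  ob$value[ob$time == t_read]
}

#' Gefitinib alpha scan
#'
#' Simulates the variant over a grid of gefitinib factors alpha (k3
#' multiplied by alpha for the whole run) and reports the four phospho
#' readouts at the read time, normalised per protein to the alpha = 1
#' (drug-free) value.
#'
#' @param variant an \code{egfr_variant}.
#' @param alphas factors in (0, 1]; the default grid follows the
#'   simulation protocol of the drug-response analysis.
#' @param t_read read time in minutes (default 5).
#' @param egf_dose EGF dose in nM (default 10).
#' @param normalize divide by the alpha = 1 response (default TRUE).
#' @param ... passed to \code{simulate_pathway}.
#' @return Tidy data frame with columns alpha, protein, value.
#' @export
alpha_scan <- function(variant,
                       alphas = c(1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001,
                                  0.0005),
                       t_read = 5, egf_dose = 10, normalize = TRUE, ...) {
  if (any(alphas <= 0 | alphas > 1)) stop("alphas must lie in (0, 1]")
  prot <- c("pEGFR", "pShc", "pMEK", "pERK")
  rows <- lapply(alphas, function(a)
    data.frame(alpha = a, protein = prot,
               value = .readout_at(variant, prot, alpha = a,
                                   egf_dose = egf_dose, t_read = t_read,
                                   ...),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (normalize) {
    for (pr in prot) {
      ref <- out$value[out$alpha == 1 & out$protein == pr]
      i <- out$protein == pr
      if (ref > 0) out$value[i] <- out$value[i] / ref
    }
  }
  out
}

#' Inhibition ratio R of a readout under strong gefitinib
#'
#' \code{R = readout(alpha_on) / readout(alpha_off)} at the read time
#' (default 5 min, 10 nM EGF), with any context parameter multipliers
#' applied in both numerator and denominator.
#'
#' @param variant an \code{egfr_variant}.
#' @param readout observable name (phospho readout or raw species).
#' @param alpha_on strong-inhibition factor (default 0.0005).
#' @param alpha_off reference factor (default 1).
#' @param multipliers named positive factors on parameters (the
#'   perturbation context, for example Mig6-style slow-downs).
#' @param egf_dose,t_read stimulus dose and read time.
#' @param ... passed to \code{simulate_pathway}.
#' @return Positive scalar; errors if the reference readout is zero.
#' @export
#' @examples
#' v <- make_variant("EGFR_WT", reference_network())
#' r_index(v, "pShc")
r_index <- function(variant, readout, alpha_on = 5e-4, alpha_off = 1,
                    multipliers = NULL, egf_dose = 10, t_read = 5, ...) {
  num <- .readout_at(variant, readout, alpha = alpha_on,
                     multipliers = multipliers, egf_dose = egf_dose,
                     t_read = t_read, ...)
  den <- .readout_at(variant, readout, alpha = alpha_off,
                     multipliers = multipliers, egf_dose = egf_dose,
                     t_read = t_read, ...)
  if (den <= 0)
    stop("undefined index: reference readout is zero for ", readout)
  num / den
}

#' Upstream/downstream sensitivity ratio R_Shc / R_ERK
#'
#' Ratio of the inhibition ratios of total phosphorylated Shc (upstream
#' output) and of doubly phosphorylated ERK (downstream output).  Values
#' above 1 mean gefitinib inhibition is amplified on the way from Shc to
#' ERK.
#'
#' @inheritParams r_index
#' @param upstream,downstream observable names (defaults pShc, pERK).
#' @return Positive scalar.
#' @export
sensitivity_ratio <- function(variant, multipliers = NULL,
                              upstream = "pShc", downstream = "pERK",
                              alpha_on = 5e-4, alpha_off = 1,
                              egf_dose = 10, t_read = 5, ...) {
  r_index(variant, upstream, alpha_on, alpha_off, multipliers,
          egf_dose, t_read, ...) /
    r_index(variant, downstream, alpha_on, alpha_off, multipliers,
            egf_dose, t_read, ...)
}

.mig6_parameters <- c("k3", "k5", "k7", "k8")

#' Sensitivity-ratio grid over a pair of Mig6-affected parameters
#'
#' Computes R_Shc / R_ERK on a factor grid for two of the four
#' Mig6-affected parameters (k3, k5, k7, k8), the remaining two held at
#' their EGFR-WT (factor 1) values.  The (1, 1) corner reproduces the
#' EGFR-WT index; evaluating the k3 & k8 pair at the L858R_A factors with
#' k5, k7 at the L858R_A factors as fixed context reproduces the full
#' L858R_A index.
#'
#' @param pair two distinct names from k3, k5, k7, k8.
#' @param grid1,grid2 factor grids for the two parameters (must include 1).
#' @param variant base variant (default the EGFR_WT model).
#' @param fixed named factors for the two remaining parameters (default 1).
#' @param ... passed to \code{sensitivity_ratio}.
#' @return An \code{egfr_index_grid}: list with the grids and the index
#'   matrix (rows = grid1, cols = grid2).
#' @export
pairwise_index_grid <- function(pair, grid1, grid2,
                                variant = make_variant("EGFR_WT",
                                                       reference_network()),
                                fixed = NULL, ...) {
  if (length(pair) != 2 || anyDuplicated(pair) ||
      !all(pair %in% .mig6_parameters))
    stop("pair must be two distinct names among k3, k5, k7, k8")
  if (!1 %in% grid1 || !1 %in% grid2)
    stop("grids must include the factor 1 (unperturbed corner)")
  M <- matrix(NA_real_, length(grid1), length(grid2),
              dimnames = list(as.character(grid1), as.character(grid2)))
  for (i in seq_along(grid1)) for (j in seq_along(grid2)) {
    mult <- setNames(c(grid1[i], grid2[j]), pair)
    if (!is.null(fixed)) mult <- c(mult, fixed)
    M[i, j] <- sensitivity_ratio(variant, multipliers = mult, ...)
  }
  structure(list(pair = pair, grid1 = grid1, grid2 = grid2, index = M,
                 fixed = fixed, definition = "R_Shc/R_ERK"),
            class = "egfr_index_grid")
}

#' All six pairwise Mig6-parameter combinations
#'
#' @return List of the six unordered pairs k3&k5, k3&k7, k3&k8, k5&k7,
#'   k5&k8, k7&k8.
#' @export
mig6_parameter_pairs <- function() {
  combn(.mig6_parameters, 2, simplify = FALSE)
}

#' Downstream amplification indices R_upstream / R_Y
#'
#' With the receptor-Shc-Grb2/SOS complex as the upstream output, computes
#' the ratio of its inhibition ratio to that of each downstream readout Y
#' in {RasGTP, Raf1A, MEKP, MEKPP, ERKP, ERKPP} on a (k3, k8) factor grid.
#' Large values flag the steps where gefitinib inhibition is amplified.
#'
#' @param grid3,grid8 factor grids for k3 and k8 (must include 1).
#' @param variant base variant (default EGFR_WT model).
#' @param fixed named factors for k5, k7 context (default none).
#' @param alpha_on,alpha_off,egf_dose,t_read as in \code{r_index}.
#' @param ... passed to \code{simulate_pathway}.
#' @return List of six \code{egfr_index_grid}s, one per downstream Y.
#' @export
downstream_amplification <- function(grid3, grid8,
                                     variant = make_variant("EGFR_WT",
                                       reference_network()),
                                     fixed = NULL, alpha_on = 5e-4,
                                     alpha_off = 1, egf_dose = 10,
                                     t_read = 5, ...) {
  ys <- c("RasGTP", "Raf1A", "MEKP", "MEKPP", "ERKP", "ERKPP")
  upstream <- "E11P_ShcP_GS"
  read_all <- function(alpha, m) {
    .readout_at(variant, c(upstream, ys), alpha = alpha, multipliers = m,
                egf_dose = egf_dose, t_read = t_read, ...)
  }
  grids <- lapply(ys, function(y)
    matrix(NA_real_, length(grid3), length(grid8),
           dimnames = list(as.character(grid3), as.character(grid8))))
  names(grids) <- ys
  for (i in seq_along(grid3)) for (j in seq_along(grid8)) {
    m <- c(k3 = grid3[i], k8 = grid8[j], fixed)
    on_ <- read_all(alpha_on, m)
    off <- read_all(alpha_off, m)
    if (any(off <= 0)) stop("undefined index: zero reference readout")
    R <- on_ / off
    for (y in ys) {
      k <- match(y, c(upstream, ys))
      grids[[y]][i, j] <- R[1] / R[k]
    }
  }
  lapply(setNames(ys, ys), function(y)
    structure(list(pair = c("k3", "k8"), grid1 = grid3, grid2 = grid8,
                   index = grids[[y]], fixed = fixed,
                   definition = paste0("R_E11P/ShcP/Grb2/SOS/R_", y)),
              class = "egfr_index_grid"))
}

#' Invert the ERKPP inhibition curve for a single parameter
#'
#' Finds the multiplicative factor on k3 or k8 that produces a target
#' percentage inhibition of ERKPP at the read time, by bisection on the
#' log10 factor in [-6, 0].  Inhibition is
#' \code{100 * (1 - ERKPP_perturbed / ERKPP_baseline)} against the
#' unperturbed variant.
#'
#' @param parameter \code{"k3"} or \code{"k8"}.
#' @param target_inhibition target in [0, 100) percent.
#' @param variant baseline variant (default EGFR_WT model).
#' @param tol_pp tolerance in percentage points (default 0.05).
#' @param egf_dose,t_read stimulus dose and read time.
#' @param ... passed to \code{simulate_pathway}.
#' @return List with \code{factor} and \code{achieved} inhibition.
#' @export
invert_inhibition <- function(parameter = c("k3", "k8"),
                              target_inhibition,
                              variant = make_variant("EGFR_WT",
                                                     reference_network()),
                              tol_pp = 0.05, egf_dose = 10, t_read = 5,
                              ...) {
  parameter <- match.arg(parameter)
  if (target_inhibition < 0 || target_inhibition >= 100)
    stop("target inhibition must lie in [0, 100)")
  base <- .readout_at(variant, "ERKPP", egf_dose = egf_dose,
                      t_read = t_read, ...)
  if (base <= 0) stop("baseline ERKPP is zero; inhibition undefined")
  inhib <- function(lf) {
    v <- .readout_at(variant, "ERKPP",
                     multipliers = setNames(10^lf, parameter),
                     egf_dose = egf_dose, t_read = t_read, ...)
    100 * (1 - v / base)
  }
  if (target_inhibition == 0)
    return(list(factor = 1, achieved = 0))
  lo <- -6; hi <- 0
  f_lo <- inhib(lo)
  if (f_lo < target_inhibition) {
    scan <- vapply(seq(-6, 0, by = 0.5), inhib, numeric(1))
    stop(sprintf(
      "target %.1f%% unreachable for %s within factor range [1e-6, 1]; scan: %s",
      target_inhibition, parameter,
      paste(sprintf("%.2f", scan), collapse = " ")))
  }
  # bisection: inhibition decreases as the factor rises toward 1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- inhib(mid)
    if (abs(fm - target_inhibition) < tol_pp) {
      return(list(factor = 10^mid, achieved = fm))
    }
    if (fm > target_inhibition) lo <- mid else hi <- mid
  }
  fm <- inhib((lo + hi) / 2)
  if (abs(fm - target_inhibition) >= max(tol_pp, 0.5))
    stop(sprintf("bisection failed to bracket %.2f%% (achieved %.2f%%): response may be non-monotone",
                 target_inhibition, fm))
  list(factor = 10^((lo + hi) / 2), achieved = fm)
}

#' Classify the combined Mig6 + gefitinib perturbation
#'
#' For each inhibitory intensity X on the grid: find the k3 factor and the
#' k8 factor that individually achieve X/2 percent ERKPP inhibition, apply
#' both together, and classify the combined inhibition as additive
#' (within \code{eps} percentage points of X), antagonistic (less than
#' X - eps) or synergistic (more than X + eps).
#'
#' @param X_grid inhibitory intensities in percent (default 0, 10, ..., 90).
#' @param variant baseline variant (default EGFR_WT model).
#' @param eps additivity tolerance in percentage points (default 0.5).
#' @param egf_dose,t_read stimulus dose and read time.
#' @param ... passed to \code{simulate_pathway}.
#' @return Data frame with columns X, k3_factor, k8_factor,
#'   combined_inhibition, class.  Inversion failures are reported per row
#'   (class NA), not fatal.
#' @export
classify_combination <- function(X_grid = seq(0, 90, by = 10),
                                 variant = make_variant("EGFR_WT",
                                   reference_network()),
                                 eps = 0.5, egf_dose = 10, t_read = 5,
                                 ...) {
  base <- .readout_at(variant, "ERKPP", egf_dose = egf_dose,
                      t_read = t_read, ...)
  rows <- lapply(X_grid, function(X) {
    res <- tryCatch({
      f3 <- invert_inhibition("k3", X / 2, variant, egf_dose = egf_dose,
                              t_read = t_read, ...)
      f8 <- invert_inhibition("k8", X / 2, variant, egf_dose = egf_dose,
                              t_read = t_read, ...)
      v <- .readout_at(variant, "ERKPP",
                       multipliers = c(k3 = f3$factor, k8 = f8$factor),
                       egf_dose = egf_dose, t_read = t_read, ...)
      comb <- 100 * (1 - v / base)
      cls <- if (abs(comb - X) <= eps) "additive"
             else if (comb < X - eps) "antagonistic" else "synergistic"
      data.frame(X = X, k3_factor = f3$factor, k8_factor = f8$factor,
                 combined_inhibition = comb, class = cls,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(X = X, k3_factor = NA_real_, k8_factor = NA_real_,
                 combined_inhibition = NA_real_, class = NA_character_,
                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}

#' @export
print.egfr_index_grid <- function(x, ...) {
  cat(sprintf("%s over %s x %s\n", x$definition, x$pair[1], x$pair[2]))
  print(signif(x$index, 5))
  invisible(x)
}
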