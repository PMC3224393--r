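---
title: "Kinetic modelling of EGFR-ERK signalling and gefitinib response in H1299 variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of EGFR-ERK signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrpath)
```

## The model

`egfrpath` implements a deterministic, single-compartment ODE model of EGF
receptor signalling to ERK in H1299 non-small-cell lung cancer cells.  The
network has 27 reaction steps over 29 components, 27 of which are
integrated states.  The receptor module is of the classical
receptor-adaptor type: EGF binds EGFR (step 1), occupied receptors
dimerise (2), dimers autophosphorylate with rate constant `k3` (3) and are
dephosphorylated by a lumped phosphatase (4, Michaelis-Menten).
Phosphorylated dimers bind Cbl (5) and are internalised and degraded into
a counted sink (6), bind GAP (7), or bind Shc (8), which is then
phosphorylated (9).  ShcP can be released (10) and dephosphorylated (11,
MM), or recruit the Grb2/SOS pair (12) to form the signalling complex
E11P/ShcP/Grb2/SOS, whose dissociation products (13, 14) recycle.  The
complex catalyses Ras GDP-to-GTP exchange (15, MM); RasGTP is hydrolysed
basally (16, MM) and, much faster, by receptor-bound GAP (17, MM).
RasGTP activates Raf1 (18), which is deactivated by a lumped phosphatase
(19); active Raf1 doubly phosphorylates MEK (20, 22) against PP2A (21,
23), and MEKPP doubly phosphorylates ERK (24, 26) against MKP3 (25, 27).
Steps 4, 11 and 15-27 are Michaelis-Menten; all other steps are mass
action.

Two modelling conventions deserve note:

* **EGF is a clamped bath.** Doses are in the 0.1-10 nM range while the
  overexpressing lines carry ~100 nM receptor; if free ligand were
  consumed stoichiometrically it would be depleted within minutes and no
  dose-response would survive.  The extracellular medium is vastly larger
  than the cell volume, so EGF is carried as a state with zero net flux.
  It still counts among the 27 integrated states.
* **Component count.** The 29 components are the 27 states (including the
  clamped EGF bath and the degradation sink, which makes receptor mass
  auditable) plus PP2A and MKP3, carried as constant species whose
  concentrations enter the maximal rates of steps 21/23 and 25/27 as
  `kcat * [phosphatase]`.  Lumping them into bare Vmax constants would
  have been equivalent dynamically; keeping them explicit preserves the
  declared component count and lets phosphatase abundance be perturbed.

Where the narrative network description admits two readings we chose:
step 11 is the Michaelis-Menten dephosphorylation of free ShcP (the
rate-law assignment is explicit about steps 4, 11, 15-27, which
arbitrates over reading step 11 as a plain dissociation); steps 16/17
are split into basal hydrolysis (16) and hydrolysis catalysed by
receptor-bound GAP (17), which realises "deactivation accelerated by
receptor-associated GAP" while keeping a drug-free deactivation route.

## The four cell-line variants

| variant | meaning | implementation |
|---|---|---|
| `WT` | parental H1299, low endogenous EGFR | EGFR(0) = 10 nM |
| `EGFR_WT` | overexpressed wild-type EGFR | EGFR(0) = 100 nM |
| `L858R_A` | L858R + endogenous Mig6 | EGFR(0) = 100 nM; k3 x 0.15, k5 x 0.5, k7 x 0.5, k8 x 0.15 |
| `L858R_B` | L858R + enhanced Cbl degradation | EGFR(0) = 100 nM; Cbl(0) = 80 nM |

Mig6 binds the active EGFR kinase domain, so its overexpression is
represented implicitly as multiplicative slow-downs of receptor
autophosphorylation (`k3`) and of phospho-receptor binding to Cbl, GAP
and Shc (`k5`, `k7`, `k8`) — no explicit Mig6 species is introduced.
Gefitinib is likewise a multiplicative factor `alpha` on `k3`, applied
for the whole simulation; drug pre-incubation needs no separate phase
because the unstimulated state is exactly stationary.  Variants never
mutate the shared base network: overrides and multipliers are applied at
simulation time.

## Parameters, units, and calibration

Concentrations are nM and time is minutes; bimolecular constants are
1/(nM min), Michaelis constants nM.  The authoritative fitted parameter
tables of the original study ship only in its supplementary material,
which is not bundled here, so `default_parameters()` carries fallback
values: magnitudes seeded from the classical receptor-module and
MAPK-cascade ancestor models this network descends from, then calibrated
**once** so that the four variants jointly reproduce the hallmark
behaviours of the H1299 panel:

1. the EGFR-overexpressing line sets the panel-wide maximum for all four
   phospho readouts (the normalisation anchor);
2. ERK output of `EGFR_WT` is nearly insensitive to gefitinib down to
   `alpha = 5e-4` while `L858R_A` is inhibited by orders of magnitude,
   with comparable upstream (pEGFR/pShc) responses — and `L858R_B` fails
   to show the ERK effect;
3. inhibition is amplified at the MEK and ERK
   phosphorylation/dephosphorylation cycles, not at Ras/Raf;
4. combining Mig6-type (`k8`) and gefitinib-type (`k3`) inhibition is
   synergistic on ERKPP.

The mechanism behind 2-4 is zero-order ultrasensitivity: the MEK and ERK
dephosphorylation steps run saturated (small `Km21`, `Km23`, `Km25`), so
each cycle acts as a switch whose threshold sits far below the baseline
drive of the overexpressing model but above the residual drive of the
Mig6 model under strong gefitinib.  A consequence worth knowing when
extending the model: because every variant's baseline sits deep in the
saturated zone, the MEK/ERK panel maxima of the receptor-overexpressing
variants are separated only by tiny margins (relative differences around
1e-6 to 1e-7 at the default tolerances), which is why simulations default
to tight tolerances (`rtol = 1e-10`, `atol = 1e-12`; the solver is
`deSolve`'s lsoda, stiff-capable).  The pEGFR and pShc maxima are
separated by healthy margins (>10%).  These defaults were frozen before
the test suite was written and are not revisited by any test.

Parameter search bounds default to two decades either side of each value.

## Estimation

The objective is the sum over cell lines, phospho proteins and the time
points {1, 5, 10, 30} min of squared differences between normalised data
and normalised simulation.  Normalisation follows the western-blot
procedure: per protein, each series' t = 0 value is subtracted, then all
series within a dose panel are divided jointly by the panel maximum.

The estimation problem is decomposed into two stages solved in order:
stage A frees parameters of steps 1-17 (and any variant-level multipliers
or initial-concentration deltas, which act upstream) against pEGFR/pShc;
stage B freezes the stage-A winners and frees parameters of steps 18-27
against pMEK/pERK.  Upstream dynamics influence the downstream fit but
not conversely, which is what makes the decomposition sound; the stage-B
search structurally cannot touch a stage-A parameter.

The optimiser is a real-coded genetic algorithm on log10 parameters:
tournament selection, blend crossover, per-gene Gaussian mutation,
elitism, Nelder-Mead polish of the incumbent each generation, and
archive-based diversity control that resamples offspring falling within a
fixed radius (in normalised log space) of any archived elite.  The
original study's estimator is of this family (global stochastic search
with local refinement and diversity maintenance); its exact internals are
not published, so the algorithm here is a documented re-implementation
with every knob exposed in `ga_config()`.  Failed integrations score a
finite penalty (1e6) so ranking still works.  Runs are deterministic
given the seed and leave the caller's RNG stream untouched.

## Synthetic data and what passing tests mean

`generate_dataset()` emulates the study's measurement tables: simulate
each cell line at each dose, apply multiplicative log-normal noise
(densitometry noise scales with band intensity; default sdlog 0.1) plus a
small additive floor (1e-4, avoiding exact zeros) per replicate (default
2, as in duplicate blots), average replicates, and normalise per protein
across cell lines within a dose.  Ground truth travels only in a
provenance attribute that the fitting path never reads.

The generator does **not** emulate several features of real blots:
antibody cross-reactivity, lane-loading and transfer artefacts,
film/detector saturation, batch effects between days, or biological
heterogeneity between passages.  Parameter recovery on these data
therefore demonstrates that the estimation machinery is correct and that
trajectories are recoverable under the stated noise model — not that the
fallback parameter values are those of the real cells.  Because many
kinetic parameters are structurally non-identifiable from four normalised
readouts, the recovery contract is trajectory RMSE (< 0.02 noiseless,
< 0.05 at 5% noise per observable), not parameter equality; the default
harness frees a small representative subset (`k3`, `k8`, `kcat18`,
`kcat24`) spanning both stages.  Problem sizes in the shipped tests and
acceptance script (three cell lines, one dose, five time points, GA
population 20 for 8 generations) were chosen as the smallest
configuration that exercises both stages meaningfully.

## Perturbation analyses

* `alpha_scan()` reproduces the gefitinib dose scan: one simulation per
  `alpha` in {1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005}, responses
  at t = 5 min normalised per protein to the drug-free value.
* `r_index()` is the strong-inhibition ratio
  R_X = X(alpha = 0.0005) / X(alpha = 1) at t = 5 min under 10 nM EGF;
  `sensitivity_ratio()` is R_Shc / R_ERK, and `pairwise_index_grid()`
  evaluates it over factor grids for any two of the four Mig6-affected
  parameters (six pairs), the remaining two held at a fixed context.
* `downstream_amplification()` replaces the upstream output by the
  signalling complex E11P/ShcP/Grb2/SOS and ranks
  R_upstream / R_Y for Y in {RasGTP, Raf1A, MEKP, MEKPP, ERKP, ERKPP}.
  With the default parameters the ERKPP index at the Mig6 corner is
  astronomically large because ERKPP collapses through two stacked
  zero-order switches; the printed magnitude is therefore not a
  biologically calibrated number — the robust, parameterisation-stable
  statement is the ranking (MEK/ERK cycle outputs far above Ras/Raf).
* `invert_inhibition()` inverts the ERKPP-vs-factor curve by bisection on
  the log10 factor in [-6, 0] to 0.05 percentage points, with an explicit
  range error and a diagnostic scan when the target is unreachable.
* `classify_combination()` finds, for each intensity X, the `k3` and
  `k8` factors that individually give X/2 % ERKPP inhibition, applies
  both, and classifies the result as additive within `eps` percentage
  points of X, antagonistic below, synergistic above.  The additivity
  tolerance `eps` is not specified by the source analysis; the default is
  0.5 percentage points and the classification of the default model is
  insensitive to `eps` across [0.25, 1].  The baseline for inhibition
  percentages is the `EGFR_WT` model, to which both perturbations are
  applied.

## Numerical choices

* Solver: lsoda via `deSolve::ode` (automatic stiff/non-stiff switching,
  BDF when stiff), `rtol = 1e-10`, `atol = 1e-12`, 50000 step cap.  A
  hand-written C right-hand side backs the reference topology (about
  500x faster than the generic R interpreter, which remains available
  via `engine = "interpreted"` for declarative or SBML-imported networks
  and as a cross-check; the two agree to ~1e-8 on the default panel).
* Degenerate inputs: an all-zero panel normalises to zeros without
  division; a zero reference readout raises an explicit undefined-index
  error rather than propagating NaN; integration failures abort
  simulation (or score the penalty inside the objective).
* Ties and tie-breaks: the GA breaks fitness ties by population order
  (stable sort), making runs reproducible bit for bit.

## Interchange formats

The model round-trips through a declarative YAML file (species,
reactions, laws, parameters, bounds, variants) and through SBML Level 2
Version 4 written and parsed with `xml2`.  The SBML documents carry
standard constructs (species with boundary conditions, reactions with
stoichiometry, modifiers and MathML kinetic laws) plus a private
annotation recording each reaction's rate-law type, which makes
re-import lossless; `diff_networks()` reports structural differences
between an imported document and the built-in network.  Measurement
tables are plain CSV with a documented column contract and line-numbered
validation errors.

## Known limitations

* Single well-mixed compartment; no receptor trafficking beyond the one
  degradation step; no stochasticity.
* The fallback parameterisation reproduces the qualitative physiology of
  the panel, not the quantitative values of the original fit; headline
  index magnitudes (for example the R_Shc/R_ERK ratio of the Mig6 model)
  are far larger than a fitted parameterisation would give, though their
  orderings and ratios between variants are the meaningful, tested
  quantities.
* The gefitinib abstraction (`alpha` on `k3`) has no pharmacokinetic
  mapping to molar drug dose.
* `pERK` follows the doubly-phosphorylated antibody (ERKPP only) and
  `pMEK` the Ser217/221 antibody (MEKP + MEKPP); both mappings are
  configurable in `phospho_observable_map()` should a different antibody
  convention be needed.
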