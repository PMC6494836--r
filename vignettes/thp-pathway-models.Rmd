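---
title: "Kinetic models of DHPAAS-mediated tetrahydropapaveroline production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of DHPAAS-mediated tetrahydropapaveroline production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thpkin)
```

## The system being modeled

Tetrahydropapaveroline (THP, norlaudanosoline, C16H17NO4) is the entry
point of the benzylisoquinoline alkaloid (BIA) pathway that leads to
reticuline and the opioids. THP forms by a spontaneous Pictet–Spengler
condensation between one molecule of dopamine and one molecule of
3,4-dihydroxyphenylacetaldehyde (DHPAA), so every THP consumes two
DOPA-equivalents. Microbial THP production can be wired in several ways
from L-DOPA:

* **Nonsymmetrical (MAO) route.** DOPA decarboxylase (DDC) makes
  dopamine; monoamine oxidase (MAO) then oxidises dopamine to DHPAA.
  The two condensation partners are made in series.
* **Symmetrical (DDC–DHPAAS) route.** DDC makes dopamine while the
  insect enzyme DHPAA synthase (DHPAAS) makes DHPAA directly from
  L-DOPA. The partners are made in parallel from the same substrate.
* **Single bifunctional enzyme.** An engineered DHPAAS carries flux to
  *both* products; the fraction routed to the aldehyde branch is the
  partition parameter `phi_aldehyde`, the "% DHPAAS activity" of a
  variant divided by 100.

The package provides the ODE models of these three topologies, a
Monte-Carlo machinery to compare them under parameter uncertainty,
Michaelis–Menten fitting for characterizing DHPAAS variants from
H2O2-production assays, deterministic mass/yield arithmetic for the
alkaloid bookkeeping, and an active-site signature classifier for
AAAD-family sequences.

## The ODE model

The state is `(S, DA, AL, T)` — L-DOPA, dopamine, DHPAA and THP in mM —
plus two bookkeeping integrals, cumulative substrate fed and cumulative
DHPAA drained. With `V_DDC`, `V_MAO` and the split DHPAAS velocity
`V_ald + V_dec`:

```
dS/dt  = feed − V_DDC − (V_ald + V_dec)
dDA/dt = V_DDC + V_dec − V_MAO − k_cond·DA·AL
dAL/dt = V_ald + V_MAO − k_cond·DA·AL − k_drain·AL
dT/dt  = k_cond·DA·AL
```

All enzymatic velocities are irreversible Michaelis–Menten laws with
competitive inhibition entering through an effective Michaelis constant
`Km_eff = Km·(1 + Σ I/Ki)`. This is the simplest family consistent with
a competitive mechanism; the condensation is elementary second-order
mass action because it is non-enzymatic. Product feedback inhibition,
when enabled, follows the products each enzyme sees: dopamine inhibits
DDC and the decarboxylation branch, dopamine and DHPAA inhibit DHPAAS,
and DHPAA inhibits MAO. MAO additionally sees a fixed competing-amine
pool in every model, reflecting its broad amine specificity. THP itself
is assumed not to feed back — no inhibition by THP has been
characterized — and O2, CO2, H2O2 and NH4+ are not state variables:
they do not couple back into the modeled dynamics (cumulative H2O2 can
be recovered post hoc as the integral of the aldehyde-branch flux).

The DHPAA "drain" is a first-order loss `k_drain·AL` representing
chemical and enzymatic side reactions of this very reactive aldehyde;
first-order is the minimal model for an unspecified mechanism, and the
drained amount is tracked so that the DOPA-equivalent balance

```
S + DA + AL + 2·T + drained − fed = constant
```

is conserved to solver tolerance. `conservation_residual()` reports the
worst relative imbalance of a trajectory and is the package's primary
regression guard on the integrator.

### Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
  `atol = 1e-10`, with a 501-point uniform output grid over the default
  0–50 h horizon. These tolerances keep the conservation residual
  comfortably below the 1e-6 target used in the tests.
* Substrate feeding is a constant term that stops when the cumulative
  fed amount reaches `feed_cap` (default 100 mM). Because the feed
  integral is linear in time, the crossing time is computed analytically
  and the integration is restarted there with the integral pinned to the
  cap — the fed amount can never overshoot, which keeps the conservation
  accounting exact.
* Rate laws clamp concentrations at zero, so solver-tolerance undershoot
  cannot reverse a flux; output values below zero by more than a
  tolerance-scaled bound are treated as integration failures, tiny ones
  are clamped to zero.
* The THP yield is reported on the DOPA-equivalent molar basis,
  `100·2·T(t_end) / (initial DOPA-equivalents + fed)`, matching the 2:1
  L-DOPA:THP stoichiometry used in the worked titer conversions.

### A structural property worth knowing

For the single bifunctional enzyme with symmetric consumption of the two
products, the yield as a function of `phi_aldehyde` is maximized at
0.5 — the balanced split — and falls off symmetrically (tested over a
0.05–0.95 scan). Balance of dopamine and DHPAA production is the central
design criterion for bifunctional DHPAAS engineering.

## Monte-Carlo ensembles

`run_ensemble()` samples each named parameter uniformly (linear scale)
or log-uniformly (log scale, the default choice for constants spanning
more than an order of magnitude, which keeps neither bound dominating)
and integrates 10,000 models by default over 0–50 h; the tests and the
acceptance script use 200 iterations per scenario, which is enough to
stabilize the median orderings while keeping runtimes in minutes.
Yields are summarized by box statistics (median, quartiles by the
linear-interpolation percentile convention, mean, min, max). Failed
integrations are excluded, never imputed, and their count is reported;
more than 1% failures raises a warning and 100% an error.

Two RNG design decisions matter for reproducibility and comparisons:

* Every iteration derives its own substream from the ensemble seed, so
  two ensembles sharing a seed and a common prefix of the range table
  draw *identical* values for the shared parameters (common random
  numbers). The shipped range tables list `k_drain` last for exactly
  this reason: a drain and a no-drain ensemble with the same seed are
  pathwise paired, and since draining DHPAA can only remove product,
  every paired yield — and hence the median — is lower with drain.
* `compare_scenarios()` splits a master seed into independent
  per-scenario streams, so adding a scenario never perturbs the others.

### The default range table

The original ensemble study drew parameters from a literature/BRENDA
survey that is not reproduced here, so the packaged table
(`inst/extdata/fig2_grid_ranges_synthetic.csv`, returned by
`gen_default_ranges()`) is a documented synthetic stand-in. Its choices:

* Soluble, overexpressed DDC and DHPAAS: `Vmax` 1–50 mM/h (log), `Km`
  0.02–2 mM (DDC) and 0.01–1 mM (DHPAAS, bracketing the measured tens
  of µM), `Ki` 0.1–10 mM.
* MAO: `Km` 0.05–2 mM, `Ki` 0.1–10 mM, but `Vmax` 0.05–2 mM/h — an
  order of magnitude below the soluble enzymes. This encodes the
  premise that motivates DHPAAS engineering in the first place:
  effective whole-cell MAO flux is small (membrane-bound, hard to
  express, promiscuous; the best MAO-mediated benchmark converted
  12.6 mM dopamine at 15.9% over days, i.e. well under 1 mM/h).
  A 10 mM competing-amine pool acts on MAO in every scenario.
* Spontaneous condensation `k_cond` 0.1–10 mM⁻¹h⁻¹ (log), drain
  `k_drain` 0.05–1 h⁻¹ (log), feed rate 1–4 mM/h (linear) against the
  100 mM cap.

This calibration is load-bearing for the qualitative scenario ordering:
with irreversible MM kinetics a *serial* DDC→MAO pathway is
self-balancing (MAO flux stops whenever dopamine runs short, so the two
condensation partners never diverge), and if MAO is given the same
velocity range as the soluble enzymes the MAO pathway's median yield
*exceeds* the symmetrical pathway's. The published ordering — the
symmetrical design winning once drain and feedback are modeled — emerges
from MAO's handicap, not from the topology alone. Users probing other
regimes can edit the CSV; the package makes no attempt to defend the
ordering outside the shipped ranges.

## Michaelis–Menten fitting

`mm_fit()` fits `v = Vmax·S/(Km+S)` by nonlinear least squares
(Levenberg–Marquardt first, a bounded port fit and a fresh-start
restart as fallbacks; Hanes–Woolf linearisation supplies starting
values). Three reporting decisions:

* **Outlier policy.** Iterative studentized-residual elimination: after
  each fit the single worst point with `|r| > 3` (leverage-corrected via
  the gradient matrix) is removed and the model refit, up to 20% of the
  data. The assays this emulates discarded one or two gross outliers per
  variant without naming an algorithm; one-at-a-time deletion with a cap
  is the conservative default.
* **Confidence intervals.** Profile likelihood (`confint` on the
  underlying `nls` object), because kinetic-parameter intervals are
  visibly asymmetric at realistic noise. Where a profile is flat or
  profiling fails (e.g. noise-free data), the curvature-based asymptotic
  interval is substituted and flagged in the `"method"` attribute —
  never silently.
* **Partition percentage.** `percent_aas()` reports
  `100·v_aas/(v_aas+v_ddc)` rounded to two significant figures, the
  convention of the published variant table (95, 67, 22, 5.9).

Closed-loop behaviour under the synthetic generator: noise-free data
reproduce the generating `Km`/`kcat` to 1e-6 relative; at 5% CV noise
with 16 points the 95% profile intervals cover the true `Km` in roughly
19 of 20 seeded replicates (the acceptance suite requires at least 85%
over 200 replicates).

## Chemistry bookkeeping

`bia` arithmetic is fully deterministic: element masses come from an
embedded 2021 IUPAC standard-atomic-weight table and a principal-isotope
monoisotopic table, with the electron mass 0.000548579909 u applied to
every charged species. The `M-3H` adduct is defined as loss of three
hydrogen *atoms* followed by loss of one electron — the quinone-type
oxidation ion of catechol alkaloids — which reproduces the observed THP
quinone at m/z 284.0917. One reporting caveat: the published titer
conversions used 287 g/mol for THP (three figures); the full-precision
average mass is 287.315, so 9.45 µM converts to 2.7151 mg/L, which
agrees with the printed 2.71 to 0.2% but differs in the third
significant figure. The package returns full precision and leaves
presentation rounding to the caller.

## Active-site signature classification

Queries are aligned to a reference (Needleman–Wunsch global alignment
via Biostrings, BLOSUM62, gap open 10 / extend 1, a gap of length L
costing `open + extend·L`), and the residues aligned to reference
positions 79, 80 and 192 (1-based reference numbering) are read off.
The rule table: F79-Y80-N192 is DHPAAS-like, Y79-F80-H192 is DDC-like,
any other combination of F/Y at 79–80 with N/H at 192 is intermediate
(with a note recording the archetype mix, e.g. the Y79-Y80 motif of
some insect isoform-X2 sequences), and a gap, an X, or a non-archetype
residue makes the call undetermined. No quantitative activity
prediction is attached to intermediate calls — the mapping from mixed
triads to partition percentages is an experimental question, not a rule.

The alignment score is validated against an exhaustive enumeration
oracle over a 3-letter alphabet: every pair up to length 3 exhaustively
(1,521 pairs in the unit suite), plus seeded random pairs up to length
6. Full enumeration of *all* pairs up to length 6 would be ~1.2 million
pairs with up to ~9,000 alignment paths each; the chosen depth keeps the
check exhaustive where enumeration is cheap and sampled where it is not.

## What the synthetic generators do and do not emulate

The generators produce: MM rate data with multiplicative (CV) Gaussian
noise — chosen over additive noise because fluorometric assay error
scales with signal — and injected gross outliers; noisy observations of
simulated trajectories alongside their exact truth; and sequence
families with planted triads and uniform random substitutions away from
the triad. They do not emulate instrument-level artifacts (plate-reader
drift, LC-MS chromatograms), real phylogenetic correlation structure, or
biological replicate hierarchies. Tests passing on these fixtures
demonstrate correctness of the algorithms under their stated noise
models, not robustness to every failure mode of real assay data.

## Problem sizes used by the shipped tests

Unit and acceptance tests run at deliberately modest sizes chosen as the
smallest that make the checked properties stable: 100 random models for
the conservation sweep, 200 Monte-Carlo iterations per scenario and five
master seeds for the ordering checks, 200 replicates for CI coverage,
200 synthetic sequences for the classification closed loop, length-3
exhaustive alignment enumeration. The defaults of the exported functions
(10,000 iterations, 501-point grids) are the full study conditions.

## Known limitations

* Rate-law forms beyond competitive-inhibition MM (substrate inhibition
  at high L-DOPA, reversibility, pH/temperature effects) are not
  modeled; no compartmentalization or transport.
* The ensemble range table is a synthetic stand-in; scenario *medians*
  are therefore not comparable to published figures — only orderings
  are, and only within the documented ranges.
* Intermediate signature calls are qualitative; no tree building or
  database search is included.
* Downstream methyltransferase kinetics (6-OMT/CNMT/4-OMT) appear only
  as fold-change bookkeeping, not in the ODE.
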