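# thpkin

Kinetic modelling and enzyme characterization for microbial production
of tetrahydropapaveroline (THP), the benzylisoquinoline alkaloid (BIA)
precursor of reticuline and the opioids.

THP forms by spontaneous Pictet–Spengler condensation of dopamine with
3,4-dihydroxyphenylacetaldehyde (DHPAA), so two L-DOPA equivalents are
consumed per THP. The package is built around the bifunctional insect
enzyme DHPAA synthase (DHPAAS), which can produce *both* condensation
partners from L-DOPA, and covers the computational layer of engineering
such a pathway:

* **Pathway ODE models** of three topologies — the nonsymmetrical
  DDC→MAO route, the symmetrical DDC + DHPAAS route, and a single
  bifunctional DHPAAS — with constant substrate feeding up to a cap,
  competitive product-feedback inhibition (`Km_eff = Km(1 + Σ I/Ki)`),
  second-order condensation `k_cond·[DA]·[DHPAA]`, and first-order DHPAA
  drain. Trajectories conserve DOPA-equivalents
  (`S + DA + AL + 2T + drained − fed`) to solver tolerance.
* **Monte-Carlo ensembles** over parameter ranges (uniform or
  log-uniform), summarized as box statistics of the molar THP yield
  `100·2T/(input)`, with seeded, paired comparisons across scenario
  grids (drain on/off × feedback on/off × topology).
* **Michaelis–Menten fitting** (`v = Vmax·S/(Km+S)`, `kcat = Vmax/E0`)
  with iterative studentized-residual outlier elimination and
  profile-likelihood confidence intervals, for H2O2-production assays of
  DHPAAS variants, plus the bifunctional activity partition
  `%AAS = 100·v_aas/(v_aas + v_ddc)`.
* **Alkaloid bookkeeping**: Hill-notation formula parsing, average and
  monoisotopic masses, adduct m/z (including the `[M−3H]+` quinone
  oxidation ion of catechols), µM↔mg/L conversion, stoichiometric molar
  yields, fold changes.
* **Active-site signature classification** of AAAD-family protein
  sequences: global alignment to a reference, then the
  F79/Y80/N192-vs-Y79/F80/H192 rule table (DHPAAS-like, DDC-like,
  intermediate, undetermined).
* **Seeded synthetic-data generators** for all of the above, emitting
  ground-truth sidecars for closed-loop validation.

## Worked example

```r
library(thpkin)

## a bifunctional DHPAAS fed 2 mM/h L-DOPA up to 100 mM, balanced split
spec <- pathway_spec("SINGLE_DHPAAS_PATH",
                     dhpaas = enzyme_params(4, 0.1),   # Vmax mM/h, Km mM
                     phi_aldehyde = 0.5, k_cond = 2, feed_rate = 2)
simulate_pathway(spec, t_end = 50)
#> THP pathway trajectory (SINGLE_DHPAAS_PATH), 501 points over [0, 50] h
#>   final: S = 0.1, DA = 0.7071, AL = 0.7071, THP = 49.24 mM
#>   fed = 100 mM, drained = 0 mM, yield = 98.5%
```

98.5% of the 100 mM L-DOPA fed ended up in THP (49.24 mM, two
DOPA-equivalents each); the leftover dopamine and DHPAA pools are equal
because the split is balanced.

```r
## characterize a variant from a synthetic H2O2 rate assay (5% noise)
d <- gen_mm_dataset(km = 41.7, kcat = 6.51, enzyme_conc = 1,
                    noise_cv = 0.05, seed = 7)
summary(mm_fit(d$substrate, d$rate, enzyme_conc = 1))
#> Michaelis-Menten fit with profile-likelihood intervals
#>   Km   = 46.43 (40.05-53.79)
#>   Vmax = 7.032 (6.748-7.329)
#>   kcat = 7.032 (6.748-7.329)
#>   residual SS 0.6402 on 16 kept points (0 outliers, 0 rounds)

percent_aas(115, 5.59)                       # wild-type partition
#> [1] 95
round(monoisotopic_mz("C16H17NO4", "M-3H"), 4)  # THP-quinone ion
#> [1] 284.0917
classify_signature("Y", "Y", "N")
#> intermediate (Y-Y-N): 79/80 mixed archetype (Y79-Y80); 192 DHPAAS-type
```

The fitted Km of 46.4 µM carries a profile interval (40.0–53.8) that
covers the generating value 41.7 µM; the partition says 95% of the
wild-type enzyme's flux goes to the aldehyde branch; the Y79-Y80-N192
triad is a mixed archetype between synthase and decarboxylase.

See `vignette("thp-pathway-models")` for the model equations, the
parameter-range rationale, and numerical details.

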