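---
title: "Partitioning N2O sources by multi-isotope mass balance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning N2O sources by multi-isotope mass balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2osource)
```

## The inference problem

A sediment core incubated under continuous flow reaches a steady state in
which the effluent composition is time-invariant, so the net flux of any
dissolved species is `(effluent − influent) × flow rate / area`. The N₂O
efflux so measured is the net of up to five production pathways and one
consumption pathway. `n2osource` treats the production side as a
four-component mixture — bacterial denitrification (bDNF), a high-SP
NO₂⁻-consuming pathway (fungal denitrification fDNF in case 1, or
chemodenitrification cDNF in case 2), ammonia oxidation via NH₂OH
decomposition (AMO, bacterial and archaeal pooled), and
nitrifier-denitrification (nDNF) — and treats respiratory N₂O reduction as
a prescribed modification of the mixed signal, not a solved unknown.

Three steady-state observables constrain the four fractions (with the
closure constraint supplying the fourth equation):

1. **Δδ¹⁵N** — the offset δ¹⁵N(NO₃⁻) − δ¹⁵N(N₂O). Each process carries an
   endmember offset on this common NO₃⁻-referenced scale.
2. **SP** — the N₂O site preference δ¹⁵Nα − δ¹⁵Nβ, set by the enzyme (or
   abiotic mechanism) forming the N–N bond and insensitive to the
   substrate's δ¹⁵N.
3. **Δ¹⁷O ratio** — when the nitrate supply carries a ¹⁷O anomaly,
   Δ¹⁷O(N₂O)/Δ¹⁷O(NO₂⁻) is the fraction of N₂O oxygen that derives from
   the anomalous NO₂⁻/NO₃⁻ pool, because mass-dependent fractionation
   moves δ¹⁷O and δ¹⁸O along a slope-λ line and leaves Δ¹⁷O unchanged.
   Only O-atom incorporation from O₂ or H₂O (anomaly ≈ 0) dilutes it.

The linear system solved by `build_system()`/`solve_fractions()` is

```
closure:   Σ fᵢ                  = 1
oxygen:    Σ fᵢ oᵢ               = Δ¹⁷O_N2O / Δ¹⁷O_NO2
nitrogen:  Σ fᵢ Δδ¹⁵Nᵢ − f_red ε15 = Δδ¹⁵N_meas
SP:        Σ fᵢ SPᵢ    − f_red εSP = SP_meas
```

### Assumptions

* **Steady state.** All pools and isotope deltas are time-invariant over
  the analysis window; offsets, not Rayleigh distillation curves, encode
  the fractionation (open-system, supply-limited regime).
* **Four processes, one high-SP reductive pathway at a time.** fDNF and
  cDNF occupy the same corner of (SP, O-transfer) space; solving with both
  simultaneously would be collinear. They are evaluated as alternative
  cases (`default_endmembers("fDNF")` / `"cDNF"`).
* **Reduction is prescribed.** With four equations and four fractions,
  f_red cannot also be estimated; it is swept as a scenario input
  (defaults 0.1 and 0.9, a low- and a high-consumption case). The SP
  balance carries the reduction term with εSP = −6 ‰, signed so that
  larger f_red *raises* the SP of the residual N₂O; the Δδ¹⁵N balance
  carries no reduction term by default (ε15 = 0, configurable). The
  oxygen row never carries one: reduction is mass-dependent and cannot
  alter Δ¹⁷O.
* **TRN as NH₄⁺ proxy.** The δ¹⁵N of total reduced nitrogen (TDN minus the
  molar contribution of NO₃⁻ and NO₂⁻; `trn_d15n()`) stands in for the
  δ¹⁵N of the ammonium substrate when building the AMO endmember.

## Parameters and defaults

### Endmembers

The shipped default set (`default_endmembers()`, mirrored in
`inst/extdata/endmembers_default.yml`) is a literature-guided working
parameterisation, labelled non-authoritative and fully overridable. Units
are permil throughout; `o_transfer` is dimensionless in [0, 1].

| process | Δδ¹⁵N | SP | o_transfer | rationale |
|---|---|---|---|---|
| bDNF | 0 ± 2 | −5 ± 5 | 1 | diffusion limitation suppresses expression of the intrinsic N isotope effect in organic-rich sediments; bacterial NOR yields low/negative SP |
| fDNF | 0 ± 2 | 37 ± 3 | 1 | fungal P450nor clusters near 35–37 ‰ SP; 37 is the conservative (high) choice, probed downward (30.3) in a scenario |
| cDNF | 0 ± 2 | 16 ± 5 | 1 | Fe(II)-driven nitrite reduction reports SP generally above 10 ‰ and up to ~26 ‰ |
| AMO | data-dependent | 33 ± 4 | 0 | NH₂OH-route SP is high; O comes from O₂/H₂O, no anomaly transfer |
| nDNF | 56.9 ± 5 | −5 ± 5 | 0 | large net N offset under O₂-limited nitrifier growth; assumed to reduce nitrifier-internal NO₂⁻ carrying no ¹⁷O label (probed with o_transfer = 1 in a scenario) |

The AMO Δδ¹⁵N endmember is built per record as
`(δ¹⁵N_NO3 − δ¹⁵N_NH4) + ε` with ε = 3.7 ± 3 ‰ (N₂O depleted relative to
the NH₃ source), so it moves with the measured pools rather than being a
fixed constant (`amo_dd15n()`).

Reduction constants: εSP = −6 ‰, ε15 = 0 ‰, both configurable on the
endmember set, not perturbed in the Monte Carlo (they are treated as fixed
literature constants; the perturbed quantities are the endmember Δδ¹⁵N and
SP values, the AMO ε and all measurements).

### Δ¹⁷O convention

`cap_delta_17o()` supports the linear form Δ¹⁷O = δ¹⁷O − λδ¹⁸O (default,
λ = 0.52) and the logarithmic form
1000·[(1+δ¹⁷O/1000)/(1+δ¹⁸O/1000)^λ − 1]. The linear form with λ = 0.52 is
the dominant convention in nitrate ¹⁷O work and is the package default;
both are exposed because published data sets mix conventions. The two
differ quadratically, about λ(1−λ)δ¹⁸O²/2000 — under 0.05 ‰ for
|δ¹⁸O| ≤ 15 ‰ but ~0.3 ‰ by δ¹⁸O = 50 ‰ — so the convention should be
matched to the data source before comparing anomalies near the 1 ‰
informative floor. λ is validated to (0.5, 0.535].

### Numerical choices

* **Informative-anomaly floor** (`floor = 1` ‰): the precursor ratio is
  refused when |Δ¹⁷O(NO₂⁻)| < 1 ‰, where the ratio of two small noisy
  anomalies carries no information. Unlabelled (low-nitrate) records fail
  loudly with a missing-measurement error rather than returning a
  meaningless partition. Monte Carlo draws crossing the floor are counted
  infeasible.
* **Feasibility tolerance** (`feas_tol = 0.02`): raw fractions in
  [−0.02, 1.02] are treated as solvable-with-noise; anything further out
  flags the record (or draw) as violating mass balance.
* **Clipping rule** (`clip_renormalize()`): negative fractions are set to
  zero and the remainder rescaled to sum to 1 — the presentation rule for
  stacked contribution figures. It is idempotent, applied per Monte Carlo
  draw (so summaries live on the simplex), and errors if no fraction is
  positive. Raw fractions are always reported alongside for diagnostics.
* **Collinearity**: the 4×4 system is rank-checked before solving;
  duplicate endmember signatures are named in the error.
* **Steady-state detection** (`detect_steady_state()`): the largest
  trailing window starting at or after `min_day = 3` whose fitted linear
  trend of (effluent − influent), relative to the window mean, is below
  `slope_tol = 0.05` per day. A trailing-trend test was chosen over a
  changepoint model because the domain rule of thumb ("steady after about
  3 days") calls for something simple, reported and overridable. A
  concentration floor of 0.05 µM guards the relative-trend denominator for
  near-zero fluxes.
* **Flux uncertainty**: s.d. of the window-mean concentration difference
  and of the flow rate are propagated independently to first order —
  they are measured by different instruments, so no covariance is assumed.
  Per-timepoint fluxes are averaged; with constant flow this equals the
  flux of the averaged difference.

## Monte Carlo error propagation

`run_monte_carlo()` perturbs, per draw, every measurement (using the
record's own `_sd` columns) and every endmember parameter (using the
endmember `_sd` values and the AMO ε s.d.) by independent Gaussians,
re-derives the AMO endmember and the measured offsets from the perturbed
pools (so their correlations through shared pools are respected), solves,
clips, and summarises the clipped draws (mean, s.d., 2.5/50/97.5
percentiles). Independence across parameters is a deliberate model choice;
no covariance structure is estimated. The default is 10,000 draws;
summaries stabilise well before that. Draws outside the feasibility
tolerance are excluded and reported as an infeasible fraction; above 50%
the result carries a warning-level flag, since the summaries then describe
a strongly truncated distribution. Runs are bit-reproducible from an
integer seed, and `mc_partition()` derives per-core seeds from one master
seed.

At the noise scales of the bundled treatment-mean records, infeasible
fractions of 30–60% are normal: the endmember polytope is narrow in the
SP direction relative to ±3–5 ‰ noise, so many perturbed systems land
outside the simplex. This is information — it is how the case-2
(chemodenitrification) configuration reveals records it cannot explain —
not a numerical failure.

## The synthetic-data generator

The generator exists so that every stage — flux estimation, inversion,
Monte Carlo calibration — can be tested against known ground truth without
any external data.

* **Study design**: 3 sites × 4 treatments (LN, LOLN, HN, LOHN) × 2 cores
  = 24 cores, mirroring a realistic incubation campaign. Only the
  nitrate-amended treatments (HN/LOHN) carry the ¹⁷O label; generated
  LN/LOLN records have absent Δ¹⁷O fields and are rejected by the
  inversion, by design.
* **Truths**: per-core fractions are drawn from a Dirichlet distribution
  centred on a denitrification-dominated composition (bDNF : fDNF : AMO :
  nDNF = 45 : 36 : 12 : 8, normalised; concentration parameter 10), which
  allows occasional strongly fungal cores without making them typical.
  f_red defaults to 0.1. Per-core overrides are exposed rather than
  guessing a tighter between-core distribution.
* **Steady records**: the three observables are composed exactly by the
  forward model, converted to absolute pool compositions using the
  treatment's source values (δ¹⁵N(N₂O) = δ¹⁵N(NO₃⁻)_source − Δδ¹⁵N;
  Δ¹⁷O(N₂O) = o-ratio × Δ¹⁷O(NO₂⁻)_source), then jittered with independent
  Gaussian measurement noise. δ¹⁵N and SP noise follow the treatment-level
  dispersions of published incubation tables (e.g. SP ± 3 ‰); Δ¹⁷O noise
  is set at the analytical reproducibility scale (± 1.2 ‰) rather than the
  treatment-level spread (± 2.4 ‰), because a single core's steady-state
  record does not contain between-core heterogeneity — at a Δ¹⁷O(NO₂⁻)
  coefficient of variation of ~0.28 the O-ratio would acquire a
  ratio-of-Gaussians bias of several percent that is a property of the
  noise model, not of the inversion.
* **Time series**: effluent concentrations approach steady state as
  c(t) = c_ss + (c₀ − c_ss)·exp(−t/τ), τ = 1 d by default (so "steady
  after about 3 days" ≈ 3τ), sampled twice daily over 8 days, with flow
  jittered around 1.8 ± 0.06 mL min⁻¹ and additive concentration noise
  (1.0/0.2/0.5/0.003 µM for NO₃⁻/NO₂⁻/NH₄⁺/N₂O, i.e. a few percent of the
  signal, N₂O at IRMS precision).

What the generator does **not** emulate: porewater reaction–diffusion
structure and microsensor-scale heterogeneity, temporal drift in source
composition, covariance between endmembers, and non-Gaussian outliers.
Passing tests therefore demonstrate the correctness and calibration of the
inference given the assumed error model, not robustness to structured
model error in field data.

## Validation design and known limitations

The test suite validates at these problem sizes (chosen to exercise the
statistics while keeping a default run in tens of seconds): exact
forward–inverse round trips at 1,000 random truths × three reduction
fractions; agreement of the linear solve with a 0.01-resolution
brute-force simplex grid search on 50 random full-rank systems (truths
drawn on the grid, so the discrete optimum is exact); interval calibration
over 200 synthetic cores (2,000 draws each) with endmember truth drawn
from the endmember uncertainty — the central 95% interval is required to
cover each true fraction for 90–98% of cores; flux unbiasedness over 200
noisy replicates; and directional sensitivity of the built-in scenarios on
eight forward-generated high-nitrate records.

Known limitations:

* The inversion is exactly unbiased only in the quantities that enter
  linearly. The O-ratio is a ratio of noisy anomalies and the clipping
  step acts at the simplex boundary, leaving a second-order bias of order
  cv² (about 0.02 in absolute fraction at default noise) that shrinks
  quadratically as measurement noise shrinks; the suite asserts this
  behaviour rather than exact unbiasedness.
* Endmember values are the dominant systematic. The default table is a
  working choice; conclusions should always be read against
  `run_scenarios()` output, and the per-row `config_hash` ties every
  result to the endmember configuration that produced it.
* f_red is not identifiable from these data; results are conditional on
  the prescribed value and should be reported for the swept range.
* No Rayleigh (closed-system) reduction model, no joint Bayesian
  inversion, no covariance between endmembers: the model is deliberately
  the linear open-system mass balance described above.
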