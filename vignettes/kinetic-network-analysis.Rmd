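---
title: "Kinetic network analysis of single-molecule visibility trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic network analysis of single-molecule visibility trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmfkin)
```

## The measurement and its statistical observables

A polarization-sweep single-molecule fluorescence (PS-SMF) experiment on an
exciton-coupled dye dimer probe yields, per molecule, a time series of the
signal *visibility* `v(t)`, a dimensionless conformational reporter confined
to [−1, 1]. The raw signal is averaged over an integration (bin) period
`T_w`, giving a uniformly binned trajectory `v_1 … v_N` of scan duration
`T = N T_w`. Typical acquisition: `T ≈ 30` s, `T_w = 250` µs, ~100
trajectories per condition, ~8000 detected counts per second.

Because the underlying conformational dynamics are stochastic and stationary,
all information the analysis uses is carried by three ensemble statistics:

* the probability distribution `P(v)`, estimated as a pooled normalized
  histogram (`empirical_pdf()`);
* the two-point time-correlation function
  `C⁽²⁾(nΔt) = (1/(N−n)) Σ_i δv_{i+n} δv_i` (`two_point_tcf()`);
* the three-point time-correlation function
  `C⁽³⁾(nΔt, mΔt) = (1/(N−n−m)) Σ_i δv_{i+n+m} δv_{i+n} δv_i`
  (`three_point_tcf()`),

with `δv_i = v_i − ⟨v⟩`. Two conventions matter and are fixed here
deliberately:

* **Per-trajectory mean subtraction.** `⟨v⟩` is each trajectory's own mean.
  Per-trajectory functions are computed first and then averaged
  (`ensemble_average()`); this removes slow molecule-to-molecule offsets at
  the cost of a small O(τ_c/T) downward bias at the longest lags.
* **Biased denominators.** The estimators use `1/(N−n)` and `1/(N−n−m)`
  verbatim, with no unbiased-covariance correction; `C⁽²⁾(0)` is therefore
  exactly the biased sample variance of the fluctuations.

Both normalized (divided by `C⁽²⁾(0)`) and unnormalized TCFs are supported;
the fit uses unnormalized functions, which retain amplitude information.

## The kinetic network model

The system is modeled as `N` quasi-stable macrostates interconverting by
first-order kinetics (master equation `ṗ_i = Σ_{j≠i}(−k_ij p_i + k_ji p_j)`),
each emitting Gaussian-distributed visibilities with mean `v̄_i` and width
`σ_i`. The model statistics are

* `P(v) = Σ_i A_i exp[−(v − v̄_i)²/2σ_i²]` with `p_i^eq = A_i σ_i √(2π)`
  (`model_pdf()`, `state_weight()`);
* `C⁽²⁾(τ) = Σ_ij δv̄_j p_ij(τ) δv̄_i p_i^eq` (`model_c2()`);
* `C⁽³⁾(τ₁,τ₂) = Σ_ijk δv̄_k p_jk(τ₂) δv̄_j p_ij(τ₁) δv̄_i p_i^eq`
  (`model_c3()`),

where `δv̄_i = v̄_i − Σ_j p_j^eq v̄_j` and `p_ij(τ) = [exp(Qτ)]_ij`. Note
that only the macrostate *means* enter the model TCFs: within-state Gaussian
spread contributes to the PDF (and to the zero-lag point of real data) but
not to the lag-dependent correlations. Consequently the fit excludes the
zero-lag point of the empirical C⁽²⁾, whose value also carries detection
noise; the first fitted lag is `T_w`.

### Numerical realization of the propagator

The generator convention is `Q[i,j] = k_ij` (i ≠ j) with zero row sums, so
`p(t)ᵀ = p(0)ᵀ exp(Qt)`. For reversible networks (the default: detailed
balance is enforced by construction) the similarity transform
`S = D Q D⁻¹`, `D = diag(√p^eq)`, is symmetric, and a symmetric
eigendecomposition gives a numerically stable spectral propagator — fast on
the dense lag grids the fit evaluates. Irreversible networks fall back to a
general eigendecomposition, and to a dense matrix exponential
(`Matrix::expm`) when the eigenvector basis is ill-conditioned
(reciprocal condition < 1e−9); in that case eigenmodes are flagged
unavailable. Negative entries below −1e−12 from round-off are clipped to
zero.

The relaxation spectrum of a connected N-state network has exactly one zero
rate and at most `N − 1` distinct nonzero rates: this is the basis of the
macrostate-count rule implemented by `infer_state_count()` — the number of
*resolvable* decay components of C⁽²⁾, plus one. "Resolvable" is made
explicit: time constants separated by at least a factor 3 and amplitudes of
at least 2% of the fitted zero-lag value; both thresholds are arguments.

### Detailed balance

`build_detailed_balance_network()` parameterizes a reversible network by its
stationary distribution and symmetric exchange coefficients
(`k_ij = c_ij / p_i^eq`), making `k_ij p_i^eq = k_ji p_j^eq` an identity
rather than a penalty — the constraint then survives unconstrained
optimization exactly. Networks built from raw rates can be audited with
`detailed_balance_residual()` (maximum absolute net flux). Transitions that
an experiment does not observe are represented by a symmetric boolean edge
mask pinning both rates to exactly zero, never by tiny rates; the masked
graph must stay connected.

## The simultaneous fit

`fit_network()` minimizes
`χ² = Σ_b w_b Σ_points (model − data)² / s_b` over the three blocks
(PDF, C⁽²⁾, C⁽³⁾), with `s_b` each block's sum of squared data values so
every block starts O(1), and user-adjustable weights (default 1, 1, 1).
The free parameters are logit-simplex populations (N − 1), log exchange
coefficients on open edges, log mean visibilities and log widths — so
positivity, the simplex constraint, and detailed balance hold exactly
throughout the search. All means are fitted nonnegative: the measurement
does not distinguish the sign of the visibility, and sign assignment is
deferred to the free-energy-surface step.

The search is multi-start bounded Levenberg–Marquardt (`minpack.lm`): the
first start is data-driven (clustering a sample drawn from the empirical PDF
for populations/means/widths; a multi-exponential fit of C⁽²⁾ for the
exchange-coefficient time scale), the remaining starts are log-space
perturbations of it. A single master seed expands into per-start substreams,
so identical seed and configuration reproduce the result bit for bit.
Returned states are canonicalized by increasing mean visibility and labelled
S1…SN. `select_model()` steps through candidate state counts and stops when
adding a state improves χ² by less than 5% (relative, configurable).

Multi-exponential TCF fitting (`fit_multiexponential()`) uses separable
(variable-projection) least squares: decay constants are optimized while
amplitudes are profiled out linearly, over 32 log-uniform starting points by
default. A constant offset is excluded by default, since mean-subtracted
TCFs of ergodic systems decay to zero; it can be enabled.

## Pathway decomposition

Because the model TCFs are finite sums, they decompose exactly:
`c2_terms()` returns the N² two-point terms
(`product δv̄_j δv̄_i` × `weight w_ij = p_ij(τ) p_i^eq`), `c3_terms()` the
N³ three-point terms (`w_ijk = p_jk(τ₂) p_ij(τ₁) p_i^eq`); in both cases
the contributions sum to the model value at machine precision, which the
tests assert at 1e−12. `rank_terms()` orders terms by |contribution| (ties
broken by path label) with sign filtering — the conventional reporting lags
are τ = 250 µs for two-point tables and τ₁ = τ₂ = 10 ms for three-point
tables, both arguments. For a 4-state network the counts are 16 and 64; at
short lags survival pathways (`i→i`) dominate because the survival
probabilities are near one, and positive/negative term cancellation grows as
barriers between states on opposite sides of the mean visibility drop.

## Free-energy-surface parameterization

`build_surface()` converts fit output to energies in units of `k_BT`:

* minima `G_i = −ln(p_i^eq / p_max)` (Boltzmann; ground state pinned to 0);
* barriers `G‡_ij = ln(t_ij / t_min)` (Arrhenius), with `t_min` the
  *per-dataset* smallest fitted time constant, so the fastest process has
  zero barrier by construction;
* vertical offsets `G°‡_ij = G‡_ij + G_i`, referencing forward and backward
  barriers of an edge to a common saddle. For exactly reversible rates the
  two offsets agree identically; for fitted rates small disagreements are
  possible and are reported as a soft warning (`db_consistency`), not an
  error.

Temperatures enter only through the kcal/mol conversion
(`to_kcal_per_mol()`, default 298 K, factor `RT/4184 ≈ 0.5922`). The signed
reaction coordinate is `x_i = ±v̄_i`, with the sign assignment an explicit
argument (`negative_states`) — conventionally the left-handed conformation
gets the negative sign. The rendered surface is a documented visualization
convention, not a physical potential: Gaussian wells of width 0.02
visibility units joined at saddles placed midway between connected minima at
the offset-barrier height; missing edges draw no barrier segment.

## The synthetic-data generator

`generate_ensemble()` realizes the model the analysis assumes: exact
Gillespie simulation of the network (exponential dwells, jump probabilities
`k_ij/Σ_j k_ij`, equilibrium initial state), then binned emission in which
each bin value is the *occupancy-time-weighted* mean of the state means plus
zero-mean Gaussian noise with the occupancy-weighted state width. Defaults
emulate the experiment: 30 s scans, 250 µs bins, 100 trajectories, 8000
counts/s. An optional shot-noise mode scales the per-bin noise by
`√(ref counts / Poisson counts)`. Values are clipped to [−1, 1] with clip
events counted (defaults never clip). Per-trajectory seeds derive
deterministically from the master seed, so ensembles are byte-reproducible.

Exact time-weighting of dwells shorter than `T_w` reproduces the
motional-narrowing bias of a real binned measurement: states that exchange
on time scales at or below the bin width blur into intermediate visibility
values. The fit model ignores this (sub-bin dynamics fold into the fitted
σ), which is the main realism gap a passing test suite does *not* close.
Other features of real data the generator does not emulate: photophysics
(blinking, bleaching), detector dead time, molecule-to-molecule parameter
heterogeneity, and drift.

The package's reference truth (`ps_truth_network()`) is a detailed-balance
4-state chain with populations (0.02, 0.82, 0.14, 0.02), means
(0.02, 0.11, 0.14, 0.30), common width 0.02, and chain exchange coefficients
(5.276254, 0.777107, 58.321176) s⁻¹ calibrated once so the relaxation times
are 0.30, 3.70 and 173.0 ms — the parameter regime reported for a dimer
probe just inside the duplex side of a DNA fork junction at physiological
salt. The fastest mode sits near the default bin width, which is the hard
case: the high-visibility minority state exchanges at the bin scale and its
fitted mean/width absorb the resulting blur, while the majority-state
population and the slower time constants remain well determined.

## Problem sizes and numerical choices

Grids: the PDF uses 60 equal bins on [−0.05, 0.55] (covering the observed
0–0.4 range with margins); C⁽²⁾ lags are log-spaced, snapped to integer bin
multiples, 60 points by default; C⁽³⁾ is evaluated on a square 24-point
log-spaced grid after rebinning to `T_w = 10` ms (`rebin()` averages whole
bins and drops the remainder). The packaged test-and-benchmark workloads are
sized for a single desktop core: recovery experiments use 10–25 trajectories
of 30–80 s and 6–10 optimizer starts, which keeps the full suite under a
minute of fitting while leaving the recovered majority-state population
within ±0.05 of truth; production analyses would simply raise
`n_trajectories` and `n_starts`.

Tolerances worth knowing: detailed-balance residuals of constructed networks
are ≤ 1e−12; spectral and dense propagators agree to 1e−8; pathway
completeness holds to 1e−12; emission weights must match the paired
network's stationary distribution to relative 1e−6; time-constant sorting is
ascending with ties broken by state-pair label.

## Known limitations

* The model TCFs omit within-state broadening and any sub-bin dynamics; fits
  of data whose fastest process is at or below `T_w` will report biased
  minority-state emission parameters (populations are more robust).
* Uncertainty is reported only as the multi-start χ² spread — no posterior
  or bootstrap errors.
* The edge mask (which transitions are observable) is an input, not an
  inference; model selection chooses only the state count.
* Non-Markovian dynamics, time-dependent rates, and absorbing states are out
  of scope by design.
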