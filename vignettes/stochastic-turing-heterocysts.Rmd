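---
title: "Methods: stochastic Turing patterns on a growing cell chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic Turing patterns on a growing cell chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetpattern)
```

This vignette is the package's own account of the model it implements, the
conventions it fixes where the mathematics leaves freedom, and what its
tests do and do not establish.

## The model

A filament is a chain of `Ω` cells. Each cell `i` carries integer counts
`r_i, s_i, n_i` of the activator HetR and the inhibitors PatS and HetN.
The reaction scheme per cell is

* constitutive production of all three species at rates `α_R, α_S, α_N`
  (propensities `α V` with `V` the cell volume);
* Hill-type autoactivation of HetR and HetR-driven activation of PatS,
  propensities `β_R V h(r/V)` and `β_S V h(r/V)` with
  `h(x) = x²/(K²+x²)` — the quadratic Hill form encodes that the active
  HetR species is the dimer;
* first-order decay `k_R r`, `k_S s`, `k_N n`;
* trimolecular capture `2R + S → ∅` and `2R + N → ∅` with propensities
  `μ_S r(r−1)s/V²` and `μ_N r(r−1)n/V²` — the `r(r−1)` factor is exact
  mass-action counting of unordered HetR pairs;
* nearest-neighbour hops of the inhibitors only, `D_S s` and `D_N n`
  towards each adjacent cell. HetR is immobile; there is no evidence for
  activator transfer between cells, which is precisely why a third species
  is needed for a diffusion-driven instability.

All quantities are dimensionless. `V` is a free control parameter setting
the demographic-noise strength (`1/√V` relative fluctuations); it cannot
currently be mapped to an absolute molecule density for the organism, so it
is explored as a dial.

The propensity scaling in `V` is the unique convention whose infinite-`V`
limit reproduces the mean-field equations term by term; the test suite
enforces this contract by comparing the summed channel drift
(`channel_drift()`) against `rhs_deterministic()` and by checking ensemble
Gillespie means against the deterministic integration at increasing `V`.

## Spatial support

The chain is open: interior cells have two neighbours, edge cells one,
giving the zero-flux discrete Laplacian `Δ = W − diag(k)`. Its eigenvalues
on `Ω` cells are `−2(1 − cos(πα/Ω))`, `α = 0..Ω−1`, which the constructor
is tested against to `1e-9` for every size up to 64. Conventions fixed
here, because downstream results must be reproducible bit for bit:

* eigenpairs are sorted by descending eigenvalue, so mode 1 is always the
  uniform (kernel) mode;
* each eigenvector's sign is chosen so its first non-negligible component
  is positive (spectra are sign-invariant, tests are not);
* degenerate eigenspaces (they occur for the periodic variant, never for
  the open path) are re-orthonormalised deterministically by QR in sorted
  order.

A periodic variant exists behind a flag for testing; it is not part of the
biological model.

## Deterministic analysis

Homogeneous equilibria are found by a scalar reduction: the inhibitor
nullclines `ψ*(φ) = (α_S + β_S h(φ))/(k_S + μ_S φ²)` and
`η*(φ) = α_N/(k_N + μ_N φ²)` are substituted into the activator balance,
which is then scanned on 2000 grid points over `[0, (α_R + β_R)/k_R]`
(an upper bound since the Hill response is at most 1) with bisection
refinement to `1e-13`. When several non-negative roots exist, the
*reference* equilibrium is the stable one with the largest activator
level, with a warning on ties — the Turing analysis is only meaningful
about a homogeneous-stable base state.

The linear-stability matrix at Laplacian eigenvalue `Λ` is
`Q = J0 + diag(0, D_S, D_N) Λ`. `J0` is derived **analytically** from the
rate equations:

```
J0 = [ −k_R + β_R h'(φ) − 4μ_S φψ − 4μ_N φη    −2μ_S φ²    −2μ_N φ² ]
     [ β_S h'(φ) − 2μ_S φψ                      −k_S − μ_S φ²      0 ]
     [ −2μ_N φη                                  0      −k_N − μ_N φ² ]
```

with `h'(φ) = 2φK²/(K²+φ²)²`. The factor 4 in the activator row (against
the factor 2 sometimes quoted for such schemes) is forced by
differentiating `−2μφ²ψ`; the implementation validates every entry against
central finite differences of the right-hand side, and the package's
threshold results below depend on it.

The dispersion relation is `λ_max(Λ^(α))`, the largest real part of the
eigenvalues of `Q`; the continuum limit replaces `Λ` by `−k²` and the
discrete values lie exactly on that smooth curve (tested to `1e-10`).
A parameter point is Turing-unstable when the uniform mode is stable and
some non-uniform mode grows. Threshold location uses a grid scan followed
by bisection on the instability indicator to `1e-4`; the headline numbers,
recomputed by `scripts/acceptance.R`, are a critical `β_S = 3.675` at
`β_R = 6.5` under diffusivity ratio 3, and a critical `β_R = 5.70` at
`β_S = 2.99` under equal diffusivities — equal inhibitor diffusivities
shrink the deterministic region markedly (tested by counting unstable grid
cells at ratio 1 versus ratio 3).

## Stochastic simulation

The Gillespie engine (direct method, compiled) keeps per-cell propensity
sums and updates only the cells an event touches; the event-driven state is
piecewise constant and read out on a fixed sampling grid (default spacing
1). Runs are seeded through R's RNG, so a stored seed reproduces a
trajectory exactly. Zero total propensity terminates cleanly in the frozen
state. Tau-leaping is deliberately absent: every reported stochastic result
is statistically exact.

Filament growth adds a duplication channel of propensity `ρV` per cell, so
the expected size is `Ω(τ) = Ω₀ e^{ρVτ}` (a Yule process, which the tests
check in mean and, by bootstrap, in variance). A duplicating cell is
replaced in place by two adjacent daughters; molecules split either equally
(odd molecule to the left daughter — a deterministic rule, again for
reproducibility) or binomially. Both rules conserve molecules exactly. A
configurable cap stops duplication (with a flag) to bound memory.

## Linear-noise approximation

Expanding the master equation to next-to-leading order in `1/√V` about the
stable homogeneous state gives linear Langevin dynamics per spatial mode
with drift `M = J0 + diag(0, D_S, D_N) Λ` and white-noise covariance
`B(Λ) = B_NS + B_SP Λ`. `B_NS` is assembled channel by channel as
stoichiometry-outer-product times rate at equilibrium; e.g. the
trimolecular PatS channel (stoichiometry `(−2, −1, 0)`) contributes
`4μ_S φ²ψ` to `B₁₁`, `2μ_S φ²ψ` to `B₁₂` and `μ_S φ²ψ` to `B₂₂`. The hop
channels contribute `−2D_S ψ*` and `−2D_N η*` on the inhibitor diagonal of
`B_SP`; the sign convention is chosen so that the product `B_SP Λ` (with
`Λ ≤ 0`) adds a non-negative diffusion noise, and the whole construction is
verified in the tests against an independent full-lattice assembly from the
channel list, projected mode by mode.

The stationary fluctuation spectrum is
`P_q(ω, Λ) = [F⁻¹ B(Λ) (F†)⁻¹]_qq` with `F = −iωI − M`. Reported slices
follow the convention of the spatial slice `P₁(0, Λ)` versus `−Λ` and the
temporal slice at `Λ = 0` versus `ω`. Consistency checks: the fully
decoupled limit collapses to the Ornstein–Uhlenbeck Lorentzian
`2α_R/(ω² + k_R²)` to `1e-10`, and for every mode the frequency integral
`∫P dω/2π` equals the Lyapunov equal-time variance to `1e-6`.

Empirical spectra from simulation project the fluctuations
`ξ = √V (counts/V − equilibrium)` on the Laplacian eigenmodes and apply a
plain rectangular-window Fourier transform over a stated interval,
`P = |dt Σ_t ξ(t) e^{iωt}|²/T`; no tapering by default (a deliberate
choice: the spectra of interest are smooth Lorentzian-like profiles where
leakage is negligible, and the plain window matches the theoretical
normalization pointwise). Discrete sampling aliases the `1/ω²` tails, which
inflates ensemble-averaged spectra by roughly ten percent near the Nyquist
frequency at the default sampling; the tests' tolerances account for this,
and finer sampling removes it.

The noise-driven instability map marks a grid point when `P₁(0, Λ)` has an
interior local maximum over the non-uniform modes at least 1.2 times the
value at the mode nearest `Λ = 0⁻` (the factor is configurable; no sharper
criterion is canonical). Points already inside the deterministic region are
counted as noise-driven by definition, because the stationary spectrum does
not exist there — the linear solution grows secularly at the unstable
modes, and the formula's output at such points is dominated by near-singular
resolvent artefacts.

## Growing domain, continuum limit

Rescaling a uniformly growing domain to the fixed unit interval turns
exponential growth `Ω(τ) = Ω₀e^{ρ̃τ}` into a dilution term `−ρ̃c` on every
species plus time-modulated diffusivities `D/Ω(τ)²`; the package integrates
this by the method of lines with zero-flux (ghost-node) ends. This is the
standard uniform-growth reaction–diffusion form and matches the stochastic
model's verbal continuum limit; it is validated against its two exact
limits (no growth: stationary homogeneity; no chemistry: pure exponential
dilution).

Two complementary statements about spacing under growth are tested:

* the number of linearly unstable modes is non-decreasing in `Ω` and the
  leading-mode index grows linearly (`R² > 0.99`), so the preferred
  spacing in *cell units* is size-independent;
* integrating through one full domain doubling at the nominal growth rate
  (`ρ̃ = 5·10⁻⁵`, 40 → 80 cells) returns the mean inter-peak spacing to
  the fixed-domain value within 2 cells. The doubling window matters: at
  intermediate sizes the spacing oscillates — it stretches with the domain
  until a wave of insertions roughly halves it — so a comparison at an
  arbitrary instant would sit anywhere inside that sawtooth.

## Calibration and trace alignment

If a mother's fluorescence is `ν n` and its `n` molecules partition
binomially between the daughters, then
`E[(f_d1 − f_d2)²] = ν² n = ν f_mother`, so
`ν̂ = ⟨(f_d1 − f_d2)²/f_mother⟩` estimates the fluorescence per molecule;
copy numbers follow as `f/ν̂`. A constant background is subtracted first
(negatives clipped with a warning count); uncertainty is bootstrap over
triplets. The estimator is scale-equivariant, and with measurement noise
`σ` it carries a positive bias `2σ²/(νn)` per triplet — at the synthetic
regimes tested (copy numbers 20–200, 300+ triplets) total bias stays below
ten percent. With ~50 triplets the relative standard error is of order
twenty percent, which is why absolute copy-number estimates from such data
legitimately carry wide error bars.

Traces are aligned at the autofluorescence half-decay: plateau and floor
are the means of the first and last tenth of samples of a lightly smoothed
(3-sample rolling mean) trace, and the downward crossing of their midpoint,
located by linear interpolation, defines time zero per cell. Traces with no
crossing are excluded with a recorded reason rather than guessed.

## Synthetic data and what it does not emulate

The generators are pure functions of their parameters and a seed: binomial
partitioning triplets (optional Gaussian measurement noise and constant
background), sigmoidal autofluorescence decays with jittered onsets and an
optional lagged switch-like reporter, and uniformly perturbed equilibrium
fields (relative amplitude, independent per cell and species — the
perturbation distribution is a package choice; nothing in the model fixes
it). Parameter presets freeze the standard study conditions
(`k_R = 0.2, α_R = 0.2, K = 2, k_S = 0.1, α_S = 0.1, μ_S = 0.1, k_N = 0.7,
α_N = 0.3, μ_N = 3`, chain of 40 cells, `V = 5000`, and the named
activation/diffusivity variants).

The synthetic data deliberately omit several features of real microscopy:
segmentation error, photobleaching (a ~2 % mother/daughter deficit is
reported in practice; an optional multiplicative correction exists but is
off by default), cell-to-cell volume variation, and any distinction between
heterocysts and vegetative cells — the model does not enforce
differentiation or stop heterocysts from dividing. Passing tests therefore
validate the mathematics and the implementation, not the biology of any
particular dataset.

## Numerical choices and problem sizes

* ODE integration: `lsoda` with `rtol = 1e-8`, `atol = 1e-10`; the sharp
  trimolecular terms make the system locally stiff. Concentrations are
  never clipped inside the dynamics; only sub-tolerance negative jitter is
  zeroed on output.
* Eigenvalues of the 3×3 stability matrices come from the dense solver;
  only the maximal real part is consumed, so tie-breaking is moot.
* The test suite's stochastic comparisons use fixed seeds throughout and
  sizes chosen to keep the whole suite in a few minutes: LNA-vs-SSA
  covariances at `V = 2000` on 3 cells with a fast-relaxing parameter set
  (at the figure-level parameters the activator mode relaxes on a ~100 τ
  timescale, which biases any affordable time-averaged variance estimate);
  ensemble-mean convergence with 100 runs at `V ∈ {200, 2000}`; the
  noise-selected-wavelength checks at `V = 500` on 30–40 cells; the
  splitting-rule comparison at `V = 100` on a 20-cell filament growing by
  half. The threshold scans and all deterministic checks run at the full
  nominal sizes.

## Known limitations

* The linear-noise spectrum is stationary; time-dependent (transient or
  growing-domain) fluctuation spectra are out of scope.
* The stochastic engine is specific to nearest-neighbour chains; no 2-D
  lattices, weighted edges, or hybrid ODE/SSA schemes.
* Region boundaries are resolved by grid+bisection, not continuation;
  oscillatory instabilities are not classified beyond the real-part
  criterion.
* `V` is not experimentally anchored; all stochastic statements are
  relative to the chosen noise strength.
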