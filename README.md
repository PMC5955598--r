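# hetpattern

Stochastic Turing patterns of heterocyst development on one-dimensional
cell chains.

## The scientific problem

Filamentous cyanobacteria such as *Anabaena* respond to nitrogen starvation
by differentiating single nitrogen-fixing heterocysts separated by nearly
regular intervals of ~10 vegetative cells. The patterning circuit couples a
non-diffusing activator (HetR, which autoactivates through its dimeric
form) to two diffusing inhibitors: PatS, produced under HetR control, and
HetN. Both inhibitors capture HetR dimers into complexes that are degraded.
Because regulator copy numbers per cell are small (tens of molecules),
demographic noise is strong, and the interesting regime is the one where a
*deterministically stable* homogeneous state is driven into a patterned
state by molecular noise — a stochastic Turing pattern.

`hetpattern` implements this three-morphogen model end to end for
theorists and modellers:

* **Chain lattice** — the discrete Laplacian `Δ = W − diag(k)` of an open
  (zero-flux) cell chain, its eigensystem, and the spatial eigenmode
  transform used to analyse fluctuations.
* **Mean field** — the rate equations

  ```
  dφ_i/dτ = α_R − k_R φ_i + β_R h(φ_i) − 2 μ_S φ_i² ψ_i − 2 μ_N φ_i² η_i
  dψ_i/dτ = α_S − k_S ψ_i + β_S h(φ_i) − μ_S φ_i² ψ_i + D_S Σ_j Δ_ij ψ_j
  dη_i/dτ = α_N − k_N η_i − μ_N φ_i² η_i + D_N Σ_j Δ_ij η_j
  ```

  with `h(x) = x²/(K² + x²)`, their homogeneous equilibria, and stiff-safe
  integration.
* **Turing linear stability** — the analytic Jacobian, the discrete
  dispersion relation `λ_max(Λ^(α))` of `Q = J0 + diag(0, D_S, D_N) Λ`,
  its continuum limit (`Λ → −k²`), region scans in the `(β_S, β_R)` plane
  and threshold bracketing.
* **Exact stochastic simulation** — a compiled Gillespie (direct-method)
  engine for the full chemical master equation on the chain, with cell
  volume `V` setting the noise strength, plus filament growth by per-cell
  duplication with equal or binomial molecule splitting.
* **Linear-noise analysis** — drift and noise matrices of the system-size
  expansion, the theoretical fluctuation power spectrum
  `P_q(ω, Λ) = [F⁻¹ (B_NS + B_SP Λ) (F†)⁻¹]_qq` with
  `F = −iωI − M_NS − M_SP Λ`, empirical spectra from single realizations,
  and the noise-driven instability region map.
* **Calibration** — absolute copy numbers from fluorescence via binomial
  partitioning statistics (`ν̂ = ⟨(f_d1 − f_d2)²/f_mother⟩`), and
  alignment of fluorescence traces at the autofluorescence half-decay
  time.
* **Synthetic data** — seeded generators for every input the pipeline
  consumes, plus named parameter presets for the standard study
  conditions.

## Worked example

Just outside the deterministic instability region the homogeneous state is
linearly stable, yet a single stochastic realization develops a patterned
spectrum peaked at the wavelength the deterministic analysis would
destabilize:

```r
library(hetpattern)

lat <- build_chain(40)
pre <- preset_params("ratio3_stable")   # beta_S = 3.65: outside the region
eq  <- find_equilibrium(pre$params)
eq
#> Homogeneous equilibrium: phi* = 0.939959, psi* = 4.03688, eta* = 0.089537
#>   residual 1.11e-16, stable (1 non-negative root found)

discrete_dispersion(pre$params, eq, lat)
#> discrete dispersion relation over 40 modes
#>   lambda(0) = -0.04679 (stable), max over non-uniform modes = -0.007429
#>   Turing unstable: FALSE

threshold_search(pre$params, "beta_S", c(3.0, 4.5), step = 0.005,
                 lattice = lat)$grid_value
#> [1] 3.675

tr  <- gillespie_run(pre$params, lat, V = 500, tau_end = 600, seed = 11)
emp <- empirical_spectrum(tr, eq, lat, window = c(200, 600), omega_grid = 0)
th  <- theoretical_spectrum(pre$params, eq, lattice = lat, omega_grid = 0)
emp
#> Power spectrum (empirical): 1 frequencies x 40 modes
#>   HetR peak at omega = 0, Lambda = -0.382 (height 1.845e+04)
th
#> Power spectrum (theoretical): 1 frequencies x 40 modes
#>   HetR peak at omega = 0, Lambda = -0.2947 (height 5.481e+04)
```

Reading the output: the homogeneous state is stable (all dispersion values
negative), and the instability would only set in at `beta_S = 3.675`. Yet
the fluctuation spectrum of the simulated filament peaks at
`Λ = −0.382`, one discrete mode away from the theoretical prediction
`Λ* = −0.295` — i.e. a noise-sustained pattern with the same ~12-cell
spacing the unstable regime selects. (Empirical and theoretical heights are
on different normalizations; pass `match_to = th` to rescale.)

Batch runs can be driven by config files: `run_config()` dispatches
`dispersion | scan | simulate-det | simulate-ssa | spectrum | grow |
calibrate | align | synth` from YAML and writes tab-separated tables plus a
run manifest.

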