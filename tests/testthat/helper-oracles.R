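# Shared helpers for the test suite.  Everything here is generated in code;
# no stored fixtures.

# Closed-form Laplacian spectrum of the open (Neumann) chain.
chain_spectrum_closed_form <- function(omega)
  -2 * (1 - cos(pi * (0:(omega - 1)) / omega))

# Closed-form spectrum of the ring (periodic chain).
ring_spectrum_closed_form <- function(omega)
  -2 * (1 - cos(2 * pi * (0:(omega - 1)) / omega))

# A stable parameter set whose relaxation times are all O(1), used for
# stochastic-vs-theory comparisons where time averaging must converge fast.
fast_relax_params <- function()
  model_params(alpha_R = 1, alpha_S = 1, alpha_N = 1, beta_R = 2,
               beta_S = 1.5, K = 1, k_R = 1, k_S = 0.8, k_N = 0.9,
               mu_S = 0.3, mu_N = 0.5, D_S = 1, D_N = 0.5)

# All reaction and transport rates zero: the frozen / pure-growth limit.
chem_off_params <- function()
  model_params(alpha_R = 0, alpha_S = 0, alpha_N = 0, beta_R = 0,
               beta_S = 0, k_R = 0, k_S = 0, k_N = 0,
               mu_S = 0, mu_N = 0, D_S = 0, D_N = 0)

# Fully decoupled linear (birth-death) system: no feedback, no trimolecular
# capture, no diffusion.
decoupled_params <- function(alpha_R = 0.2, k_R = 0.2)
  model_params(alpha_R = alpha_R, alpha_S = 0.1, alpha_N = 0.3,
               beta_R = 0, beta_S = 0, k_R = k_R, k_S = 0.1, k_N = 0.7,
               mu_S = 0, mu_N = 0, D_S = 0, D_N = 0)

# Index of the lattice mode whose eigenvalue is closest to a given Lambda.
mode_index <- function(lattice, Lambda) which.min(abs(lattice$values - Lambda))

# Arg-max mode of the HetR zero-frequency spatial spectrum slice,
# restricted to non-uniform modes.
spatial_peak_mode <- function(spec, lattice) {
  nz <- which(lattice$values < -1e-12)
  nz[which.max(spec$P[1, nz, 1])]
}
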