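# Frozen study conditions: the nominal rate constants shared by every
# analysis, and the named variants that differ only in the activation
# strengths, diffusivities and growth rates.
preset_registry <- function() {
  base <- list(alpha_R = 0.2, alpha_S = 0.1, alpha_N = 0.3, K = 2,
               k_R = 0.2, k_S = 0.1, k_N = 0.7, mu_S = 0.1, mu_N = 3)
  list(
    # D_S/D_N = 3; "turing" sits just inside the deterministic instability
    # region, "stable" just outside it
    ratio3_turing = c(base, beta_R = 6.5, beta_S = 3.7, D_S = 3, D_N = 1),
    ratio3_stable = c(base, beta_R = 6.5, beta_S = 3.65, D_S = 3, D_N = 1),
    # equal diffusivities (D_S = D_N = 4)
    equalD_turing = c(base, beta_R = 5.82, beta_S = 2.99, D_S = 4, D_N = 4),
    equalD_stable = c(base, beta_R = 5.69, beta_S = 2.99, D_S = 4, D_N = 4),
    equalD_map    = c(base, beta_R = 6.5, beta_S = 3.7, D_S = 4, D_N = 4),
    # growing-filament conditions
    growth_ssa       = c(base, beta_R = 6.5, beta_S = 3.7, D_S = 3, D_N = 1),
    growth_continuum = c(base, beta_R = 6.5, beta_S = 3.7, D_S = 3, D_N = 1)
  )
}

#' Named parameter presets for the study conditions
#'
#' Canned [model_params()] sets for the standard conditions of the model's
#' headline analyses, each with the standard chain size `Omega = 40` and
#' cell volume `V = 5000`:
#'
#' * `"ratio3_turing"` / `"ratio3_stable"`: diffusivity ratio 3
#'   (`D_S = 3`, `D_N = 1`) with `beta_R = 6.5` and `beta_S = 3.7`
#'   (inside the deterministic Turing region) or `3.65` (outside).
#' * `"equalD_turing"` / `"equalD_stable"`: equal diffusivities (`D_S = D_N = 4`)
#'   with `beta_S = 2.99` and `beta_R = 5.82` (inside) or `5.69` (outside).
#' * `"equalD_map"`: equal diffusivities for the stochastic-region map.
#' * `"growth_ssa"`: growing stochastic filament, duplication rate `rho = 1e-8`.
#' * `"growth_continuum"`: growing continuum filament, growth rate `rho_tilde = 5e-5`.
#'
#' @param name Preset name.
#' @return List with `params` (a `het_params`), `omega`, `V`, and for the
#'   growth presets a `growth` ([growth_config()]).
#' @export
preset_params <- function(name = c("ratio3_turing", "ratio3_stable", "equalD_turing",
                                   "equalD_stable", "equalD_map", "growth_ssa", "growth_continuum")) {
  name <- match.arg(name)
  reg <- preset_registry()
  out <- list(params = do.call(model_params, reg[[name]]),
              omega = 40L, V = 5000)
  if (name == "growth_ssa")
    out$growth <- growth_config(rho = 1e-8, omega0 = 40L)
  if (name == "growth_continuum")
    out$growth <- growth_config(rho_tilde = 5e-5, omega0 = 40L)
  out
}

#' Synthetic mother/daughter partitioning data
#'
#' Emulates the division statistics used for fluorescence calibration:
#' mother cells carry `n` fluorescent molecules, each molecule is allocated
#' to one of the two daughters independently with probability 1/2
#' (binomial partitioning), and measured fluorescence is
#' `nu * molecules + background + Gaussian noise`.  A pure function of its
#' arguments and the seed.
#'
#' @param nu Fluorescence per molecule (> 0).
#' @param n_mean Mean mother copy number.
#' @param n_triplets Number of mother/daughter triplets.
#' @param n_dist `"poisson"` (mother copy numbers drawn Poisson with mean
#'   `n_mean`) or `"fixed"` (all mothers carry `round(n_mean)`).
#' @param background Constant additive background on every measurement.
#' @param noise_sd Gaussian measurement noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with `f_mother`, `f_d1`, `f_d2` and the ground-truth
#'   columns `n_mother`, `n_d1`.
#' @export
gen_partition_data <- function(nu, n_mean = 40, n_triplets = 500L,
                               n_dist = c("poisson", "fixed"),
                               background = 0, noise_sd = 0, seed = 1L) {
  n_dist <- match.arg(n_dist)
  if (nu <= 0) stop("'nu' must be positive", call. = FALSE)
  set.seed(seed)
  n <- if (n_dist == "poisson") rpois(n_triplets, n_mean)
       else rep(round(n_mean), n_triplets)
  x <- rbinom(n_triplets, n, 0.5)
  noise <- function() if (noise_sd > 0) stats::rnorm(n_triplets, 0, noise_sd)
                      else 0
  data.frame(
    f_mother = nu * n + background + noise(),
    f_d1 = nu * x + background + noise(),
    f_d2 = nu * (n - x) + background + noise(),
    n_mother = n, n_d1 = x)
}

#' Synthetic autofluorescence decay traces
#'
#' Sigmoidal decay traces emulating the loss of photosynthetic
#' autofluorescence in differentiating cells, with per-cell onset times
#' jittered around a common mean; the onset time is exactly the half-decay
#' time of the sigmoid and is recorded as ground truth.  Optionally a
#' switch-like reporter channel turning on a fixed lag after the onset is
#' added (emulating the delayed HetN reporter), for testing alignment.
#'
#' @param count Number of traces.
#' @param onset_jitter Standard deviation of the onset times around
#'   `onset_mean`.
#' @param decay_width Width (time units) of the sigmoidal decline.
#' @param onset_mean Mean onset time.
#' @param times Common sampling grid.
#' @param plateau,floor Pre- and post-decay autofluorescence levels.
#' @param reporter_lag If non-`NULL`, add a `reporter` column switching on
#'   at `onset + reporter_lag`.
#' @param seed Integer seed.
#' @return List of data frames (`time`, `af`, optionally `reporter`), with
#'   attribute `onsets` carrying the true onset times.
#' @export
gen_decay_traces <- function(count, onset_jitter = 2, decay_width = 1.5,
                             onset_mean = 20, times = seq(0, 48, by = 0.5),
                             plateau = 1, floor = 0.1,
                             reporter_lag = NULL, seed = 1L) {
  set.seed(seed)
  if (count == 0L) return(structure(list(), onsets = numeric(0)))
  onsets <- onset_mean + if (onset_jitter > 0)
    stats::rnorm(count, 0, onset_jitter) else rep(0, count)
  traces <- lapply(seq_len(count), function(i) {
    af <- floor + (plateau - floor) / (1 + exp((times - onsets[i]) /
                                                 decay_width))
    df <- data.frame(time = times, af = af)
    if (!is.null(reporter_lag)) {
      df$reporter <- 1 / (1 + exp(-(times - onsets[i] - reporter_lag) /
                                    (decay_width / 3)))
    }
    df
  })
  structure(traces, onsets = onsets)
}

#' Randomly perturbed homogeneous initial field
#'
#' Equilibrium concentrations plus independent uniform relative
#' perturbations on `[-amplitude, +amplitude]` per cell and species,
#' clipped at zero.  This is the standard initial condition for probing
#' the Turing instability of the homogeneous state.
#'
#' @param eq A `het_equilibrium`.
#' @param amplitude Relative perturbation amplitude (>= 0).
#' @param omega Number of cells.
#' @param seed Integer seed.
#' @return `omega x 3` concentration matrix.
#' @export
gen_perturbed_field <- function(eq, amplitude, omega, seed = 1L) {
  stopifnot(amplitude >= 0)
  set.seed(seed)
  base <- matrix(c(eq$phi, eq$psi, eq$eta), omega, 3L, byrow = TRUE)
  pert <- matrix(runif(omega * 3L, -amplitude, amplitude), omega, 3L)
  pmax(base * (1 + pert), 0)
}
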