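#' Growth configuration for a duplicating filament
#'
#' @param rho Per-cell duplication rate parameter of the stochastic model;
#'   each of the `Omega` cells duplicates at propensity `rho * V`, so the
#'   expected filament size is `Omega_0 * exp(rho * V * tau)`.
#' @param rho_tilde Growth rate of the continuum description (dilution rate
#'   and diffusion-rescaling exponent).
#' @param omega0 Initial cell count (>= 2).
#' @param split One of `"equal"` (counts halved, odd molecule to the left
#'   daughter) or `"binomial"` (each molecule assigned to a daughter
#'   independently with probability 1/2).
#' @param max_omega Cap on the filament size; duplication stops (with a
#'   `truncated` flag) once reached.
#' @return A `het_growth` configuration list.
#' @export
growth_config <- function(rho = 1e-8, rho_tilde = 5e-5, omega0 = 40L,
                          split = c("equal", "binomial"),
                          max_omega = 200L) {
  split <- match.arg(split)
  stopifnot(rho >= 0, rho_tilde >= 0, omega0 >= 2, max_omega >= omega0)
  structure(list(rho = rho, rho_tilde = rho_tilde,
                 omega0 = as.integer(omega0), split = split,
                 max_omega = as.integer(max_omega)),
            class = "het_growth")
}

#' Gillespie simulation of a growing filament
#'
#' Extends [gillespie_run()] with a duplication channel of propensity
#' `rho * V` per cell.  When a cell duplicates it is replaced in place by
#' two adjacent daughters, its molecules split according to the configured
#' rule, the chain adjacency is re-wired and all reaction channels rebuilt.
#' With `rho = 0` this reduces exactly (same seed, same trajectory) to the
#' fixed-domain algorithm.
#'
#' @inheritParams gillespie_run
#' @param growth A [growth_config()].
#' @param init `omega0 x 3` integer counts; defaults to the rounded
#'   homogeneous equilibrium.
#' @return A `het_trajectory` with additional elements `omega_t` (cell
#'   count per sample time), `dup_times`, `dup_cells` (event log, cell
#'   indices at the moment of the event) and `truncated`.  The count array
#'   is `n_t x max_omega x 3`; entries beyond the current filament size are
#'   zero.
#' @export
ssa_growing_run <- function(params, V, growth, init = NULL, tau_end,
                            seed = 1L, sample_dt = 1) {
  p <- as_het_params(params)
  stopifnot(inherits(growth, "het_growth"))
  if (is.null(init)) {
    eq <- find_equilibrium(p)
    init <- matrix(round(V * c(eq$phi, eq$psi, eq$eta)),
                   growth$omega0, 3L, byrow = TRUE)
  }
  init <- as.matrix(init)
  if (nrow(init) != growth$omega0 || ncol(init) != 3L)
    stop("'init' must be an omega0 x 3 matrix", call. = FALSE)

  times <- seq(0, tau_end, by = sample_dt)
  set.seed(seed)
  res <- ssa_chain_cpp(par_vector(p), V, init, tau_end, times,
                       rho = growth$rho,
                       split_rule = if (growth$split == "binomial") 1L else 0L,
                       max_omega = growth$max_omega,
                       periodic = FALSE)
  fields <- res$counts
  dimnames(fields) <- list(NULL, NULL, c("HetR", "PatS", "HetN"))
  structure(list(times = times, fields = fields,
                 omega = res$omega[length(res$omega)],
                 omega_t = res$omega,
                 dup_times = res$dup_times, dup_cells = res$dup_cells,
                 truncated = res$truncated,
                 params = p, V = V, seed = seed, growth = growth,
                 mode = "ssa-growing", n_events = res$n_events),
            class = "het_trajectory")
}

#' Deterministic growth dynamics on the unit interval
#'
#' Continuum counterpart of the growing filament: the domain is rescaled to
#' the fixed interval `[0, 1]` with `Omega(tau) = omega0 * exp(rho_tilde *
#' tau)` cells.  Uniform exponential growth then adds a linear dilution
#' term `-rho_tilde * c` to every species and divides the inhibitor
#' diffusivities by `Omega(tau)^2` (time-modulated diffusion).  Integrated
#' by the method of lines with zero-flux ends.
#'
#' @inheritParams integrate_deterministic
#' @param rho_tilde Continuum growth rate (1/time).
#' @param omega0 Initial filament size defining the diffusion rescaling.
#' @param init `M x 3` matrix: the concentration profile on `M` equally
#'   spaced grid points spanning `[0, 1]`.
#' @return A `het_trajectory` (`mode = "continuum-growing"`) whose
#'   `fields` live on the fixed grid; element `omega_t` gives
#'   `Omega(tau)` at the output times.
#' @export
integrate_growing_continuum <- function(params, rho_tilde, omega0, init,
                                        tau_end, n_out = 201L,
                                        rtol = 1e-8, atol = 1e-10) {
  p <- as_het_params(params)
  init <- as.matrix(init)
  if (ncol(init) != 3L || nrow(init) < 3L)
    stop("'init' must be an M x 3 profile with M >= 3", call. = FALSE)
  if (any(init < 0)) stop("'init' must be non-negative", call. = FALSE)
  M <- nrow(init)
  dx <- 1 / (M - 1)

  lap1d <- function(u) {
    # zero-flux second difference on [0, 1]
    c(2 * (u[2L] - u[1L]),
      u[seq_len(M - 2L)] - 2 * u[2:(M - 1L)] + u[3:M],
      2 * (u[M - 1L] - u[M])) / dx^2
  }

  deriv <- function(t, y, parms) {
    st <- matrix(y, M, 3L)
    phi <- st[, 1L]; psi <- st[, 2L]; eta <- st[, 3L]
    h <- hill(phi, p$K); phi2 <- phi^2
    Om2 <- (omega0 * exp(rho_tilde * t))^2
    dphi <- p$alpha_R - p$k_R * phi + p$beta_R * h -
      2 * p$mu_S * phi2 * psi - 2 * p$mu_N * phi2 * eta -
      rho_tilde * phi
    dpsi <- p$alpha_S - p$k_S * psi + p$beta_S * h -
      p$mu_S * phi2 * psi - rho_tilde * psi +
      p$D_S / Om2 * lap1d(psi)
    deta <- p$alpha_N - p$k_N * eta - p$mu_N * phi2 * eta -
      rho_tilde * eta + p$D_N / Om2 * lap1d(eta)
    list(c(dphi, dpsi, deta))
  }

  times <- seq(0, tau_end, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(init), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("growing-domain integration failed", call. = FALSE)
  fields <- array(sol[, -1L], dim = c(nrow(sol), M, 3L),
                  dimnames = list(NULL, NULL, c("HetR", "PatS", "HetN")))
  structure(list(times = sol[, 1L], fields = fields, omega = M,
                 omega_t = omega0 * exp(rho_tilde * sol[, 1L]),
                 params = p, rho_tilde = rho_tilde, omega0 = omega0,
                 mode = "continuum-growing"),
            class = "het_trajectory")
}

#' Unstable-mode band as a function of filament size
#'
#' For each filament size `Omega` in `omegas`, evaluates the discrete
#' dispersion relation at the (size-independent) homogeneous equilibrium
#' and reports how many non-uniform modes grow, together with the index of
#' the fastest-growing mode and the extremes of the unstable band.  On a
#' filament inside the deterministic instability region, the unstable-mode
#' count is non-decreasing with size and the leading-mode index grows
#' linearly, which is why patterns keep a fixed spacing in cell units as
#' the filament elongates.
#'
#' @inheritParams discrete_dispersion
#' @param omegas Integer vector of filament sizes.
#' @return Data frame with `omega`, `n_unstable`, `leading_mode` (index
#'   with `Lambda` sorted descending; `NA` when no mode grows),
#'   `band_low`, `band_high` (smallest / largest unstable mode index).
#' @export
unstable_band <- function(params, omegas, eq = NULL) {
  p <- as_het_params(params)
  if (is.null(eq)) eq <- find_equilibrium(p)
  J <- jacobian_matrices(p, eq)
  rows <- lapply(omegas, function(om) {
    lat <- build_chain(om)
    lam <- vapply(lat$values, function(L)
      lambda_max_at(J$J0, p$D_S, p$D_N, L), numeric(1))
    nz <- lat$values < -1e-12
    up <- which(nz & lam > 0)
    data.frame(omega = om, n_unstable = length(up),
               leading_mode = if (length(up)) up[which.max(lam[up])] else NA,
               band_low = if (length(up)) min(up) else NA,
               band_high = if (length(up)) max(up) else NA)
  })
  do.call(rbind, rows)
}
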