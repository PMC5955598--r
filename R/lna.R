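#' Drift and noise matrices of the linear-noise approximation
#'
#' Next-to-leading order of the system-size expansion about the homogeneous
#' equilibrium: fluctuations obey a linear Langevin equation with drift
#' `M = M_NS + M_SP * Lambda` and white-noise covariance
#' `B = B_NS + B_SP * Lambda` in the Laplacian mode basis.
#'
#' `M_NS` is the reaction Jacobian and `M_SP = diag(0, D_S, D_N)`.  The
#' noise covariances are assembled channel by channel from the reaction
#' scheme as the sum of (stoichiometry outer product) x (rate at
#' equilibrium).  The on-site part is
#' \deqn{B_{11} = \alpha_R + \beta_R h + k_R\phi + 4\mu_S\phi^2\psi
#'       + 4\mu_N\phi^2\eta, \quad
#'       B_{12} = 2\mu_S\phi^2\psi, \quad B_{13} = 2\mu_N\phi^2\eta,}
#' \deqn{B_{22} = \alpha_S + \beta_S h + k_S\psi + \mu_S\phi^2\psi, \quad
#'       B_{33} = \alpha_N + k_N\eta + \mu_N\phi^2\eta, \quad B_{23} = 0.}
#' The hop channels contribute `-2 D_S psi*` and `-2 D_N eta*` on the
#' inhibitor diagonal of `B_SP`; since `Lambda <= 0`, the product
#' `B_SP * Lambda` adds non-negative diffusion noise.
#'
#' @inheritParams jacobian_matrices
#' @return List of 3x3 matrices `M_NS`, `M_SP`, `B_NS`, `B_SP`, plus the
#'   equilibrium used.  Warns when the equilibrium is not stable (the
#'   stationary spectrum assumes relaxation about a stable point).
#' @export
lna_matrices <- function(params, eq) {
  p <- as_het_params(params)
  J <- jacobian_matrices(p, eq)
  phi <- eq$phi; psi <- eq$psi; eta <- eq$eta
  h <- hill(phi, p$K)
  phi2 <- phi^2

  B_NS <- matrix(0, 3L, 3L)
  B_NS[1L, 1L] <- p$alpha_R + p$beta_R * h + p$k_R * phi +
    4 * p$mu_S * phi2 * psi + 4 * p$mu_N * phi2 * eta
  B_NS[2L, 2L] <- p$alpha_S + p$beta_S * h + p$k_S * psi +
    p$mu_S * phi2 * psi
  B_NS[3L, 3L] <- p$alpha_N + p$k_N * eta + p$mu_N * phi2 * eta
  B_NS[1L, 2L] <- B_NS[2L, 1L] <- 2 * p$mu_S * phi2 * psi
  B_NS[1L, 3L] <- B_NS[3L, 1L] <- 2 * p$mu_N * phi2 * eta

  B_SP <- diag(c(0, -2 * p$D_S * psi, -2 * p$D_N * eta))

  if (isFALSE(eq$stable_homogeneous))
    warning("equilibrium is not homogeneously stable; ",
            "the stationary spectrum formula does not apply")
  list(M_NS = J$J0, M_SP = J$JD, B_NS = B_NS, B_SP = B_SP, eq = eq)
}

# Resolvent power spectrum at one (omega, Lambda) grid point.
spectrum_point <- function(m, w, Lambda) {
  A <- m$M_NS + m$M_SP * Lambda
  B <- m$B_NS + m$B_SP * Lambda
  F <- -1i * w * diag(3L) - A
  Fi <- tryCatch(solve(F), error = function(e) NULL)
  if (is.null(Fi)) return(rep(NA_real_, 3L))
  Re(diag(Fi %*% B %*% Conj(t(Fi))))
}

#' Theoretical power spectrum of demographic fluctuations
#'
#' Evaluates the stationary linear-noise power spectrum
#' `P_q(omega, Lambda) = [F^-1 (B_NS + B_SP Lambda) (F^dagger)^-1]_qq`
#' with `F = -i omega I - M_NS - M_SP Lambda`, for each species `q`
#' (HetR, PatS, HetN), on a frequency grid crossed with either the discrete
#' Laplacian eigenvalues of a lattice or an explicit `Lambda` grid
#' (continuum: `Lambda = -k^2`).
#'
#' @inheritParams jacobian_matrices
#' @param lattice Optional [build_chain()] lattice supplying the discrete
#'   modes.
#' @param Lambda Explicit Laplacian-eigenvalue grid (used when `lattice` is
#'   `NULL`).
#' @param omega_grid Numeric grid of time frequencies.
#' @return A `het_spectrum` object: list with `omega`, `Lambda`, `P`
#'   (array `n_omega x n_Lambda x 3`), `peak` (arg-max of the HetR
#'   spectrum) and `normalization = "theoretical"`.
#' @export
theoretical_spectrum <- function(params, eq = NULL, lattice = NULL,
                                 Lambda = NULL, omega_grid = 0) {
  p <- as_het_params(params)
  if (is.null(eq)) eq <- find_equilibrium(p)
  if (is.null(Lambda)) {
    if (is.null(lattice))
      stop("supply either 'lattice' or 'Lambda'", call. = FALSE)
    Lambda <- lattice$values
  }
  m <- lna_matrices(p, eq)
  P <- array(NA_real_, c(length(omega_grid), length(Lambda), 3L),
             dimnames = list(NULL, NULL, c("HetR", "PatS", "HetN")))
  for (b in seq_along(Lambda))
    for (a in seq_along(omega_grid))
      P[a, b, ] <- spectrum_point(m, omega_grid[a], Lambda[b])

  pk <- which(P[, , 1L, drop = FALSE] == max(P[, , 1L], na.rm = TRUE),
              arr.ind = TRUE)[1L, ]
  structure(list(omega = omega_grid, Lambda = Lambda, P = P,
                 peak = list(omega = omega_grid[pk[1L]],
                             Lambda = Lambda[pk[2L]],
                             height = max(P[, , 1L], na.rm = TRUE)),
                 normalization = "theoretical"),
            class = "het_spectrum")
}

#' @export
print.het_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum (%s): %d frequencies x %d modes\n",
              x$normalization, length(x$omega), length(x$Lambda)))
  cat(sprintf("  HetR peak at omega = %.4g, Lambda = %.4g (height %.4g)\n",
              x$peak$omega, x$peak$Lambda, x$peak$height))
  invisible(x)
}

#' Empirical power spectrum from stochastic trajectories
#'
#' Reconstructs the fluctuation power spectrum from one or more Gillespie
#' realizations: fluctuations `xi = sqrt(V) (counts/V - equilibrium)` are
#' projected on the Laplacian eigenmodes ([mode_transform()]) and Fourier
#' transformed in time over a stated window with a plain rectangular
#' window, `P = |dt * sum_t xi(t) exp(i omega t)|^2 / T`.  Supplying a list
#' of trajectories averages the periodograms.
#'
#' @param trajectory A `het_trajectory` from [gillespie_run()], or a list
#'   of them (ensemble average).
#' @inheritParams theoretical_spectrum
#' @param lattice The lattice the trajectory was simulated on.
#' @param window Length-2 numeric, time interval `[tau_start, tau_end]`
#'   analysed.
#' @param omega_grid Frequencies at which to evaluate the transform;
#'   defaults to the natural Fourier frequencies of the window.
#' @param match_to Optional `het_spectrum`; if given, the empirical HetR
#'   spectrum is rescaled so its maximum matches `match_to`'s.
#' @return A `het_spectrum` with `normalization` `"empirical"` or
#'   `"empirical-matched"`.
#' @export
empirical_spectrum <- function(trajectory, eq, lattice, window,
                               omega_grid = NULL, match_to = NULL) {
  runs <- if (inherits(trajectory, "het_trajectory")) list(trajectory)
          else trajectory
  stopifnot(length(runs) >= 1L, inherits(lattice, "chain_lattice"))
  tr1 <- runs[[1L]]
  sel <- which(tr1$times >= window[1L] & tr1$times <= window[2L])
  if (length(sel) < 4L)
    stop("window [", window[1L], ", ", window[2L],
         "] is outside the trajectory", call. = FALSE)
  tsel <- tr1$times[sel]
  dt <- diff(tsel[1:2])
  Tw <- tsel[length(tsel)] - tsel[1L] + dt
  if (is.null(omega_grid))
    omega_grid <- 2 * pi * (0:(length(sel) %/% 2L)) / Tw

  E <- exp(1i * outer(tsel, omega_grid))  # T x n_omega
  eqv <- c(eq$phi, eq$psi, eq$eta)
  Pacc <- array(0, c(length(omega_grid), lattice$omega, 3L))
  for (tr in runs) {
    stopifnot(tr$omega == lattice$omega)
    for (q in 1:3) {
      xi <- sqrt(tr$V) * (tr$fields[sel, , q] / tr$V - eqv[q])
      A <- mode_transform(xi, lattice)          # T x modes
      S <- crossprod(E, A) * dt                 # n_omega x modes
      Pacc[, , q] <- Pacc[, , q] + Mod(S)^2 / Tw
    }
  }
  P <- Pacc / length(runs)
  dimnames(P) <- list(NULL, NULL, c("HetR", "PatS", "HetN"))

  norm <- "empirical"
  if (!is.null(match_to)) {
    P <- P * max(match_to$P[, , 1L], na.rm = TRUE) / max(P[, , 1L])
    norm <- "empirical-matched"
  }
  pk <- which(P[, , 1L, drop = FALSE] == max(P[, , 1L]),
              arr.ind = TRUE)[1L, ]
  structure(list(omega = omega_grid, Lambda = lattice$values, P = P,
                 peak = list(omega = omega_grid[pk[1L]],
                             Lambda = lattice$values[pk[2L]],
                             height = max(P[, , 1L])),
                 normalization = norm),
            class = "het_spectrum")
}

#' Stationary mode-resolved covariances from the linear-noise model
#'
#' Solves the Lyapunov equation `A C + C A^T + B = 0` with
#' `A = M_NS + M_SP Lambda` and `B = B_NS + B_SP Lambda` for each mode.
#' The diagonal of `C` gives the stationary variance of the fluctuations
#' per species in that mode, the quantity measured by mode-projected
#' Gillespie ensembles.
#'
#' @inheritParams theoretical_spectrum
#' @return Array `3 x 3 x n_Lambda` of covariance matrices.
#' @export
mode_variances <- function(params, eq, lattice = NULL, Lambda = NULL) {
  p <- as_het_params(params)
  if (is.null(Lambda)) {
    stopifnot(!is.null(lattice))
    Lambda <- lattice$values
  }
  m <- lna_matrices(p, eq)
  out <- array(NA_real_, c(3L, 3L, length(Lambda)))
  I3 <- diag(3L)
  for (b in seq_along(Lambda)) {
    A <- m$M_NS + m$M_SP * Lambda[b]
    B <- m$B_NS + m$B_SP * Lambda[b]
    K <- kronecker(I3, A) + kronecker(A, I3)
    out[, , b] <- matrix(solve(K, -as.numeric(B)), 3L, 3L)
  }
  out
}

#' Map the stochastic (noise-driven) instability region
#'
#' For each point of a `(beta_S, beta_R)` grid with a stable homogeneous
#' equilibrium, evaluates the zero-frequency HetR spectrum `P_1(0, Lambda)`
#' over the discrete modes and records whether it displays a localized
#' interior maximum: the arg-max over non-uniform modes must be interior
#' (neither the mode closest to `Lambda = 0` nor the last mode) and its
#' height at least `height_ratio` times the value at the mode closest to
#' zero.  The deterministic instability flag is computed alongside; points
#' already inside the deterministic region are counted as noise-driven by
#' definition, since the stationary fluctuation spectrum does not exist
#' there (the linear-noise solution grows secularly at the unstable
#' modes).
#'
#' @inheritParams region_scan
#' @param height_ratio Peak-height criterion relative to the
#'   near-uniform-mode boundary value.
#' @return Data frame with columns `beta_S`, `beta_R`, `has_equilibrium`,
#'   `stable`, `det_turing`, `stoch_peak`, `peak_height`, `peak_Lambda`.
#' @export
stochastic_region_scan <- function(params, beta_S, beta_R, lattice,
                                   height_ratio = 1.2) {
  p <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  Lall <- lattice$values
  nz <- which(Lall < -1e-12)            # non-uniform modes, Lambda descending
  grid <- expand.grid(beta_S = beta_S, beta_R = beta_R,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  has_eq <- logical(n); stable <- logical(n); det <- logical(n)
  speak <- logical(n); ph <- rep(NA_real_, n); pl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pi <- p; pi$beta_S <- grid$beta_S[i]; pi$beta_R <- grid$beta_R[i]
    eqi <- tryCatch(suppressWarnings(find_equilibrium(pi)),
                    het_no_equilibrium = function(e) NULL)
    if (is.null(eqi)) next
    has_eq[i] <- TRUE
    stable[i] <- eqi$stable_homogeneous
    if (!stable[i]) next
    J0 <- jacobian_nonspatial(pi, eqi$phi, eqi$psi, eqi$eta)
    lam <- vapply(Lall[nz], function(L)
      lambda_max_at(J0, pi$D_S, pi$D_N, L), numeric(1))
    det[i] <- max(lam) > 0
    m <- lna_matrices(pi, eqi)
    P1 <- vapply(Lall[nz], function(L) spectrum_point(m, 0, L)[1L],
                 numeric(1))
    j <- which.max(P1)
    interior <- j > 1L && j < length(P1)
    # inside the deterministic region the stationary spectrum does not
    # exist (fluctuations grow secularly at the unstable modes), so those
    # points belong to the noise-driven region by definition
    speak[i] <- det[i] ||
      (interior && P1[j] >= height_ratio * P1[1L])
    ph[i] <- P1[j]; pl[i] <- Lall[nz][j]
  }
  cbind(grid, has_equilibrium = has_eq, stable = stable,
        det_turing = det, stoch_peak = speak,
        peak_height = ph, peak_Lambda = pl)
}
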