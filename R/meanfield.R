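#' Deterministic rate equations of the three-morphogen model
#'
#' Right-hand side of the mean-field limit of the chemical master equation.
#' With `phi`, `psi`, `eta` the concentrations of HetR, PatS, HetN in cell
#' `i` and `h(x) = x^2/(K^2 + x^2)` the dimeric Hill response:
#'
#' \deqn{\dot\phi_i = \alpha_R - k_R\phi_i + \beta_R h(\phi_i)
#'   - 2\mu_S\phi_i^2\psi_i - 2\mu_N\phi_i^2\eta_i}
#' \deqn{\dot\psi_i = \alpha_S - k_S\psi_i + \beta_S h(\phi_i)
#'   - \mu_S\phi_i^2\psi_i + D_S \sum_j \Delta_{ij}\psi_j}
#' \deqn{\dot\eta_i = \alpha_N - k_N\eta_i - \mu_N\phi_i^2\eta_i
#'   + D_N \sum_j \Delta_{ij}\eta_j}
#'
#' The factor 2 on the trimolecular terms in the activator equation reflects
#' that each complex-degradation event removes two HetR molecules but only
#' one inhibitor molecule.  Only the inhibitors diffuse.
#'
#' @param state Numeric `omega x 3` matrix of non-negative concentrations,
#'   columns (HetR, PatS, HetN).
#' @param params A [model_params()] object.
#' @param lattice A [build_chain()] lattice with matching `omega`.
#' @return An `omega x 3` matrix of time derivatives.
#' @export
rhs_deterministic <- function(state, params, lattice) {
  params <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  state <- as.matrix(state)
  if (nrow(state) != lattice$omega || ncol(state) != 3L)
    stop("'state' must be an omega x 3 matrix", call. = FALSE)
  if (anyNA(state) || any(!is.finite(state)))
    stop("'state' contains NA or non-finite values", call. = FALSE)
  if (any(state < 0))
    stop("'state' contains negative concentrations", call. = FALSE)

  phi <- state[, 1L]; psi <- state[, 2L]; eta <- state[, 3L]
  h <- hill(phi, params$K)
  phi2 <- phi^2
  dphi <- params$alpha_R - params$k_R * phi + params$beta_R * h -
    2 * params$mu_S * phi2 * psi - 2 * params$mu_N * phi2 * eta
  dpsi <- params$alpha_S - params$k_S * psi + params$beta_S * h -
    params$mu_S * phi2 * psi +
    params$D_S * drop(lattice$laplacian %*% psi)
  deta <- params$alpha_N - params$k_N * eta -
    params$mu_N * phi2 * eta +
    params$D_N * drop(lattice$laplacian %*% eta)
  cbind(dphi, dpsi, deta, deparse.level = 0)
}

# Closed forms of the inhibitor nullclines given the activator level.
psi_nullcline <- function(phi, p)
  (p$alpha_S + p$beta_S * hill(phi, p$K)) / (p$k_S + p$mu_S * phi^2)
eta_nullcline <- function(phi, p)
  p$alpha_N / (p$k_N + p$mu_N * phi^2)

# Scalar reduction of the fixed-point condition: activator balance after
# substituting both inhibitor nullclines.
equilibrium_scalar <- function(phi, p) {
  p$alpha_R - p$k_R * phi + p$beta_R * hill(phi, p$K) -
    2 * p$mu_S * phi^2 * psi_nullcline(phi, p) -
    2 * p$mu_N * phi^2 * eta_nullcline(phi, p)
}

#' Homogeneous equilibria of the rate equations
#'
#' Finds all real, non-negative homogeneous fixed points
#' `(phi*, psi*, eta*)` by a bracketed scan of the scalar activator balance
#' over `[0, (alpha_R + beta_R)/k_R]` (an upper bound because the Hill
#' response is at most 1), followed by bisection refinement.  Each root is
#' back-substituted into the closed-form inhibitor nullclines and flagged
#' for local stability of the non-spatial (uniform-mode) Jacobian.
#'
#' The reference equilibrium is the stable root; when several roots are
#' stable the one with the largest activator level is returned with a
#' warning (the Turing analysis requires a homogeneous-stable base state).
#'
#' @inheritParams rhs_deterministic
#' @param all If `TRUE`, return a data frame of every non-negative root.
#' @param n_grid Number of scan points for root bracketing.
#' @return For `all = FALSE`, an object of class `het_equilibrium`: a list
#'   with `phi`, `psi`, `eta`, `residual` (max absolute rate at the point)
#'   and `stable_homogeneous`.  For `all = TRUE`, a data frame with one row
#'   per root.
#' @examples
#' eq <- find_equilibrium(model_params())
#' eq$residual
#' @export
find_equilibrium <- function(params, all = FALSE, n_grid = 2000L) {
  p <- as_het_params(params)
  phi_max <- if (p$k_R > 0) (p$alpha_R + p$beta_R) / p$k_R else
    max(1, (p$alpha_R + p$beta_R)) * 100
  grid <- seq(0, phi_max, length.out = n_grid + 1L)
  g <- equilibrium_scalar(grid, p)

  roots <- numeric(0)
  if (any(g == 0)) roots <- c(roots, grid[g == 0])
  sgn <- which(g[-1L] * g[-length(g)] < 0)
  for (i in sgn) {
    r <- uniroot(equilibrium_scalar, c(grid[i], grid[i + 1L]), p = p,
                 tol = 1e-13)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  roots <- roots[roots >= 0]
  if (length(roots) == 0)
    stop(structure(class = c("het_no_equilibrium", "error", "condition"),
                   list(message = "no non-negative homogeneous equilibrium found",
                        call = sys.call(-1))))

  rows <- lapply(roots, function(phi) {
    psi <- psi_nullcline(phi, p)
    eta <- eta_nullcline(phi, p)
    lat1 <- build_chain(1L)
    res <- max(abs(rhs_deterministic(matrix(c(phi, psi, eta), 1L), p, lat1)))
    J0 <- jacobian_nonspatial(p, phi, psi, eta)
    stable <- all(Re(eigen(J0, only.values = TRUE)$values) < 0)
    data.frame(phi = phi, psi = psi, eta = eta, residual = res,
               stable_homogeneous = stable)
  })
  tab <- do.call(rbind, rows)
  if (all) return(tab)

  stab <- tab[tab$stable_homogeneous, , drop = FALSE]
  pick <- if (nrow(stab) > 0) {
    if (nrow(stab) > 1)
      warning("multiple stable homogeneous equilibria; using largest phi*")
    stab[which.max(stab$phi), ]
  } else {
    tab[which.max(tab$phi), ]
  }
  structure(list(phi = pick$phi, psi = pick$psi, eta = pick$eta,
                 residual = pick$residual,
                 stable_homogeneous = pick$stable_homogeneous,
                 n_roots = nrow(tab)),
            class = "het_equilibrium")
}

#' @export
print.het_equilibrium <- function(x, ...) {
  cat(sprintf("Homogeneous equilibrium: phi* = %.6g, psi* = %.6g, eta* = %.6g\n",
              x$phi, x$psi, x$eta))
  cat(sprintf("  residual %.2e, %s (%d non-negative root%s found)\n",
              x$residual,
              if (x$stable_homogeneous) "stable" else "UNSTABLE",
              x$n_roots, if (x$n_roots == 1) "" else "s"))
  invisible(x)
}

#' Integrate the deterministic rate equations
#'
#' Stiff-safe time integration (method of lines via [deSolve::ode()] with
#' `lsoda`) of the mean-field equations on a fixed chain.
#'
#' @inheritParams rhs_deterministic
#' @param init `omega x 3` matrix of non-negative initial concentrations.
#' @param tau_end Final dimensionless time.
#' @param n_out Number of output time points (including `tau = 0`).
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @return A `het_trajectory` object: list with `times`, `fields` (array
#'   `n_out x omega x 3`), `omega`, `params`, `mode = "deterministic"`.
#' @export
integrate_deterministic <- function(params, lattice, init, tau_end,
                                    n_out = 201L, rtol = 1e-8, atol = 1e-10) {
  params <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  init <- as.matrix(init)
  if (nrow(init) != lattice$omega || ncol(init) != 3L)
    stop("'init' must be an omega x 3 matrix", call. = FALSE)
  if (any(init < 0)) stop("'init' must be non-negative", call. = FALSE)
  omega <- lattice$omega

  deriv <- function(t, y, parms) {
    st <- matrix(y, omega, 3L)
    # lsoda can probe slightly negative states; evaluate the smooth RHS
    # directly rather than clipping inside the dynamics.
    phi <- st[, 1L]; psi <- st[, 2L]; eta <- st[, 3L]
    h <- hill(phi, params$K); phi2 <- phi^2
    dphi <- params$alpha_R - params$k_R * phi + params$beta_R * h -
      2 * params$mu_S * phi2 * psi - 2 * params$mu_N * phi2 * eta
    dpsi <- params$alpha_S - params$k_S * psi + params$beta_S * h -
      params$mu_S * phi2 * psi + params$D_S * drop(lattice$laplacian %*% psi)
    deta <- params$alpha_N - params$k_N * eta - params$mu_N * phi2 * eta +
      params$D_N * drop(lattice$laplacian %*% eta)
    list(c(dphi, dpsi, deta))
  }

  times <- seq(0, tau_end, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(init), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("deterministic integration failed (istate = ",
         attr(sol, "istate")[1L], ")", call. = FALSE)

  fields <- array(sol[, -1L], dim = c(nrow(sol), omega, 3L),
                  dimnames = list(NULL, NULL, c("HetR", "PatS", "HetN")))
  fields[fields < 0 & fields > -atol * 10] <- 0  # clip integrator jitter
  structure(list(times = sol[, 1L], fields = fields, omega = omega,
                 params = params, mode = "deterministic"),
            class = "het_trajectory")
}

#' @export
print.het_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d time points, omega = %d\n",
              x$mode, length(x$times), x$omega))
  if (!is.null(x$V)) cat(sprintf("  cell volume V = %g, seed = %s\n",
                                 x$V, format(x$seed)))
  invisible(x)
}

#' Summary statistics of a spatial concentration profile
#'
#' Locates the local maxima of a one-dimensional field (above a configurable
#' prominence), the inter-peak spacings in cells, and the field amplitude
#' `max - min`.  Used to quantify the characteristic separation between
#' activator crests.
#'
#' @param field Numeric vector (length >= 3).
#' @param prominence Minimum height of a peak above the higher of the two
#'   flanking minima (same units as `field`).  Defaults to 5 percent of the
#'   field amplitude.
#' @return List with `peaks` (indices), `spacings` (cells) and `amplitude`.
#' @export
pattern_metrics <- function(field, prominence = NULL) {
  field <- as.numeric(field)
  if (length(field) < 3L) stop("'field' must have length >= 3", call. = FALSE)
  amp <- max(field) - min(field)
  if (is.null(prominence)) prominence <- 0.05 * amp
  n <- length(field)

  cand <- which(diff(sign(diff(field))) < 0) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    # prominence: drop from the peak to the higher of the two valley floors
    # reached before any taller point.
    left <- field[seq_len(i - 1L)]
    higher_l <- which(left >= field[i])
    lmin <- if (length(higher_l)) min(field[(max(higher_l)):(i - 1L)]) else
      min(left)
    right <- field[(i + 1L):n]
    higher_r <- which(right >= field[i])
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else
      min(right)
    keep[j] <- (field[i] - max(lmin, rmin)) >= prominence
  }
  peaks <- cand[keep]
  list(peaks = peaks,
       spacings = if (length(peaks) > 1L) diff(peaks) else numeric(0),
       amplitude = amp)
}
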