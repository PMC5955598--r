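# Analytic non-spatial Jacobian of the reaction part at a homogeneous point.
# Row 1 couples the activator to itself and to both inhibitors; the
# inhibitors never couple to each other directly.
jacobian_nonspatial <- function(p, phi, psi, eta) {
  hp <- hill_prime(phi, p$K)
  rbind(
    c(-p$k_R + p$beta_R * hp - 4 * p$mu_S * phi * psi -
        4 * p$mu_N * phi * eta,
      -2 * p$mu_S * phi^2, -2 * p$mu_N * phi^2),
    c(p$beta_S * hp - 2 * p$mu_S * phi * psi,
      -p$k_S - p$mu_S * phi^2, 0),
    c(-2 * p$mu_N * phi * eta, 0, -p$k_N - p$mu_N * phi^2))
}

# Largest real part of the eigenvalues of the 3x3 stability matrix at a
# given Laplacian eigenvalue.  Ties in the real part are irrelevant for the
# reported maximum.
lambda_max_at <- function(J0, D_S, D_N, Lambda) {
  Q <- J0
  Q[2L, 2L] <- Q[2L, 2L] + D_S * Lambda
  Q[3L, 3L] <- Q[3L, 3L] + D_N * Lambda
  max(Re(eigen(Q, only.values = TRUE)$values))
}

#' Jacobian of the homogeneous state
#'
#' Returns the non-spatial reaction Jacobian `J0` (the derivative of the
#' reaction part of the rate equations at `(phi*, psi*, eta*)`, computed
#' analytically) and the diffusion matrix `J_D = diag(0, D_S, D_N)`.  The
#' linear-stability matrix at Laplacian eigenvalue `Lambda` is
#' `Q = J0 + J_D * Lambda`.
#'
#' @inheritParams rhs_deterministic
#' @param eq A `het_equilibrium` (or list with `phi`, `psi`, `eta`).
#' @param tol Maximum admissible residual of `eq`.
#' @return List with `J0` and `JD` (both 3x3).
#' @export
jacobian_matrices <- function(params, eq, tol = 1e-8) {
  p <- as_het_params(params)
  lat1 <- build_chain(1L)
  res <- max(abs(rhs_deterministic(matrix(c(eq$phi, eq$psi, eq$eta), 1L),
                                   p, lat1)))
  if (res > tol)
    stop("'eq' is not a fixed point (residual ", format(res), ")",
         call. = FALSE)
  list(J0 = jacobian_nonspatial(p, eq$phi, eq$psi, eq$eta),
       JD = diag(c(0, p$D_S, p$D_N)))
}

new_dispersion <- function(df, J0, type, band = NULL) {
  lam0 <- max(Re(eigen(J0, only.values = TRUE)$values))
  nonuni <- df$Lambda < -1e-12
  max_nu <- if (any(nonuni)) max(df$lambda_max[nonuni]) else -Inf
  arg <- if (any(nonuni)) {
    i <- which(nonuni)[which.max(df$lambda_max[nonuni])]
    df[i, , drop = FALSE]
  } else NULL
  structure(df,
            lambda0 = lam0,
            homogeneous_stable = lam0 < 0,
            max_nonuniform = max_nu,
            argmax = arg,
            turing_unstable = (lam0 < 0) && (max_nu > 0),
            type = type, band = band,
            class = c("het_dispersion", "data.frame"))
}

#' Discrete dispersion relation on the cell chain
#'
#' For every Laplacian eigenvalue `Lambda^(alpha)` of the chain, the growth
#' rate of linear perturbations is the largest real part of the eigenvalues
#' of `Q = J0 + diag(0, D_S, D_N) Lambda^(alpha)`.  The uniform mode
#' (`Lambda = 0`) recovers the stability of the non-spatial system; a
#' positive maximum over the non-uniform modes, together with a stable
#' uniform mode, signals a diffusion-driven (Turing) instability.
#'
#' @inheritParams jacobian_matrices
#' @param lattice A [build_chain()] lattice.
#' @return A `het_dispersion` data frame (`mode`, `Lambda`, `lambda_max`)
#'   with attributes `lambda0`, `homogeneous_stable`, `max_nonuniform`,
#'   `argmax`, `turing_unstable`.
#' @export
discrete_dispersion <- function(params, eq = NULL, lattice) {
  p <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  if (is.null(eq)) eq <- find_equilibrium(p)
  J <- jacobian_matrices(p, eq)
  lam <- vapply(lattice$values, function(L)
    lambda_max_at(J$J0, p$D_S, p$D_N, L), numeric(1))
  df <- data.frame(mode = seq_len(lattice$omega), Lambda = lattice$values,
                   lambda_max = lam)
  new_dispersion(df, J$J0, type = "discrete")
}

#' Continuum dispersion relation
#'
#' The continuum limit replaces the discrete Laplacian eigenvalue with
#' `-k^2`, `k` the spatial Fourier wavenumber.  The discrete relation is a
#' collection of `omega` points lying exactly on this smooth curve.  Also
#' reports `k_max` (the arg-max) and, when present, the band `[k_low,
#' k_high]` of positive growth.
#'
#' @inheritParams jacobian_matrices
#' @param k Numeric grid of wavenumbers (>= 0).
#' @return A `het_dispersion` data frame (`k`, `Lambda`, `lambda_max`) with
#'   the same attributes as [discrete_dispersion()] plus `k_max` and `band`.
#' @export
continuum_dispersion <- function(params, eq = NULL, k) {
  p <- as_het_params(params)
  if (is.null(eq)) eq <- find_equilibrium(p)
  J <- jacobian_matrices(p, eq)
  lam <- vapply(k, function(kk)
    lambda_max_at(J$J0, p$D_S, p$D_N, -kk^2), numeric(1))
  df <- data.frame(mode = seq_along(k), k = k, Lambda = -k^2,
                   lambda_max = lam)

  band <- NULL
  pos <- lam > 0 & k > 0
  if (any(pos)) {
    f <- function(kk) lambda_max_at(J$J0, p$D_S, p$D_N, -kk^2)
    i1 <- which(pos)[1L]
    i2 <- rev(which(pos))[1L]
    k_low <- if (i1 > 1L) uniroot(f, c(k[i1 - 1L], k[i1]), tol = 1e-10)$root
      else k[i1]
    k_high <- if (i2 < length(k)) uniroot(f, c(k[i2], k[i2 + 1L]),
                                          tol = 1e-10)$root else k[i2]
    band <- c(k_low = k_low, k_high = k_high)
  }
  out <- new_dispersion(df, J$J0, type = "continuum", band = band)
  attr(out, "k_max") <- k[which.max(lam)]
  out
}

#' @export
print.het_dispersion <- function(x, ...) {
  cat(sprintf("%s dispersion relation over %d modes\n",
              attr(x, "type"), nrow(x)))
  cat(sprintf("  lambda(0) = %.4g (%s), max over non-uniform modes = %.4g\n",
              attr(x, "lambda0"),
              if (attr(x, "homogeneous_stable")) "stable" else "unstable",
              attr(x, "max_nonuniform")))
  cat(sprintf("  Turing unstable: %s\n", attr(x, "turing_unstable")))
  invisible(x)
}

#' Scan the (beta_S, beta_R) plane for the Turing instability region
#'
#' At each grid point the homogeneous equilibrium is recomputed, its local
#' stability checked, and the discrete dispersion maximum over non-uniform
#' modes evaluated.  A point belongs to the deterministic instability region
#' when the uniform state is stable and the non-uniform maximum positive.
#'
#' @inheritParams discrete_dispersion
#' @param beta_S,beta_R Numeric grid values for the two activation
#'   strengths.
#' @return Data frame with one row per grid point: `beta_S`, `beta_R`,
#'   `has_equilibrium`, `stable`, `max_lambda`, `turing`.
#' @export
region_scan <- function(params, beta_S, beta_R, lattice) {
  p <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  Lnz <- lattice$values[lattice$values < -1e-12]
  grid <- expand.grid(beta_S = beta_S, beta_R = beta_R,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  has_eq <- logical(n); stable <- logical(n); maxl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pi <- p; pi$beta_S <- grid$beta_S[i]; pi$beta_R <- grid$beta_R[i]
    eq <- tryCatch(suppressWarnings(find_equilibrium(pi)),
                   het_no_equilibrium = function(e) NULL)
    if (is.null(eq)) next
    has_eq[i] <- TRUE
    stable[i] <- eq$stable_homogeneous
    if (!stable[i]) next
    J0 <- jacobian_nonspatial(pi, eq$phi, eq$psi, eq$eta)
    maxl[i] <- max(vapply(Lnz, function(L)
      lambda_max_at(J0, pi$D_S, pi$D_N, L), numeric(1)))
  }
  cbind(grid, has_equilibrium = has_eq, stable = stable,
        max_lambda = maxl,
        turing = has_eq & stable & !is.na(maxl) & maxl > 0)
}

#' Bracket the instability threshold along one parameter axis
#'
#' Scans a single parameter over a bracket on a regular grid, locates the
#' first grid value at which the Turing instability holds, then refines the
#' boundary by bisection on the instability indicator.  Assumes the
#' unstable side lies at the upper end of the bracket.
#'
#' @inheritParams discrete_dispersion
#' @param axis Name of the scanned parameter (e.g. `"beta_S"`).
#' @param bracket Length-2 numeric: scan range, stable at the lower end and
#'   unstable somewhere inside.
#' @param step Grid step of the initial scan.
#' @param tol Bisection tolerance on the critical value.
#' @return List with `critical` (bisection estimate of the boundary),
#'   `grid_value` (smallest scanned grid value that is unstable), and the
#'   final bisection bracket `lower`, `upper`.
#' @export
threshold_search <- function(params, axis, bracket, step = 0.005,
                             lattice, tol = 1e-4) {
  p <- as_het_params(params)
  if (!axis %in% names(p)) stop("unknown parameter '", axis, "'",
                                call. = FALSE)
  Lnz <- lattice$values[lattice$values < -1e-12]
  unstable <- function(v) {
    pv <- p; pv[[axis]] <- v
    eq <- tryCatch(suppressWarnings(find_equilibrium(pv)),
                   het_no_equilibrium = function(e) NULL)
    if (is.null(eq) || !eq$stable_homogeneous) return(FALSE)
    J0 <- jacobian_nonspatial(pv, eq$phi, eq$psi, eq$eta)
    any(vapply(Lnz, function(L)
      lambda_max_at(J0, pv$D_S, pv$D_N, L), numeric(1)) > 0)
  }
  vals <- seq(bracket[1L], bracket[2L], by = step)
  flags <- vapply(vals, unstable, logical(1))
  if (!any(flags) || flags[1L])
    stop(structure(class = c("het_not_bracketed", "error", "condition"),
                   list(message = paste0(
                     "instability boundary not bracketed on [",
                     bracket[1L], ", ", bracket[2L], "]"),
                     call = sys.call(-1))))
  i <- which(flags)[1L]
  lo <- vals[i - 1L]; hi <- vals[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable(mid)) hi <- mid else lo <- mid
  }
  list(critical = (lo + hi) / 2, grid_value = vals[i],
       lower = lo, upper = hi)
}
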