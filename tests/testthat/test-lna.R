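# Assemble the full-lattice noise covariance directly from the reaction
# channel list (stoichiometry outer products times rates), then project it
# on a Laplacian eigenmode.  Independent oracle for the closed-form
# B_NS + B_SP * Lambda used by the spectrum.
channel_B_mode <- function(params, lattice, V, eq, mode) {
  ch <- build_channels(params, lattice, V)
  om <- lattice$omega
  counts <- matrix(round(V * c(eq$phi, eq$psi, eq$eta)), om, 3,
                   byrow = TRUE)
  Bfull <- matrix(0, 3 * om, 3 * om)  # index (q, i) -> q + 3 (i - 1)
  for (x in ch) {
    nu <- numeric(3 * om)
    nu[3 * (x$cell - 1) + 1:3] <- x$change
    if (!is.na(x$partner))
      nu[3 * (x$partner - 1) + 1:3] <-
        nu[3 * (x$partner - 1) + 1:3] + x$partner_change
    Bfull <- Bfull + (x$propensity(counts) / V) * tcrossprod(nu)
  }
  v <- lattice$vectors[, mode]
  Bm <- matrix(0, 3, 3)
  for (q in 1:3) for (l in 1:3) {
    blk <- Bfull[3 * (seq_len(om) - 1) + q, 3 * (seq_len(om) - 1) + l]
    Bm[q, l] <- drop(v %*% blk %*% v)
  }
  Bm
}

test_that("noise matrices follow the channel outer-product rule", {
  p <- preset_params("ratio3_turing")$params
  eq <- find_equilibrium(p)
  m <- lna_matrices(p, eq)

  # drift blocks are the Jacobian pieces
  J <- jacobian_matrices(p, eq)
  expect_equal(m$M_NS, J$J0)
  expect_equal(m$M_SP, diag(c(0, p$D_S, p$D_N)))

  # closed forms of the on-site entries
  phi <- eq$phi; psi <- eq$psi; eta <- eq$eta
  h <- phi^2 / (p$K^2 + phi^2)
  expect_equal(m$B_NS[1, 1],
               p$alpha_R + p$beta_R * h + p$k_R * phi +
                 4 * p$mu_S * phi^2 * psi + 4 * p$mu_N * phi^2 * eta)
  expect_equal(m$B_NS[1, 2], 2 * p$mu_S * phi^2 * psi)
  expect_equal(m$B_NS[2, 2],
               p$alpha_S + p$beta_S * h + p$k_S * psi +
                 p$mu_S * phi^2 * psi)
  expect_identical(m$B_NS[2, 3], 0)
  expect_equal(m$B_SP, diag(c(0, -2 * p$D_S * psi, -2 * p$D_N * eta)))

  # B_NS symmetric positive semidefinite
  expect_equal(m$B_NS, t(m$B_NS))
  expect_true(all(eigen(m$B_NS, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))

  # full-lattice channel bookkeeping reproduces B_NS + B_SP * Lambda,
  # including the hop (diffusion) noise, on every mode of a 3-cell chain
  lat3 <- build_chain(3)
  for (md in 1:3) {
    Bm <- channel_B_mode(p, lat3, V = 1e6, eq, md)
    expect_equal(Bm, m$B_NS + m$B_SP * lat3$values[md], tolerance = 1e-4)
  }

  # decoupled birth-death limit: B_11 = 2 alpha_R
  pd <- decoupled_params()
  eqd <- find_equilibrium(pd)
  md <- lna_matrices(pd, eqd)
  expect_equal(md$B_NS[1, 1], 2 * pd$alpha_R, tolerance = 1e-10)
})

test_that("the decoupled spectrum is the Ornstein-Uhlenbeck Lorentzian", {
  pd <- decoupled_params()
  eqd <- find_equilibrium(pd)
  w <- seq(0, 3, by = 0.1)
  sp <- theoretical_spectrum(pd, eqd, Lambda = 0, omega_grid = w)
  lorentz <- 2 * pd$alpha_R / (w^2 + pd$k_R^2)
  expect_lt(max(abs(sp$P[, 1, 1] - lorentz)), 1e-10)

  # reality and symmetry of the spectrum
  sp2 <- theoretical_spectrum(pd, eqd, Lambda = -1,
                              omega_grid = c(-1.3, 1.3))
  expect_true(all(sp2$P >= 0))
  expect_equal(sp2$P[1, , ], sp2$P[2, , ], tolerance = 1e-12)
})

test_that("spectrum integral matches the Lyapunov equal-time variance", {
  pf <- fast_relax_params()
  eqf <- find_equilibrium(pf)
  lat3 <- build_chain(3)
  C <- mode_variances(pf, eqf, lattice = lat3)
  for (b in 1:3) {
    for (q in 1:3) {
      f <- function(w) vapply(w, function(wi)
        theoretical_spectrum(pf, eqf, Lambda = lat3$values[b],
                             omega_grid = wi)$P[1, 1, q], numeric(1))
      intval <- 2 * integrate(f, 0, Inf, rel.tol = 1e-10)$value / (2 * pi)
      expect_equal(intval, C[q, q, b], tolerance = 1e-6)
    }
  }
})

test_that("Gillespie mode variances agree with the linear-noise solution", {
  pf <- fast_relax_params()
  eqf <- find_equilibrium(pf)
  lat3 <- build_chain(3)
  C <- mode_variances(pf, eqf, lattice = lat3)
  V <- 2000
  n_run <- 16
  eqv <- c(eqf$phi, eqf$psi, eqf$eta)
  vars <- array(0, c(n_run, 3, 3))  # run x mode x species
  for (s in seq_len(n_run)) {
    tr <- gillespie_run(pf, lat3, V = V, tau_end = 220, seed = 500 + s,
                        sample_dt = 0.25)
    sel <- tr$times >= 20
    for (q in 1:3) {
      xi <- sqrt(V) * (tr$fields[sel, , q] / V - eqv[q])
      vars[s, , q] <- apply(mode_transform(xi, lat3), 2, var)
    }
  }
  for (q in 1:3) {
    m <- colMeans(vars[, , q])
    se <- apply(vars[, , q], 2, sd) / sqrt(n_run)
    z <- (m - C[q, q, ]) / se
    expect_lt(max(abs(z)), 3)
  }
})

test_that("an ensemble-averaged empirical spectrum matches the theory", {
  pf <- fast_relax_params()
  eqf <- find_equilibrium(pf)
  lat3 <- build_chain(3)
  runs <- lapply(1:40, function(s)
    gillespie_run(pf, lat3, V = 500, tau_end = 140, seed = 700 + s,
                  sample_dt = 0.25))
  emp <- empirical_spectrum(runs, eqf, lat3, window = c(20, 140))
  th <- theoretical_spectrum(pf, eqf, lattice = lat3,
                             omega_grid = emp$omega)
  sel <- emp$omega > 0 & emp$omega < 6
  for (md in 1:3) {
    ratio <- emp$P[sel, md, 1] / th$P[sel, md, 1]
    expect_gt(mean(ratio), 0.8)
    expect_lt(mean(ratio), 1.25)
    expect_gt(cor(emp$P[sel, md, 1], th$P[sel, md, 1]), 0.9)
  }
})

test_that("a constant-equilibrium trajectory has an identically zero
           spectrum", {
  lat <- build_chain(4)
  V <- 100
  fake_counts <- array(rep(c(30, 50, 20), each = 21 * 4), c(21, 4, 3))
  fake <- structure(list(times = 0:20, fields = fake_counts, omega = 4L,
                         V = V, mode = "ssa"),
                    class = "het_trajectory")
  eq0 <- list(phi = 30 / V, psi = 50 / V, eta = 20 / V)
  emp <- empirical_spectrum(fake, eq0, lat, window = c(0, 20))
  expect_equal(max(abs(emp$P)), 0)

  expect_error(empirical_spectrum(fake, eq0, lat, window = c(100, 200)),
               "outside")
})

test_that("the noise-driven spectrum peaks at the wavelength the unstable
           set selects", {
  lat <- build_chain(40)
  pd <- preset_params("ratio3_stable")$params
  eqd <- find_equilibrium(pd)
  th <- theoretical_spectrum(pd, eqd, lattice = lat, omega_grid = 0)
  m_th <- spatial_peak_mode(th, lat)
  # interior maximum, not at the uniform-mode end
  expect_gt(m_th, 2)
  expect_lt(m_th, 40)

  ps <- preset_params("ratio3_turing")$params
  dsp <- discrete_dispersion(ps, lattice = lat)
  expect_lte(abs(m_th - attr(dsp, "argmax")$mode), 1)
})

test_that("the stochastic instability region contains the deterministic one
           and needs autoactivation", {
  lat <- build_chain(40)
  p <- preset_params("equalD_map")$params   # equal diffusivities
  sc <- stochastic_region_scan(p, beta_S = c(2.8, 3.0, 3.2),
                               beta_R = c(0, 5.8, 6.1), lat)
  expect_true(all(!sc$det_turing | sc$stoch_peak))
  expect_true(all(!sc$stoch_peak[sc$beta_R == 0]))
  expect_true(all(is.finite(sc$peak_height[sc$stable])))
})
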