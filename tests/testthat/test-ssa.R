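test_that("reaction channels respect counting and topology", {
  p <- preset_params("ratio3_turing")$params
  lat <- build_chain(4)
  ch <- build_channels(p, lat, V = 100)

  # trimolecular propensities vanish when fewer than two activator molecules
  counts <- matrix(5, 4, 3)
  counts[, 1] <- c(0, 1, 2, 5)
  tri <- Filter(function(x) x$label %in% c("tri_S", "tri_N"), ch)
  for (x in tri) {
    a <- x$propensity(counts)
    if (counts[x$cell, 1] < 2) expect_identical(a, 0) else expect_gt(a, 0)
  }

  # edge cells have one outgoing hop per diffusing species, interior two
  hops <- Filter(function(x) x$label == "hop_S", ch)
  n_by_cell <- table(vapply(hops, function(x) x$cell, numeric(1)))
  expect_equal(as.numeric(n_by_cell), c(1, 2, 2, 1))

  # propensities are non-negative on valid states
  set.seed(1)
  rnd <- matrix(rpois(12, 50), 4, 3)
  expect_true(all(vapply(ch, function(x) x$propensity(rnd), numeric(1)) >= 0))
})

test_that("channel drift reproduces the deterministic rate equations", {
  p <- preset_params("ratio3_turing")$params
  lat <- build_chain(4)
  V <- 1e6
  eq <- find_equilibrium(p)
  set.seed(7)
  conc <- matrix(c(eq$phi, eq$psi, eq$eta), 4, 3, byrow = TRUE) *
    matrix(runif(12, 0.5, 1.5), 4, 3)
  counts <- round(conc * V)
  ch <- build_channels(p, lat, V)
  drift <- channel_drift(ch, counts, V)
  rhs <- rhs_deterministic(counts / V, p, lat)
  expect_lt(max(abs(drift - rhs)), 1e-4)
})

test_that("simulation is frozen without rates and reproducible with a seed", {
  lat <- build_chain(3)
  init <- matrix(c(4, 5, 6), 3, 3, byrow = FALSE)

  tr <- gillespie_run(chem_off_params(), lat, V = 10, init = init,
                      tau_end = 20, seed = 1)
  expect_true(all(apply(tr$fields, c(2, 3), function(x) all(x == x[1]))))

  p <- preset_params("ratio3_stable")$params
  t1 <- gillespie_run(p, lat, V = 50, tau_end = 10, seed = 9)
  t2 <- gillespie_run(p, lat, V = 50, tau_end = 10, seed = 9)
  t3 <- gillespie_run(p, lat, V = 50, tau_end = 10, seed = 10)
  expect_identical(t1$fields, t2$fields)
  expect_false(identical(t1$fields, t3$fields))

  expect_true(all(t1$fields >= 0))
  expect_true(all(t1$fields == round(t1$fields)))
})

test_that("single-cell birth-death matches the Poisson stationary law", {
  # only production and decay of the activator: stationary count is
  # Poisson with mean alpha_R V / k_R
  p <- model_params(alpha_R = 1, alpha_S = 0, alpha_N = 0, beta_R = 0,
                    beta_S = 0, k_R = 1, k_S = 1, k_N = 1,
                    mu_S = 0, mu_N = 0, D_S = 0, D_N = 0)
  lat1 <- build_chain(1)
  V <- 50
  finals <- vapply(1:200, function(s) {
    tr <- gillespie_run(p, lat1, V = V,
                        init = matrix(c(V, 0, 0), 1, 3),
                        tau_end = 10, seed = 1000 + s, sample_dt = 10)
    tr$fields[2, 1, 1]
  }, numeric(1))
  m <- mean(finals); v <- var(finals)
  expect_lt(abs(m - V), 3 * sd(finals) / sqrt(200))
  # variance equals the mean (Poisson), within 3 SE of the variance estimate
  se_var <- v * sqrt(2 / 199)
  expect_lt(abs(v - V), 3 * se_var)
})

test_that("ensemble means converge to the deterministic solution as V grows", {
  p <- preset_params("ratio3_stable")$params
  lat <- build_chain(3)
  eq <- find_equilibrium(p)

  det <- integrate_deterministic(p, lat, matrix(0, 3, 3), tau_end = 20,
                                 n_out = 21)
  dev_at <- function(V, n_runs = 100) {
    acc <- 0
    for (s in seq_len(n_runs)) {
      tr <- gillespie_run(p, lat, V = V, init = matrix(0L, 3, 3),
                          tau_end = 20, seed = 2000 + s, sample_dt = 1)
      acc <- acc + tr$fields / V
    }
    max(abs(acc / n_runs - det$fields))
  }
  d200 <- dev_at(200)
  d2000 <- dev_at(2000)
  expect_lt(d2000, d200)
  expect_lt(d2000, 0.05)
})

test_that("fluctuation amplitude scales as the inverse square root of V", {
  p <- preset_params("ratio3_stable")$params
  lat1 <- build_chain(1)
  Vs <- c(100, 400, 1600, 6400)
  slopes <- vapply(c(42, 43, 44), function(sd0) {
    sds <- vapply(Vs, function(V) {
      tr <- gillespie_run(p, lat1, V = V, tau_end = 400, seed = sd0,
                          sample_dt = 0.5)
      sel <- tr$times >= 100
      sd(tr$fields[sel, 1, 1] / V)
    }, numeric(1))
    unname(coef(lm(log(sds) ~ log(Vs)))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.5), 0.1)
})

test_that("stochastic runs outside the deterministic region still select the
           unstable wavelength", {
  om <- 30
  lat <- build_chain(om)
  pd <- preset_params("ratio3_stable")$params
  eqd <- find_equilibrium(pd)
  runs <- lapply(1:5, function(s)
    gillespie_run(pd, lat, V = 500, tau_end = 300, seed = 4 + s))
  emp <- empirical_spectrum(runs, eqd, lat, window = c(100, 300),
                            omega_grid = 0)
  th <- theoretical_spectrum(pd, eqd, lattice = lat, omega_grid = 0)
  m_emp <- spatial_peak_mode(emp, lat)
  m_th <- spatial_peak_mode(th, lat)
  expect_lte(abs(m_emp - m_th), 1)

  # ... and that wavelength is the one the star set destabilizes
  ps <- preset_params("ratio3_turing")$params
  dsp <- discrete_dispersion(ps, lattice = lat)
  expect_lte(abs(m_th - attr(dsp, "argmax")$mode), 1)
})
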