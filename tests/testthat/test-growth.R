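test_that("zero duplication rate reproduces the fixed-domain run exactly", {
  p <- preset_params("ratio3_stable")$params
  lat <- build_chain(5)
  eq <- find_equilibrium(p)
  init <- matrix(round(100 * c(eq$phi, eq$psi, eq$eta)), 5, 3, byrow = TRUE)
  gc0 <- growth_config(rho = 0, omega0 = 5, max_omega = 5)
  tr_fix <- gillespie_run(p, lat, V = 100, init = init, tau_end = 20,
                          seed = 3)
  tr_grow <- ssa_growing_run(p, V = 100, growth = gc0, init = init,
                             tau_end = 20, seed = 3)
  expect_identical(tr_fix$fields, tr_grow$fields)
  expect_length(tr_grow$dup_times, 0)
})

test_that("pure growth is a Yule process with the predicted moments", {
  p0 <- chem_off_params()
  V <- 100
  gc_ <- growth_config(rho = 1e-4, omega0 = 2, max_omega = 500)
  oms <- vapply(1:300, function(s) {
    tr <- ssa_growing_run(p0, V = V, growth = gc_,
                          init = matrix(5, 2, 3), tau_end = 100,
                          seed = s, sample_dt = 100)
    tr$omega_t[length(tr$omega_t)]
  }, numeric(1))
  g <- exp(1e-4 * V * 100)          # per-lineage expected size e^{rho V tau}
  m_th <- 2 * g
  v_th <- 2 * g * (g - 1)
  expect_lt(abs(mean(oms) - m_th), 3 * sd(oms) / sqrt(300))
  # bootstrap standard error for the sample variance
  set.seed(99)
  bv <- vapply(1:500, function(b) var(sample(oms, replace = TRUE)),
               numeric(1))
  expect_lt(abs(var(oms) - v_th), 4 * sd(bv))
})

test_that("duplication conserves molecules under both splitting rules", {
  p0 <- chem_off_params()
  for (rule in c("equal", "binomial")) {
    gc_ <- growth_config(rho = 5e-4, omega0 = 4, max_omega = 50,
                         split = rule)
    tr <- ssa_growing_run(p0, V = 100, growth = gc_,
                          init = matrix(7, 4, 3), tau_end = 60,
                          seed = 11, sample_dt = 10)
    expect_gt(length(tr$dup_times), 0)
    totals <- apply(tr$fields, c(1, 3), sum)
    expect_true(all(totals == 28))
  }

  # equal splitting: cap the filament at one duplication and check the two
  # daughters share the mother's odd counts with the extra molecule left
  gc_eq <- growth_config(rho = 2e-3, omega0 = 2, max_omega = 3,
                         split = "equal")
  tr <- ssa_growing_run(p0, V = 100, growth = gc_eq,
                        init = matrix(c(7, 9, 11), 2, 3, byrow = TRUE),
                        tau_end = 200, seed = 5, sample_dt = 200)
  expect_true(tr$truncated)
  fin <- tr$fields[2, 1:3, ]
  mother_cell <- tr$dup_cells[1]
  daughters <- fin[c(mother_cell, mother_cell + 1), ]
  expect_equal(colSums(daughters), c(7, 9, 11), ignore_attr = TRUE)
  expect_true(all(daughters[1, ] - daughters[2, ] == c(1, 1, 1)))
})

test_that("equal and binomial splitting give indistinguishable spacings", {
  p <- preset_params("ratio3_turing")$params
  V <- 100; om0 <- 20; tau <- 250
  rho <- log(1.5) / (V * tau)
  spacing_of <- function(rule, seeds) {
    unlist(lapply(seeds, function(s) {
      gc_ <- growth_config(rho = rho, omega0 = om0, split = rule,
                           max_omega = 60)
      tr <- ssa_growing_run(p, V = V, growth = gc_, tau_end = tau,
                            seed = s, sample_dt = 5)
      omf <- tr$omega_t[length(tr$times)]
      sel <- tr$times >= tau - 50 & tr$omega_t == omf
      f <- colMeans(tr$fields[sel, seq_len(omf), 1, drop = FALSE])
      pattern_metrics(f, prominence = 0.25 * (max(f) - min(f)))$spacings
    }))
  }
  s_eq <- spacing_of("equal", 1:2)
  s_bi <- spacing_of("binomial", 11:12)
  expect_gt(length(s_eq), 2)
  expect_gt(length(s_bi), 2)
  p_val <- suppressWarnings(wilcox.test(s_eq, s_bi))$p.value
  expect_gt(p_val, 0.01)
})

test_that("the continuum description dilutes and keeps homogeneity exact", {
  p <- preset_params("growth_continuum")$params
  eq <- find_equilibrium(p)

  # no growth: a homogeneous profile stays homogeneous and stationary
  init <- matrix(c(eq$phi, eq$psi, eq$eta), 21, 3, byrow = TRUE)
  tr0 <- integrate_growing_continuum(p, rho_tilde = 0, omega0 = 40,
                                     init = init, tau_end = 50, n_out = 11)
  expect_lt(max(abs(sweep(tr0$fields, 3, c(eq$phi, eq$psi, eq$eta)))),
            1e-6)

  # chemistry off, growth on: pure exponential dilution
  p0 <- chem_off_params()
  c0 <- c(2, 3, 4)
  initc <- matrix(c0, 21, 3, byrow = TRUE)
  trd <- integrate_growing_continuum(p0, rho_tilde = 1e-2, omega0 = 40,
                                     init = initc, tau_end = 100,
                                     n_out = 11)
  expected <- outer(exp(-1e-2 * trd$times), c0)
  for (q in 1:3)
    expect_equal(trd$fields[, 11, q], expected[, q], tolerance = 1e-6)
  expect_true(all(trd$fields >= 0))
})

test_that("growth preserves the pattern spacing through one domain
           doubling", {
  p <- preset_params("growth_continuum")$params
  eq <- find_equilibrium(p)
  lat <- build_chain(40)

  # fixed-domain reference spacing
  init <- gen_perturbed_field(eq, 1e-3, 40, seed = 2)
  trf <- integrate_deterministic(p, lat, init, tau_end = 6000, n_out = 2)
  sp_fixed <- mean(pattern_metrics(trf$fields[2, , 1])$spacings)

  # grow 40 -> 80 cells (one full insertion cycle) at the nominal rate
  M <- 81
  initg <- gen_perturbed_field(eq, 1e-3, M, seed = 3)
  tau_end <- log(2) / 5e-5
  trg <- integrate_growing_continuum(p, 5e-5, 40, initg,
                                     tau_end = tau_end, n_out = 2)
  fin <- trg$fields[2, , 1]
  x <- seq(0, 1, length.out = M)
  pk <- pattern_metrics(fin)$peaks
  sp_grow <- mean(diff(x[pk])) * trg$omega_t[2]
  expect_lt(abs(sp_grow - sp_fixed), 2)
})

test_that("the unstable band widens linearly with filament size", {
  p <- preset_params("ratio3_turing")$params
  band <- unstable_band(p, omegas = seq(10, 80, by = 5))
  expect_true(all(diff(band$n_unstable) >= 0))

  sel <- band$omega >= 20
  fit <- lm(leading_mode ~ omega, data = band[sel, ])
  expect_gt(summary(fit)$r.squared, 0.99)

  # a two-cell filament has at most one non-uniform mode
  b2 <- unstable_band(p, omegas = 2)
  expect_lte(b2$n_unstable, 1)

  # a stable parameter set yields empty bands, not an error
  bd <- unstable_band(preset_params("ratio3_stable")$params,
                      omegas = c(20, 40))
  expect_true(all(bd$n_unstable == 0))
  expect_true(all(is.na(bd$leading_mode)))
})
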