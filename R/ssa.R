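#' Reaction channels of the chemical master equation
#'
#' Explicit list of every jump channel of the stochastic model on a fixed
#' chain, with its per-cell stoichiometry and propensity as a function of
#' the integer count state.  The propensity convention is the unique one
#' whose infinite-volume limit reproduces the mean-field rate equations
#' term by term: production channels scale as `rate * V`, the Hill-driven
#' channels as `V * h(r/V)`, linear decay as `rate * count`, trimolecular
#' capture as `mu * r (r - 1) x / V^2` (exact mass-action counting of HetR
#' pairs), and hops as `D * count` towards each adjacent cell.
#'
#' This list is the reference definition used to validate the compiled
#' simulator; [gillespie_run()] implements the same channels in C++.
#'
#' @inheritParams rhs_deterministic
#' @param V Cell volume (controls demographic-noise strength, > 0).
#' @return List of channels; each is a list with `label`, `cell`, optional
#'   `partner`, `change` (3-vector per affected cell, species order
#'   HetR/PatS/HetN) and `propensity(counts)`, where `counts` is the
#'   `omega x 3` integer state.
#' @export
build_channels <- function(params, lattice, V) {
  p <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  if (!is.numeric(V) || V <= 0) stop("'V' must be positive", call. = FALSE)
  omega <- lattice$omega
  K <- p$K
  ch <- list()
  add <- function(label, cell, change, propensity, partner = NA_integer_,
                  partner_change = NULL) {
    ch[[length(ch) + 1L]] <<- list(label = label, cell = cell,
                                   partner = partner, change = change,
                                   partner_change = partner_change,
                                   propensity = propensity)
  }
  for (i in seq_len(omega)) {
    local({
      i <- i
      add("prod_R", i, c(1, 0, 0), function(x) p$alpha_R * V)
      add("prod_S", i, c(0, 1, 0), function(x) p$alpha_S * V)
      add("prod_N", i, c(0, 0, 1), function(x) p$alpha_N * V)
      add("auto_R", i, c(1, 0, 0),
          function(x) p$beta_R * V * hill(x[i, 1L] / V, K))
      add("act_S", i, c(0, 1, 0),
          function(x) p$beta_S * V * hill(x[i, 1L] / V, K))
      add("dec_R", i, c(-1, 0, 0), function(x) p$k_R * x[i, 1L])
      add("dec_S", i, c(0, -1, 0), function(x) p$k_S * x[i, 2L])
      add("dec_N", i, c(0, 0, -1), function(x) p$k_N * x[i, 3L])
      add("tri_S", i, c(-2, -1, 0),
          function(x) p$mu_S * x[i, 1L] * (x[i, 1L] - 1) * x[i, 2L] / V^2)
      add("tri_N", i, c(-2, 0, -1),
          function(x) p$mu_N * x[i, 1L] * (x[i, 1L] - 1) * x[i, 3L] / V^2)
      for (j in which(lattice$W[i, ] > 0)) {
        local({
          j <- j
          add("hop_S", i, c(0, -1, 0), function(x) p$D_S * x[i, 2L],
              partner = j, partner_change = c(0, 1, 0))
          add("hop_N", i, c(0, 0, -1), function(x) p$D_N * x[i, 3L],
              partner = j, partner_change = c(0, 0, 1))
        })
      }
    })
  }
  ch
}

#' Mean drift implied by the reaction channels
#'
#' Sums `stoichiometry * propensity / V` over all channels, i.e. the
#' expected instantaneous rate of change of the concentration field.  In
#' the infinite-volume limit this equals [rhs_deterministic()]; the
#' identity (at finite V, up to the `r(r-1)` vs `r^2` counting correction)
#' is the contract fixing the propensity convention.
#'
#' @param channels Output of [build_channels()].
#' @param counts `omega x 3` count state.
#' @param V Cell volume used to build the channels.
#' @return `omega x 3` matrix of concentration drifts.
#' @export
channel_drift <- function(channels, counts, V) {
  counts <- as.matrix(counts)
  drift <- matrix(0, nrow(counts), 3L)
  for (ch in channels) {
    a <- ch$propensity(counts)
    drift[ch$cell, ] <- drift[ch$cell, ] + a * ch$change / V
    if (!is.na(ch$partner))
      drift[ch$partner, ] <- drift[ch$partner, ] + a * ch$partner_change / V
  }
  drift
}

#' Exact Gillespie simulation on a fixed chain
#'
#' Direct-method stochastic simulation of the full reaction network (see
#' [build_channels()] for the channel definitions).  The event-driven state
#' is held piecewise constant and read out on a fixed time grid.  Runs are
#' reproducible: the R random number generator is seeded with `seed`.
#'
#' @inheritParams build_channels
#' @param init `omega x 3` matrix of non-negative integer initial counts;
#'   defaults to the homogeneous equilibrium scaled by `V` and rounded.
#' @param tau_end Final time.
#' @param seed Integer seed.
#' @param sample_dt Spacing of the output time grid.
#' @return A `het_trajectory` with integer `fields` (counts), `V`, `seed`,
#'   and `mode = "ssa"`.
#' @examples
#' lat <- build_chain(5)
#' tr <- gillespie_run(model_params(), lat, V = 50, tau_end = 5, seed = 1)
#' dim(tr$fields)
#' @export
gillespie_run <- function(params, lattice, V, init = NULL, tau_end,
                          seed = 1L, sample_dt = 1) {
  p <- as_het_params(params)
  stopifnot(inherits(lattice, "chain_lattice"))
  if (is.null(init)) {
    eq <- find_equilibrium(p)
    init <- matrix(round(V * c(eq$phi, eq$psi, eq$eta)),
                   lattice$omega, 3L, byrow = TRUE)
  }
  init <- as.matrix(init)
  if (nrow(init) != lattice$omega || ncol(init) != 3L)
    stop("'init' must be an omega x 3 matrix", call. = FALSE)
  if (any(init < 0) || any(init != round(init)))
    stop("'init' must contain non-negative integers", call. = FALSE)

  times <- seq(0, tau_end, by = sample_dt)
  set.seed(seed)
  res <- ssa_chain_cpp(par_vector(p), V, init, tau_end, times,
                       rho = 0, split_rule = 0L,
                       max_omega = lattice$omega,
                       periodic = isTRUE(lattice$periodic))
  fields <- res$counts
  dimnames(fields) <- list(NULL, NULL, c("HetR", "PatS", "HetN"))
  structure(list(times = times, fields = fields, omega = lattice$omega,
                 params = p, V = V, seed = seed, mode = "ssa",
                 n_events = res$n_events),
            class = "het_trajectory")
}
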