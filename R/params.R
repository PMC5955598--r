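#' Kinetic and transport parameters of the three-morphogen model
#'
#' Bundles every rate constant of the heterocyst patterning model in one
#' validated record: constitutive production of the activator HetR and the
#' two inhibitors PatS and HetN, Hill-type HetR autoactivation and
#' HetR-driven PatS activation, linear degradation, trimolecular
#' complex-mediated degradation (two HetR molecules captured together with
#' one inhibitor molecule), and nearest-neighbour hop rates for the two
#' inhibitors.  HetR does not diffuse: the activator is immobile by
#' construction and therefore carries no transport coefficient.
#'
#' All quantities are dimensionless (concentrations relative to the Hill
#' scale `K`, time in units of the inverse degradation rates).
#'
#' @param alpha_R,alpha_S,alpha_N Constitutive production rates
#'   (concentration/time) of HetR, PatS, HetN.
#' @param beta_R Strength of HetR positive autoregulation.
#' @param beta_S Strength of the HetR -> PatS activation.
#' @param K Hill dissociation scale (concentration, > 0); the active HetR
#'   form is dimeric, so the Hill response is `x^2 / (K^2 + x^2)`.
#' @param k_R,k_S,k_N Linear degradation rates (1/time).
#' @param mu_S,mu_N Trimolecular complex-degradation rates
#'   (1/(concentration^2 * time)): `2R + S -> 0` and `2R + N -> 0`.
#' @param D_S,D_N Inhibitor hop rates to each adjacent cell (1/time).
#'
#' @return An object of class `het_params` (a named list).
#' @examples
#' p <- model_params(beta_R = 6.5, beta_S = 3.7)
#' p$D_S / p$D_N
#' @export
model_params <- function(alpha_R = 0.2, alpha_S = 0.1, alpha_N = 0.3,
                         beta_R = 6.5, beta_S = 3.7, K = 2,
                         k_R = 0.2, k_S = 0.1, k_N = 0.7,
                         mu_S = 0.1, mu_N = 3,
                         D_S = 3, D_N = 1) {
  p <- list(alpha_R = alpha_R, alpha_S = alpha_S, alpha_N = alpha_N,
            beta_R = beta_R, beta_S = beta_S, K = K,
            k_R = k_R, k_S = k_S, k_N = k_N,
            mu_S = mu_S, mu_N = mu_N, D_S = D_S, D_N = D_N)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (K <= 0) stop("'K' must be strictly positive", call. = FALSE)
  structure(p, class = "het_params")
}

#' @export
print.het_params <- function(x, ...) {
  cat("Three-morphogen model parameters (HetR / PatS / HetN)\n")
  cat(sprintf("  production  alpha: %g / %g / %g\n",
              x$alpha_R, x$alpha_S, x$alpha_N))
  cat(sprintf("  activation  beta_R = %g, beta_S = %g, Hill K = %g\n",
              x$beta_R, x$beta_S, x$K))
  cat(sprintf("  decay       k: %g / %g / %g\n", x$k_R, x$k_S, x$k_N))
  cat(sprintf("  trimolecular mu_S = %g, mu_N = %g\n", x$mu_S, x$mu_N))
  cat(sprintf("  hop rates   D_S = %g, D_N = %g (HetR immobile)\n",
              x$D_S, x$D_N))
  invisible(x)
}

as_het_params <- function(p) {
  if (inherits(p, "het_params")) return(p)
  if (is.list(p)) return(do.call(model_params, p))
  stop("expected 'het_params' or a named list of rates", call. = FALSE)
}

# Parameter vector in the fixed order expected by the compiled simulator.
par_vector <- function(p) {
  as.numeric(unlist(p[c("alpha_R", "alpha_S", "alpha_N", "beta_R", "beta_S",
                        "K", "k_R", "k_S", "k_N", "mu_S", "mu_N",
                        "D_S", "D_N")]))
}

# Hill response of the dimeric activator.
hill <- function(x, K) x^2 / (K^2 + x^2)

# d/dx of the Hill response.
hill_prime <- function(x, K) 2 * x * K^2 / (K^2 + x^2)^2
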