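#' Build the one-dimensional cell-chain lattice
#'
#' Constructs the spatial support of the model: a path of `omega` cells with
#' nearest-neighbour coupling, its adjacency matrix `W`, per-cell
#' connectivity `k` (2 in the interior, 1 at the two ends of an open chain),
#' the discrete Laplacian `Delta = W - diag(k)`, and the Laplacian
#' eigensystem used both by the dispersion relation and by the spatial mode
#' transform.
#'
#' Eigenpairs are sorted by descending eigenvalue, so mode 1 is the uniform
#' (kernel) mode with `Lambda = 0`.  Eigenvector signs are fixed so that the
#' first component of magnitude above tolerance is positive; eigenvectors
#' within a degenerate eigenspace (possible only for the periodic variant)
#' are re-orthonormalised deterministically by Gram-Schmidt in that order.
#'
#' @param omega Number of cells (integer, >= 1).
#' @param periodic If `TRUE`, close the chain into a ring.  The open
#'   (zero-flux) chain is the model's boundary condition; the ring is
#'   exposed for testing only.
#' @return An object of class `chain_lattice` with elements `omega`, `W`,
#'   `k`, `laplacian`, `values` (eigenvalues, descending) and `vectors`
#'   (orthonormal eigenvectors as columns).
#' @examples
#' lat <- build_chain(5)
#' rowSums(lat$laplacian)   # exactly zero
#' lat$values[1]            # uniform mode, Lambda = 0
#' @export
build_chain <- function(omega, periodic = FALSE) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega < 1 || omega != round(omega))
    stop("'omega' must be a positive integer", call. = FALSE)
  omega <- as.integer(omega)

  W <- matrix(0, omega, omega)
  if (omega > 1L) {
    idx <- seq_len(omega - 1L)
    W[cbind(idx, idx + 1L)] <- 1
    W[cbind(idx + 1L, idx)] <- 1
    if (periodic && omega > 2L) {
      W[1L, omega] <- W[omega, 1L] <- 1
    }
  }
  k <- rowSums(W)
  Delta <- W - diag(k, omega)

  es <- eigen(Delta, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]

  # Deterministic orthonormalisation inside (numerically) degenerate
  # eigenspaces, then a sign convention: first non-negligible entry > 0.
  vecs <- orthonormalize_degenerate(vals, vecs)
  for (a in seq_len(omega)) {
    j <- which(abs(vecs[, a]) > 1e-8)[1L]
    if (!is.na(j) && vecs[j, a] < 0) vecs[, a] <- -vecs[, a]
  }

  structure(list(omega = omega, W = W, k = k, laplacian = Delta,
                 values = vals, vectors = vecs, periodic = periodic),
            class = "chain_lattice")
}

orthonormalize_degenerate <- function(vals, vecs, tol = 1e-9) {
  n <- length(vals)
  grp <- cumsum(c(TRUE, diff(vals) < -tol))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) > 1L) {
      # QR gives a deterministic orthonormal basis of the span.
      q <- qr.Q(qr(vecs[, cols, drop = FALSE]))
      vecs[, cols] <- q
    }
  }
  vecs
}

#' @export
print.chain_lattice <- function(x, ...) {
  cat(sprintf("Cell chain: omega = %d (%s)\n", x$omega,
              if (isTRUE(x$periodic)) "periodic ring" else "open, zero-flux"))
  cat(sprintf("  Laplacian eigenvalues in [%.4f, %.4f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Project a spatial field onto the Laplacian eigenmodes
#'
#' The spatial part of the transform used to analyse fluctuations on the
#' discrete chain: `a_alpha(tau) = sum_j f_j(tau) v_j^(alpha)`.  Because the
#' eigenvectors are orthonormal this is an isometry (Parseval) and
#' [mode_reconstruct()] inverts it exactly.
#'
#' @param field Numeric vector of length `omega`, or a matrix with one time
#'   point per row and `omega` columns.
#' @param lattice A [build_chain()] lattice.
#' @return Projection coefficients with the same shape as `field` (columns
#'   indexed by mode).
#' @export
mode_transform <- function(field, lattice) {
  stopifnot(inherits(lattice, "chain_lattice"))
  if (is.null(dim(field))) {
    if (length(field) != lattice$omega)
      stop("field length ", length(field), " does not match omega = ",
           lattice$omega, call. = FALSE)
    return(drop(field %*% lattice$vectors))
  }
  if (ncol(field) != lattice$omega)
    stop("field has ", ncol(field), " columns; expected omega = ",
         lattice$omega, call. = FALSE)
  field %*% lattice$vectors
}

#' Reconstruct a spatial field from its mode coefficients
#'
#' Inverse of [mode_transform()].
#'
#' @param coefs Coefficient vector (length `omega`) or matrix (modes in
#'   columns).
#' @inheritParams mode_transform
#' @return The spatial field, same shape as `coefs`.
#' @export
mode_reconstruct <- function(coefs, lattice) {
  stopifnot(inherits(lattice, "chain_lattice"))
  if (is.null(dim(coefs))) {
    if (length(coefs) != lattice$omega)
      stop("coefficient length does not match omega", call. = FALSE)
    return(drop(coefs %*% t(lattice$vectors)))
  }
  if (ncol(coefs) != lattice$omega)
    stop("coefficient columns do not match omega", call. = FALSE)
  coefs %*% t(lattice$vectors)
}

#' Write / read a chain lattice as a plain-text edge list
#'
#' The edge list (`from`, `to`, one row per undirected edge) is enough to
#' rebuild the lattice; `read_chain_edges()` validates that the edges form a
#' path (or ring) and returns the corresponding [build_chain()] object.
#'
#' @param lattice A `chain_lattice`.
#' @param path File path for the tab-separated edge list.
#' @return `write_chain_edges()` returns `path` invisibly;
#'   `read_chain_edges()` returns a `chain_lattice`.
#' @export
write_chain_edges <- function(lattice, path) {
  stopifnot(inherits(lattice, "chain_lattice"))
  idx <- which(upper.tri(lattice$W) & lattice$W > 0, arr.ind = TRUE)
  df <- data.frame(from = idx[, 1L], to = idx[, 2L])
  df <- df[order(df$from, df$to), , drop = FALSE]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chain_edges
#' @export
read_chain_edges <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  omega <- max(df$from, df$to)
  n_edge <- nrow(df)
  periodic <- n_edge == omega && omega > 2
  if (!periodic && n_edge != omega - 1L)
    stop("edge list is not a path or ring over ", omega, " cells",
         call. = FALSE)
  lat <- build_chain(omega, periodic = periodic)
  have <- lat$W[as.matrix(df[, c("from", "to")])]
  if (any(have != 1))
    stop("edge list does not describe a nearest-neighbour chain",
         call. = FALSE)
  lat
}

#' Export the Laplacian eigensystem as a numeric table
#'
#' @inheritParams mode_transform
#' @return A data frame with columns `mode`, `Lambda`, and `v1 ... v<omega>`
#'   (eigenvector components).
#' @export
eigensystem_table <- function(lattice) {
  stopifnot(inherits(lattice, "chain_lattice"))
  comp <- t(lattice$vectors)
  colnames(comp) <- paste0("v", seq_len(lattice$omega))
  data.frame(mode = seq_len(lattice$omega), Lambda = lattice$values, comp)
}
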