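#' Fluorescence-to-copy-number calibration from mother/daughter partitions
#'
#' When a mother cell's fluorescent molecules are partitioned binomially
#' between its two daughters at division, the variance of the daughter
#' fluorescence difference is proportional to the mother fluorescence:
#' `E[(f_d1 - f_d2)^2] = nu * f_mother`, where `nu` is the fluorescence
#' emitted per molecule.  The estimator is therefore
#' \deqn{\hat\nu = \langle (f_{2i} - f_{2i+1})^2 / f_i \rangle}
#' over mother/daughter triplets, after subtracting a constant background
#' from every fluorescence value.  Copy numbers follow as
#' `n_i = f_i / nu`.  The standard error is obtained by bootstrap over
#' triplets.
#'
#' @param triplets Data frame with columns `f_mother`, `f_d1`, `f_d2`
#'   (fluorescence of a mother cell and its two daughters).
#' @param background Constant background fluorescence subtracted from every
#'   value before estimation.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `nu` (estimate), `se` (bootstrap standard error),
#'   `n_copies` (estimated mother copy numbers), `n_triplets` used, and
#'   `n_clipped` (values clipped to zero after background subtraction,
#'   reported with a warning).
#' @export
estimate_nu <- function(triplets, background = 0, n_boot = 200L,
                        seed = 1L) {
  req <- c("f_mother", "f_d1", "f_d2")
  if (!all(req %in% names(triplets)))
    stop("'triplets' needs columns f_mother, f_d1, f_d2", call. = FALSE)
  fm <- triplets$f_mother - background
  f1 <- triplets$f_d1 - background
  f2 <- triplets$f_d2 - background
  n_clip <- sum(fm < 0) + sum(f1 < 0) + sum(f2 < 0)
  if (n_clip > 0) {
    warning(n_clip, " fluorescence value(s) negative after background ",
            "subtraction; clipped to zero")
    fm <- pmax(fm, 0); f1 <- pmax(f1, 0); f2 <- pmax(f2, 0)
  }
  ok <- fm > 0
  if (sum(ok) < 2L)
    stop("estimator undefined: fewer than 2 triplets with positive ",
         "mother fluorescence after background subtraction", call. = FALSE)
  ratio <- (f1[ok] - f2[ok])^2 / fm[ok]
  nu <- mean(ratio)

  set.seed(seed)
  nb <- length(ratio)
  boots <- vapply(seq_len(n_boot), function(b)
    mean(ratio[sample.int(nb, nb, replace = TRUE)]), numeric(1))

  list(nu = nu, se = sd(boots),
       n_copies = fm / nu, n_triplets = sum(ok), n_clipped = n_clip)
}

#' Align fluorescence traces at the autofluorescence half-decay time
#'
#' Developing cells lose photosynthetic autofluorescence as phycobilisomes
#' are degraded; the time at which a cell's autofluorescence has decayed
#' halfway between its pre-decay plateau and post-decay floor provides a
#' per-cell temporal reference.  Each trace (autofluorescence plus an
#' arbitrary reporter channel) is shifted so that this half-decay crossing
#' defines time zero, which collapses traces whose decays started at
#' different absolute times.
#'
#' Plateau and floor are estimated as the means of the first and last
#' `plateau_frac` of samples of the (lightly smoothed) autofluorescence;
#' the crossing time is located by linear interpolation between samples.
#' Traces with no crossing are excluded, with the reason recorded.
#'
#' @param traces List of data frames, each with columns `time`, `af`
#'   (autofluorescence) and optionally further reporter columns; all
#'   columns other than `time` are shifted together.
#' @param smooth_window Rolling-mean window (samples) applied to `af`
#'   before locating the crossing.
#' @param plateau_frac Fraction of samples averaged at each end for the
#'   plateau / floor levels.
#' @return List with `aligned` (the shifted traces, each carrying a
#'   `shift` attribute) and `excluded` (named character vector of
#'   exclusion reasons).
#' @export
align_traces_by_half_decay <- function(traces, smooth_window = 3L,
                                       plateau_frac = 0.1) {
  aligned <- list()
  excluded <- character(0)
  for (nm in seq_along(traces)) {
    tr <- traces[[nm]]
    lab <- if (!is.null(names(traces)) && nzchar(names(traces)[nm]))
      names(traces)[nm] else as.character(nm)
    t0 <- half_decay_time(tr$time, tr$af, smooth_window, plateau_frac)
    if (is.na(t0)) {
      excluded[lab] <- "no crossing"
      next
    }
    out <- tr
    out$time <- tr$time - t0
    attr(out, "shift") <- -t0
    aligned[[lab]] <- out
  }
  list(aligned = aligned, excluded = excluded)
}

# Half-decay crossing time of a decaying signal; NA when no crossing.
half_decay_time <- function(time, af, smooth_window = 3L,
                            plateau_frac = 0.1) {
  n <- length(af)
  if (n < 4L) return(NA_real_)
  if (smooth_window > 1L) {
    k <- min(smooth_window, n)
    sm <- as.numeric(stats::filter(af, rep(1 / k, k), sides = 2))
    # rolling mean leaves NAs at the ends; keep the raw values there
    sm[is.na(sm)] <- af[is.na(sm)]
    af <- sm
  }
  m <- max(1L, round(plateau_frac * n))
  plateau <- mean(af[seq_len(m)])
  floorv <- mean(af[(n - m + 1L):n])
  if (plateau - floorv <= 0) return(NA_real_)
  mid <- (plateau + floorv) / 2
  below <- which(af <= mid)
  below <- below[below > 1L]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  # linear interpolation on the downward crossing
  t1 <- time[i - 1L]; t2 <- time[i]
  y1 <- af[i - 1L]; y2 <- af[i]
  if (y1 == y2) return(t2)
  t1 + (y1 - mid) / (y1 - y2) * (t2 - t1)
}
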