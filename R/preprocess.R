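#' First-order differencing of a lung-sound signal
#'
#' Removes slowly varying instrumental baseline disturbances by replacing
#' the signal with its first difference, `y[n] - y[n-1]`. The output is one
#' sample shorter than the input; rate and label are preserved.
#'
#' @param signal A [lung_sound()] object.
#' @return A [lung_sound()] of length `length(signal) - 1`.
#' @export
first_difference <- function(signal) {
  if (!inherits(signal, "lung_sound")) stop("signal must be a lung_sound", call. = FALSE)
  if (length(signal$samples) < 2L) {
    stop("signal must have at least 2 samples to difference", call. = FALSE)
  }
  out <- lung_sound(diff(signal$samples), signal$sampling_rate_hz)
  out$label <- signal$label
  out
}

# Interior local extrema of a numeric vector. Returns 1-based indices.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  left <- x[2:(n - 1L)] - x[1:(n - 2L)]
  right <- x[2:(n - 1L)] - x[3:n]
  list(maxima = which(left > 0 & right >= 0) + 1L,
       minima = which(left < 0 & right <= 0) + 1L)
}

# Count of zero crossings (strict sign changes).
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

# Cubic-spline envelope through extrema, mirror-extending up to two extrema
# beyond each edge to suppress end swings.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  take_l <- seq_len(min(2L, k))
  take_r <- seq.int(k, by = -1L, length.out = min(2L, k))
  xi <- c(2L - idx[rev(take_l)], idx, 2L * n - idx[take_r])
  yi <- c(val[rev(take_l)], val, val[take_r])
  keep <- !duplicated(xi)
  splinefun(xi[keep], yi[keep], method = "fmm")(seq_len(n))
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting with
#' cubic-spline envelopes through the local maxima and minima. Sifting of
#' one IMF stops when Huang's Cauchy-type normalized standard-deviation
#' criterion drops below `sd_threshold` and the IMF property (extrema and
#' zero-crossing counts differing by at most one) holds, or after
#' `max_sift_iters` iterations. Decomposition stops at `max_imfs` or when
#' the residue has fewer than two maxima or minima.
#'
#' The decomposition is exactly additive: `Reduce("+", imfs) + residue`
#' reconstructs the input to floating-point accuracy, since each IMF is
#' subtracted from the running residue.
#'
#' @param signal A [lung_sound()] object or numeric vector.
#' @param max_imfs Maximum number of IMFs to extract (default 12).
#' @param sd_threshold Sifting stop threshold (default 0.2).
#' @param max_sift_iters Maximum sifting iterations per IMF (default 10).
#' @return An object of class `emd_result`: list with `imfs` (list of
#'   numeric vectors, fastest oscillation first), `residue`, and
#'   `sampling_rate_hz` (NA for bare vectors).
#' @export
emd_decompose <- function(signal, max_imfs = 12L, sd_threshold = 0.2,
                          max_sift_iters = 10L) {
  rate <- if (inherits(signal, "lung_sound")) signal$sampling_rate_hz else NA_real_
  x <- as_samples(signal)
  stop_if_not_finite(x, "signal samples")
  n <- length(x)
  if (n < 8L) stop("signal too short for EMD (need >= 8 samples)", call. = FALSE)
  stopifnot(max_imfs >= 1L, sd_threshold > 0, max_sift_iters >= 1L)

  imfs <- list()
  residue <- x
  for (k in seq_len(max_imfs)) {
    ext <- local_extrema(residue)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break

    h <- residue
    for (it in seq_len(max_sift_iters)) {
      e <- local_extrema(h)
      if (length(e$maxima) < 2L || length(e$minima) < 2L) break
      upper <- spline_envelope(e$maxima, h[e$maxima], n)
      lower <- spline_envelope(e$minima, h[e$minima], n)
      m <- (upper + lower) / 2
      h1 <- h - m
      sd_k <- sum((h - h1)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h1
      e1 <- local_extrema(h)
      n_ext <- length(e1$maxima) + length(e1$minima)
      if (sd_k < sd_threshold && abs(n_ext - zero_crossings(h)) <= 1L) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue, sampling_rate_hz = rate),
            class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMFs + residue, %d samples\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

#' Reconstruct the original signal from an EMD result
#'
#' @param emd An `emd_result` from [emd_decompose()].
#' @return Numeric vector: sum of all IMFs plus the residue.
#' @export
emd_reconstruct <- function(emd) {
  Reduce(`+`, emd$imfs, emd$residue)
}

#' Suppress heart-sound interference by selective EMD reconstruction
#'
#' Decomposes the recording with [emd_decompose()] and rebuilds the
#' lung-sound estimate from the intrinsic mode functions whose spectral
#' centroid lies at or above `cutoff_hz`. Modes with lower centroids and
#' the residue are attributed to the heart-sound/trend component, returned
#' alongside for inspection. The 150 Hz default reflects the usual spectral
#' split on the chest wall: S1/S2 heart-sound energy concentrates below
#' about 150 Hz while breath-sound energy extends well above it.
#'
#' @param signal A [lung_sound()] object.
#' @param cutoff_hz Spectral-centroid threshold in Hz (default 150).
#' @param ... Passed to [emd_decompose()] (`max_imfs`, `sd_threshold`,
#'   `max_sift_iters`).
#' @return An object of class `hs_removal`: list with `signal` (cleaned
#'   [lung_sound()]), `heart` (removed component as a `lung_sound`),
#'   `centroids_hz` (per IMF) and `kept` (logical per IMF).
#' @export
remove_heart_sound <- function(signal, cutoff_hz = 150, ...) {
  if (!inherits(signal, "lung_sound")) stop("signal must be a lung_sound", call. = FALSE)
  stopifnot(cutoff_hz > 0)
  emd <- emd_decompose(signal, ...)
  rate <- signal$sampling_rate_hz
  n <- length(signal$samples)

  if (length(emd$imfs) <= 1L) {
    warning("EMD produced a single mode; nothing separable, returning input unchanged")
    heart <- lung_sound(numeric(n), rate)
    return(structure(list(signal = signal, heart = heart,
                          centroids_hz = vapply(emd$imfs, spectral_centroid,
                                                numeric(1), sampling_rate_hz = rate),
                          kept = rep(TRUE, length(emd$imfs)), emd = emd),
                     class = "hs_removal"))
  }

  centroids <- vapply(emd$imfs, spectral_centroid, numeric(1),
                      sampling_rate_hz = rate)
  kept <- centroids >= cutoff_hz
  lung <- Reduce(`+`, emd$imfs[kept], numeric(n))
  heart <- Reduce(`+`, emd$imfs[!kept], emd$residue)

  clean <- signal
  clean$samples <- lung
  hs <- lung_sound(heart, rate)
  structure(list(signal = clean, heart = hs, centroids_hz = centroids,
                 kept = kept, emd = emd),
            class = "hs_removal")
}

#' @export
print.hs_removal <- function(x, ...) {
  cat(sprintf("<hs_removal> kept %d/%d IMFs (centroids %s Hz)\n",
              sum(x$kept), length(x$kept),
              paste(round(x$centroids_hz), collapse = ", ")))
  invisible(x)
}
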