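# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not_finite <- function(x, what = "samples") {
  if (!is.numeric(x) || length(x) == 0L) {
    stop(sprintf("%s must be a non-empty numeric vector", what), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("%s contain non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

#' One-sided power spectrum of a signal
#'
#' Periodogram-style power spectrum from the discrete Fourier transform,
#' used internally for spectral centroids and band powers and exported as a
#' convenience for inspecting enhancement results.
#'
#' @param x Numeric vector or [lung_sound()] object.
#' @param sampling_rate_hz Sampling rate in Hz; taken from `x` when it is a
#'   `lung_sound`.
#' @return A data frame with columns `freq_hz` and `power`.
#' @export
power_spectrum <- function(x, sampling_rate_hz = NULL) {
  if (inherits(x, "lung_sound")) {
    sampling_rate_hz <- x$sampling_rate_hz
    x <- x$samples
  }
  stop_if_not_finite(x, "signal samples")
  if (is.null(sampling_rate_hz)) stop("sampling_rate_hz is required", call. = FALSE)
  n <- length(x)
  # zero-pad to a 2-3-5-smooth length: R's fft degrades badly on lengths
  # with large prime factors
  m <- stats::nextn(n, c(2L, 3L, 5L))
  if (m > n) x <- c(x, numeric(m - n))
  nf <- m %/% 2L + 1L
  p <- Mod(fft(x))[seq_len(nf)]^2 / n
  data.frame(freq_hz = (seq_len(nf) - 1) * sampling_rate_hz / m, power = p)
}

#' Total power of a signal within a frequency band
#'
#' @inheritParams power_spectrum
#' @param band_hz Length-2 numeric, inclusive band edges in Hz.
#' @return Scalar band power (sum of periodogram bins in the band).
#' @export
band_power <- function(x, band_hz, sampling_rate_hz = NULL) {
  ps <- power_spectrum(x, sampling_rate_hz)
  keep <- ps$freq_hz >= band_hz[1] & ps$freq_hz <= band_hz[2]
  sum(ps$power[keep])
}

#' Spectral centroid of a signal
#'
#' First moment of the one-sided power spectrum; used to attribute intrinsic
#' mode functions to the heart-sound or lung-sound component.
#'
#' @inheritParams power_spectrum
#' @return Centroid frequency in Hz.
#' @export
spectral_centroid <- function(x, sampling_rate_hz = NULL) {
  ps <- power_spectrum(x, sampling_rate_hz)
  tot <- sum(ps$power)
  if (tot <= 0) return(0)
  sum(ps$freq_hz * ps$power) / tot
}

# Dominant spectral peak (Hz), ignoring DC.
peak_frequency <- function(x, sampling_rate_hz) {
  ps <- power_spectrum(x, sampling_rate_hz)
  ps <- ps[-1L, , drop = FALSE]
  ps$freq_hz[which.max(ps$power)]
}
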