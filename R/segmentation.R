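#' Hilbert envelope of a lung-sound signal
#'
#' Instantaneous amplitude computed as the magnitude of the analytic
#' signal, `sqrt(y(t)^2 + H(y(t))^2)` with `H` the Hilbert transform,
#' constructed in the frequency domain.
#'
#' @param signal A [lung_sound()] object.
#' @return An object of class `envelope_trace`: list with `raw_envelope`,
#'   `smoothed_envelope` (NULL until [smooth_envelope()] is applied) and
#'   `sampling_rate_hz`.
#' @export
hilbert_envelope <- function(signal) {
  if (!inherits(signal, "lung_sound")) stop("signal must be a lung_sound", call. = FALSE)
  x <- signal$samples
  n <- length(x)
  # zero-pad to a 2-3-5-smooth length for fft speed; the padded tail is
  # discarded and its edge influence is negligible next to the 5 Hz
  # envelope smoothing that follows
  m <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- if (m > n) c(x, numeric(m - n)) else x
  X <- fft(xp)
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[c(1L, m / 2L + 1L)] <- 1
    h[2:(m / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((m + 1L) / 2L)] <- 2
  }
  analytic <- (fft(X * h, inverse = TRUE) / m)[seq_len(n)]
  structure(list(raw_envelope = Mod(analytic),
                 smoothed_envelope = NULL,
                 sampling_rate_hz = signal$sampling_rate_hz),
            class = "envelope_trace")
}

#' @export
print.envelope_trace <- function(x, ...) {
  cat(sprintf("<envelope_trace> %d samples @ %g Hz, smoothed: %s\n",
              length(x$raw_envelope), x$sampling_rate_hz,
              !is.null(x$smoothed_envelope)))
  invisible(x)
}

#' Low-pass smooth the Hilbert envelope
#'
#' Removes the fast intra-breath vibration of the raw envelope so that only
#' the breathing-phase modulation (well below a few Hz) remains. The default
#' is an order-4 Butterworth low-pass at 5 Hz applied forward-backward
#' (zero phase), so envelope minima are not displaced in time. A linear-phase
#' windowed-sinc FIR with matched cutoff is available as an alternative; it
#' is also applied forward-backward.
#'
#' @param trace An `envelope_trace` from [hilbert_envelope()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 5); must be below Nyquist.
#' @param order Butterworth order (default 4).
#' @param kind `"iir_butterworth"` (default) or `"fir_sinc"`.
#' @return The trace with `smoothed_envelope` filled (clamped at 0).
#' @export
smooth_envelope <- function(trace, cutoff_hz = 5, order = 4L,
                            kind = c("iir_butterworth", "fir_sinc")) {
  if (!inherits(trace, "envelope_trace")) stop("trace must be an envelope_trace", call. = FALSE)
  kind <- match.arg(kind)
  nyq <- trace$sampling_rate_hz / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyq), call. = FALSE)
  }
  env <- trace$raw_envelope
  n <- length(env)
  # odd-reflection padding keeps the filter transient out of the data:
  # plain forward-backward filtering assumes zeros beyond the edges, which
  # would drag the smoothed envelope down at both ends of the recording
  pad <- max(1L, min(n - 1L,
                     as.integer(ceiling(8 * trace$sampling_rate_hz / cutoff_hz))))
  xp <- c(2 * env[1L] - env[(pad + 1L):2L], env,
          2 * env[n] - env[(n - 1L):(n - pad)])
  if (kind == "iir_butterworth") {
    bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
    sm <- signal::filtfilt(bf, xp)
  } else {
    ntap <- 2L * ceiling(2 * trace$sampling_rate_hz / cutoff_hz) + 1L
    fir <- signal::fir1(ntap - 1L, cutoff_hz / nyq, type = "low")
    sm <- signal::filtfilt(fir, xp)
  }
  trace$smoothed_envelope <- pmax(sm[pad + seq_len(n)], 0)
  trace
}

#' Breathing-phase transition points from the smoothed envelope
#'
#' Transition points are the local minima of the smoothed envelope: indices
#' where its discrete first derivative changes sign from non-positive to
#' positive. On sampled data the derivative is almost never exactly zero,
#' so the zero-derivative condition is realized as this sign change, with
#' ties over flat valleys broken toward the earliest index. Recording
#' edges count as transition points when the envelope moves away from
#' (start) or toward (end) a boundary minimum, so recordings that begin and
#' end at a phase boundary segment into the right number of phases.
#' Candidate minima closer together than `min_phase_s` are merged, keeping
#' the deeper one; minima of low topographic prominence (the envelope
#' rise separating them from their neighbours) are pruned; and only deep
#' minima qualify — a breathing-phase boundary sits near the envelope
#' floor, so candidates above a low quantile of the smoothed envelope
#' (ripple notches, gaps between adventitious bursts) are discarded.
#' These guards suppress the spurious minima that survive 5 Hz smoothing
#' of a noisy instantaneous amplitude.
#'
#' @param trace An `envelope_trace` with the smoothed envelope present.
#' @param min_phase_s Minimum credible phase duration in seconds
#'   (default 0.3).
#' @param min_prominence Minimum prominence of a kept minimum as a
#'   fraction of the smoothed envelope's 95th percentile (default 0.1).
#' @param depth_quantile Quantile of the smoothed envelope below which a
#'   candidate minimum must lie (default 0.25); set to 1 to disable.
#' @param include_endpoints Treat the first/last sample as candidate
#'   transition points when the envelope rises from the start or falls into
#'   the end (default TRUE).
#' @return Integer vector of 0-based sample indices, strictly increasing.
#' @export
find_transition_points <- function(trace, min_phase_s = 0.3,
                                   min_prominence = 0.1,
                                   depth_quantile = 0.25,
                                   include_endpoints = TRUE) {
  if (!inherits(trace, "envelope_trace") || is.null(trace$smoothed_envelope)) {
    stop("trace must be an envelope_trace with a smoothed envelope", call. = FALSE)
  }
  env <- trace$smoothed_envelope
  n <- length(env)
  d <- diff(env)
  # minima: d[t-1] <= 0 and d[t] > 0 (1-based t in 2..n-1)
  cand <- which(d[-1L] > 0 & d[-length(d)] <= 0) + 1L
  # flat valleys: walk back over zero-derivative runs to the earliest index
  if (length(cand)) {
    cand <- vapply(cand, function(t) {
      while (t > 2L && d[t - 1L] == 0) t <- t - 1L
      t
    }, integer(1))
  }
  thr <- if (depth_quantile < 1) stats::quantile(env, depth_quantile) else Inf
  if (include_endpoints) {
    # a recording edge counts as a boundary when the envelope moves away
    # from it or when it sits in the quiet (sub-threshold) range
    if (d[1L] > 0 || env[1L] <= thr) cand <- c(1L, cand)
    if (d[length(d)] < 0 || env[n] <= thr) cand <- c(cand, n)
  }
  cand <- sort(unique(cand))

  # depth gate: phase boundaries live near the envelope floor
  if (depth_quantile < 1) {
    cand <- cand[env[cand] <= thr]
  }

  # prune low-prominence minima (envelope ripple): iteratively drop the
  # candidate with the smallest rise separating it from its neighbours
  prom_floor <- min_prominence * stats::quantile(env, 0.95)
  repeat {
    if (length(cand) < 2L) break
    prom <- vapply(seq_along(cand), function(i) {
      # rises toward neighbouring candidates; the outward side of the
      # first/last candidate is unbounded (the envelope cannot be
      # expected to rise beyond the recording edge)
      rise_l <- if (i == 1L) Inf else
        max(env[cand[i - 1L]:cand[i]]) - env[cand[i]]
      rise_r <- if (i == length(cand)) Inf else
        max(env[cand[i]:cand[i + 1L]]) - env[cand[i]]
      min(rise_l, rise_r)
    }, numeric(1))
    weak <- which.min(prom)
    if (prom[weak] >= prom_floor) break
    cand <- cand[-weak]
  }

  # merge minima closer than min_phase_s, keeping the deeper one
  min_gap <- min_phase_s * trace$sampling_rate_hz
  while (length(cand) >= 2L) {
    gaps <- diff(cand)
    j <- which(gaps < min_gap)
    if (!length(j)) break
    j <- j[1L]
    drop <- if (env[cand[j]] <= env[cand[j + 1L]]) j + 1L else j
    cand <- cand[-drop]
  }

  if (length(cand) < 2L) {
    stop("no complete phase detectable: fewer than 2 envelope minima found",
         call. = FALSE)
  }
  as.integer(cand - 1L) # 0-based
}

#' Assemble respiratory cycles from transition points
#'
#' Consecutive transition points delimit breathing phases; consecutive
#' phase pairs form complete respiratory cycles (one inspiration plus one
#' expiration). A trailing unpaired phase is dropped with a message. Cycle
#' intervals are half-open `[start, end)` in 0-based samples.
#'
#' @param transition_points Integer vector of 0-based transition points
#'   (at least 3), e.g. from [find_transition_points()].
#' @param signal_length Total signal length in samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A data frame of class `respiratory_cycles` with columns
#'   `cycle_id`, `start_sample`, `end_sample`, `transition_sample` (the
#'   interior phase boundary) and `duration_s`.
#' @export
assemble_cycles <- function(transition_points, signal_length, sampling_rate_hz) {
  tp <- sort(as.integer(transition_points))
  if (length(tp) < 3L) {
    stop("need at least 3 transition points (two phases) to form a cycle",
         call. = FALSE)
  }
  if (tp[1L] < 0L || tp[length(tp)] > signal_length) {
    stop("transition points outside the signal", call. = FALSE)
  }
  n_cycles <- (length(tp) - 1L) %/% 2L
  if ((length(tp) - 1L) %% 2L == 1L) {
    message("dropping trailing unpaired breathing phase")
  }
  i <- seq_len(n_cycles)
  out <- data.frame(
    cycle_id = i,
    start_sample = tp[2L * i - 1L],
    end_sample = tp[2L * i + 1L],
    transition_sample = tp[2L * i],
    duration_s = (tp[2L * i + 1L] - tp[2L * i - 1L]) / sampling_rate_hz
  )
  class(out) <- c("respiratory_cycles", "data.frame")
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  out
}

#' Segment a lung-sound signal into respiratory cycles
#'
#' Convenience wrapper chaining [hilbert_envelope()], [smooth_envelope()],
#' [find_transition_points()] and [assemble_cycles()].
#'
#' @param signal A [lung_sound()] object.
#' @param cutoff_hz Envelope smoothing cutoff in Hz (default 5).
#' @param min_phase_s Minimum phase duration in seconds (default 0.3).
#' @param min_prominence,depth_quantile See [find_transition_points()].
#' @param kind Smoothing filter kind, see [smooth_envelope()].
#' @param include_endpoints See [find_transition_points()].
#' @return A `respiratory_cycles` data frame.
#' @export
segment_cycles <- function(signal, cutoff_hz = 5, min_phase_s = 0.3,
                           min_prominence = 0.1, depth_quantile = 0.25,
                           kind = "iir_butterworth",
                           include_endpoints = TRUE) {
  trace <- smooth_envelope(hilbert_envelope(signal), cutoff_hz = cutoff_hz,
                           kind = kind)
  tp <- find_transition_points(trace, min_phase_s = min_phase_s,
                               min_prominence = min_prominence,
                               depth_quantile = depth_quantile,
                               include_endpoints = include_endpoints)
  assemble_cycles(tp, length(signal$samples), signal$sampling_rate_hz)
}
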