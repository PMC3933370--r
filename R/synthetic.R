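# Seeded generator of labelled synthetic lung-sound recordings with
# ground-truth cycle boundaries, adventitious events and heart-sound
# mixtures. It emulates the statistical structure the pipeline assumes:
# band-limited breath noise amplitude-modulated by per-phase envelopes,
# crackle transients and wheeze tones in the abnormal class, and periodic
# low-frequency S1/S2 heart bursts mixed at a controlled energy ratio.

#' Configuration for the synthetic lung-sound generator
#'
#' Defaults follow standard respiratory-acoustics ranges: vesicular breath
#' noise band 150-900 Hz with expiration quieter than inspiration;
#' crackles as short damped wideband transients around 600 Hz; wheezes as
#' sustained tones near 400 Hz; heart sounds as periodic paired S1/S2
#' bursts at 40/60 Hz, about one beat per second. Abnormal recordings
#' additionally carry breath-noise energy to higher frequencies
#' (`abnormal_band_hz`), reflecting the harsher, more bronchial character
#' of pathological breath sounds.
#'
#' @param rate_hz Sampling rate (default 8000).
#' @param n_cycles Breathing cycles per recording (default 4).
#' @param inspiration_s,expiration_s Mean phase durations in seconds
#'   (defaults 1.2 and 1.8).
#' @param phase_jitter_sd SD of per-phase duration jitter in seconds
#'   (default 0.1).
#' @param breath_band_hz Breath-noise carrier pass band for the normal
#'   class, Hz (default `c(150, 900)`).
#' @param abnormal_band_hz Carrier pass band for the abnormal class
#'   (default `c(150, 2200)`).
#' @param expiration_amp Expiration envelope peak relative to inspiration.
#'   Either a scalar or a length-2 range from which one value is drawn per
#'   recording (default `c(0.3, 0.75)`), emulating the wide inter-subject
#'   spread of expiratory loudness at the chest wall.
#' @param floor_amp Constant background-noise envelope level (default 0.05).
#' @param amp_scale Overall output amplitude scale (default 0.15); fixed,
#'   not data-dependent, so equal seeds give comparable signals.
#' @param crackle List: `rate` per cycle (Poisson, default 12),
#'   `duration_ms` (10), `center_freq_hz` (600), `amplitude` relative to
#'   the local envelope (3.5).
#' @param wheeze List: `probability` per cycle (0.7), `freq_hz` (400),
#'   `duration_s` (0.4), `amplitude_ratio` relative to the local envelope
#'   (0.6).
#' @param irregularity List controlling the irregular airflow of the
#'   abnormal class: `envelope` (default 0.5), the relative depth of slow
#'   multiplicative roughness imposed on the breath envelope, and
#'   `phase_amp` (default 0), the log-SD of the breath-to-breath
#'   amplitude jitter; `knot_s` (default 0.04) sets the roughness
#'   timescale in seconds (kept well above the envelope-smoothing band so
#'   segmentation is unaffected). Both depths are 0 for the normal class
#'   by construction.
#' @param heart List: `period_s` (1.0), `s1_freq_hz` (40), `s2_freq_hz`
#'   (60), `s2_delay_s` (0.3), `burst_s` (0.07), `s2_amp` (0.6).
#' @param mix_ratio_ls Fraction of total signal energy contributed by the
#'   lung sound when heart sound is mixed in (default 1 = no heart sound).
#' @param severity Scalar multiplying crackle rate and wheeze amplitude in
#'   the abnormal class (default 1), a single difficulty dial for tests.
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class `gen_config`.
#' @export
gen_config <- function(rate_hz = 8000, n_cycles = 4L,
                       inspiration_s = 1.2, expiration_s = 1.8,
                       phase_jitter_sd = 0.1,
                       breath_band_hz = c(150, 900),
                       abnormal_band_hz = c(150, 2200),
                       expiration_amp = c(0.3, 0.75), floor_amp = 0.05,
                       amp_scale = 0.15,
                       crackle = list(), wheeze = list(), heart = list(),
                       irregularity = list(),
                       mix_ratio_ls = 1, severity = 1, seed = 1L) {
  crackle <- utils::modifyList(
    list(rate = 12, duration_ms = 10, center_freq_hz = 600, amplitude = 3.5),
    crackle)
  wheeze <- utils::modifyList(
    list(probability = 0.7, freq_hz = 400, duration_s = 0.4,
         amplitude_ratio = 0.6),
    wheeze)
  irregularity <- utils::modifyList(
    list(envelope = 0.5, knot_s = 0.04, phase_amp = 0),
    irregularity)
  heart <- utils::modifyList(
    list(period_s = 1.0, s1_freq_hz = 40, s2_freq_hz = 60,
         s2_delay_s = 0.3, burst_s = 0.07, s2_amp = 0.6),
    heart)
  cfg <- list(rate_hz = rate_hz, n_cycles = as.integer(n_cycles),
              inspiration_s = inspiration_s, expiration_s = expiration_s,
              phase_jitter_sd = phase_jitter_sd,
              breath_band_hz = breath_band_hz,
              abnormal_band_hz = abnormal_band_hz,
              expiration_amp = expiration_amp, floor_amp = floor_amp,
              amp_scale = amp_scale, crackle = crackle, wheeze = wheeze,
              heart = heart, irregularity = irregularity,
              mix_ratio_ls = mix_ratio_ls,
              severity = severity, seed = as.integer(seed))
  stopifnot(cfg$rate_hz > 0, cfg$n_cycles >= 1L,
            cfg$inspiration_s > 0, cfg$expiration_s > 0,
            cfg$phase_jitter_sd >= 0,
            length(cfg$breath_band_hz) == 2L,
            cfg$breath_band_hz[1] > 0,
            cfg$breath_band_hz[2] > cfg$breath_band_hz[1],
            cfg$breath_band_hz[2] < cfg$rate_hz / 2,
            cfg$abnormal_band_hz[2] < cfg$rate_hz / 2,
            length(cfg$expiration_amp) %in% c(1L, 2L),
            all(cfg$expiration_amp > 0), !is.unsorted(cfg$expiration_amp),
            cfg$floor_amp >= 0, cfg$amp_scale > 0,
            cfg$crackle$rate >= 0, cfg$crackle$duration_ms > 0,
            cfg$crackle$center_freq_hz > 0, cfg$crackle$amplitude >= 0,
            cfg$wheeze$probability >= 0, cfg$wheeze$probability <= 1,
            cfg$wheeze$freq_hz > 0, cfg$wheeze$duration_s > 0,
            cfg$heart$period_s > 0, cfg$heart$s1_freq_hz > 0,
            cfg$heart$s2_freq_hz > 0,
            cfg$irregularity$envelope >= 0, cfg$irregularity$phase_amp >= 0,
            cfg$mix_ratio_ls >= 0, cfg$mix_ratio_ls <= 1,
            cfg$severity >= 0)
  class(cfg) <- "gen_config"
  cfg
}

bandpass_noise <- function(n, band_hz, rate_hz) {
  bf <- signal::butter(4, band_hz / (rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

# Draw the phase timeline; jittered durations truncated at half the mean.
draw_phases <- function(cfg) {
  n_ph <- 2L * cfg$n_cycles
  means <- rep(c(cfg$inspiration_s, cfg$expiration_s), cfg$n_cycles)
  dur <- pmax(means + rnorm(n_ph, 0, cfg$phase_jitter_sd), means / 2)
  n_samp <- as.integer(round(dur * cfg$rate_hz))
  data.frame(phase = rep(c("inspiration", "expiration"), cfg$n_cycles),
             cycle = rep(seq_len(cfg$n_cycles), each = 2L),
             n_samples = n_samp)
}

# Raised-cosine amplitude envelope over the phase timeline (modulated part
# only; the constant background floor is added by the callers).
phase_envelope <- function(phases, cfg, exp_amp) {
  amps <- ifelse(phases$phase == "inspiration", 1, exp_amp)
  unlist(lapply(seq_len(nrow(phases)), function(i) {
    n <- phases$n_samples[i]
    amps[i] * 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  }), use.names = FALSE)
}

# Slow unit-variance Gaussian roughness track built by cubic interpolation
# of iid knots spaced knot_s seconds apart (bandwidth ~ 1/(2 knot_s) Hz);
# used for the irregular turbulent flow of abnormal breathing.
slow_noise <- function(n, rate_hz, knot_s = 0.15) {
  k <- max(4L, as.integer(ceiling(n / rate_hz / knot_s)) + 3L)
  knots <- rnorm(k)
  splinefun(seq(1L, n, length.out = k), knots, method = "fmm")(seq_len(n))
}

# Shared construction of the modulated breath-noise base. Must be called
# inside with_seed(); RNG order: phase jitter, then carrier noise.
build_base <- function(cfg, band_hz) {
  ea <- cfg$expiration_amp
  exp_amp <- if (length(ea) == 2L) runif(1, ea[1], ea[2]) else ea
  phases <- draw_phases(cfg)
  total <- sum(phases$n_samples)
  env_mod <- phase_envelope(phases, cfg, exp_amp)
  carrier <- bandpass_noise(total, band_hz, cfg$rate_hz)
  boundaries <- c(0L, cumsum(phases$n_samples))
  list(phases = phases, env_mod = env_mod,
       env = env_mod + cfg$floor_amp, carrier = carrier,
       boundaries = as.integer(boundaries))
}

new_recording <- function(samples, cfg, boundaries, label, events = list(),
                          clean_ls = NULL, clean_hs = NULL) {
  sig <- lung_sound(samples, cfg$rate_hz,
                    label = if (label %in% c("normal", "abnormal")) label else "unknown")
  structure(list(signal = sig, true_boundaries = boundaries,
                 true_label = label, events = events,
                 clean_ls = if (is.null(clean_ls)) samples else clean_ls,
                 clean_hs = clean_hs, config = cfg),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s, %d cycles, %d samples @ %g Hz, %d events\n",
              x$true_label, x$config$n_cycles, length(x$signal$samples),
              x$config$rate_hz, length(x$events)))
  invisible(x)
}

#' Generate a synthetic normal lung-sound recording
#'
#' Band-limited Gaussian breath noise amplitude-modulated by smooth
#' raised-cosine per-phase envelopes (expiration at about half the
#' inspiration amplitude), with phase boundaries recorded exactly. With
#' `n_cycles` cycles the recording carries `2 * n_cycles + 1` ground-truth
#' boundaries, including the first and last sample.
#'
#' @param config A [gen_config()].
#' @return A `synthetic_recording`: list with `signal` ([lung_sound()]),
#'   `true_boundaries` (0-based), `true_label`, `events`, `clean_ls`,
#'   `clean_hs` (NULL until [mix_heart_sound()]), `config`.
#' @export
generate_normal <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  base <- with_seed(config$seed, build_base(config, config$breath_band_hz))
  x <- config$amp_scale * base$env * base$carrier
  new_recording(x, config, base$boundaries, "normal")
}

crackle_wave <- function(n, freq_hz, rate_hz) {
  t <- (seq_len(n) - 1) / rate_hz
  tau <- (n / rate_hz) / 4
  sin(2 * pi * freq_hz * t) * exp(-t / tau)
}

hann_ramped_tone <- function(n, freq_hz, rate_hz, ramp_s = 0.05) {
  t <- (seq_len(n) - 1) / rate_hz
  w <- rep(1, n)
  nr <- min(as.integer(ramp_s * rate_hz), n %/% 2L)
  if (nr > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    w[seq_len(nr)] <- ramp
    w[n - nr + seq_len(nr)] <- rev(ramp)
  }
  sin(2 * pi * freq_hz * t) * w
}

#' Generate a synthetic abnormal lung-sound recording
#'
#' The abnormal class is the normal construction with four pathological
#' departures: the breath-noise carrier extends to higher frequencies
#' (`abnormal_band_hz`, the harsher bronchial spectrum), the breath
#' envelope is made irregular (slow multiplicative roughness and
#' breath-to-breath amplitude jitter, the `irregularity` config), crackles
#' (short exponentially damped sinusoid bursts, Poisson-placed within
#' inspirations) are inserted, and a sustained wheeze tone is added to the
#' expiration of a cycle with the configured probability. Event times and
#' parameters are recorded. With crackle rate 0, wheeze probability 0,
#' both irregularity terms 0 and `abnormal_band_hz` equal to
#' `breath_band_hz`, the output is identical to [generate_normal()] under
#' the same seed.
#'
#' @param config A [gen_config()].
#' @return A `synthetic_recording`, see [generate_normal()].
#' @export
generate_abnormal <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  cfg <- config
  out <- with_seed(cfg$seed, {
    base <- build_base(cfg, cfg$abnormal_band_hz)
    rate <- cfg$rate_hz
    env <- base$env
    # irregular airflow: breath-to-breath amplitude jitter and slow
    # multiplicative roughness of the modulated envelope; the background
    # floor and the boundary minima are untouched. Drawn after the carrier
    # so that zeroed departures reproduce the normal construction exactly.
    env_mod <- base$env_mod
    if (cfg$irregularity$phase_amp > 0) {
      fac <- exp(rnorm(nrow(base$phases), 0, cfg$irregularity$phase_amp))
      env_mod <- env_mod * rep(fac, base$phases$n_samples)
    }
    if (cfg$irregularity$envelope > 0) {
      rough <- slow_noise(length(env_mod), rate, cfg$irregularity$knot_s)
      env_mod <- env_mod * pmax(1 + cfg$irregularity$envelope * rough, 0.1)
    }
    env <- env_mod + cfg$floor_amp
    x <- cfg$amp_scale * env * base$carrier
    events <- list()

    starts <- base$boundaries[-length(base$boundaries)] + 1L # 1-based
    for (i in seq_len(nrow(base$phases))) {
      ph <- base$phases[i, ]
      n_ph <- ph$n_samples
      if (ph$phase == "inspiration" && cfg$crackle$rate > 0) {
        n_cr <- rpois(1L, cfg$crackle$rate * cfg$severity)
        if (n_cr > 0L) {
          n_burst <- max(8L, as.integer(cfg$crackle$duration_ms / 1000 * rate))
          pos <- sort(as.integer(runif(n_cr, 0.05, 0.9) * (n_ph - n_burst)))
          for (p in pos) {
            at <- starts[i] + p
            amp <- cfg$amp_scale * cfg$crackle$amplitude *
              env[at] * runif(1, 0.8, 1.2)
            seg <- at:(at + n_burst - 1L)
            x[seg] <- x[seg] + amp * crackle_wave(n_burst, cfg$crackle$center_freq_hz, rate)
            events[[length(events) + 1L]] <-
              list(type = "crackle", at_sample = at - 1L, n_samples = n_burst)
          }
        }
      }
      if (ph$phase == "expiration" && cfg$wheeze$probability > 0) {
        if (runif(1) < cfg$wheeze$probability) {
          n_wh <- min(as.integer(cfg$wheeze$duration_s * rate),
                      as.integer(0.8 * n_ph))
          if (n_wh > 16L) {
            p <- as.integer(runif(1, 0.05, 0.9) * (n_ph - n_wh))
            at <- starts[i] + p
            f <- cfg$wheeze$freq_hz * runif(1, 0.95, 1.05)
            seg <- at:(at + n_wh - 1L)
            amp <- cfg$amp_scale * cfg$wheeze$amplitude_ratio * cfg$severity *
              max(env[seg])
            x[seg] <- x[seg] + amp * hann_ramped_tone(n_wh, f, rate)
            events[[length(events) + 1L]] <-
              list(type = "wheeze", at_sample = at - 1L, n_samples = n_wh,
                   freq_hz = f)
          }
        }
      }
    }
    list(x = x, boundaries = base$boundaries, events = events)
  })
  new_recording(out$x, cfg, out$boundaries, "abnormal", out$events)
}

#' Generate a periodic heart-sound interference signal
#'
#' Paired S1/S2 bursts (Hann-windowed sinusoids at the configured
#' low frequencies) repeating at roughly the beat period with small
#' timing jitter. The returned signal has unit standard deviation; its
#' level in a mixture is set by [mix_heart_sound()].
#'
#' @param config A [gen_config()].
#' @param n_samples Length of the signal to generate.
#' @return A [lung_sound()] with the heart-sound waveform.
#' @export
generate_heart_sound <- function(config = gen_config(), n_samples) {
  stopifnot(inherits(config, "gen_config"), n_samples > 0)
  cfg <- config
  rate <- cfg$rate_hz
  x <- with_seed(cfg$seed + 7919L, {
    x <- numeric(n_samples)
    n_burst <- as.integer(cfg$heart$burst_s * rate)
    add_burst <- function(x, at, freq, amp) {
      if (at < 1L || at + n_burst - 1L > n_samples) return(x)
      seg <- at:(at + n_burst - 1L)
      x[seg] <- x[seg] + amp * hann_ramped_tone(n_burst, freq, rate,
                                                ramp_s = cfg$heart$burst_s / 2)
      x
    }
    t <- 0.2
    while (t < n_samples / rate) {
      at <- as.integer(t * rate) + 1L
      x <- add_burst(x, at, cfg$heart$s1_freq_hz, 1)
      x <- add_burst(x, at + as.integer(cfg$heart$s2_delay_s * rate),
                     cfg$heart$s2_freq_hz, cfg$heart$s2_amp)
      t <- t + cfg$heart$period_s * runif(1, 0.98, 1.02)
    }
    x
  })
  s <- sd(x)
  if (s > 0) x <- x / s
  lung_sound(x, rate)
}

#' Mix heart-sound interference into a synthetic recording
#'
#' Scales a generated heart-sound signal so that the lung-sound component
#' contributes exactly `mix_ratio_ls` of the total energy (e.g. 0.2 for a
#' 20% LS + 80% HS mixture) and adds it to the recording. The clean
#' components are kept for oracle comparisons; the mixture equals
#' `clean_ls + clean_hs` exactly.
#'
#' @param recording A `synthetic_recording`.
#' @param mix_ratio_ls Lung-sound energy fraction in `[0, 1]`; defaults to
#'   the recording config's `mix_ratio_ls`.
#' @return The recording with `signal`, `clean_ls` and `clean_hs` updated.
#' @export
mix_heart_sound <- function(recording, mix_ratio_ls = NULL) {
  stopifnot(inherits(recording, "synthetic_recording"))
  cfg <- recording$config
  m <- if (is.null(mix_ratio_ls)) cfg$mix_ratio_ls else mix_ratio_ls
  stopifnot(m >= 0, m <= 1)
  ls <- recording$clean_ls
  n <- length(ls)
  if (m == 1) {
    recording$clean_hs <- numeric(n)
    recording$signal$samples <- ls
    return(recording)
  }
  hs <- generate_heart_sound(cfg, n)$samples
  e_ls <- sum(ls^2)
  e_hs <- sum(hs^2)
  if (m == 0) {
    # all-heart-sound limit: match the LS energy so the mixture is audible
    k <- sqrt(e_ls / e_hs)
    recording$clean_ls <- numeric(n)
    recording$clean_hs <- k * hs
    recording$signal$samples <- k * hs
    return(recording)
  }
  k <- sqrt(e_ls * (1 - m) / (m * e_hs))
  recording$clean_hs <- k * hs
  recording$signal$samples <- ls + recording$clean_hs
  recording
}

#' Generate a labelled dataset of synthetic recordings
#'
#' Convenience wrapper generating `n_normal` normal and `n_abnormal`
#' abnormal recordings with per-recording seeds derived from `seed`, and
#' heart sound mixed in at the config's `mix_ratio_ls`.
#'
#' @param n_normal,n_abnormal Numbers of recordings per class.
#' @param config Base [gen_config()]; its `seed` is overridden per
#'   recording as `seed + index`.
#' @param seed Base integer seed.
#' @return List of `synthetic_recording` objects.
#' @export
simulate_dataset <- function(n_normal, n_abnormal, config = gen_config(),
                             seed = 1L) {
  recs <- vector("list", n_normal + n_abnormal)
  for (i in seq_len(n_normal)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    recs[[i]] <- mix_heart_sound(generate_normal(cfg))
  }
  for (j in seq_len(n_abnormal)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 100000L + j)
    recs[[n_normal + j]] <- mix_heart_sound(generate_abnormal(cfg))
  }
  recs
}
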