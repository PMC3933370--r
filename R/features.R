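#' Excess kurtosis of a sample distribution
#'
#' Fourth standardized moment minus 3, using population (1/N) moments:
#' `E[(y - mu)^4] / (E[(y - mu)^2])^2 - 3`. Measures the tailedness /
#' peakedness of the amplitude distribution of a breathing cycle; crackle
#' transients push it up.
#'
#' @param x Numeric vector, length >= 4, with positive variance.
#' @return Scalar excess kurtosis (0 for a Gaussian).
#' @export
excess_kurtosis <- function(x) {
  x <- as_samples(x)
  stop_if_not_finite(x, "x")
  if (length(x) < 4L) stop("need at least 4 samples for kurtosis", call. = FALSE)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v <= 0) stop("degenerate distribution: zero variance", call. = FALSE)
  mean((x - mu)^4) / v^2 - 3
}

#' Skewness of a sample distribution
#'
#' Third standardized moment with population (1/N) normalization:
#' `E[(y - mu)^3] / sd^3`. Zero for symmetric amplitude distributions.
#'
#' @param x Numeric vector, length >= 3, with positive variance.
#' @return Scalar skewness.
#' @export
skewness <- function(x) {
  x <- as_samples(x)
  stop_if_not_finite(x, "x")
  if (length(x) < 3L) stop("need at least 3 samples for skewness", call. = FALSE)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v <= 0) stop("degenerate distribution: zero variance", call. = FALSE)
  mean((x - mu)^3) / v^1.5
}

#' Gliding-box lacunarity at a single box length
#'
#' Texture/heterogeneity index of a one-dimensional series. A box of
#' `l` samples glides along the series with stride one; the box mass is the
#' sum of the mass-transformed samples it covers. Lacunarity is the ratio
#' of the second moment of the box-mass distribution to the square of its
#' first moment, `M2 / M1^2`; it equals 1 for a homogeneous series and
#' grows with gappiness/burstiness. Signed acoustic samples are made
#' nonnegative by the mass transform (`abs` by default, `square`
#' optionally).
#'
#' @param x Numeric vector of length `L > l`.
#' @param l Box length in samples, `1 <= l < L`.
#' @param mass_transform `"abs"` (default) or `"square"`.
#' @return Scalar lacunarity, `>= 1`.
#' @export
lacunarity <- function(x, l, mass_transform = c("abs", "square")) {
  x <- as_samples(x)
  stop_if_not_finite(x, "x")
  mass_transform <- match.arg(mass_transform)
  L <- length(x)
  l <- as.integer(l)
  if (l < 1L || l >= L) stop("box length l must satisfy 1 <= l < length(x)", call. = FALSE)
  m <- if (mass_transform == "abs") abs(x) else x^2
  cs <- cumsum(m)
  masses <- cs[l:L] - c(0, cs[seq_len(L - l)])
  m1 <- mean(masses)
  if (m1 <= 0) stop("undefined lacunarity: all box masses are zero", call. = FALSE)
  mean(masses^2) / m1^2
}

# Default dyadic box-length sweep: 2, 4, 8, ... up to L / 16. The cap keeps
# boxes well below the breathing-phase timescale, so the profile measures
# texture within phases rather than the inspiration/expiration geometry
# itself.
dyadic_box_lengths <- function(L) {
  k <- floor(log2(L / 16))
  if (k < 1) stop("series too short for the default box-length sweep", call. = FALSE)
  2^seq_len(k)
}

#' Lacunarity profile and scalar summary over box lengths
#'
#' Computes [lacunarity()] for each box length and summarizes the profile
#' by the geometric mean of the per-length values, a scale-balanced single
#' scalar for classification. The default sweep is dyadic,
#' `l = 2, 4, 8, ..., <= L/16`; the cap keeps boxes below the
#' breathing-phase timescale so the summary reflects within-phase texture.
#'
#' @param x Numeric vector.
#' @param box_lengths Integer vector of box lengths; default dyadic sweep.
#' @param mass_transform `"abs"` (default) or `"square"`.
#' @return List with `summary` (geometric-mean lacunarity) and `profile`
#'   (data frame of `box_length`, `lacunarity`).
#' @export
lacunarity_profile <- function(x, box_lengths = NULL,
                               mass_transform = c("abs", "square")) {
  x <- as_samples(x)
  mass_transform <- match.arg(mass_transform)
  if (is.null(box_lengths)) box_lengths <- dyadic_box_lengths(length(x))
  if (!length(box_lengths)) stop("box_lengths must be non-empty", call. = FALSE)
  zeta <- vapply(box_lengths, function(l) lacunarity(x, l, mass_transform),
                 numeric(1))
  list(summary = exp(mean(log(zeta))),
       profile = data.frame(box_length = as.integer(box_lengths),
                            lacunarity = zeta))
}

#' Sample entropy of a series
#'
#' Negative logarithm of the conditional probability that two templates
#' matching pointwise for `m` samples within tolerance `r` (Chebyshev
#' distance, self-matches excluded) still match at `m + 1` samples. Higher
#' values indicate a more irregular series. The tolerance is expressed as
#' a multiple of the series' standard deviation by default
#' (`r_mode = "sd"`), the convention of Richman & Moorman, which makes the
#' index amplitude-scale invariant.
#'
#' @param x Numeric vector of length `>= m + 2`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance (default 0.2), interpreted per `r_mode`.
#' @param r_mode `"sd"`: tolerance is `r` times `sd(x)` (default);
#'   `"absolute"`: `r` is used as-is.
#' @return Scalar sample entropy, `>= 0`.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, r_mode = c("sd", "absolute")) {
  x <- as_samples(x)
  stop_if_not_finite(x, "x")
  r_mode <- match.arg(r_mode)
  m <- as.integer(m)
  if (m < 1L) stop("embedding dimension m must be >= 1", call. = FALSE)
  if (length(x) < m + 2L) stop("series too short for sample entropy", call. = FALSE)
  if (r <= 0) stop("tolerance r must be positive", call. = FALSE)
  r_abs <- if (r_mode == "sd") {
    s <- sd(x)
    if (s <= 0) stop("degenerate series: zero standard deviation, cannot scale r",
                     call. = FALSE)
    r * s
  } else {
    r
  }
  counts <- sampen_counts(as.numeric(x), m, r_abs)
  if (counts[["B"]] == 0) {
    stop(sprintf("SampEn undefined (no template matches at m = %d; B = 0, A = 0)", m),
         call. = FALSE)
  }
  if (counts[["A"]] == 0) {
    stop(sprintf("SampEn undefined (no template matches at m + 1 = %d; B = %g, A = 0)",
                 m + 1L, counts[["B"]]), call. = FALSE)
  }
  -log(counts[["A"]] / counts[["B"]])
}

#' Per-cycle morphological complexity features
#'
#' Computes the morphological feature vector of each respiratory cycle on
#' the (enhanced) signal samples it spans. The three standard feature sets
#' are nested: set 1 is kurtosis and skewness `(chi, xi)`, set 2 adds
#' lacunarity `zeta`, and set 3 adds sample entropy `alpha`. Fields outside
#' the requested set are `NA`. Cycles with degenerate (zero-variance)
#' samples are skipped with a warning rather than failing the pipeline.
#'
#' @param signal A [lung_sound()] object (typically after enhancement).
#' @param cycles A `respiratory_cycles` data frame from
#'   [assemble_cycles()] / [segment_cycles()].
#' @param feature_set `"set1"`, `"set2"` or `"set3"` (default).
#' @param sampen_m,sampen_r Sample-entropy parameters (defaults 2 and
#'   0.2·SD).
#' @param box_lengths,mass_transform Lacunarity parameters, see
#'   [lacunarity_profile()].
#' @param label Optional class tag recorded per row; defaults to the
#'   signal's label.
#' @param source Optional provenance string (e.g. source file).
#' @return A data frame with one row per retained cycle: `cycle_id`,
#'   `start_sample`, `end_sample`, `label`, `source`, `chi`, `xi`, `zeta`,
#'   `alpha`.
#' @export
extract_features <- function(signal, cycles, feature_set = c("set3", "set1", "set2"),
                             sampen_m = 2L, sampen_r = 0.2,
                             box_lengths = NULL, mass_transform = "abs",
                             label = NULL, source = NA_character_) {
  if (!inherits(signal, "lung_sound")) stop("signal must be a lung_sound", call. = FALSE)
  feature_set <- match.arg(feature_set)
  if (is.null(label)) label <- signal$label
  n <- length(signal$samples)
  if (!nrow(cycles)) stop("cycles must be non-empty", call. = FALSE)
  if (any(cycles$start_sample < 0L) || any(cycles$end_sample > n)) {
    stop("cycles extend outside the signal", call. = FALSE)
  }

  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    seg <- signal$samples[(cycles$start_sample[i] + 1L):cycles$end_sample[i]]
    if (length(seg) < 4L || sd(seg) <= 0) {
      warning(sprintf("skipping degenerate cycle %d (zero variance)",
                      cycles$cycle_id[i]))
      return(NULL)
    }
    chi <- excess_kurtosis(seg)
    xi <- skewness(seg)
    zeta <- if (feature_set %in% c("set2", "set3")) {
      lacunarity_profile(seg, box_lengths, mass_transform)$summary
    } else NA_real_
    alpha <- if (feature_set == "set3") {
      tryCatch(sample_entropy(seg, m = sampen_m, r = sampen_r),
               error = function(e) {
                 warning(sprintf("cycle %d: %s", cycles$cycle_id[i],
                                 conditionMessage(e)))
                 NA_real_
               })
    } else NA_real_
    data.frame(cycle_id = cycles$cycle_id[i],
               start_sample = cycles$start_sample[i],
               end_sample = cycles$end_sample[i],
               label = label, source = source,
               chi = chi, xi = xi, zeta = zeta, alpha = alpha)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("all cycles were degenerate; no features extracted", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "feature_set") <- feature_set
  out
}

# Columns that make up each feature set.
feature_set_columns <- function(feature_set) {
  switch(feature_set,
         set1 = c("chi", "xi"),
         set2 = c("chi", "xi", "zeta"),
         set3 = c("chi", "xi", "zeta", "alpha"),
         stop(sprintf("unknown feature set '%s'", feature_set), call. = FALSE))
}
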