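# Independent brute-force oracles used to validate the package's feature
# and classifier implementations. These deliberately use the most direct
# formulation (explicit loops, direct moment sums) and share no code with
# the implementations under test.

oracle_kurtosis <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m4 <- sum((x - mu)^4) / n
  m4 / m2^2 - 3
}

oracle_skewness <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m3 / m2^1.5
}

# Exhaustive gliding-box lacunarity: enumerate every window explicitly.
oracle_lacunarity <- function(x, l, transform = "abs") {
  m <- if (transform == "abs") abs(x) else x^2
  L <- length(m)
  masses <- vapply(seq_len(L - l + 1L), function(i) sum(m[i:(i + l - 1L)]),
                   numeric(1))
  B <- length(masses)
  M1 <- sum(masses) / B
  M2 <- sum(masses^2) / B
  M2 / M1^2
}

# O(N^2) double-loop sample entropy with explicit template construction.
oracle_sampen <- function(x, m, r_abs) {
  N <- length(x)
  nt <- N - m
  cheb <- function(i, j, mm) {
    max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
  }
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (cheb(i, j, m) <= r_abs) {
        B <- B + 1L
        if (cheb(i, j, m + 1L) <= r_abs) A <- A + 1L
      }
    }
  }
  list(A = A, B = B, sampen = -log(A / B))
}

# Independent soft-margin SVM dual solve with kernlab's interior-point QP:
# maximize sum(a) - a' Q a / 2 s.t. 0 <= a <= C, sum(a * y) = 0.
oracle_svm_dual <- function(x, y, C, gamma) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  K <- exp(-gamma * d2)
  Q <- K * tcrossprod(y)
  sol <- kernlab::ipop(c = matrix(-1, n, 1), H = Q,
                       A = matrix(y, 1, n), b = 0,
                       l = matrix(0, n, 1), u = matrix(C, n, 1),
                       r = 0, sigf = 9, maxiter = 200)
  a <- kernlab::primal(sol)
  list(alpha = a, objective = sum(a) - 0.5 * drop(t(a) %*% Q %*% a))
}

# Least-squares residual by QR on the normal equations (independent of the
# SVD pseudoinverse route used by the ELM).
oracle_lstsq_residual <- function(M, d) {
  beta <- qr.coef(qr(M, LAPACK = TRUE), d)
  beta[is.na(beta)] <- 0
  sqrt(sum((M %*% beta - d)^2))
}

# Band power of a plain numeric vector via periodogram bins (independent
# binning of the fft, no shared code with band_power on padded lengths).
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  keep <- f >= lo & f <= hi & f <= rate / 2
  sum(p[keep])
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# 50%/50% energy mixture of breath-band noise and periodic 40 Hz cardiac
# bursts; the canonical scenario for the heart-sound suppression checks.
make_hs_mixture <- function(seed, fs = 8000, dur = 3, phase = 0.1) {
  set.seed(seed)
  n <- dur * fs
  ls <- signal::filtfilt(signal::butter(4, c(150, 900) / (fs / 2), "pass"),
                         rnorm(n))
  ls <- ls / sd(ls)
  hs <- numeric(n)
  for (beat in seq(phase, dur - 0.2, by = 1)) {
    at <- round(beat * fs)
    nb <- round(0.07 * fs)
    w <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / nb))
    hs[at:(at + nb - 1)] <- hs[at:(at + nb - 1)] +
      w * sin(2 * pi * 40 * (seq_len(nb) - 1) / fs)
  }
  hs <- hs / sd(hs)
  list(mix = lung_sound(0.1 * (ls + hs), fs), ls = ls, hs = hs)
}

make_tone <- function(freq, amp = 1, dur = 1, fs = 8000) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  lung_sound(amp * sin(2 * pi * freq * tt), fs)
}
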