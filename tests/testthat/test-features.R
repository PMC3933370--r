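test_that("closed-form moment examples are exact", {
  expect_equal(excess_kurtosis(rep(c(1, -1), 50)), -2)
  expect_equal(skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 2 / sqrt(3))
  set.seed(41)
  x <- rnorm(1e6)
  expect_equal(excess_kurtosis(x), 0, tolerance = 0.05)
})

test_that("moments match direct-summation oracles and flip correctly", {
  expect_equal(excess_kurtosis(c(0, 0, 0, 1, 5)), oracle_kurtosis(c(0, 0, 0, 1, 5)))
  set.seed(42)
  for (k in 1:25) {
    x <- rnorm(sample(10:200, 1)) * runif(1, 0.1, 10)
    expect_equal(excess_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-12)
    expect_equal(skewness(x), oracle_skewness(x), tolerance = 1e-12)
    expect_equal(skewness(-x), -skewness(x))
  }
  expect_error(excess_kurtosis(rep(1, 10)), "degenerate")
  expect_error(skewness(rep(2, 10)), "degenerate")
})

test_that("lacunarity matches exhaustive window enumeration", {
  # worked example: |1,2,3,4|, l = 2 -> masses 3,5,7 -> 83/75
  expect_equal(lacunarity(c(1, 2, 3, 4), 2), 83 / 75)
  expect_equal(lacunarity(rep(0.7, 50), 13), 1, tolerance = 1e-12)
  set.seed(43)
  for (k in 1:25) {
    x <- rnorm(sample(20:200, 1))
    l <- sample.int(length(x) - 1L, 1)
    tf <- sample(c("abs", "square"), 1)
    expect_equal(lacunarity(x, l, tf), oracle_lacunarity(x, l, tf),
                 tolerance = 1e-12)
  }
  expect_error(lacunarity(numeric(10), 3), "undefined")
  expect_error(lacunarity(rnorm(10), 10), "box length")
})

test_that("lacunarity is at least 1 on random nonnegative series", {
  set.seed(44)
  for (k in 1:100) {
    x <- runif(50) * rbinom(50, 1, 0.4)
    if (sum(x) == 0) next
    expect_gte(lacunarity(x, sample.int(20, 1)), 1 - 1e-12)
  }
})

test_that("the lacunarity profile summary behaves like a geometric mean", {
  expect_equal(lacunarity_profile(rep(1, 64))$summary, 1, tolerance = 1e-12)
  x <- abs(rnorm(200))
  expect_equal(lacunarity_profile(x, box_lengths = 7)$summary,
               lacunarity(x, 7))
  set.seed(45)
  burst <- rbinom(300, 1, 0.1) * runif(300)
  pr <- lacunarity_profile(burst)
  expect_gte(pr$summary, min(pr$profile$lacunarity))
  expect_lte(pr$summary, max(pr$profile$lacunarity))
})

test_that("sample entropy handles periodic and constant series", {
  # strictly alternating: every m-match extends to an (m+1)-match
  expect_equal(sample_entropy(rep(c(1, 2), 30), m = 2, r = 0.5,
                              r_mode = "absolute"), 0)
  expect_equal(sample_entropy(rep(5, 30), m = 2, r = 0.1,
                              r_mode = "absolute"), 0)
  expect_error(sample_entropy(rep(5, 30), m = 2, r = 0.2), "zero standard deviation")
  expect_error(sample_entropy(c(0, 100, -50, 200, -100, 300, -200, 400),
                              m = 2, r = 1e-6, r_mode = "absolute"),
               "no template matches")
})

test_that("sample entropy equals the O(N^2) double-loop oracle", {
  set.seed(46)
  x50 <- runif(50)
  o <- oracle_sampen(x50, 2, 0.2 * sd(x50))
  expect_equal(sample_entropy(x50, m = 2, r = 0.2), o$sampen, tolerance = 1e-12)
  for (k in 1:20) {
    x <- rnorm(sample(30:150, 1))
    m <- sample(1:3, 1)
    r_abs <- runif(1, 0.1, 0.5) * sd(x)
    got <- tryCatch(sample_entropy(x, m = m, r = r_abs, r_mode = "absolute"),
                    error = function(e) NA_real_)
    want <- oracle_sampen(x, m, r_abs)
    if (is.na(got)) {
      expect_true(want$A == 0 || want$B == 0)
    } else {
      expect_equal(got, want$sampen, tolerance = 1e-12)
    }
  }
})

test_that("scale-free features are invariant under amplitude scaling", {
  set.seed(47)
  x <- rnorm(400)
  a <- 37.5
  expect_equal(excess_kurtosis(a * x), excess_kurtosis(x), tolerance = 1e-9)
  expect_equal(skewness(a * x), skewness(x), tolerance = 1e-9)
  expect_equal(lacunarity(a * x, 8), lacunarity(x, 8), tolerance = 1e-9)
  expect_equal(sample_entropy(a * x), sample_entropy(x), tolerance = 1e-9)
})

test_that("per-cycle extraction fills exactly the requested feature set", {
  rec <- generate_normal(gen_config(seed = 51, n_cycles = 2))
  cyc <- segment_cycles(rec$signal)
  f1 <- extract_features(rec$signal, cyc, "set1")
  expect_true(all(!is.na(f1$chi)) && all(!is.na(f1$xi)))
  expect_true(all(is.na(f1$zeta)) && all(is.na(f1$alpha)))
  f3 <- extract_features(rec$signal, cyc, "set3")
  expect_true(all(!is.na(f3[c("chi", "xi", "zeta", "alpha")])))
  expect_identical(nrow(f3), nrow(cyc))
  expect_identical(unique(f3$label), "normal")
})

test_that("degenerate cycles are skipped without failing the extraction", {
  sig <- lung_sound(c(rep(0, 4000), rnorm(4000) * 0.1), 8000)
  cyc <- data.frame(cycle_id = 1:2, start_sample = c(0L, 4000L),
                    end_sample = c(4000L, 8000L),
                    transition_sample = c(2000L, 6000L),
                    duration_s = c(0.5, 0.5))
  expect_warning(ft <- extract_features(sig, cyc, "set1"), "degenerate")
  expect_identical(nrow(ft), 1L)
  expect_error(suppressWarnings(
    extract_features(lung_sound(rep(0, 8000), 8000), cyc, "set1")), "all cycles")
})

test_that("features are stable across windows of stationary noise", {
  set.seed(52)
  x <- signal::filtfilt(signal::butter(4, c(150, 900) / 4000, "pass"),
                        rnorm(48000))
  sig <- lung_sound(x / max(abs(x)) * 0.8, 8000)
  cyc <- data.frame(cycle_id = 1:2, start_sample = c(0L, 24000L),
                    end_sample = c(24000L, 48000L),
                    transition_sample = c(12000L, 36000L),
                    duration_s = 3)
  ft <- extract_features(sig, cyc, "set3")
  for (v in c("zeta", "alpha")) {
    expect_lt(abs(ft[[v]][1] - ft[[v]][2]) / abs(ft[[v]][1]), 0.1)
  }
})
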