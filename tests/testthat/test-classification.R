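make_blobs <- function(n_per, sep, d = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per))
  list(x = x, y = rep(c("normal", "abnormal"), each = n_per))
}

test_that("ELM attains zero training error when hidden size equals sample size", {
  b <- make_blobs(5, 1.5, seed = 61) # 10 distinct samples
  m <- elm_train(b$x, b$y, n_hidden = 10, rng_seed = 3)
  p <- elm_predict(m, b$x)
  expect_identical(p$label, b$y)
  # residual of the square system is numerically zero
  xs <- lungmorph:::apply_scaler(lungmorph:::as_feature_matrix(b$x), m$scaler)
  M <- lungmorph:::rbf_hidden(xs, m$centers, m$widths)
  y <- ifelse(b$y == "abnormal", 1, -1)
  expect_lt(sqrt(sum((M %*% m$output_weights - y)^2)), 1e-6)
})

test_that("ELM training is seed-deterministic and order-invariant", {
  b <- make_blobs(20, 2, seed = 62)
  m1 <- elm_train(b$x, b$y, rng_seed = 9)
  m2 <- elm_train(b$x, b$y, rng_seed = 9)
  expect_identical(m1, m2)
  m3 <- elm_train(b$x, b$y, rng_seed = 10)
  expect_false(identical(m1$centers, m3$centers))
  perm <- sample(seq_along(b$y))
  m4 <- elm_train(b$x[perm, ], b$y[perm], rng_seed = 9)
  expect_equal(m4$centers, m1$centers)
  expect_equal(m4$output_weights, m1$output_weights, tolerance = 1e-8)
})

test_that("ELM output weights solve the least-squares problem optimally", {
  set.seed(63)
  for (k in 1:20) {
    n <- sample(15:40, 1)
    d <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n)
    y <- sample(c("normal", "abnormal"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    m <- elm_train(x, y, n_hidden = 10, rng_seed = k)
    xs <- lungmorph:::apply_scaler(lungmorph:::as_feature_matrix(x), m$scaler)
    M <- lungmorph:::rbf_hidden(xs, m$centers, m$widths)
    tgt <- ifelse(y == "abnormal", 1, -1)
    got <- sqrt(sum((M %*% m$output_weights - tgt)^2))
    expect_lt(got, oracle_lstsq_residual(M, tgt) + 1e-8)
  }
})

test_that("ELM has the capacity to fit an XOR pattern", {
  set.seed(64)
  base <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  x <- base[rep(1:4, each = 40), ] + matrix(rnorm(320, sd = 0.08), 160)
  y <- rep(c("normal", "normal", "abnormal", "abnormal"), each = 40)
  acc <- vapply(1:10, function(s) {
    m <- elm_train(x, y, n_hidden = 10, rng_seed = s)
    mean(elm_predict(m, x)$label == y)
  }, numeric(1))
  expect_gte(sum(acc >= 0.95), 8)
})

test_that("ELM scores are smooth and match a from-scratch forward pass", {
  b <- make_blobs(15, 2, seed = 65)
  m <- elm_train(b$x, b$y, rng_seed = 2)
  x0 <- b$x[3, , drop = FALSE]
  s0 <- elm_predict(m, x0)$score
  s1 <- elm_predict(m, x0 + 1e-9)$score
  expect_lt(abs(s1 - s0), 1e-6)
  # independent forward pass with explicit loops
  xs <- (x0[1, ] - m$scaler$mu) / m$scaler$sd
  h <- vapply(seq_len(m$n_hidden), function(j) {
    exp(-m$widths[j] * sum((xs - m$centers[j, ])^2))
  }, numeric(1))
  expect_lt(abs(sum(h * m$output_weights) - s0), 1e-10)
  expect_error(elm_predict(m, cbind(b$x, 1)), "dimension mismatch")
  expect_error(elm_train(b$x, rep("normal", nrow(b$x))), "both classes")
})

test_that("the SVM separates the minimal two-point problem", {
  x <- rbind(c(0, 0), c(2, 2))
  m <- svm_train(x, c("normal", "abnormal"), C = 1)
  expect_identical(nrow(m$support_vectors), 2L)
  expect_identical(svm_predict(m, x)$label, c("normal", "abnormal"))
})

test_that("the SVM classifies separable blobs perfectly at large C", {
  b <- make_blobs(20, 6, seed = 66)
  m <- svm_train(b$x, b$y, C = 1e3)
  expect_identical(svm_predict(m, b$x)$label, b$y)
})

test_that("SVM dual solution satisfies the box and equality constraints", {
  b <- make_blobs(15, 1.2, seed = 67)
  for (C in c(0.5, 1, 10)) {
    m <- svm_train(b$x, b$y, C = C)
    expect_true(all(abs(m$dual_coefs) <= C + 1e-8))
    expect_lt(abs(sum(m$dual_coefs)), 1e-6)
  }
})

test_that("SVM dual objective matches an independent QP solver", {
  set.seed(68)
  for (k in 1:5) {
    n <- 20
    x <- matrix(rnorm(n * 2), n)
    y <- rep(c(1, -1), each = n / 2)
    x[y == 1, ] <- x[y == 1, ] + 1.2
    C <- 1
    m <- svm_train(x, ifelse(y > 0, "abnormal", "normal"), C = C)
    xs <- lungmorph:::apply_scaler(lungmorph:::as_feature_matrix(x), m$scaler)
    o <- oracle_svm_dual(xs, y, C, m$gamma)
    expect_equal(svm_dual_objective(m), o$objective, tolerance = 1e-6)
  }
})

test_that("KKT margins hold at the reported solution", {
  b <- make_blobs(25, 2.5, seed = 69)
  m <- svm_train(b$x, b$y, C = 1)
  f <- svm_predict(m, b$x)$margin
  y <- ifelse(b$y == "abnormal", 1, -1)
  margins <- y * f
  # training points with alpha = 0 lie at or beyond the +/-1 margin
  expect_true(all(margins[-m$sv_index] >= 1 - 1e-4))
  # margin support vectors (0 < alpha < C) sit on the margin
  on_margin <- m$sv_index[abs(m$dual_coefs) > 1e-6 * m$C &
                            abs(m$dual_coefs) < m$C * (1 - 1e-6)]
  expect_gt(length(on_margin), 0L)
  expect_true(all(abs(margins[on_margin] - 1) <= 1e-4))
})

test_that("svm_predict agrees with a direct kernel-sum evaluation", {
  b <- make_blobs(15, 1.5, seed = 70)
  m <- svm_train(b$x, b$y)
  xq <- matrix(rnorm(10), 5)
  got <- svm_predict(m, xq)$margin
  xs <- sweep(sweep(xq, 2, m$scaler$mu), 2, m$scaler$sd, "/")
  want <- vapply(seq_len(5), function(i) {
    sum(vapply(seq_len(nrow(m$support_vectors)), function(j) {
      m$dual_coefs[j] *
        exp(-m$gamma * sum((xs[i, ] - m$support_vectors[j, ])^2))
    }, numeric(1))) + m$bias
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(svm_predict(m, xq[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("models survive a JSON save/load round trip exactly", {
  b <- make_blobs(12, 2, seed = 71)
  for (trainer in list(function() elm_train(b$x, b$y, rng_seed = 4),
                       function() svm_train(b$x, b$y))) {
    m <- trainer()
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    # decimal serialization round-trips to the last couple of ulps
    expect_equal(m2, m, tolerance = 1e-13)
    if (inherits(m, "elm_model")) {
      p <- elm_predict(m, b$x); p2 <- elm_predict(m2, b$x)
      expect_identical(p2$label, p$label)
      expect_equal(p2$score, p$score, tolerance = 1e-12)
    } else {
      p <- svm_predict(m, b$x); p2 <- svm_predict(m2, b$x)
      expect_identical(p2$label, p$label)
      expect_equal(p2$margin, p$margin, tolerance = 1e-12)
    }
  }
})
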