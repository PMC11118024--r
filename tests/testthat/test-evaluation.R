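test_that("classification metrics match hand-computed contingency values", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$accuracy, 1)
  expect_equal(m$kappa, 1)

  m <- classification_metrics(c(1, 0, 0, 0), c(1, 1, 0, 0), positive = "1")
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-10)
  expect_equal(m$kappa, 0.5)

  expect_warning(m1 <- classification_metrics(c(1, 1), c(1, 0)),
                 "kappa undefined")
  expect_true(is.nan(m1$kappa))
})

test_that("kappa of shuffled labels is centred on zero", {
  withr::local_seed(31)
  truth <- factor(rep(c("a", "b"), each = 50))
  ks <- replicate(200, {
    suppressWarnings(
      classification_metrics(truth, sample(truth))$kappa)
  })
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("e1071")
  withr::local_seed(32)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    truth <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                    levels = c("a", "b", "c"))
    pred <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                   levels = c("a", "b", "c"))
    if (length(unique(truth)) < 2) next
    m <- suppressWarnings(classification_metrics(truth, pred))
    ref <- e1071::classAgreement(table(truth, pred))
    expect_equal(m$accuracy, ref$diag, tolerance = 1e-12)
    expect_equal(m$kappa, ref$kappa, tolerance = 1e-12)
  }
})

test_that("wavelet coherence is 1 on self, symmetric, and in [0, 1]", {
  withr::local_seed(33)
  x <- rnorm(256)
  y <- rnorm(256)
  self <- wavelet_coherence(x, x)
  expect_equal(dim(self$matrix), c(32, 256))
  expect_lt(max(abs(self$matrix - 1)), 1e-6)

  a <- wavelet_coherence(x, y)
  b <- wavelet_coherence(y, x)
  expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
  expect_true(all(a$matrix >= 0 & a$matrix <= 1))
  expect_lt(a$scalar, self$scalar)

  expect_error(wavelet_coherence(x, y[1:100]), "length")
  expect_error(wavelet_coherence(rnorm(16), rnorm(16)), "32")
  expect_error(wavelet_coherence(rep(1, 64), rnorm(64)), "constant")
})

test_that("the coherence peak tracks a shared narrowband component", {
  withr::local_seed(34)
  t <- seq_len(512)
  shared <- sin(2 * pi * t / 32)
  x <- shared + 0.3 * rnorm(512)
  y <- shared + 0.3 * rnorm(512)
  wc <- wavelet_coherence(x, y)
  prof <- rowMeans(wc$matrix)
  peak_period <- wc$periods[which.max(prof)]
  expect_gt(peak_period, 32 / 1.5)
  expect_lt(peak_period, 32 * 1.5)
})

test_that("scalar collapse is mean over time then scales", {
  expect_equal(wc_scalar(matrix(1, 4, 7)), 1)
  expect_equal(wc_scalar(matrix(0, 4, 7)), 0)
  expect_equal(wc_scalar(matrix(c(1, 0.5, 0, 0.5), 2, 2)), 0.5)
})

test_that("multi-channel and group scores reduce as documented", {
  withr::local_seed(35)
  x <- matrix(rnorm(3 * 128), 3)
  expect_equal(wc_multidim(x, x), 1, tolerance = 1e-6)

  y <- matrix(rnorm(3 * 128), 3)
  half <- rbind(x[1:2, ], y[3, , drop = FALSE])
  s_ident <- wc_multidim(x, x)
  s_noise <- wc_multidim(x, y)
  s_half <- wc_multidim(x, half)
  expect_gt(s_half, s_noise)
  expect_lt(s_half, s_ident)

  p <- sample(3)
  expect_equal(wc_multidim(x[p, ], y[p, ]), s_noise, tolerance = 1e-12)

  A <- list(x, x)
  expect_equal(wc_groups(A, A), 1, tolerance = 1e-6)
  B <- list(y, half, x)
  hand <- mean(c(wc_multidim(x, y), wc_multidim(x, half), wc_multidim(x, x)))
  expect_equal(wc_groups(list(x), B), hand, tolerance = 1e-12)
  # |A| = 2, |B| = 3 is the mean of the six pair scores
  hand6 <- mean(vapply(A, function(a) {
    mean(vapply(B, function(b) wc_multidim(a, b), numeric(1)))
  }, numeric(1)))
  expect_equal(wc_groups(A, B), hand6, tolerance = 1e-12)
})

test_that("feature profiles expose one band-frame series per electrode", {
  x <- random_features(seed = 36)[, , , , 1]
  pr <- feature_profile(x)
  expect_equal(dim(pr), c(17, 80))
  g <- electrode_grid()
  expect_equal(pr[3, 1:5], x[g$row[3], g$col[3], , 1])
})
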