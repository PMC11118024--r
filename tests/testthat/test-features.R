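test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  t <- (seq_len(1600) - 1) / 200
  tone10 <- sin(2 * pi * 10 * t)
  ya <- bandpass_filter(tone10, 8, 14, 200)
  yg <- bandpass_filter(tone10, 31, 51, 200)
  expect_lt(abs(stats::sd(ya) / stats::sd(tone10) - 1), 0.1)
  expect_lt(10 * log10(stats::var(yg) / stats::var(tone10)), -20)

  # >= 20 dB one octave beyond the band edge (28 Hz vs alpha's 14 Hz edge)
  tone28 <- sin(2 * pi * 28 * t)
  y28 <- bandpass_filter(tone28, 8, 14, 200)
  expect_lt(10 * log10(stats::var(y28) / stats::var(tone28)), -20)

  expect_identical(bandpass_filter(rep(0, 400), 8, 14, 200), rep(0, 400))
  expect_error(bandpass_filter(tone10, 31, 120, 200), "Nyquist")
})

test_that("spectral band-pass agrees with filtfilt away from edges", {
  withr::local_seed(4)
  x <- rnorm(1600)
  y1 <- bandpass_filter(x, 8, 14, 200)
  bf <- signal::butter(4, c(8, 14) / 100, type = "pass")
  y2 <- signal::filtfilt(bf, x)
  mid <- 300:1300
  expect_lt(max(abs(y1[mid] - y2[mid])), 1e-3 * stats::sd(y2[mid]) * 10)
})

test_that("differential entropy matches the Gaussian closed form", {
  withr::local_seed(7)
  x <- rnorm(1e5)
  expect_lt(abs(differential_entropy(x) - 0.5 * log(2 * pi * exp(1))),
            0.02 * 0.5 * log(2 * pi * exp(1)))
  # doubling sigma adds exactly ln 2 for the same underlying sample
  expect_equal(differential_entropy(2 * x) - differential_entropy(x),
               log(2), tolerance = 1e-10)

  # quadrature oracle: entropy of the Gaussian fitted to a uniform sample
  u <- runif(1e5)
  sig <- stats::sd(u)
  f <- function(z) {
    d <- stats::dnorm(z, mean(u), sig)
    ifelse(d > 0, -d * log(d), 0)
  }
  oracle <- stats::integrate(f, mean(u) - 10 * sig, mean(u) + 10 * sig,
                             rel.tol = 1e-10)$value
  expect_equal(differential_entropy(u), oracle, tolerance = 1e-4)

  expect_warning(de0 <- differential_entropy(rep(1, 100)), "floored")
  expect_equal(de0, 0.5 * log(2 * pi * exp(1) * 1e-12))
  expect_error(differential_entropy(1), "at least 2")
})

test_that("array-form differential entropy matches the per-frame scalar", {
  withr::local_seed(8)
  fr <- array(rnorm(3 * 4 * 50), c(3, 4, 50))
  de <- differential_entropy(fr)
  expect_equal(dim(de), c(3, 4))
  expect_equal(de[2, 3], differential_entropy(fr[2, 3, ]))
})

test_that("grid mapping conserves totals and zeroes unmapped cells", {
  g <- electrode_grid()
  ch <- vigilance_channels()
  de <- array(1, c(17, 5, 16))
  f4 <- map_to_grid(de, g, ch)
  expect_equal(dim(f4), c(6, 9, 5, 16))
  expect_equal(apply(f4, c(3, 4), sum), matrix(17, 5, 16),
               ignore_attr = TRUE)

  de1 <- array(0, c(17, 5, 16))
  de1[5, , ] <- 3
  f1 <- map_to_grid(de1, g, ch)
  expect_equal(sum(f1 != 0), 5 * 16)

  # unmapped cells are exactly zero for random inputs
  withr::local_seed(9)
  fr <- map_to_grid(array(rnorm(17 * 5 * 16), c(17, 5, 16)), g, ch)
  mask <- grid_mask(g)
  expect_true(all(fr[!array(mask, dim(fr))] == 0))

  expect_error(map_to_grid(de, g, c(ch[-1], "XX")), "XX")
})

test_that("channel permutation with matching grid leaves features unchanged", {
  withr::local_seed(10)
  g <- electrode_grid()
  ch <- vigilance_channels()
  seg <- matrix(rnorm(17 * 1600), 17)
  f1 <- build_features(seg, 200, ch, g)
  p <- sample(17)
  f2 <- build_features(seg[p, ], 200, ch[p], g)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("build_features localises a posterior alpha source", {
  withr::local_seed(11)
  g <- electrode_grid()
  ch <- vigilance_channels()
  t <- (seq_len(1600) - 1) / 200
  seg <- matrix(rnorm(17 * 1600, sd = 1), 17)
  post <- grep("^(PO|O)", ch)
  seg[post, ] <- seg[post, ] + 20 * sin(2 * pi * 10 * outer(rep(1, length(post)), t))
  f4 <- build_features(seg, 200, ch, g)
  expect_equal(dim(f4), c(6, 9, 5, 16))
  alpha <- f4[, , 3, 1]
  peak <- which(alpha == max(alpha), arr.ind = TRUE)
  hit <- g[g$row == peak[1] & g$col == peak[2], ]
  expect_match(hit$channel, "^(PO|O)")

  # determinism and identical frames give identical entropies
  expect_identical(f4, build_features(seg, 200, ch, g))
  rep_seg <- matrix(rep(seg[, 1:100], 16), 17)
  fr <- build_features(rep_seg, 200, ch, g)
  expect_lt(max(abs(sweep(fr, c(1, 2, 3), fr[, , , 1]))), 1e-9)
})

test_that("feature scaling standardises mapped cells only", {
  ds <- small_dataset()
  mask <- grid_mask(ds$grid)
  mask5 <- array(mask, dim(ds$x))
  vals <- ds$x[mask5]
  expect_equal(mean(vals), 0, tolerance = 1e-8)
  expect_equal(stats::sd(vals), 1, tolerance = 1e-6)
  expect_true(all(ds$x[!mask5] == 0))
  # unscaling restores the raw entropies
  raw <- unscale_features(ds$x, ds$scaler)
  expect_equal(stats::sd(raw[mask5]) / ds$scaler$sd, 1, tolerance = 1e-6)
})
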