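# The tape engine is validated against central finite differences, both
# for first-order gradients across the primitive set and for the double
# backprop the gradient penalty relies on.

fd_grad <- function(f, x0, h = 1e-6) {
  g <- x0 * 0
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

leaf <- fatiguegan:::ad_leaf
val <- fatiguegan:::ad_value

test_that("first-order gradients match finite differences", {
  withr::local_seed(1)
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(rnorm(6), 3, 2)
  W0 <- matrix(rnorm(8), 4, 2)
  ad <- fatiguegan:::`ad_sum`

  cases <- list(
    matmul_sigmoid = function(Wn) {
      fatiguegan:::ad_sum(fatiguegan:::ad_mul(
        fatiguegan:::ad_sigmoid(fatiguegan:::ad_matmul(leaf(X), Wn)),
        leaf(Y)))
    },
    softmax_log = function(Wn) {
      sm <- fatiguegan:::ad_softmax_rows(fatiguegan:::ad_matmul(leaf(X), Wn))
      fatiguegan:::ad_sum(fatiguegan:::ad_mul(fatiguegan:::ad_log(
        fatiguegan:::ad_cadd(sm, 1e-9)), leaf(Y)))
    },
    layernorm = function(Wn) {
      h <- fatiguegan:::ad_matmul(leaf(X), Wn)
      ln <- fatiguegan:::ad_layernorm(h, leaf(matrix(1, 1, 2)),
                                      leaf(matrix(0.1, 1, 2)))
      fatiguegan:::ad_sum(fatiguegan:::ad_mul(ln, leaf(Y)))
    },
    gelu_scalecols = function(Wn) {
      h <- fatiguegan:::ad_gelu(fatiguegan:::ad_matmul(leaf(X), Wn))
      fatiguegan:::ad_sum(fatiguegan:::ad_scale_cols(
        h, leaf(matrix(c(0.5, -2), 1))))
    }
  )
  for (nm in names(cases)) {
    Wn <- leaf(W0)
    g <- fatiguegan:::ad_grad(cases[[nm]](Wn), list(Wn))[[1]]
    num <- fd_grad(function(w) val(cases[[nm]](leaf(w))), W0)
    expect_lt(max(abs(val(g) - num)), 1e-6, label = nm)
  }
})

test_that("fused depthwise kernel matches a naive R convolution and FD", {
  withr::local_seed(2)
  ops <- fatiguegan:::.shift_ops(3, 4)
  S <- 12; G <- 2; C <- 3
  x0 <- matrix(rnorm(S * G * C), S * G, C)
  W0 <- matrix(rnorm(9 * C), 9, C)
  b0 <- matrix(rnorm(C), 1, C)

  naive <- matrix(rep(b0, each = S * G), S * G, C)
  for (tp in 1:9) for (g in 1:G) for (s in 1:S) {
    src <- ops$fwd[s, tp]
    if (src > 0) {
      naive[(g - 1) * S + s, ] <- naive[(g - 1) * S + s, ] +
        W0[tp, ] * x0[(g - 1) * S + src, ]
    }
  }
  node <- fatiguegan:::ad_dwmix(leaf(x0), leaf(W0), ops$fwd, ops$bwd,
                                leaf(b0))
  expect_equal(val(node), naive, tolerance = 1e-12)

  f <- function(Wv) {
    n <- fatiguegan:::ad_dwmix(leaf(x0), leaf(Wv), ops$fwd, ops$bwd,
                               leaf(b0))
    val(fatiguegan:::ad_sum(fatiguegan:::ad_mul(n, n)))
  }
  Wn <- leaf(W0)
  nn <- fatiguegan:::ad_dwmix(leaf(x0), Wn, ops$fwd, ops$bwd, leaf(b0))
  g <- fatiguegan:::ad_grad(fatiguegan:::ad_sum(fatiguegan:::ad_mul(nn, nn)),
                            list(Wn))[[1]]
  expect_lt(max(abs(val(g) - fd_grad(f, W0))), 1e-5)
})

test_that("double backprop through an input-gradient norm matches FD", {
  withr::local_seed(3)
  x0 <- matrix(rnorm(4), 1, 4)
  W0 <- matrix(rnorm(8), 4, 2)
  v <- matrix(rnorm(2), 2, 1)

  penalty <- function(Wn) {
    xn <- leaf(x0)
    D <- fatiguegan:::ad_sum(fatiguegan:::ad_matmul(
      fatiguegan:::ad_sigmoid(fatiguegan:::ad_matmul(xn, Wn)),
      leaf(v)))
    gx <- fatiguegan:::ad_grad(D, list(xn))[[1]]
    nrm <- fatiguegan:::ad_sqrt(fatiguegan:::ad_sum(
      fatiguegan:::ad_mul(gx, gx)))
    dev <- fatiguegan:::ad_cadd(nrm, -1)
    fatiguegan:::ad_mul(dev, dev)
  }
  Wn <- leaf(W0)
  g <- fatiguegan:::ad_grad(penalty(Wn), list(Wn))[[1]]
  num <- fd_grad(function(w) val(penalty(leaf(w))), W0)
  expect_lt(max(abs(val(g) - num)), 1e-6)
})

test_that("gradients accumulate over shared subexpressions and reshapes", {
  withr::local_seed(4)
  x0 <- matrix(rnorm(24), 6, 4)
  f <- function(xn) {
    a <- fatiguegan:::ad_reshape(xn, c(4, 6))
    b <- fatiguegan:::ad_aperm(fatiguegan:::ad_reshape(xn, c(2, 3, 4)),
                               c(3, 1, 2))
    fatiguegan:::ad_add(
      fatiguegan:::ad_sum(fatiguegan:::ad_mul(a, a)),
      fatiguegan:::ad_sum(fatiguegan:::ad_exp(
        fatiguegan:::ad_cmul(fatiguegan:::ad_reshape(b, c(6, 4)), 0.3))))
  }
  xn <- leaf(x0)
  g <- fatiguegan:::ad_grad(f(xn), list(xn))[[1]]
  num <- fd_grad(function(x) val(f(leaf(x))), x0)
  expect_lt(max(abs(val(g) - num)), 1e-6)
})
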