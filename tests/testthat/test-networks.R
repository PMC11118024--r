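full_cfg <- model_config()

test_that("attention modules preserve shape and gate as documented", {
  x <- random_features(seed = 21)[, , , , 1]
  out <- attention_module(x, cfg = full_cfg)
  expect_equal(dim(out), c(6, 9, 5, 16))
  expect_false(isTRUE(all.equal(out, x)))        # non-identity in general

  # zero input stays zero under multiplicative gating
  z0 <- array(0, c(6, 9, 5, 16))
  expect_equal(attention_module(z0, cfg = full_cfg), z0)
  expect_equal(spatial_attention(z0, cfg = full_cfg), z0)
  expect_equal(frequency_attention(z0, cfg = full_cfg), z0)

  # saturated gates (zero weights, large bias) reproduce the input exactly
  sat <- withr::with_seed(1, fatiguegan:::.init_attention(list(), "att", 5))
  sat <- lapply(sat, function(p) p * 0)
  sat$att.sp.b <- matrix(50, 1, 1)
  sat$att.fq2.b <- matrix(50, 1, 5)
  expect_equal(attention_module(x, params = sat, cfg = full_cfg), x,
               tolerance = 1e-12)
})

test_that("frequency attention weights ignore spatial permutations", {
  x <- random_features(seed = 22)[, , , , 1]
  perm_r <- sample(6); perm_c <- sample(9)
  xp <- x[perm_r, perm_c, , ]
  # gates are global over space, so gated/input ratios match cellwise
  g1 <- frequency_attention(x, cfg = full_cfg, seed = 3) / x
  g2 <- frequency_attention(xp, cfg = full_cfg, seed = 3) / xp
  expect_equal(g1[perm_r, perm_c, , ], g2, tolerance = 1e-10)
})

test_that("bottleneck block honours its residual/identity contracts", {
  x <- withr::with_seed(23, array(rnorm(6 * 9 * 64), c(6, 9, 64)))
  # all-zero weights with matching channels: pure residual identity
  p0 <- withr::with_seed(1, fatiguegan:::.init_block(list(), "blk", 64, 64,
                                                     6))
  p0 <- lapply(p0, function(w) w * 0)
  expect_equal(bottleneck_block(x, 64, 64, k = 6, params = p0), x)

  # ReLU6 clamps the expansion activations at 6
  r <- fatiguegan:::cpp_relu6(matrix(c(-1, 0.5, 6.5, 7), 2))
  expect_equal(as.vector(r$value), c(0, 0.5, 6, 6))

  out <- bottleneck_block(x, 64, 48, k = 6)
  expect_equal(dim(out), c(6, 9, 48))

  # closed-form parameter count for C = 64, k = 6, C' = 64:
  # 64*384 + 384*9 + 384*64 + biases (384 + 384 + 64)
  p <- withr::with_seed(1, fatiguegan:::.init_block(list(), "blk", 64, 64,
                                                    6))
  expect_equal(count_params(p),
               64 * 384 + 384 * 9 + 384 * 64 + 384 + 384 + 64)
})

test_that("discriminator trunk maps features to 64 x 16 tokens", {
  x <- random_features(seed = 24)[, , , , 1]
  q <- bottleneck_module_d(x, cfg = full_cfg)
  expect_equal(dim(q), c(64, 16))

  # the 3x4 pooling condenses the 6x9 grid to 2x2 cells
  expect_equal(dim(fatiguegan:::.pool_op(full_cfg)), c(4, 54))
  expect_equal(full_cfg$pooled_h, 2)
  expect_equal(full_cfg$pooled_w, 2)

  # frames are processed independently: permuting frames permutes columns
  perm <- withr::with_seed(5, sample(16))
  q2 <- bottleneck_module_d(x[, , , perm], cfg = full_cfg)
  expect_equal(q2, q[, perm], tolerance = 1e-10)
})

test_that("generator trunk preserves the tensor shape with bounded output", {
  x <- random_features(seed = 25)[, , , , 1]
  y <- bottleneck_module_g(x, cfg = full_cfg)
  expect_equal(dim(y), c(6, 9, 5, 16))
  expect_true(all(is.finite(y)))
  expect_identical(y, bottleneck_module_g(x, cfg = full_cfg))
})

test_that("transformer encoder preserves shape and has exact identity mode", {
  tok <- withr::with_seed(26, matrix(rnorm(64 * 16), 64, 16))
  out <- transformer_encoder(tok, cfg = full_cfg)
  expect_equal(dim(out), c(64, 16))

  # zeroed output projections + zero positional embedding: pure residual
  p <- withr::with_seed(1, fatiguegan:::.init_transformer(list(), "tf",
                                                          full_cfg))
  for (nm in grep("(\\.o\\.|mlp2|pos)", names(p), value = TRUE)) {
    p[[nm]] <- p[[nm]] * 0
  }
  cfg0 <- model_config(dropout = 0)
  expect_equal(transformer_encoder(tok, params = p, cfg = cfg0), tok,
               tolerance = 1e-12)

  # token-permutation equivariance without positional encoding
  cfg_np <- model_config(positional = FALSE, dropout = 0)
  perm <- withr::with_seed(6, sample(16))
  o1 <- transformer_encoder(tok, params = p2 <- withr::with_seed(
    2, fatiguegan:::.init_transformer(list(), "tf", cfg_np)), cfg = cfg_np)
  o2 <- transformer_encoder(tok[, perm], params = p2, cfg = cfg_np)
  expect_equal(o2, o1[, perm], tolerance = 1e-10)

  bad <- model_config()
  bad$heads <- 5L
  expect_error(transformer_encoder(tok, cfg = model_config(heads = 5)),
               "divisible")
})

test_that("generator and discriminator satisfy their end-to-end contracts", {
  G <- init_generator(full_cfg, seed = 31)
  D <- init_discriminator(full_cfg, seed = 32)
  z <- withr::with_seed(33, matrix(rnorm(3 * full_cfg$nz), 3))
  lab <- factor(c("awake", "fatigue", "awake"))

  y <- generator_forward(G, z, lab)
  expect_equal(dim(y), c(6, 9, 5, 16, 3))
  expect_identical(y, generator_forward(G, z, lab))   # eval determinism
  # generated tensors satisfy the unmapped-cells-are-zero invariant
  mask <- grid_mask(electrode_grid())
  expect_true(all(y[!array(mask, dim(y))] == 0))

  out <- discriminator_forward(D, y)
  expect_length(out$adv, 3)
  expect_true(is.numeric(out$adv))
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)

  # no cross-sample mixing: single-sample forward equals batched forward
  o1 <- discriminator_forward(D, y[, , , , 1])
  expect_equal(o1$adv, out$adv[1], tolerance = 1e-10)
  expect_equal(o1$probs[1, ], out$probs[1, ], tolerance = 1e-10)
})

test_that("every parameter tensor receives gradient on a random batch", {
  D <- init_discriminator(full_cfg, seed = 41)
  G <- init_generator(full_cfg, seed = 42)
  x <- random_features(batch = 2, seed = 43)

  P <- fatiguegan:::wrap_params(D$params, leaf = TRUE)
  out <- fatiguegan:::.fwd_discriminator(
    fatiguegan:::ad_const(fatiguegan:::features_to_conv(x, full_cfg)),
    P, full_cfg, 2, train = FALSE)
  loss <- fatiguegan:::ad_add(
    fatiguegan:::ad_mean(out$adv),
    fatiguegan:::ad_mean(fatiguegan:::ad_log(
      fatiguegan:::ad_cadd(out$probs, 1e-9))))
  gs <- fatiguegan:::ad_grad(loss, P)
  nz <- vapply(gs, function(g) any(fatiguegan:::ad_value(g) != 0), TRUE)
  expect_true(all(nz), info = paste(names(D$params)[!nz], collapse = ", "))

  PG <- fatiguegan:::wrap_params(G$params, leaf = TRUE)
  z <- fatiguegan:::ad_const(withr::with_seed(44,
    matrix(rnorm(2 * full_cfg$nz), 2)))
  oh <- fatiguegan:::ad_const(one_hot(factor(c("a", "b")), 2))
  fake <- fatiguegan:::.fwd_generator(z, oh, PG, full_cfg, 2,
                                      train = FALSE)
  gsg <- fatiguegan:::ad_grad(fatiguegan:::ad_sum(
    fatiguegan:::ad_mul(fake, fake)), PG)
  nzg <- vapply(gsg, function(g) any(fatiguegan:::ad_value(g) != 0), TRUE)
  expect_true(all(nzg),
              info = paste(names(G$params)[!nzg], collapse = ", "))
})

test_that("the FLOP audit reports the documented complexity", {
  fl <- count_flops(full_cfg)
  expect_true(all(c("component", "flops") %in% names(fl)))
  total <- sum(fl$flops)
  expect_gt(total / 1e9, 0.1)
  expect_lt(total / 1e9, 0.45)
  # compact profile is at least an order of magnitude lighter
  expect_lt(sum(count_flops(model_config("compact"))$flops), total / 10)
  # parameter counter agrees with structural expectations
  expect_equal(count_params(init_discriminator(full_cfg)),
               count_params(init_discriminator(full_cfg)$params))
})
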