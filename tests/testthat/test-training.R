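test_that("gradient penalty matches the closed form for linear critics", {
  withr::local_seed(71)
  B <- 6; p <- 10
  real <- matrix(rnorm(B * p), B)
  fake <- matrix(rnorm(B * p), B)

  lin_critic <- function(w) {
    function(xn) fatiguegan:::ad_matmul(xn, fatiguegan:::ad_const(
      matrix(w, ncol = 1)))
  }
  w1 <- rnorm(p); w1 <- w1 / sqrt(sum(w1^2))          # unit norm
  gp1 <- gradient_penalty(lin_critic(w1), real, fake, lambda_gp = 10)
  expect_lt(abs(gp1$penalty), 1e-10)

  w3 <- 3 * w1                                        # norm 3
  gp3 <- gradient_penalty(lin_critic(w3), real, fake, lambda_gp = 10)
  expect_equal(gp3$penalty, 10 * (3 - 1)^2, tolerance = 1e-5)
  expect_equal(gp3$grad_norms, rep(3, B), tolerance = 1e-6)

  # identical real and fake batches cancel the Wasserstein gap
  al <- adversarial_loss(lin_critic(w1), real, real, lambda_gp = 10)
  expect_equal(al$wasserstein, 0, tolerance = 1e-12)
  expect_equal(al$total, al$gp, tolerance = 1e-12)
})

test_that("cross-entropy terms evaluate hand-set probability tables", {
  ce <- function(p, labels) {
    as.numeric(fatiguegan:::ad_value(fatiguegan:::.ce_node(
      fatiguegan:::ad_const(p), labels, ncol(p))))
  }
  expect_equal(ce(rbind(c(1, 0), c(0, 1)), c(1, 2)), 0, tolerance = 1e-9)
  expect_equal(ce(matrix(0.5, 4, 2), c(1, 2, 1, 2)), log(2),
               tolerance = 1e-9)
  expect_equal(ce(rbind(c(0.8, 0.2)), 1), -log(0.8), tolerance = 1e-9)

  # the model-facing wrappers agree with direct evaluation
  cfg <- model_config("compact")
  D <- init_discriminator(cfg, seed = 72)
  x <- random_features(batch = 4, seed = 73)
  lab <- factor(c("a", "b", "a", "b"))
  probs <- discriminator_forward(D, x)$probs
  hand <- mean(-log(probs[cbind(1:4, as.integer(lab))]))
  expect_equal(classification_loss_real(D, x, lab), hand,
               tolerance = 1e-9)

  G <- init_generator(cfg, seed = 74)
  z <- withr::with_seed(75, matrix(rnorm(4 * cfg$nz), 4))
  fake <- generator_forward(G, z, lab)
  expect_equal(classification_loss_fake(D, G, z, lab),
               classification_loss_real(D, fake, lab), tolerance = 1e-9)
})

test_that("train_step composes its losses exactly and is seed-deterministic", {
  ds <- small_dataset()
  cfg <- model_config("compact")
  run <- function(lambda = 1) {
    tc <- train_config(batch = 8, seed = 76, lambda = lambda,
                       lr_g = 2e-4, lr_d = 4e-4)
    gan <- gan_init(cfg, tc)
    withr::with_seed(76, {
      for (i in 1:2) {
        gan <- train_step(gan, ds$x[, , , , (8 * i - 7):(8 * i)],
                          ds$labels[(8 * i - 7):(8 * i)])
      }
    })
    gan
  }
  g1 <- run()
  # composition identity: L_D = -(wasserstein gap) + GP + lambda * L_cls_r
  expect_equal(g1$last$l_d,
               -g1$last$l_adv + g1$last$gp + g1$last$lambda * g1$last$l_cls_r,
               tolerance = 1e-6)

  g2 <- run()
  expect_identical(g1$last, g2$last)               # bitwise determinism
  expect_equal(g1$G$params, g2$G$params, tolerance = 0)

  # lambda = 0 degenerates to plain WGAN-GP: classification terms carry
  # no weight in the composed losses
  g0 <- run(lambda = 0)
  expect_equal(g0$last$l_d, -g0$last$l_adv + g0$last$gp, tolerance = 1e-6)
  expect_gt(g0$last$l_cls_r, 0)                    # still reported
})

test_that("the class head learns real data within a short training run", {
  gan <- small_gan()
  ds <- small_dataset()
  # after 150 steps the discriminator classifies the training data well
  # above chance
  pred <- predict_classifier(list(D = gan$D, model_cfg = gan$model_cfg,
                                  levels = gan$levels), ds)
  acc <- mean(pred$class == ds$labels)
  expect_gt(acc, 0.75)
  # and the logged real-classification loss dropped along the way
  expect_lt(mean(tail(gan$log$l_cls_r, 20)), mean(head(gan$log$l_cls_r, 20)))
  expect_true(all(is.finite(gan$log$l_d)))
})

test_that("generation from a trained model is conditional and reproducible", {
  gan <- small_gan()
  z_lab <- rep(c("awake", "fatigue"), 8)
  a <- generate_samples(gan, z_lab, seed = 9)
  b <- generate_samples(gan, z_lab, seed = 9)
  expect_identical(a$x, b$x)
  # same latent draw, swapped labels: outputs differ for a trained model
  flipped <- generate_samples(gan, rev(z_lab), seed = 9)
  expect_gt(mean(abs(a$x - flipped$x)), 1e-4)
})

test_that("cross-validation folds partition the data with stratification", {
  ds <- small_dataset()
  sub <- subset_dataset(ds, 1:60)
  cv <- crossvalidate(sub, folds = 3, seed = 77, epochs = 1, batch = 16,
                      lr = 1e-3, model_cfg = model_config("compact"))
  expect_s3_class(cv$per_fold, "tbl_df")
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$summary$accuracy, mean(cv$per_fold$accuracy))
  expect_equal(cv$summary$kappa, mean(cv$per_fold$kappa))

  # the fold assignment partitions all samples into near-equal folds
  fold_sizes <- withr::with_seed(77, {
    id <- integer(60)
    for (cl in levels(sub$labels)) {
      idx <- sample(which(sub$labels == cl))
      id[idx] <- rep_len(1:3, length(idx))
    }
    table(id)
  })
  expect_equal(sum(fold_sizes), 60)
  expect_true(all(fold_sizes == 20))

  tiny <- subset_dataset(ds, c(1:6, which(ds$labels == "fatigue")[1]))
  expect_error(crossvalidate(tiny, folds = 5, seed = 1, epochs = 1,
                             model_cfg = model_config("compact")),
               "absent")
})
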