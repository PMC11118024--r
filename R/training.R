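# Adversarial losses (Wasserstein critic with gradient penalty, auxiliary
# classification terms), the training loop, and stratified cross-validation.

#' Training configuration
#'
#' Defaults follow the study conditions: generator learning rate 1e-4,
#' discriminator 3e-4, batch size 150, AdamW with weight-decay coefficient
#' 0.02, loss weights lambda = 1 (classification) and lambda_gp = 10
#' (gradient penalty), five folds, one critic step per generator step.
#'
#' @param lr_g,lr_d Learning rates of generator and discriminator.
#' @param batch Minibatch size.
#' @param weight_decay AdamW decoupled weight-decay coefficient (applied
#'   to weight matrices, not biases/gains).
#' @param lambda Weight of the classification loss.
#' @param lambda_gp Weight of the gradient penalty.
#' @param n_critic Critic updates per generator update.
#' @param epochs Training epochs.
#' @param folds Cross-validation folds.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr_g = 1e-4, lr_d = 3e-4, batch = 150,
                         weight_decay = 0.02, lambda = 1, lambda_gp = 10,
                         n_critic = 1, epochs = 100, folds = 5, seed = 1L) {
  stopifnot(lr_g > 0, lr_d > 0, batch >= 2, folds >= 2)
  structure(list(lr_g = lr_g, lr_d = lr_d, batch = as.integer(batch),
                 weight_decay = weight_decay, lambda = lambda,
                 lambda_gp = lambda_gp, n_critic = as.integer(n_critic),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- AdamW -----------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamw_step <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    # decoupled decay on weight matrices only (names ending in .W)
    if (weight_decay > 0 && grepl("\\.W$", nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# ---- loss components -------------------------------------------------------

# cross-entropy of class probabilities against integer labels, as a node
.ce_node <- function(probs, labels, n_classes) {
  oh <- ad_const(one_hot(labels, n_classes))
  ad_neg(ad_mean(ad_log(ad_cadd(ad_rowsum(ad_mul(probs, oh)), 1e-12))))
}

#' WGAN gradient penalty
#'
#' For mixed samples `xhat = eps * real + (1 - eps) * fake` (one uniform
#' `eps` per sample) the penalty is
#' `lambda_gp * mean((||grad_xhat critic(xhat)||_2 - 1)^2)`, the soft
#' 1-Lipschitz constraint of the Wasserstein critic. The critic's input
#' gradient is obtained by reverse-mode differentiation on the tape, so
#' the returned node can itself be differentiated with respect to the
#' critic parameters (double backprop) during training.
#'
#' @param critic Function mapping an input node to a (samples x 1) score
#'   node.
#' @param real,fake Numeric matrices of equal shape; rows are grouped in
#'   `rows_per_sample` consecutive blocks per sample.
#' @param lambda_gp Penalty weight.
#' @param rows_per_sample Rows belonging to one sample (1 for plain
#'   vector inputs; h*w*2T for conv-layout feature tensors).
#' @param eps Optional per-sample mixing weights (drawn uniformly when
#'   omitted).
#' @return A list: `penalty` (numeric), `node` (tape node for training),
#'   `grad_norms` (per-sample input-gradient norms).
#' @export
gradient_penalty <- function(critic, real, fake, lambda_gp = 10,
                             rows_per_sample = 1, eps = NULL) {
  stopifnot(all(dim(real) == dim(fake)))
  n_samp <- nrow(real) / rows_per_sample
  if (is.null(eps)) eps <- stats::runif(n_samp)
  mix <- rep(eps, each = rows_per_sample)
  xhat <- ad_leaf(mix * real + (1 - mix) * fake)
  score <- critic(xhat)
  gx <- ad_grad(ad_sum(score), list(xhat))[[1]]
  sq <- ad_rowsum(ad_mul(gx, gx))
  Msum <- .mean_rows_op(n_samp, rows_per_sample) * rows_per_sample
  norms <- ad_sqrt(ad_cadd(ad_matmul(ad_const(Msum), sq), 1e-12))
  dev <- ad_cadd(norms, -1)
  node <- ad_cmul(ad_mean(ad_mul(dev, dev)), lambda_gp)
  list(penalty = as.numeric(ad_value(node)), node = node,
       grad_norms = as.numeric(ad_value(norms)))
}

#' Adversarial (Wasserstein + gradient penalty) loss
#'
#' `E[critic(real)] - E[critic(fake)] + lambda_gp * E[(||grad|| - 1)^2]`.
#' The discriminator maximises the Wasserstein gap while the penalty
#' holds its critic near unit input gradient.
#'
#' @inheritParams gradient_penalty
#' @return A list with `total`, `wasserstein` (the gap) and `gp`
#'   components.
#' @export
adversarial_loss <- function(critic, real, fake, lambda_gp = 10,
                             rows_per_sample = 1, eps = NULL) {
  w_real <- mean(ad_value(critic(ad_const(real))))
  w_fake <- mean(ad_value(critic(ad_const(fake))))
  gp <- gradient_penalty(critic, real, fake, lambda_gp, rows_per_sample,
                         eps)
  list(total = w_real - w_fake + gp$penalty,
       wasserstein = w_real - w_fake, gp = gp$penalty)
}

#' Classification losses of the auxiliary head
#'
#' `classification_loss_real()` is the mean cross-entropy of the class
#' head on real samples against their true labels;
#' `classification_loss_fake()` evaluates generated samples `G(z, c)`
#' against their conditioning labels `c`, the term that pushes the
#' generator towards class-consistent output.
#'
#' @param D An `fg_discriminator`.
#' @param x Feature array (batched).
#' @param labels True (respectively conditioning) labels.
#' @param G An `fg_generator`.
#' @param z Latent matrix, one row per sample.
#' @return Numeric scalar loss.
#' @export
classification_loss_real <- function(D, x, labels) {
  probs <- discriminator_forward(D, x)$probs
  idx <- cbind(seq_along(labels), as.integer(labels))
  mean(-log(pmax(probs[idx], 1e-12)))
}

#' @rdname classification_loss_real
#' @export
classification_loss_fake <- function(D, G, z, labels) {
  fake <- generator_forward(G, z, labels)
  classification_loss_real(D, fake, labels)
}

# ---- one adversarial training step ----------------------------------------

# internal: critic closure over discriminator params (nodes)
.critic_fn <- function(P, cfg, batch) {
  function(xn) .fwd_discriminator(xn, P, cfg, batch, train = FALSE)$adv
}

#' One discriminator + generator update
#'
#' Performs `n_critic` discriminator updates (minimising
#' `-wasserstein_gap + lambda_gp * GP + lambda * L_cls_real`) followed by
#' one generator update (minimising
#' `-E[critic(G(z, c))] + lambda * L_cls_fake`), both with AdamW. All
#' randomness (latents, mixing weights, dropout) comes from the current R
#' RNG stream, so a seeded caller gets identical trajectories.
#'
#' @param gan A `fatigue_gan` state from [gan_init()].
#' @param x Feature array batch (`h x w x d x 2T x B`).
#' @param labels Labels of the batch.
#' @return The updated state, with `gan$last` holding the loss bundle of
#'   this step: `l_adv` (Wasserstein gap), `gp`, `l_cls_r`, `l_cls_f`,
#'   `l_d`, `l_g`.
#' @export
train_step <- function(gan, x, labels) {
  cfg <- gan$model_cfg
  tc <- gan$train_cfg
  B <- dim(x)[5]
  rps <- cfg$h * cfg$w * cfg$frames
  xr <- features_to_conv(x, cfg)

  for (ic in seq_len(tc$n_critic)) {
    # -- discriminator update ------------------------------------------
    z <- matrix(stats::rnorm(B * cfg$nz), B)
    PG <- wrap_params(gan$G$params, leaf = FALSE)
    fake <- ad_value(.fwd_generator(ad_const(z),
                                    ad_const(one_hot(labels, cfg$n_classes)),
                                    PG, cfg, B, train = FALSE))
    PD <- wrap_params(gan$D$params, leaf = TRUE)
    out_r <- .fwd_discriminator(ad_const(xr), PD, cfg, B, train = TRUE)
    out_f <- .fwd_discriminator(ad_const(fake), PD, cfg, B, train = TRUE)
    w_real <- ad_mean(out_r$adv)
    w_fake <- ad_mean(out_f$adv)
    gp <- gradient_penalty(.critic_fn(PD, cfg, B), xr, fake,
                           tc$lambda_gp, rps)
    cls_r <- .ce_node(out_r$probs, labels, cfg$n_classes)
    l_d <- ad_add(ad_add(ad_sub(w_fake, w_real), gp$node),
                  ad_cmul(cls_r, tc$lambda))
    if (!is.finite(ad_value(l_d))) {
      stop("non-finite discriminator loss; aborting step", call. = FALSE)
    }
    gd <- lapply(ad_grad(l_d, PD), ad_value)
    names(gd) <- names(gan$D$params)
    st <- .adamw_step(gan$D$params, gd, gan$opt_d, tc$lr_d,
                      tc$weight_decay)
    gan$D$params <- st$params
    gan$opt_d <- st$state
  }

  # -- generator update ------------------------------------------------
  z <- matrix(stats::rnorm(B * cfg$nz), B)
  PG <- wrap_params(gan$G$params, leaf = TRUE)
  PDc <- wrap_params(gan$D$params, leaf = FALSE)
  fake_n <- .fwd_generator(ad_const(z),
                           ad_const(one_hot(labels, cfg$n_classes)),
                           PG, cfg, B, train = TRUE)
  out_g <- .fwd_discriminator(fake_n, PDc, cfg, B, train = TRUE)
  adv_g <- ad_mean(out_g$adv)
  cls_f <- .ce_node(out_g$probs, labels, cfg$n_classes)
  l_g <- ad_add(ad_neg(adv_g), ad_cmul(cls_f, tc$lambda))
  if (!is.finite(ad_value(l_g))) {
    stop("non-finite generator loss; aborting step", call. = FALSE)
  }
  gg <- lapply(ad_grad(l_g, PG), ad_value)
  names(gg) <- names(gan$G$params)
  st <- .adamw_step(gan$G$params, gg, gan$opt_g, tc$lr_g, tc$weight_decay)
  gan$G$params <- st$params
  gan$opt_g <- st$state

  num <- function(n) as.numeric(ad_value(n))
  gan$last <- tibble::tibble(
    l_adv = num(w_real) - num(w_fake), gp = num(gp$node),
    l_cls_r = num(cls_r), l_cls_f = num(cls_f),
    l_d = num(l_d), l_g = num(l_g),
    lambda = tc$lambda, lambda_gp = tc$lambda_gp
  )
  gan$step <- gan$step + 1L
  gan
}

#' Initialise an adversarial training state
#'
#' @param model_cfg An [model_config()].
#' @param train_cfg A [train_config()].
#' @return A `fatigue_gan` state: generator, discriminator, optimizer
#'   moments, step counter and an empty log.
#' @export
gan_init <- function(model_cfg = model_config("compact"),
                     train_cfg = train_config()) {
  G <- init_generator(model_cfg, seed = train_cfg$seed + 1L)
  D <- init_discriminator(model_cfg, seed = train_cfg$seed + 2L)
  structure(list(G = G, D = D, model_cfg = model_cfg,
                 train_cfg = train_cfg,
                 opt_g = .adamw_init(G$params), opt_d = .adamw_init(D$params),
                 step = 0L, log = NULL, last = NULL, scaler = NULL,
                 levels = NULL),
            class = "fatigue_gan")
}

#' Train the conditional GAN on a feature dataset
#'
#' Runs `steps` alternating critic/generator updates on minibatches drawn
#' without replacement (reshuffling every epoch), logging all loss
#' components per step. Fully deterministic given the seed.
#'
#' @param ds A [feature_dataset()] (scaled features recommended).
#' @param steps Number of generator updates.
#' @param model_cfg,train_cfg Configurations; `train_cfg$batch` is capped
#'   at the dataset size.
#' @return A `fatigue_gan` with trained weights, the per-step `log`
#'   tibble, and the dataset's scaler/levels for later generation.
#' @export
train_gan <- function(ds, steps = 200,
                      model_cfg = model_config("compact"),
                      train_cfg = train_config()) {
  n <- n_samples(ds)
  B <- min(train_cfg$batch, n)
  gan <- gan_init(model_cfg, train_cfg)
  gan$scaler <- ds$scaler
  gan$levels <- levels(ds$labels)
  logs <- vector("list", steps)
  withr::with_seed(train_cfg$seed, {
    order <- sample(n)
    at <- 1L
    for (s in seq_len(steps)) {
      if (at + B - 1L > n) { order <- sample(n); at <- 1L }
      idx <- order[at:(at + B - 1L)]
      at <- at + B
      gan <- train_step(gan, ds$x[, , , , idx, drop = FALSE],
                        ds$labels[idx])
      logs[[s]] <- dplyr::mutate(gan$last, step = s)
    }
  })
  gan$log <- dplyr::bind_rows(logs)
  gan
}

#' Generate labelled samples from a trained GAN
#'
#' @param gan A `fatigue_gan`.
#' @param labels Vector of class labels to condition on (factor levels of
#'   the training data).
#' @param seed Seed for the latent draw.
#' @return A [feature_dataset()] of synthetic tensors in the scaled
#'   feature space of the training data.
#' @export
generate_samples <- function(gan, labels, seed = 1L) {
  labels <- factor(labels, levels = gan$levels)
  stopifnot(!anyNA(labels))
  cfg <- gan$model_cfg
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(length(labels) * cfg$nz), length(labels))
    x <- generator_forward(gan$G, z, labels)
  })
  structure(list(x = x, labels = labels, grid = electrode_grid(),
                 perclos = NULL, scaler = gan$scaler),
            class = "feature_dataset")
}

# ---- supervised classifier (discriminator backbone) ------------------------

#' Train the discriminator backbone as a plain classifier
#'
#' Supervised cross-entropy training of the class head (the critic head
#' is left untouched), used for cross-validation and the training-set
#' mixing experiments.
#'
#' @param ds Training [feature_dataset()].
#' @param eval_ds Optional held-out dataset evaluated after every epoch;
#'   the best-accuracy epoch's weights are kept.
#' @param epochs,batch,lr Optimisation settings.
#' @param model_cfg Architecture profile.
#' @param weight_decay AdamW weight decay.
#' @param seed Seed for init, shuffling and dropout.
#' @return A `fatigue_clf`: discriminator, per-epoch `history` tibble and
#'   the index of the best epoch.
#' @export
train_classifier <- function(ds, eval_ds = NULL, epochs = 5, batch = 20,
                             lr = 1e-3, model_cfg = model_config("compact"),
                             weight_decay = 0.02, seed = 1L) {
  n <- n_samples(ds)
  B <- min(batch, n)
  ncls <- model_cfg$n_classes
  stopifnot(nlevels(ds$labels) == ncls)
  D <- init_discriminator(model_cfg, seed = seed)
  opt <- .adamw_init(D$params)
  hist <- vector("list", epochs)
  best <- list(acc = -1, params = D$params, epoch = 0L)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      order <- sample(n)
      ep_loss <- 0
      nb <- 0L
      for (at in seq(1L, n - B + 1L, by = B)) {
        idx <- order[at:(at + B - 1L)]
        P <- wrap_params(D$params, leaf = TRUE)
        xn <- ad_const(features_to_conv(ds$x[, , , , idx, drop = FALSE],
                                        model_cfg))
        out <- .fwd_discriminator(xn, P, model_cfg, length(idx),
                                  train = TRUE)
        loss <- .ce_node(out$probs, ds$labels[idx], ncls)
        g <- lapply(ad_grad(loss, P), ad_value)
        names(g) <- names(D$params)
        st <- .adamw_step(D$params, g, opt, lr, weight_decay)
        D$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + ad_value(loss)
        nb <- nb + 1L
      }
      row <- tibble::tibble(epoch = ep, loss = ep_loss / nb)
      if (!is.null(eval_ds)) {
        pred <- predict_classifier(list(D = D, model_cfg = model_cfg,
                                        levels = levels(ds$labels)),
                                   eval_ds)
        met <- classification_metrics(eval_ds$labels, pred$class)
        row <- dplyr::bind_cols(row, met)
        if (met$accuracy > best$acc) {
          best <- list(acc = met$accuracy, params = D$params, epoch = ep)
        }
      }
      hist[[ep]] <- row
    }
  })
  if (!is.null(eval_ds)) D$params <- best$params
  structure(list(D = D, model_cfg = model_cfg,
                 history = dplyr::bind_rows(hist),
                 best_epoch = if (is.null(eval_ds)) NA_integer_
                              else best$epoch,
                 levels = levels(ds$labels)),
            class = "fatigue_clf")
}

#' Predict classes for a feature dataset
#'
#' @param clf A `fatigue_clf` (or any list with `D` and `model_cfg`).
#' @param ds A [feature_dataset()] or bare feature array.
#' @param chunk Samples per forward pass.
#' @return A list: `probs` matrix and `class` factor.
#' @export
predict_classifier <- function(clf, ds, chunk = 32L) {
  x <- if (inherits(ds, "feature_dataset")) ds$x else ds
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[5]
  probs <- matrix(0, n, clf$model_cfg$n_classes)
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(at + chunk - 1L, n)
    probs[idx, ] <- discriminator_forward(clf$D,
                                          x[, , , , idx, drop = FALSE])$probs
  }
  lev <- clf$levels %||% as.character(seq_len(ncol(probs)))
  list(probs = probs,
       class = factor(lev[max.col(probs, ties.method = "first")],
                      levels = lev))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cross-validation ------------------------------------------------------

#' Stratified k-fold cross-validation of the fatigue classifier
#'
#' Splits the dataset into `folds` class-stratified folds, trains the
#' discriminator backbone on each training split and records, per fold,
#' the metrics of the best epoch on that fold's test split (mirroring the
#' convention of reporting the highest test-subset precision; note this
#' is an optimistic checkpoint-selection rule — pass a `selection` of
#' `"holdout"` to pick the epoch on an inner validation split instead).
#'
#' @param ds A [feature_dataset()].
#' @param folds Number of folds.
#' @param selection `"test-best"` (default) or `"holdout"`.
#' @param ... Passed to [train_classifier()] (`epochs`, `batch`, `lr`,
#'   `model_cfg`, ...).
#' @param seed Seed controlling fold assignment and training.
#' @return A `fatigue_cv`: tibble `per_fold` with one metrics row per
#'   fold and `summary` with their mean.
#' @export
crossvalidate <- function(ds, folds = 5, selection = c("test-best",
                                                       "holdout"),
                          seed = 1L, ...) {
  selection <- match.arg(selection)
  n <- n_samples(ds)
  fold_id <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(ds$labels)) {
      idx <- sample(which(ds$labels == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  per <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    if (length(unique(ds$labels[test_idx])) < nlevels(ds$labels) ||
        length(unique(ds$labels[train_idx])) < nlevels(ds$labels)) {
      stop("a class is absent from fold ", f,
           "; use fewer folds or more data", call. = FALSE)
    }
    tr <- subset_dataset(ds, train_idx)
    te <- subset_dataset(ds, test_idx)
    if (selection == "test-best") {
      clf <- train_classifier(tr, eval_ds = te, seed = seed + f, ...)
      met <- clf$history[clf$best_epoch, -(1:2)]
    } else {
      inner <- withr::with_seed(seed + 100L + f, {
        i <- unlist(lapply(levels(tr$labels), function(cl) {
          w <- which(tr$labels == cl)
          sample(w, max(1L, round(0.2 * length(w))))
        }))
        i
      })
      clf <- train_classifier(subset_dataset(tr, setdiff(seq_len(
        n_samples(tr)), inner)), eval_ds = subset_dataset(tr, inner),
        seed = seed + f, ...)
      pred <- predict_classifier(clf, te)
      met <- classification_metrics(te$labels, pred$class)
    }
    per[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), met)
  }
  per <- dplyr::bind_rows(per)
  structure(list(per_fold = per,
                 summary = dplyr::summarise(per, dplyr::across(
                   c("accuracy", "precision", "recall", "f1", "kappa"),
                   mean)),
                 folds = folds, selection = selection, seed = seed),
            class = "fatigue_cv")
}

#' @export
print.fatigue_cv <- function(x, ...) {
  cat(sprintf("<fatigue_cv> %d-fold stratified cross-validation (%s)\n",
              x$folds, x$selection))
  print(x$per_fold)
  cat("mean:\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.fatigue_gan <- function(x, ...) {
  cat(sprintf("<fatigue_gan> profile '%s', %d training steps\n",
              x$model_cfg$profile, x$step))
  if (!is.null(x$last)) print(x$last)
  invisible(x)
}
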