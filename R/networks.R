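# Generator and discriminator architectures: spatial/frequency attention,
# inverted bottleneck residual convolutions, and a Transformer encoder over
# time frames.
#
# Activations live in a "conv layout": a (h*w * frames * batch) x channels
# matrix whose row index runs spatial-fastest, then frame, then sample.
# All spatial structure (3x3 depthwise shifts, average pooling, deconv
# scatters) is expressed as constant linear operators applied along the
# leading spatial axis, which keeps every network op inside the
# differentiable primitive set of the tape engine.

#' Network configuration
#'
#' Widths and hyperparameters of the generator/discriminator pair. The
#' `"full"` profile is the full-size model: the discriminator's channel
#' path expands 5 -> 128, halves to 64, runs a two-branch trunk at 64,
#' reduces to 32, pools 6x9 -> 2x2 with a 3x4 averaging kernel and maps to
#' 64-dimensional frame tokens for a 2-block, 4-head Transformer. The
#' `"compact"` profile is the same architecture at a quarter of the widths,
#' used for quick training experiments. The bottleneck expansion factor
#' defaults to `k = 2`: together with the documented widths this puts the
#' discriminator's forward pass at roughly 0.2 GFLOPs (see
#' [count_flops()]); larger expansions would multiply that cost without
#' changing any shape contract.
#'
#' @param profile `"full"` or `"compact"`.
#' @param n_classes Number of vigilance classes (default 2).
#' @param k Bottleneck expansion factor.
#' @param dropout Transformer dropout probability.
#' @param positional Add a learned positional embedding to the frame
#'   tokens (default `TRUE`; `FALSE` makes the encoder
#'   permutation-equivariant, which is useful for testing).
#' @param ... Overrides for any config field.
#' @return A list of class `fg_config`.
#' @export
model_config <- function(profile = c("full", "compact"), n_classes = 2,
                         k = 2, dropout = 0.1, positional = TRUE, ...) {
  profile <- match.arg(profile)
  base <- list(h = 6L, w = 9L, d = 5L, frames = 16L,
               pool_h = 3L, pool_w = 4L,
               k = k, heads = 4L, tf_blocks = 2L,
               dropout = dropout, positional = positional,
               n_classes = as.integer(n_classes), profile = profile)
  if (profile == "full") {
    base <- c(base, list(stem = 128L, trunk = 64L, reduce = 48L, out = 32L,
                         g_tail = 16L, token_dim = 64L, mlp_hidden = 128L,
                         nz = 64L))
  } else {
    base$tf_blocks <- 1L
    base <- c(base, list(stem = 8L, trunk = 4L, reduce = 4L, out = 4L,
                         g_tail = 4L, token_dim = 16L, mlp_hidden = 32L,
                         nz = 16L))
  }
  dots <- list(...)
  base[names(dots)] <- dots
  base$pooled_h <- base$h %/% base$pool_h
  base$pooled_w <- base$w %/% base$pool_w
  base$pooled <- base$pooled_h * base$pooled_w
  if (base$token_dim %% base$heads != 0) {
    stop("token_dim must be divisible by the head count", call. = FALSE)
  }
  # generated tensors must satisfy the feature-tensor invariant that
  # unmapped electrode cells are exactly zero, so the generator output is
  # masked to the mapped cells of the electrode grid
  if (is.null(base$mask) && base$h == 6L && base$w == 9L) {
    base$mask <- grid_mask(electrode_grid())
  }
  # coarse grid of the generator's transposed convolution
  base$coarse_h <- 2L; base$coarse_w <- 2L
  base$deconv_kh <- 3L; base$deconv_kw <- 5L
  cc <- base$token_dim / (base$coarse_h * base$coarse_w)
  if (cc != round(cc)) stop("token_dim must be divisible by 4", call. = FALSE)
  base$deconv_cc <- as.integer(cc)
  structure(base, class = "fg_config")
}

# (cin, cout) channel pairs of the eight-block bottleneck modules:
# expand(1) + halve(1) + branch A(1) + branch B(2) + tail(2) + fuse(1)
.d_blocks <- function(cfg) {
  list(b1 = c(cfg$d, cfg$stem), b2 = c(cfg$stem, cfg$trunk),
       b3 = c(cfg$trunk, cfg$trunk),                       # branch A
       b4 = c(cfg$trunk, cfg$trunk), b5 = c(cfg$trunk, cfg$trunk),  # branch B
       b6 = c(cfg$trunk, cfg$reduce), b7 = c(cfg$reduce, cfg$out),
       b8 = c(cfg$out, cfg$out))
}

.g_blocks <- function(cfg) {
  list(g1 = c(cfg$d, cfg$stem), g2 = c(cfg$stem, cfg$trunk),
       g3 = c(cfg$trunk, cfg$trunk),
       g4 = c(cfg$trunk, cfg$trunk), g5 = c(cfg$trunk, cfg$trunk),
       g6 = c(cfg$trunk, cfg$trunk),
       g7 = c(cfg$trunk, cfg$g_tail), g8 = c(cfg$g_tail, cfg$d))
}

# ---- constant spatial operators -------------------------------------------

.op_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, make) {
  hit <- .op_cache[[key]]
  if (is.null(hit)) {
    hit <- make()
    .op_cache[[key]] <- hit
  }
  hit
}

# 3x3 same-padding tap index maps on the h x w grid: S x 9 matrices of
# 1-based spatial sources (0 = outside), one column per tap, plus the
# inverse maps for the vjp (spatial index runs row-fastest:
# s = r + h * (c - 1))
.shift_ops <- function(h, w) {
  .cache_get(paste0("shift", h, "x", w), function() {
    S <- h * w
    one <- function(dr, dc) {
      idx <- integer(S)
      for (c in 1:w) for (r in 1:h) {
        r2 <- r + dr; c2 <- c + dc
        idx[r + h * (c - 1)] <-
          if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
            r2 + h * (c2 - 1)
          } else 0L
      }
      idx
    }
    fwd <- matrix(0L, S, 9L)
    bwd <- matrix(0L, S, 9L)
    t <- 0L
    for (dc in -1:1) for (dr in -1:1) {
      t <- t + 1L
      fwd[, t] <- one(dr, dc)
      bwd[, t] <- one(-dr, -dc)
    }
    list(fwd = fwd, bwd = bwd)
  })
}

# average-pooling operator h x w -> pooled_h x pooled_w with a
# pool_h x pool_w kernel (trailing remainder columns/rows are dropped)
.pool_op <- function(cfg) {
  .cache_get(paste0("pool", cfg$h, "x", cfg$w, "_", cfg$pool_h, cfg$pool_w),
             function() {
    Sin <- cfg$h * cfg$w
    M <- matrix(0, cfg$pooled, Sin)
    for (pc in seq_len(cfg$pooled_w)) for (pr in seq_len(cfg$pooled_h)) {
      sp <- pr + cfg$pooled_h * (pc - 1)
      rows <- (pr - 1) * cfg$pool_h + seq_len(cfg$pool_h)
      cols <- (pc - 1) * cfg$pool_w + seq_len(cfg$pool_w)
      for (c in cols) for (r in rows) {
        M[sp, r + cfg$h * (c - 1)] <- 1 / (cfg$pool_h * cfg$pool_w)
      }
    }
    M
  })
}

# scatter operators of the transposed convolution: coarse cell p covers a
# deconv_kh x deconv_kw patch at stride (pool_h, pool_w)
.deconv_ops <- function(cfg) {
  .cache_get(paste0("deconv", cfg$h, "x", cfg$w), function() {
    S <- cfg$h * cfg$w
    K <- cfg$deconv_kh * cfg$deconv_kw
    ops <- list()
    for (pj in seq_len(cfg$coarse_w)) for (pi in seq_len(cfg$coarse_h)) {
      E <- matrix(0, S, K)
      for (jo in seq_len(cfg$deconv_kw)) for (io in seq_len(cfg$deconv_kh)) {
        r <- (pi - 1) * cfg$pool_h + io
        c <- (pj - 1) * cfg$pool_w + jo
        if (r <= cfg$h && c <= cfg$w) {
          E[r + cfg$h * (c - 1), io + cfg$deconv_kh * (jo - 1)] <- 1
        }
      }
      ops[[pi + cfg$coarse_h * (pj - 1)]] <- E
    }
    ops
  })
}

.mean_rows_op <- function(groups, per) {
  # (groups x groups*per) operator averaging blocks of `per` rows
  M <- matrix(0, groups, groups * per)
  for (g in seq_len(groups)) M[g, (g - 1) * per + seq_len(per)] <- 1 / per
  M
}

.tile_op <- function(frames, batch) {
  # (frames*batch x frames) operator repeating a frame-indexed table
  M <- matrix(0, frames * batch, frames)
  M[cbind(seq_len(frames * batch), rep(seq_len(frames), batch))] <- 1
  M
}

# ---- layout conversions ----------------------------------------------------

#' Convert between feature arrays and the internal conv layout
#'
#' `features_to_conv()` turns an `h x w x d x 2T (x N)` array into the
#' (h*w * 2T * N) x d activation matrix used by the networks;
#' `conv_to_features()` inverts it.
#'
#' @param x Feature array (4D for one sample, 5D for a batch).
#' @param m Conv-layout matrix.
#' @param cfg An `fg_config`.
#' @param batch Batch size encoded in `m`.
#' @return A matrix, respectively an array (5D, last dimension `batch`).
#' @keywords internal
features_to_conv <- function(x, cfg = model_config()) {
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1L)
  b <- dim(x)[5]
  x <- aperm(x, c(1, 2, 4, 5, 3))          # h, w, frames, batch, d
  dim(x) <- c(cfg$h * cfg$w * cfg$frames * b, cfg$d)
  x
}

#' @rdname features_to_conv
#' @keywords internal
conv_to_features <- function(m, cfg, batch) {
  dim(m) <- c(cfg$h, cfg$w, cfg$frames, batch, cfg$d)
  aperm(m, c(1, 2, 5, 3, 4))
}

# ---- parameter initialisation ---------------------------------------------

.rnd <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.init_linear <- function(p, name, cin, cout, sd = sqrt(2 / cin)) {
  p[[paste0(name, ".W")]] <- .rnd(cin, cout, sd)
  p[[paste0(name, ".b")]] <- matrix(0, 1, cout)
  p
}

.init_block <- function(p, name, cin, cout, k) {
  hid <- k * cin
  p <- .init_linear(p, paste0(name, ".expand"), cin, hid)
  p[[paste0(name, ".dw.W")]] <- .rnd(9, hid, sqrt(2 / 9))
  p[[paste0(name, ".dw.b")]] <- matrix(0, 1, hid)
  p <- .init_linear(p, paste0(name, ".proj"), hid, cout)
  p
}

.init_attention <- function(p, name, d) {
  dr <- max(2L, d %/% 2L)
  p <- .init_linear(p, paste0(name, ".sp"), d, 1L)
  p <- .init_linear(p, paste0(name, ".fq1"), d, dr)
  p <- .init_linear(p, paste0(name, ".fq2"), dr, d)
  p
}

.init_transformer <- function(p, name, cfg) {
  D <- cfg$token_dim
  p[[paste0(name, ".pos")]] <- .rnd(cfg$frames, D, 0.02)
  for (i in seq_len(cfg$tf_blocks)) {
    blk <- paste0(name, ".blk", i)
    p[[paste0(blk, ".ln1.g")]] <- matrix(1, 1, D)
    p[[paste0(blk, ".ln1.b")]] <- matrix(0, 1, D)
    for (nm in c("q", "k", "v", "o")) {
      p <- .init_linear(p, paste0(blk, ".", nm), D, D, sd = sqrt(1 / D))
    }
    p[[paste0(blk, ".ln2.g")]] <- matrix(1, 1, D)
    p[[paste0(blk, ".ln2.b")]] <- matrix(0, 1, D)
    p <- .init_linear(p, paste0(blk, ".mlp1"), D, cfg$mlp_hidden)
    p <- .init_linear(p, paste0(blk, ".mlp2"), cfg$mlp_hidden, D)
  }
  p
}

#' Initialise the discriminator
#'
#' Builds the flat parameter list of the critic/classifier network:
#' attention module, eight bottleneck residual blocks with a two-branch
#' trunk, 3x4 average pooling, the fully connected token map, the
#' Transformer encoder, and the two heads (an unbounded Wasserstein critic
#' scalar and a softmax class head sharing the encoder trunk).
#'
#' @param cfg An [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `fg_discriminator`: `list(params, cfg)`.
#' @export
init_discriminator <- function(cfg = model_config(), seed = 1L) {
  p <- withr::with_seed(seed, {
    p <- list()
    p <- .init_attention(p, "att", cfg$d)
    blocks <- .d_blocks(cfg)
    for (nm in names(blocks)) {
      p <- .init_block(p, nm, blocks[[nm]][1], blocks[[nm]][2], cfg$k)
    }
    p <- .init_linear(p, "fc", cfg$pooled * cfg$out, cfg$token_dim)
    p <- .init_transformer(p, "tf", cfg)
    p <- .init_linear(p, "adv", cfg$token_dim, 1L)
    p <- .init_linear(p, "cls", cfg$token_dim, cfg$n_classes)
    p
  })
  structure(list(params = p, cfg = cfg), class = "fg_discriminator")
}

#' Initialise the generator
#'
#' Latent noise and a one-hot class label are concatenated, linearly
#' embedded into 2T frame tokens, refined by the Transformer encoder,
#' expanded by a transposed convolution from the 2x2 coarse grid to the
#' 6x9 electrode grid, and polished by the attention module and the
#' eight-block bottleneck trunk whose two concluding blocks reduce the
#' channel count back to the five frequency bands.
#'
#' @inheritParams init_discriminator
#' @return An object of class `fg_generator`: `list(params, cfg)`.
#' @export
init_generator <- function(cfg = model_config(), seed = 2L) {
  p <- withr::with_seed(seed, {
    p <- list()
    p <- .init_linear(p, "embed", cfg$nz + cfg$n_classes,
                      cfg$frames * cfg$token_dim)
    p <- .init_transformer(p, "tf", cfg)
    K <- cfg$deconv_kh * cfg$deconv_kw
    p[[paste0("deconv.W")]] <- .rnd(cfg$deconv_cc, K * cfg$d,
                                    sqrt(2 / cfg$deconv_cc))
    p[["deconv.b"]] <- matrix(0, 1, cfg$d)
    # class-conditional output bias: gives the conditioning label a direct
    # per-band path to the generated tensor (class differences in
    # entropy features are, to first order, band-level shifts); kept out
    # of weight decay like other biases
    p[["cbias.b"]] <- matrix(0, cfg$n_classes, cfg$d)
    p <- .init_attention(p, "att", cfg$d)
    blocks <- .g_blocks(cfg)
    for (nm in names(blocks)) {
      p <- .init_block(p, nm, blocks[[nm]][1], blocks[[nm]][2], cfg$k)
    }
    # start the trunk's output projection small so early samples sit near
    # zero in the standardised feature space
    last <- paste0(names(blocks)[length(blocks)], ".proj.W")
    p[[last]] <- 0.1 * p[[last]]
    p
  })
  structure(list(params = p, cfg = cfg), class = "fg_generator")
}

wrap_params <- function(p, leaf = TRUE) {
  lapply(p, if (leaf) ad_leaf else ad_const)
}

# ---- forward passes (tape nodes) ------------------------------------------

.fwd_linear <- function(x, P, name) {
  ad_linear(x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]])
}

.fwd_depthwise <- function(x, P, name, cfg) {
  ops <- .shift_ops(cfg$h, cfg$w)
  ad_dwmix(x, P[[paste0(name, ".W")]], ops$fwd, ops$bwd,
           bias = P[[paste0(name, ".b")]])
}

.fwd_block <- function(x, P, name, cfg, cin, cout) {
  h <- ad_relu6(.fwd_linear(x, P, paste0(name, ".expand")))
  h <- ad_relu6(.fwd_depthwise(h, P, paste0(name, ".dw"), cfg))
  y <- .fwd_linear(h, P, paste0(name, ".proj"))
  if (cin == cout) ad_add(x, y) else y
}

.fwd_att_spatial <- function(x, P, name) {
  gate <- ad_sigmoid(.fwd_linear(x, P, paste0(name, ".sp")))
  ad_scale_rows(x, gate)
}

.fwd_att_freq <- function(x, P, name, cfg) {
  S <- cfg$h * cfg$w
  pooled <- ad_spatial(x, matrix(1 / S, 1, S), S)        # (F*B) x d
  a <- ad_relu6(.fwd_linear(pooled, P, paste0(name, ".fq1")))
  gate <- ad_sigmoid(.fwd_linear(a, P, paste0(name, ".fq2")))
  up <- ad_spatial(gate, matrix(1, S, 1), 1L)            # broadcast to cells
  ad_mul(x, up)
}

.fwd_attention <- function(x, P, name, cfg) {
  ad_cmul(ad_add(.fwd_att_spatial(x, P, name),
                 .fwd_att_freq(x, P, name, cfg)), 0.5)
}

.fwd_trunk <- function(x, P, blocks, cfg) {
  nm <- names(blocks)
  x <- .fwd_block(x, P, nm[1], cfg, blocks[[1]][1], blocks[[1]][2])
  x <- .fwd_block(x, P, nm[2], cfg, blocks[[2]][1], blocks[[2]][2])
  a <- .fwd_block(x, P, nm[3], cfg, blocks[[3]][1], blocks[[3]][2])
  b <- .fwd_block(x, P, nm[4], cfg, blocks[[4]][1], blocks[[4]][2])
  b <- .fwd_block(b, P, nm[5], cfg, blocks[[5]][1], blocks[[5]][2])
  x <- ad_add(a, b)
  for (i in 6:8) {
    x <- .fwd_block(x, P, nm[i], cfg, blocks[[i]][1], blocks[[i]][2])
  }
  x
}

# Self-attention restricted to within-sample token blocks: scores for the
# whole frame*batch stack are computed in one matmul per head and
# cross-sample entries are masked to -Inf before the softmax, which zeroes
# them exactly — samples never mix.
.fwd_mhsa <- function(x, P, blk, cfg, batch, train) {
  D <- cfg$token_dim
  dh <- D %/% cfg$heads
  q <- .fwd_linear(x, P, paste0(blk, ".q"))
  k <- .fwd_linear(x, P, paste0(blk, ".k"))
  v <- .fwd_linear(x, P, paste0(blk, ".v"))
  FB <- cfg$frames * batch
  mask <- .cache_get(paste0("attmask", cfg$frames, "_", batch), function() {
    grp <- rep(seq_len(batch), each = cfg$frames)
    ifelse(outer(grp, grp, "=="), 0, -1e30)
  })
  out <- NULL
  for (hd in seq_len(cfg$heads)) {
    cols <- (hd - 1) * dh + seq_len(dh)
    qs <- ad_slice_cols(q, cols)
    ks <- ad_slice_cols(k, cols)
    vs <- ad_slice_cols(v, cols)
    att <- ad_softmax_rows(ad_cadd(ad_cmul(ad_matmul(qs, ad_t(ks)),
                                           1 / sqrt(dh)), mask))
    o <- ad_embed_cols(ad_matmul(att, vs), cols, D)
    out <- if (is.null(out)) o else ad_add(out, o)
  }
  .fwd_linear(out, P, paste0(blk, ".o"))
}

.fwd_transformer <- function(x, P, name, cfg, batch, train) {
  if (cfg$positional) {
    tile <- .cache_get(paste0("tile", cfg$frames, "_", batch),
                       function() .tile_op(cfg$frames, batch))
    x <- ad_add(x, ad_matmul(ad_const(tile), P[[paste0(name, ".pos")]]))
  }
  for (i in seq_len(cfg$tf_blocks)) {
    blk <- paste0(name, ".blk", i)
    h <- ad_layernorm(x, P[[paste0(blk, ".ln1.g")]],
                      P[[paste0(blk, ".ln1.b")]])
    a <- .fwd_mhsa(h, P, blk, cfg, batch, train)
    x <- ad_add(x, ad_dropout(a, cfg$dropout, train))
    h <- ad_layernorm(x, P[[paste0(blk, ".ln2.g")]],
                      P[[paste0(blk, ".ln2.b")]])
    m <- .fwd_linear(ad_gelu(.fwd_linear(h, P, paste0(blk, ".mlp1"))),
                     P, paste0(blk, ".mlp2"))
    x <- ad_add(x, ad_dropout(m, cfg$dropout, train))
  }
  x
}

# full discriminator on a conv-layout node; returns nodes
.fwd_discriminator <- function(x, P, cfg, batch, train = FALSE) {
  S <- cfg$h * cfg$w
  x <- .fwd_attention(x, P, "att", cfg)
  x <- .fwd_trunk(x, P, .d_blocks(cfg), cfg)
  x <- ad_spatial(x, .pool_op(cfg), S)                   # pooled cells
  FB <- cfg$frames * batch
  x <- ad_reshape(x, c(cfg$pooled, FB, cfg$out))
  x <- ad_reshape(ad_aperm(x, c(2, 1, 3)), c(FB, cfg$pooled * cfg$out))
  tok <- .fwd_linear(x, P, "fc")
  tok <- .fwd_transformer(tok, P, "tf", cfg, batch, train)
  mp <- .cache_get(paste0("meanrows", cfg$frames, "_", batch),
                   function() .mean_rows_op(batch, cfg$frames))
  feat <- ad_matmul(ad_const(mp), tok)
  adv <- .fwd_linear(feat, P, "adv")
  logits <- .fwd_linear(feat, P, "cls")
  list(adv = adv, logits = logits, probs = ad_softmax_rows(logits),
       tokens = tok)
}

# full generator from latent z (batch x nz) and one-hot labels; returns a
# conv-layout node
.fwd_generator <- function(z, onehot, P, cfg, batch, train = FALSE) {
  emb <- .fwd_linear(ad_cbind(z, onehot), P, "embed")    # B x (F*D)
  tok <- ad_reshape(emb, c(batch, cfg$token_dim, cfg$frames))
  tok <- ad_reshape(ad_aperm(tok, c(3, 1, 2)),
                    c(cfg$frames * batch, cfg$token_dim))
  tok <- .fwd_transformer(tok, P, "tf", cfg, batch, train)
  # transposed convolution: coarse 2x2 grid -> 6x9 grid
  FB <- cfg$frames * batch
  cc <- cfg$deconv_cc
  nco <- cfg$coarse_h * cfg$coarse_w
  ops <- .deconv_ops(cfg)
  Kn <- cfg$deconv_kh * cfg$deconv_kw
  S <- cfg$h * cfg$w
  acc <- NULL
  for (pp in seq_len(nco)) {
    cols <- (seq_len(cc) - 1) * nco + pp                 # channel slots of p
    xp <- ad_slice_cols(tok, cols)                       # FB x cc
    patch <- ad_matmul(xp, P[["deconv.W"]])              # FB x (Kn*d)
    patch <- ad_reshape(patch, c(FB, Kn, cfg$d))
    patch <- ad_reshape(ad_aperm(patch, c(2, 1, 3)), c(Kn * FB, cfg$d))
    term <- ad_spatial(patch, ops[[pp]], Kn)             # (S*FB) x d
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  x <- ad_add(acc, ad_rep_rows(P[["deconv.b"]], S * FB))
  x <- .fwd_attention(x, P, "att", cfg)
  x <- .fwd_trunk(x, P, .g_blocks(cfg), cfg)
  rowsamp <- .cache_get(paste0("rowsamp", S, "_", cfg$frames, "_", batch),
                        function() {
    M <- matrix(0, S * cfg$frames * batch, batch)
    M[cbind(seq_len(S * cfg$frames * batch),
            rep(seq_len(batch), each = S * cfg$frames))] <- 1
    M
  })
  x <- ad_add(x, ad_matmul(ad_const(rowsamp),
                           ad_matmul(onehot, P[["cbias.b"]])))
  if (!is.null(cfg$mask)) {
    x <- ad_cmul(x, rep(as.numeric(cfg$mask), FB))
  }
  x
}

# ---- user-facing array interfaces -----------------------------------------

#' One-hot encode class labels
#' @param labels Factor, or 1-based integer vector of class indices.
#' @param n_classes Number of classes.
#' @return A `length(labels) x n_classes` 0/1 matrix.
#' @export
one_hot <- function(labels, n_classes) {
  idx <- as.integer(labels)
  if (any(idx < 1L | idx > n_classes)) {
    stop("labels must be factors or 1-based class indices", call. = FALSE)
  }
  m <- matrix(0, length(idx), n_classes)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Generator forward pass
#'
#' Maps latent noise and class labels to synthetic 4D feature tensors.
#'
#' @param G An `fg_generator` from [init_generator()].
#' @param z A batch x nz matrix of standard-normal noise.
#' @param labels Factor or 1-based integer labels, one per row of `z`.
#' @param train Apply dropout (training mode).
#' @return An `h x w x d x 2T x batch` array of synthetic features.
#' @export
generator_forward <- function(G, z, labels, train = FALSE) {
  cfg <- G$cfg
  z <- as.matrix(z)
  batch <- nrow(z)
  stopifnot(ncol(z) == cfg$nz, length(labels) == batch)
  P <- wrap_params(G$params, leaf = FALSE)
  out <- .fwd_generator(ad_const(z), ad_const(one_hot(labels, cfg$n_classes)),
                        P, cfg, batch, train)
  conv_to_features(ad_value(out), cfg, batch)
}

#' Discriminator forward pass
#'
#' @param D An `fg_discriminator` from [init_discriminator()].
#' @param x Feature array, `h x w x d x 2T` or with a trailing batch
#'   dimension.
#' @param train Apply dropout (training mode).
#' @return A list: `adv` (numeric critic scores, one per sample) and
#'   `probs` (batch x n_classes matrix of class probabilities summing
#'   to 1).
#' @export
discriminator_forward <- function(D, x, train = FALSE) {
  cfg <- D$cfg
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1L)
  batch <- dim(x)[5]
  P <- wrap_params(D$params, leaf = FALSE)
  out <- .fwd_discriminator(ad_const(features_to_conv(x, cfg)), P, cfg,
                            batch, train)
  list(adv = as.numeric(ad_value(out$adv)), probs = ad_value(out$probs))
}

#' Attention, bottleneck and Transformer building blocks
#'
#' Array-in/array-out views of the shared network modules, mainly for
#' inspection and testing. `spatial_attention()` gates each grid cell and
#' frame by a sigmoid weight computed from its five-band profile;
#' `frequency_attention()` gates each band by a weight computed from the
#' globally pooled spatial map; `attention_module()` averages the two
#' gated tensors so saturated gates reproduce the input exactly.
#' `bottleneck_module_d()` maps a feature tensor to the 2T frame tokens
#' (`token_dim x 2T`), and `bottleneck_module_g()` is the generator-side
#' trunk preserving the tensor shape.
#'
#' @param x An `h x w x d x 2T` feature array (a trailing batch dimension
#'   is accepted).
#' @param params Flat parameter list; freshly initialised when omitted.
#' @param cfg An [model_config()].
#' @param seed Seed for the default parameter draw.
#' @return An array of the same shape as `x` for the attention modules and
#'   `bottleneck_module_g()`; a `token_dim x 2T` matrix (per sample) for
#'   `bottleneck_module_d()`.
#' @export
attention_module <- function(x, params = NULL, cfg = model_config(),
                             seed = 1L) {
  .module_apply(x, params, cfg, seed, .fwd_attention)
}

#' @rdname attention_module
#' @export
spatial_attention <- function(x, params = NULL, cfg = model_config(),
                              seed = 1L) {
  .module_apply(x, params, cfg, seed,
                function(n, P, name, cfg) .fwd_att_spatial(n, P, name))
}

#' @rdname attention_module
#' @export
frequency_attention <- function(x, params = NULL, cfg = model_config(),
                                seed = 1L) {
  .module_apply(x, params, cfg, seed, .fwd_att_freq)
}

.module_apply <- function(x, params, cfg, seed, fwd) {
  if (is.null(params)) {
    params <- withr::with_seed(seed, .init_attention(list(), "att", cfg$d))
  }
  squeeze <- length(dim(x)) == 4
  if (squeeze) dim(x) <- c(dim(x), 1L)
  batch <- dim(x)[5]
  P <- wrap_params(params, leaf = FALSE)
  out <- fwd(ad_const(features_to_conv(x, cfg)), P, "att", cfg)
  out <- conv_to_features(ad_value(out), cfg, batch)
  if (squeeze) dim(out) <- dim(out)[1:4]
  out
}

#' Inverted bottleneck residual block
#'
#' Pointwise expansion to `k * cin` channels (ReLU6), 3x3 depthwise
#' convolution with stride 1 and same padding (ReLU6), and a linear
#' pointwise projection to `cout`; a residual connection is added when
#' `cin == cout`.
#'
#' @param x An `h x w x cin` array (one frame), or `h x w x cin x 2T (x N)`.
#' @param cin,cout Input/output channel counts.
#' @param k Expansion factor.
#' @param params Flat parameter list (`.expand`, `.dw`, `.proj` entries);
#'   freshly initialised when omitted.
#' @param h,w Grid size.
#' @param seed Seed for the default parameter draw.
#' @return Array shaped like `x` with `cout` channels.
#' @export
bottleneck_block <- function(x, cin, cout, k = 2, params = NULL,
                             h = dim(x)[1], w = dim(x)[2], seed = 1L) {
  if (is.null(params)) {
    params <- withr::with_seed(seed, .init_block(list(), "blk", cin, cout, k))
  }
  nd <- length(dim(x))
  d0 <- dim(x)
  if (nd == 3) dim(x) <- c(d0, 1L, 1L)
  if (nd == 4) dim(x) <- c(d0, 1L)
  cfg <- list(h = h, w = w)
  frames <- dim(x)[4]; batch <- dim(x)[5]
  xm <- aperm(x, c(1, 2, 4, 5, 3))
  dim(xm) <- c(h * w * frames * batch, cin)
  P <- wrap_params(params, leaf = FALSE)
  out <- ad_value(.fwd_block(ad_const(xm), P, "blk", cfg, cin, cout))
  dim(out) <- c(h, w, frames, batch, cout)
  out <- aperm(out, c(1, 2, 5, 3, 4))
  if (nd == 3) dim(out) <- c(h, w, cout)
  if (nd == 4) dim(out) <- c(h, w, cout, frames)
  out
}

#' @rdname attention_module
#' @export
bottleneck_module_d <- function(x, params = NULL, cfg = model_config(),
                                seed = 1L) {
  if (is.null(params)) params <- init_discriminator(cfg, seed)$params
  squeeze <- length(dim(x)) == 4
  if (squeeze) dim(x) <- c(dim(x), 1L)
  batch <- dim(x)[5]
  P <- wrap_params(params, leaf = FALSE)
  S <- cfg$h * cfg$w
  n <- ad_const(features_to_conv(x, cfg))
  n <- .fwd_trunk(n, P, .d_blocks(cfg), cfg)
  n <- ad_spatial(n, .pool_op(cfg), S)
  FB <- cfg$frames * batch
  n <- ad_reshape(n, c(cfg$pooled, FB, cfg$out))
  n <- ad_reshape(ad_aperm(n, c(2, 1, 3)), c(FB, cfg$pooled * cfg$out))
  tok <- ad_value(.fwd_linear(n, P, "fc"))               # FB x token_dim
  out <- array(t(tok), dim = c(cfg$token_dim, cfg$frames, batch))
  if (squeeze) dim(out) <- dim(out)[1:2]
  out
}

#' @rdname attention_module
#' @export
bottleneck_module_g <- function(x, params = NULL, cfg = model_config(),
                                seed = 2L) {
  if (is.null(params)) params <- init_generator(cfg, seed)$params
  squeeze <- length(dim(x)) == 4
  if (squeeze) dim(x) <- c(dim(x), 1L)
  batch <- dim(x)[5]
  P <- wrap_params(params, leaf = FALSE)
  out <- ad_value(.fwd_trunk(ad_const(features_to_conv(x, cfg)), P,
                             .g_blocks(cfg), cfg))
  out <- conv_to_features(out, cfg, batch)
  if (squeeze) dim(out) <- dim(out)[1:4]
  out
}

#' Transformer encoder over frame tokens
#'
#' `tf_blocks` pre-norm blocks of multi-head self-attention and a
#' GELU MLP, each with a residual connection and dropout; a learned
#' positional embedding is added first unless `cfg$positional` is
#' `FALSE`.
#'
#' @param tokens A `token_dim x 2T` matrix (feature dimension x time), or
#'   `token_dim x 2T x N` for a batch.
#' @param params Flat parameter list; freshly initialised when omitted.
#' @param cfg An [model_config()].
#' @param train Apply dropout.
#' @param seed Seed for the default parameter draw.
#' @return Tokens of the same shape.
#' @export
transformer_encoder <- function(tokens, params = NULL, cfg = model_config(),
                                train = FALSE, seed = 1L) {
  if (is.null(params)) {
    params <- withr::with_seed(seed, .init_transformer(list(), "tf", cfg))
  }
  squeeze <- length(dim(tokens)) == 2
  if (squeeze) dim(tokens) <- c(dim(tokens), 1L)
  batch <- dim(tokens)[3]
  stopifnot(dim(tokens)[1] == cfg$token_dim, dim(tokens)[2] == cfg$frames)
  x <- aperm(tokens, c(2, 3, 1))                  # frames, batch, dim
  dim(x) <- c(cfg$frames * batch, cfg$token_dim)
  P <- wrap_params(params, leaf = FALSE)
  out <- ad_value(.fwd_transformer(ad_const(x), P, "tf", cfg, batch, train))
  dim(out) <- c(cfg$frames, batch, cfg$token_dim)
  out <- aperm(out, c(3, 1, 2))
  if (squeeze) dim(out) <- dim(out)[1:2]
  out
}
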