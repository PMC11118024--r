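# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every network forward pass in this package is expressed in the small set of
# primitives below. Each primitive computes its value eagerly and registers
# vector-Jacobian products (vjps) that are themselves built from the same
# primitives, so gradients are ordinary tape nodes and can be differentiated
# again. Higher-order gradients are needed once, but crucially: the WGAN
# gradient penalty differentiates the norm of an input gradient with respect
# to the model parameters (double backprop). Piecewise-linear activations
# (ReLU6) register constant masks, whose second derivative is zero almost
# everywhere; smooth primitives (sigmoid, exp, sqrt, division) register vjps
# through live nodes so curvature is propagated exactly.

.ad_env <- new.env(parent = emptyenv())
.ad_env$id <- 0L

ad_next_id <- function() {
  .ad_env$id <- .ad_env$id + 1L
  .ad_env$id
}

#' Wrap a numeric array as an autodiff tape node
#'
#' `ad_const()` creates a node that does not require gradients;
#' `ad_leaf()` creates a differentiable leaf (a parameter or an input that
#' gradients are taken with respect to, e.g. the mixed sample of the
#' gradient penalty).
#'
#' Nodes are environments rather than classed lists: attribute-setting on
#' lists duplicates them (a measurable cost at one node per tensor op),
#' and environments give the tape cheap identity semantics.
#'
#' @param x Numeric vector, matrix or array.
#' @return An `adnode` environment.
#' @keywords internal
ad_const <- function(x) {
  if (!is.array(x) && !is.matrix(x)) x <- as.matrix(x)
  e <- new.env(parent = emptyenv())
  e$value <- x; e$parents <- list(); e$vjps <- list()
  e$req <- FALSE; e$id <- ad_next_id()
  e
}

#' @rdname ad_const
#' @keywords internal
ad_leaf <- function(x) {
  e <- ad_const(x)
  e$req <- TRUE
  e
}

ad_node <- function(value, parents, vjps) {
  req <- FALSE
  for (p in parents) if (p$req) { req <- TRUE; break }
  e <- new.env(parent = emptyenv())
  e$value <- value; e$parents <- parents
  e$vjps <- if (req) vjps else list()
  e$req <- req; e$id <- ad_next_id()
  e
}

is_adnode <- function(x) is.environment(x) && !is.null(x$id)

#' Value of a tape node
#' @param x An `adnode`.
#' @return The numeric array stored at the node.
#' @keywords internal
ad_value <- function(x) if (is_adnode(x)) x$value else x

as_adnode <- function(x) if (is_adnode(x)) x else ad_const(x)

# ---- arithmetic primitives -------------------------------------------------

ad_add <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value + b$value, list(a, b),
          list(function(g) g, function(g) g))
}

ad_neg <- function(a) {
  ad_node(-a$value, list(a), list(function(g) ad_neg(g)))
}

ad_sub <- function(a, b) ad_add(a, ad_neg(b))

ad_mul <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value * b$value, list(a, b),
          list(function(g) ad_mul(g, b), function(g) ad_mul(g, a)))
}

# multiply / add by a plain numeric constant (scalar or same-shape array)
ad_cmul <- function(a, k) {
  ad_node(a$value * k, list(a), list(function(g) ad_cmul(g, k)))
}

ad_cadd <- function(a, k) {
  ad_node(a$value + k, list(a), list(function(g) g))
}

ad_div <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  out <- ad_node(a$value / b$value, list(a, b), list())
  if (out$req) {
    out$vjps <- list(
      function(g) ad_div(g, b),
      function(g) ad_neg(ad_div(ad_mul(g, out), b))
    )
  }
  out
}

ad_exp <- function(a) {
  out <- ad_node(exp(a$value), list(a), list())
  if (out$req) out$vjps <- list(function(g) ad_mul(g, out))
  out
}

ad_log <- function(a) {
  ad_node(log(a$value), list(a), list(function(g) ad_div(g, a)))
}

ad_sqrt <- function(a) {
  out <- ad_node(sqrt(a$value), list(a), list())
  if (out$req) out$vjps <- list(function(g) ad_cmul(ad_div(g, out), 0.5))
  out
}

ad_sigmoid <- function(a) {
  out <- ad_node(1 / (1 + exp(-a$value)), list(a), list())
  if (out$req) {
    out$vjps <- list(function(g)
      ad_mul(ad_mul(g, out), ad_cadd(ad_neg(out), 1)))
  }
  out
}

# ReLU6 clamps to [0, 6]; the local Jacobian is a 0/1 mask, constant a.e.
ad_relu6 <- function(a) {
  r <- cpp_relu6(a$value)
  mask <- r$mask
  ad_node(r$value, list(a), list(function(g) ad_cmul(g, mask)))
}

# ---- linear-algebra primitives --------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value %*% b$value, list(a, b),
          list(function(g) ad_matmul(g, ad_t(b)),
               function(g) ad_matmul(ad_t(a), g)))
}

ad_t <- function(a) {
  ad_node(t(a$value), list(a), list(function(g) ad_t(g)))
}

ad_sum <- function(a) {
  d <- dim(a$value)
  ad_node(matrix(sum(a$value), 1, 1), list(a),
          list(function(g) ad_fill(g, d)))
}

ad_mean <- function(a) ad_cmul(ad_sum(a), 1 / length(a$value))

# broadcast a 1x1 node to an arbitrary shape
ad_fill <- function(a, d) {
  ad_node(array(a$value[1], dim = d), list(a),
          list(function(g) ad_sum(g)))
}

ad_rowsum <- function(a) {
  ad_node(matrix(rowSums(a$value), ncol = 1), list(a),
          list(function(g) ad_rep_cols(g, ncol(a$value))))
}

ad_colsum <- function(a) {
  ad_node(matrix(colSums(a$value), nrow = 1), list(a),
          list(function(g) ad_rep_rows(g, nrow(a$value))))
}

ad_rep_rows <- function(a, n) {                    # 1xC -> NxC
  ad_node(matrix(a$value, n, ncol(a$value), byrow = TRUE), list(a),
          list(function(g) ad_colsum(g)))
}

ad_rep_cols <- function(a, n) {                    # Nx1 -> NxC
  ad_node(matrix(a$value, nrow(a$value), n), list(a),
          list(function(g) ad_rowsum(g)))
}

ad_reshape <- function(a, d) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- d
  ad_node(v, list(a), list(function(g) ad_reshape(g, old)))
}

ad_aperm <- function(a, perm) {
  inv <- order(perm)
  ad_node(aperm(a$value, perm), list(a),
          list(function(g) ad_aperm(g, inv)))
}

ad_slice_cols <- function(a, idx) {
  nc <- ncol(a$value)
  ad_node(a$value[, idx, drop = FALSE], list(a),
          list(function(g) ad_embed_cols(g, idx, nc)))
}

ad_embed_cols <- function(a, idx, nc) {
  v <- matrix(0, nrow(a$value), nc)
  v[, idx] <- a$value
  ad_node(v, list(a), list(function(g) ad_slice_cols(g, idx)))
}

ad_slice_rows <- function(a, idx) {
  nr <- nrow(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a),
          list(function(g) ad_embed_rows(g, idx, nr)))
}

ad_embed_rows <- function(a, idx, nr) {
  v <- matrix(0, nr, ncol(a$value))
  v[idx, ] <- a$value
  ad_node(v, list(a), list(function(g) ad_slice_rows(g, idx)))
}

ad_cbind <- function(a, b) {
  na <- ncol(a$value)
  nb <- ncol(b$value)
  ad_node(cbind(a$value, b$value), list(a, b),
          list(function(g) ad_slice_cols(g, seq_len(na)),
               function(g) ad_slice_cols(g, na + seq_len(nb))))
}

# Apply a constant linear operator M (s_out x s_in) along the leading
# "spatial" axis of an activation stored as an (s_in * G) x C matrix whose
# row index runs spatial-fastest. Used for depthwise shifts, pooling,
# up-sampling scatters and per-group reductions; the vjp is the transposed
# operator, so the primitive family is closed under differentiation.
ad_spatial <- function(a, M, s_in) {
  v <- a$value
  nr <- nrow(v); nc <- ncol(v)
  grp <- nr / s_in
  dim(v) <- c(s_in, grp * nc)
  out <- M %*% v
  dim(out) <- c(nrow(M) * grp, nc)
  tM <- t(M)
  s_out <- nrow(M)
  ad_node(out, list(a),
          list(function(g) ad_spatial(g, tM, s_out)))
}

# Depthwise tap mixing (fused kernel): for tap index maps `fwd`/`bwd`
# (S x 9 matrices of 1-based spatial sources, 0 = outside the grid),
# out[s, c] = sum_t W[t, c] * x[shift_t(s), c] (+ bias). The operator is
# bilinear in (x, W): the x-vjp is the same mix with the inverse index
# maps, and the W-vjp is the tap-correlation kernel `ad_dwwgrad`, itself
# bilinear with vjps expressed through `ad_dwmix` — closed under
# repeated differentiation, as the gradient penalty requires.
ad_dwmix <- function(x, W, fwd, bwd, bias = NULL) {
  has_b <- !is.null(bias)
  val <- cpp_dwmix(x$value, W$value, fwd,
                   if (has_b) as.numeric(bias$value) else NULL)
  parents <- list(x, W)
  vjps <- list(
    function(g) ad_dwmix(g, W, bwd, fwd),
    function(g) ad_dwwgrad(x, g, fwd, bwd)
  )
  if (has_b) {
    parents <- c(parents, list(bias))
    vjps <- c(vjps, list(function(g) ad_colsum(g)))
  }
  ad_node(val, parents, vjps)
}

ad_dwwgrad <- function(x, g, fwd, bwd) {
  ad_node(cpp_dwwgrad(x$value, g$value, fwd), list(x, g),
          list(function(h) ad_dwmix(g, h, bwd, fwd),
               function(h) ad_dwmix(x, h, fwd, bwd)))
}

# ---- backward pass ---------------------------------------------------------

#' Gradients of a tape node with respect to leaves
#'
#' Runs reverse-mode accumulation from `out` back to the nodes in `wrt`.
#' The returned gradients are themselves tape nodes, so they can be fed into
#' further tape computation and differentiated again (double backprop).
#'
#' @param out Output node (any shape; `seed` defaults to all ones).
#' @param wrt List of nodes to differentiate with respect to.
#' @param seed Optional cotangent node or array shaped like `out`.
#' @return A list of `adnode` gradients, one per element of `wrt`; zero
#'   arrays where `out` does not depend on the node.
#' @keywords internal
ad_grad <- function(out, wrt, seed = NULL) {
  if (is.null(seed)) seed <- ad_const(array(1, dim = dim(out$value)))
  seed <- as_adnode(seed)

  # iterative topological sort over the subgraph that requires gradients;
  # stack and topo are preallocated and grown geometrically so pushes stay
  # amortised O(1)
  topo <- vector("list", 4096L)
  ntopo <- 0L
  state <- new.env(parent = emptyenv())   # id -> 1 visiting, 2 done
  stack <- vector("list", 4096L)
  stack[[1L]] <- out
  nstack <- 1L
  while (nstack > 0L) {
    node <- stack[[nstack]]
    key <- as.character(node$id)
    st <- state[[key]]
    if (is.null(st)) {
      state[[key]] <- 1L
      pushed <- FALSE
      for (p in node$parents) {
        if (p$req && is.null(state[[as.character(p$id)]])) {
          if (nstack + 1L > length(stack)) {
            stack <- c(stack, vector("list", length(stack)))
          }
          nstack <- nstack + 1L
          stack[[nstack]] <- p
          pushed <- TRUE
        }
      }
      if (!pushed) {
        state[[key]] <- 2L
        if (ntopo + 1L > length(topo)) {
          topo <- c(topo, vector("list", length(topo)))
        }
        ntopo <- ntopo + 1L
        topo[[ntopo]] <- node
        nstack <- nstack - 1L
      }
    } else if (st == 1L) {
      state[[key]] <- 2L
      if (ntopo + 1L > length(topo)) {
        topo <- c(topo, vector("list", length(topo)))
      }
      ntopo <- ntopo + 1L
      topo[[ntopo]] <- node
      nstack <- nstack - 1L
    } else {
      nstack <- nstack - 1L
    }
  }

  grads <- new.env(parent = emptyenv())
  grads[[as.character(out$id)]] <- seed
  for (i in seq(ntopo, 1L)) {
    node <- topo[[i]]
    g <- grads[[as.character(node$id)]]
    if (is.null(g)) next
    if (length(node$vjps) == 0L) next
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req) next
      gp <- node$vjps[[j]](g)
      key <- as.character(p$id)
      acc <- grads[[key]]
      grads[[key]] <- if (is.null(acc)) gp else ad_add(acc, gp)
    }
  }

  lapply(wrt, function(w) {
    g <- grads[[as.character(w$id)]]
    if (is.null(g)) ad_const(array(0, dim = dim(w$value))) else g
  })
}

# row-broadcast bias add: x (NxC) + b (1xC)
ad_addbias <- function(x, b) {
  ad_node(cpp_addbias(x$value, as.numeric(b$value)), list(x, b),
          list(function(g) g, function(g) ad_colsum(g)))
}

# column scaling: x (NxC) * w (1xC), bilinear
ad_scale_cols <- function(x, w) {
  ad_node(cpp_scalecols(x$value, as.numeric(w$value)), list(x, w),
          list(function(g) ad_scale_cols(g, w),
               function(g) ad_colsum_prod(x, g)))
}

ad_colsum_prod <- function(x, g) {
  ad_node(cpp_colsum_prod(x$value, g$value), list(x, g),
          list(function(h) ad_scale_cols(g, h),
               function(h) ad_scale_cols(x, h)))
}

# ---- composite helpers used throughout the networks ------------------------

ad_linear <- function(x, W, b) ad_addbias(ad_matmul(x, W), b)

ad_scale_rows <- function(x, w) ad_mul(x, ad_rep_cols(w, ncol(x$value)))

# numerically stabilised softmax over rows; the row maximum enters as a
# constant shift (its derivative contribution is zero a.e.)
ad_softmax_rows <- function(x) {
  v <- x$value
  rmax <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- ad_exp(ad_cadd(x, -matrix(rmax, nrow(v), ncol(v))))
  ad_div(e, ad_rep_cols(ad_rowsum(e), ncol(v)))
}

# GELU realised through its sigmoid form x * sigmoid(1.702 x), which keeps
# the op inside the differentiable primitive set
ad_gelu <- function(x) ad_mul(x, ad_sigmoid(ad_cmul(x, 1.702)))

ad_dropout <- function(x, p, train) {
  if (!train || p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= p) / (1 - p)
  ad_cmul(x, mask)
}

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  nc <- ncol(x$value)
  mu <- ad_cmul(ad_rowsum(x), 1 / nc)
  xc <- ad_sub(x, ad_rep_cols(mu, nc))
  v <- ad_cmul(ad_rowsum(ad_mul(xc, xc)), 1 / nc)
  xn <- ad_div(xc, ad_rep_cols(ad_sqrt(ad_cadd(v, eps)), nc))
  ad_add(ad_scale_cols(xn, gamma), ad_rep_rows(beta, nrow(x$value)))
}
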