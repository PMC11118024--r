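# Automated complexity accounting: parameters and forward-pass FLOPs.

#' Count trainable parameters
#'
#' Sums the sizes of every array in a flat parameter list or model object.
#'
#' @param x An `fg_generator`, `fg_discriminator`, or flat parameter list.
#' @return Integer parameter count.
#' @export
count_params <- function(x) {
  p <- if (is.list(x) && !is.null(x$params)) x$params else x
  sum(vapply(p, length, 0L))
}

#' Count forward-pass floating-point operations
#'
#' Walks the architecture implied by a [model_config()] and accounts
#' 2 FLOPs per multiply-accumulate of every pointwise/depthwise
#' convolution, linear map, attention product and pooling sum for a single
#' input tensor (batch 1); cheap elementwise activations are excluded, the
#' usual convention of FLOP audits. Under the `"full"` profile and the
#' default expansion `k = 2` the discriminator forward pass lands at about
#' 0.21 GFLOPs.
#'
#' @param cfg An [model_config()].
#' @param part `"discriminator"` or `"generator"`.
#' @return A tibble with one row per component: `component`, `flops`; the
#'   total is `sum(result$flops)`.
#' @examples
#' sum(count_flops(model_config())$flops) / 1e9   # GFLOPs
#' @export
count_flops <- function(cfg = model_config(),
                        part = c("discriminator", "generator")) {
  part <- match.arg(part)
  S <- cfg$h * cfg$w
  Fr <- cfg$frames
  N <- S * Fr                                   # spatial-temporal positions
  D <- cfg$token_dim
  rows <- list()
  add <- function(component, flops) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(component = component,
                                                 flops = flops)
  }

  att_flops <- function() {
    dr <- max(2L, cfg$d %/% 2L)
    add("attention.spatial", 2 * N * cfg$d * 1 + N * cfg$d)
    add("attention.frequency",
        N * cfg$d +                              # global spatial pooling
        2 * Fr * cfg$d * dr + 2 * Fr * dr * cfg$d +
        N * cfg$d)                               # band gating
    add("attention.merge", 2 * N * cfg$d)
  }
  block_flops <- function(name, cin, cout) {
    hid <- cfg$k * cin
    fl <- 2 * N * cin * hid + 2 * N * 9 * hid + 2 * N * hid * cout
    if (cin == cout) fl <- fl + N * cout
    add(name, fl)
  }
  tf_flops <- function() {
    dh <- D %/% cfg$heads
    per <- 4 * (2 * Fr * D * D) +               # q, k, v, o projections
      2 * 2 * Fr * Fr * dh * cfg$heads +        # scores and weighted sum
      2 * Fr * D * cfg$mlp_hidden * 2           # MLP in/out
    add("transformer", cfg$tf_blocks * per + Fr * D)
  }

  if (part == "discriminator") {
    att_flops()
    blocks <- .d_blocks(cfg)
    for (nm in names(blocks)) block_flops(nm, blocks[[nm]][1],
                                          blocks[[nm]][2])
    add("avgpool", N * cfg$out)
    add("fc", 2 * Fr * cfg$pooled * cfg$out * D)
    tf_flops()
    add("heads", 2 * D * (1 + cfg$n_classes))
  } else {
    add("embed", 2 * (cfg$nz + cfg$n_classes) * Fr * D)
    tf_flops()
    Kn <- cfg$deconv_kh * cfg$deconv_kw
    add("deconv", cfg$coarse_h * cfg$coarse_w *
          2 * Fr * cfg$deconv_cc * Kn * cfg$d)
    att_flops()
    blocks <- .g_blocks(cfg)
    for (nm in names(blocks)) block_flops(nm, blocks[[nm]][1],
                                          blocks[[nm]][2])
  }
  dplyr::bind_rows(rows)
}

#' Architecture summary
#'
#' Prints per-component parameter and FLOP counts of the full model (the
#' fatigue classifier is the discriminator path; the generator is listed
#' separately).
#'
#' @param cfg An [model_config()].
#' @return (Invisibly) a tibble with `part`, `component`, `flops`.
#' @export
model_summary <- function(cfg = model_config()) {
  d <- dplyr::mutate(count_flops(cfg, "discriminator"),
                     part = "discriminator")
  g <- dplyr::mutate(count_flops(cfg, "generator"), part = "generator")
  out <- dplyr::bind_rows(d, g)[, c("part", "component", "flops")]
  cat(sprintf("profile '%s': discriminator %.4f GFLOPs (%s params), ",
              cfg$profile, sum(d$flops) / 1e9,
              format(count_params(init_discriminator(cfg)$params),
                     big.mark = ",")))
  cat(sprintf("generator %.4f GFLOPs (%s params)\n",
              sum(g$flops) / 1e9,
              format(count_params(init_generator(cfg)$params),
                     big.mark = ",")))
  invisible(out)
}
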