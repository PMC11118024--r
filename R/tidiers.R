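# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy cross-validation results
#'
#' @param x A `fatigue_cv` from [crossvalidate()].
#' @param ... Unused.
#' @return `tidy()`: one row per fold with the classification metrics;
#'   `glance()`: a one-row tibble of fold means plus fold count.
#' @export
tidy.fatigue_cv <- function(x, ...) x$per_fold

#' @rdname tidy.fatigue_cv
#' @export
glance.fatigue_cv <- function(x, ...) {
  dplyr::bind_cols(x$summary, tibble::tibble(folds = x$folds,
                                             selection = x$selection))
}

#' @rdname tidy.fatigue_cv
#' @param object A `fatigue_cv`.
#' @export
autoplot.fatigue_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_fold, -"fold",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = "Cross-validated classification metrics") +
    ggplot2::theme_minimal()
}

#' Tidy GAN training logs
#'
#' @param x A `fatigue_gan` from [train_gan()].
#' @param ... Unused.
#' @return `tidy()`: the per-step loss log in long format; `glance()`:
#'   a one-row tibble with the final step's loss components.
#' @export
tidy.fatigue_gan <- function(x, ...) {
  tidyr::pivot_longer(x$log, c("l_adv", "gp", "l_cls_r", "l_cls_f",
                               "l_d", "l_g"),
                      names_to = "loss", values_to = "value")
}

#' @rdname tidy.fatigue_gan
#' @export
glance.fatigue_gan <- function(x, ...) {
  dplyr::bind_cols(x$last, tibble::tibble(steps = x$step,
                                          profile = x$model_cfg$profile))
}

#' @rdname tidy.fatigue_gan
#' @param object A `fatigue_gan`.
#' @export
autoplot.fatigue_gan <- function(object, ...) {
  d <- tidy.fatigue_gan(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL,
                  title = "Adversarial training losses") +
    ggplot2::theme_minimal()
}

#' Tidy a wavelet-coherence report
#'
#' @param x A `wc_report` from [wavelet_coherence()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble with `time`, `period`, `coherence`;
#'   `glance()`: a one-row tibble with the scalar score and grid size.
#' @export
tidy.wc_report <- function(x, ...) {
  tibble::tibble(
    time = rep(seq_len(ncol(x$matrix)), each = nrow(x$matrix)),
    period = rep(x$periods, ncol(x$matrix)),
    coherence = as.vector(x$matrix)
  )
}

#' @rdname tidy.wc_report
#' @export
glance.wc_report <- function(x, ...) {
  tibble::tibble(scalar = x$scalar, n_scales = nrow(x$matrix),
                 n_time = ncol(x$matrix))
}

#' @rdname tidy.wc_report
#' @param object A `wc_report`.
#' @export
autoplot.wc_report <- function(object, ...) {
  d <- tidy.wc_report(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$period,
                                  fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (samples)", y = "period (samples)",
                  title = "Wavelet coherence") +
    ggplot2::theme_minimal()
}
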