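# Confidence-based selection of generated samples and the training-set
# mixing experiment (real vs synthetic signal sources).

#' Confidence-based selection rule
#'
#' Applies the selection rule to a table of class probabilities: a sample
#' is kept when its maximum class probability meets or exceeds the
#' threshold *and* its predicted class equals its conditioning label.
#' The label-agreement requirement extends the plain confidence cut:
#' without it, confidently mis-classified samples would enter the
#' training set under the wrong label.
#'
#' @param probs A samples x classes probability matrix.
#' @param labels Conditioning labels (factor or 1-based integers mapping
#'   to the probability columns).
#' @param threshold Confidence threshold in `(0, 1]` (default 0.90).
#' @return Logical vector of kept samples.
#' @export
select_by_confidence <- function(probs, labels, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  idx <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  stopifnot(all(idx >= 1L & idx <= ncol(probs)))
  conf <- probs[cbind(seq_len(nrow(probs)), max.col(probs, "first"))]
  agree <- max.col(probs, "first") == idx
  conf >= threshold & agree
}

#' Filter generated samples by classifier confidence
#'
#' Scores every sample of a generated dataset with a trained classifier
#' (typically the GAN discriminator's class head) and keeps the samples
#' passing [select_by_confidence()]. An empty selection is allowed and
#' reported with a warning.
#'
#' @param ds A [feature_dataset()] of generated samples with conditioning
#'   labels.
#' @param classifier A `fatigue_clf`, or a `fatigue_gan` whose
#'   discriminator is used.
#' @param threshold Confidence threshold (default 0.90).
#' @return A list: `dataset` (the kept subset), `kept` (logical vector),
#'   `retention` (one-row tibble with counts and the retention rate).
#' @export
select_confident <- function(ds, classifier, threshold = 0.9) {
  if (inherits(classifier, "fatigue_gan")) {
    classifier <- list(D = classifier$D, model_cfg = classifier$model_cfg,
                       levels = classifier$levels)
  }
  probs <- predict_classifier(classifier, ds)$probs
  keep <- select_by_confidence(probs, ds$labels, threshold)
  if (!any(keep)) {
    warning("no generated sample met the confidence threshold ",
            threshold, call. = FALSE)
  }
  list(dataset = subset_dataset(ds, which(keep)), kept = keep,
       retention = tibble::tibble(n = length(keep), kept = sum(keep),
                                  rate = mean(keep),
                                  threshold = threshold))
}

#' Mixing-scenario specification
#'
#' The four training-data compositions compared in the mixing experiment:
#' purely real samples, purely synthetic samples, only a few real samples
#' (a `real_frac` fraction of the total), and the hybrid of those few
#' real samples topped up to the full total with synthetic ones. The
#' three full-size scenarios share the same aggregate volume; `few_real`
#' is deliberately smaller — it models the scarce-data regime the hybrid
#' scenario is meant to rescue.
#'
#' @param scenario One of `"pure_real"`, `"pure_synth"`, `"few_real"`,
#'   `"few_real_plus_synth"`.
#' @param total Total training-set size of the full-size scenarios.
#' @param real_frac Fraction of `total` that counts as "a few" real
#'   samples (default 0.2).
#' @return A `mix_spec` list with resolved `n_real` and `n_synth`.
#' @export
mix_spec <- function(scenario = c("pure_real", "pure_synth", "few_real",
                                  "few_real_plus_synth"),
                     total = 100, real_frac = 0.2) {
  scenario <- match.arg(scenario)
  few <- round(total * real_frac)
  n <- switch(scenario,
              pure_real = c(total, 0),
              pure_synth = c(0, total),
              few_real = c(few, 0),
              few_real_plus_synth = c(few, total - few))
  structure(list(scenario = scenario, total = total,
                 real_frac = real_frac, n_real = n[1], n_synth = n[2]),
            class = "mix_spec")
}

# stratified sample of `n` indices from a label vector, without
# replacement, preserving the class proportions
.stratified_take <- function(labels, n) {
  if (n == 0) return(integer(0))
  if (n > length(labels)) {
    stop("requested ", n, " samples but only ", length(labels),
         " available (deficit ", n - length(labels), ")", call. = FALSE)
  }
  lev <- levels(labels)
  per <- floor(n * table(labels) / length(labels))
  pick <- function(pool, k) pool[sample.int(length(pool), k)]
  take <- unlist(lapply(lev, function(cl) {
    pick(which(labels == cl), min(per[[cl]], sum(labels == cl)))
  }))
  short <- n - length(take)
  if (short > 0) {
    take <- c(take, pick(setdiff(seq_along(labels), take), short))
  }
  take
}

#' Assemble a mixed real/synthetic training set
#'
#' Draws the scenario's real and synthetic sample counts without
#' replacement, stratified by class within each source; deterministic for
#' a given seed. No sample is ever duplicated within a scenario.
#'
#' @param real,synth [feature_dataset()] objects (the synthetic one may
#'   be `NULL` for real-only scenarios).
#' @param spec A [mix_spec()].
#' @param seed Integer seed.
#' @return A [feature_dataset()] with `spec$n_real + spec$n_synth`
#'   samples and a `source` attribute marking each sample's origin.
#' @export
build_mix <- function(real, synth = NULL, spec, seed = 1L) {
  withr::with_seed(seed, {
    ir <- .stratified_take(real$labels, spec$n_real)
    is <- if (spec$n_synth > 0) {
      if (is.null(synth)) stop("scenario needs synthetic samples",
                               call. = FALSE)
      .stratified_take(synth$labels, spec$n_synth)
    } else integer(0)
  })
  parts <- list()
  if (length(ir) > 0) parts <- c(parts, list(subset_dataset(real, ir)))
  if (length(is) > 0) parts <- c(parts, list(subset_dataset(synth, is)))
  out <- if (length(parts) == 1) parts[[1]] else do.call(bind_datasets,
                                                         parts)
  attr(out, "source") <- rep(c("real", "synth"),
                             c(length(ir), length(is)))
  attr(out, "index") <- list(real = sort(ir), synth = sort(is))
  out
}

#' Run the four-scenario mixing experiment
#'
#' For each scenario a fresh classifier (the discriminator backbone with
#' the critic head unused) is trained from scratch on the scenario's
#' training set and evaluated on a common held-out real test set.
#' Synthetic samples come from the trained GAN and pass the
#' confidence-selection filter first. Scenario orderings are reported,
#' not enforced.
#'
#' @param real A real [feature_dataset()]; part is held out for testing.
#' @param gan A trained `fatigue_gan` supplying synthetic samples and the
#'   confidence classifier.
#' @param total Training-set size of the full-size scenarios.
#' @param real_frac "Few real" fraction.
#' @param threshold Confidence-selection threshold.
#' @param test_frac Fraction of `real` held out as the common test set.
#' @param epochs,batch,lr,model_cfg Classifier training settings.
#' @param seed Seed for the split, generation and training.
#' @return A tibble with one row per scenario: sample counts and
#'   classification metrics on the common test set.
#' @export
run_mixing_experiment <- function(real, gan, total = 100, real_frac = 0.2,
                                  threshold = 0.9, test_frac = 0.25,
                                  epochs = 4, batch = 20, lr = 1e-3,
                                  model_cfg = gan$model_cfg, seed = 1L) {
  n <- n_samples(real)
  test_idx <- withr::with_seed(seed,
                               .stratified_take(real$labels,
                                                round(test_frac * n)))
  test_ds <- subset_dataset(real, test_idx)
  pool <- subset_dataset(real, setdiff(seq_len(n), test_idx))

  # oversample generated candidates so the confidence filter can afford
  # to discard; if the filter keeps fewer than the scenarios need, the
  # shortfall is topped up with the highest-confidence remaining samples
  # so every scenario reaches its specified size
  want <- 2L * total
  lab <- rep(levels(real$labels), length.out = want)
  synth_raw <- generate_samples(gan, lab, seed = seed + 1L)
  sel <- suppressWarnings(select_confident(synth_raw, gan, threshold))
  synth <- sel$dataset
  if (n_samples(synth) < total) {
    probs <- predict_classifier(list(D = gan$D, model_cfg = gan$model_cfg,
                                     levels = gan$levels), synth_raw)$probs
    lab_conf <- probs[cbind(seq_len(nrow(probs)),
                            as.integer(synth_raw$labels))]
    rest <- order(lab_conf, decreasing = TRUE)
    rest <- setdiff(rest, which(sel$kept))
    need <- total - n_samples(synth)
    synth <- bind_datasets(synth,
                           subset_dataset(synth_raw, rest[seq_len(need)]))
  }

  scenarios <- c("pure_real", "pure_synth", "few_real",
                 "few_real_plus_synth")
  rows <- lapply(scenarios, function(sc) {
    spec <- mix_spec(sc, total = total, real_frac = real_frac)
    ds <- build_mix(pool, synth, spec, seed = seed + 2L)
    clf <- train_classifier(ds, eval_ds = NULL, epochs = epochs,
                            batch = batch, lr = lr,
                            model_cfg = model_cfg, seed = seed + 3L)
    pred <- predict_classifier(clf, test_ds)
    dplyr::bind_cols(
      tibble::tibble(scenario = sc, n_train = n_samples(ds),
                     n_real = spec$n_real, n_synth = spec$n_synth),
      classification_metrics(test_ds$labels, pred$class)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "retention") <- sel$retention
  out
}
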