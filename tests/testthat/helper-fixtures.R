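# Shared fixtures, generated once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  hit <- .fixtures[[name]]
  if (is.null(hit)) {
    hit <- make()
    .fixtures[[name]] <- hit
  }
  hit
}

# small balanced synthetic feature dataset (80 windows) used by most
# training-scale tests
small_dataset <- function() {
  fixture("small_ds", function() {
    generate_feature_dataset(synth_config(seed = 101L),
                             c(awake = 40, fatigue = 40))
  })
}

# a briefly trained compact GAN shared by generation/selection tests
small_gan <- function() {
  fixture("small_gan", function() {
    train_gan(small_dataset(), steps = 250,
              model_cfg = model_config("compact"),
              train_cfg = train_config(batch = 16, seed = 5,
                                       lr_g = 5e-4, lr_d = 5e-4))
  })
}

random_features <- function(batch = 1, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(6 * 9 * 5 * 16 * batch),
                               c(6, 9, 5, 16, batch)))
}
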