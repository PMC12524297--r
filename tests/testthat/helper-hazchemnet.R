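# Shared helpers: a down-scaled network configuration sized for seconds-long
# unit tests, and generators for small labelled fixtures.

tiny_config <- function(...) {
  defaults <- list(hidden_dim = 16L, latent_dim = 4L, expert_hidden = 4L,
                   M = 2L, ae_epochs = 5L, moe_epochs = 10L,
                   batch_size = 32L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(hazchemnet_config, args)
}

# mid-sized config used where the classifier actually has to learn
learn_config <- function(...) {
  defaults <- list(hidden_dim = 64L, latent_dim = 16L, expert_hidden = 16L,
                   M = 4L, ae_epochs = 40L, moe_epochs = 60L,
                   batch_size = 32L, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(hazchemnet_config, args)
}

# separable two-class feature fixture at the generator's default study
# conditions, scaled to n
separable_features <- function(n_per_class = 50, seed = 7) {
  generate_synthetic_features(n_per_class = n_per_class, seed = seed)
}

# randomized-but-reproducible network parameters with biases pulled off the
# ReLU kinks (exact-zero pre-activations make finite differences and
# subgradients disagree at the nondifferentiable point)
random_ae <- function(input_dim = 7, hidden_dim = 4, latent_dim = 3,
                      seed = 9) {
  p <- autoencoder_init(input_dim, hidden_dim, latent_dim, seed = seed)
  set.seed(seed + 1)
  for (k in c("b1", "b2", "ba", "b3", "b4")) {
    p[[k]] <- stats::rnorm(length(p[[k]]), sd = 0.3)
  }
  p
}
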