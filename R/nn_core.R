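# Shared numerical building blocks for the autoencoder and the
# mixture-of-experts: activations, stable row-wise softmax, Glorot
# initialization, an Adam optimizer over arbitrary parameter lists, and
# named sub-seeds derived from one master seed.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max subtraction: overflow-free for any finite input.
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package (weight initialization, shuffling, fold
#' assignment, synthetic data) flows from one master seed through named
#' sub-streams, so components are independently reproducible.
#'
#' @param master Integer master seed.
#' @param stream Stream name, e.g. "init", "shuffle", "split", "synth".
#' @param index Optional extra integer (e.g. fold or repeat number).
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, stream, index = 0L) {
  h <- hcn_hash(c(as.numeric(master) %% 33554393,
                  utf8ToInt(as.character(stream)),
                  as.numeric(index)))
  as.integer(h %% 2147483647)
}

# mini-batch index sets for one epoch (deterministic given the RNG state)
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
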