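#' Initialize attention-autoencoder parameters
#'
#' The network chains input -> hidden -> latent -> (attention reweighting)
#' -> hidden -> input: two ReLU encoder layers, a tanh + softmax attention
#' head over the latent code, and a two-layer decoder (ReLU hidden, linear
#' output, since the inputs are standardized and may be negative).
#'
#' @param input_dim Number of input features (516 for the full feature set).
#' @param hidden_dim,latent_dim Layer widths.
#' @param seed Seed for Glorot-uniform initialization.
#' @return Object of class \code{hcn_autoencoder}.
#' @export
autoencoder_init <- function(input_dim, hidden_dim, latent_dim, seed = 1L) {
  set.seed(seed)
  structure(list(
    W1 = glorot(input_dim, hidden_dim), b1 = numeric(hidden_dim),
    W2 = glorot(hidden_dim, latent_dim), b2 = numeric(latent_dim),
    Wa = glorot(latent_dim, latent_dim), ba = numeric(latent_dim),
    W3 = glorot(latent_dim, hidden_dim), b3 = numeric(hidden_dim),
    W4 = glorot(hidden_dim, input_dim), b4 = numeric(input_dim),
    input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
    latent_dim = as.integer(latent_dim)),
    class = "hcn_autoencoder")
}

ae_weight_names <- c("W1", "b1", "W2", "b2", "Wa", "ba", "W3", "b3",
                     "W4", "b4")

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L, ncol = length(x))
}

#' Encode features into the latent space
#'
#' \code{z = ReLU(W2 ReLU(W1 x + b1) + b2)}; all latent entries are >= 0.
#'
#' @param x Standardized feature vector or matrix (rows = samples).
#' @param p An \code{hcn_autoencoder}.
#' @return Latent matrix (n x latent_dim); a vector input gives a 1-row
#'   matrix.
#' @export
encode <- function(x, p) {
  stopifnot(inherits(p, "hcn_autoencoder"))
  X <- as_row_matrix(x)
  if (ncol(X) != nrow(p$W1)) {
    stop("input has ", ncol(X), " features, encoder expects ", nrow(p$W1))
  }
  H1 <- relu(sweep(X %*% p$W1, 2L, p$b1, "+"))
  relu(sweep(H1 %*% p$W2, 2L, p$b2, "+"))
}

#' Attention weights over the latent code
#'
#' \code{u = tanh(Wa z + ba)}, \code{alpha = softmax(u)} (over latent
#' dimensions, per sample), \code{z' = alpha * z} element-wise. The weights
#' are strictly positive and sum to 1 per sample; softmax is computed with
#' max subtraction, so any finite input is safe.
#'
#' @param z Latent vector or matrix (rows = samples).
#' @param Wa,ba Attention weight matrix (latent x latent) and bias.
#' @return List with \code{alpha} and \code{z_prime}, both n x latent_dim.
#' @export
attention_weights <- function(z, Wa, ba) {
  Z <- as_row_matrix(z)
  if (ncol(Z) != nrow(Wa)) stop("latent/attention dimension mismatch")
  U <- tanh(sweep(Z %*% Wa, 2L, ba, "+"))
  A <- softmax_rows(U)
  list(alpha = A, z_prime = A * Z, u = U)
}

#' Decode an attention-weighted latent code
#'
#' @param z_prime Weighted latent vector or matrix.
#' @param p An \code{hcn_autoencoder}.
#' @return Reconstruction matrix (n x input_dim).
#' @export
decode <- function(z_prime, p) {
  stopifnot(inherits(p, "hcn_autoencoder"))
  Zp <- as_row_matrix(z_prime)
  if (ncol(Zp) != nrow(p$W3)) stop("latent dimension mismatch in decoder")
  H2 <- relu(sweep(Zp %*% p$W3, 2L, p$b3, "+"))
  sweep(H2 %*% p$W4, 2L, p$b4, "+")
}

#' Mean squared reconstruction error
#'
#' Mean over all samples and feature dimensions of the squared difference;
#' zero if and only if the matrices are equal.
#'
#' @param X,X_hat Matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_hat) {
  X <- as_row_matrix(X); X_hat <- as_row_matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("shape mismatch in reconstruction loss")
  mean((X - X_hat)^2)
}

# Full forward pass keeping intermediates for backprop.
ae_forward <- function(X, p) {
  H1pre <- sweep(X %*% p$W1, 2L, p$b1, "+"); H1 <- relu(H1pre)
  Zpre <- sweep(H1 %*% p$W2, 2L, p$b2, "+"); Z <- relu(Zpre)
  att <- attention_weights(Z, p$Wa, p$ba)
  H2pre <- sweep(att$z_prime %*% p$W3, 2L, p$b3, "+"); H2 <- relu(H2pre)
  Xh <- sweep(H2 %*% p$W4, 2L, p$b4, "+")
  list(H1 = H1, Z = Z, U = att$u, A = att$alpha, Zp = att$z_prime,
       H2 = H2, Xh = Xh)
}

# Backprop of dL/dZp through attention and encoder (shared by the decoder
# path and by joint fine-tuning, where the gradient arrives from the MoE).
ae_backprop_encoder <- function(X, fw, p, dZp) {
  dA <- dZp * fw$Z
  dZ <- dZp * fw$A
  dU <- fw$A * (dA - rowSums(dA * fw$A))
  dUpre <- dU * (1 - fw$U^2)
  dZ <- dZ + dUpre %*% t(p$Wa)
  dZpre <- dZ * (fw$Z > 0)
  dH1 <- (dZpre %*% t(p$W2)) * (fw$H1 > 0)
  list(W1 = t(X) %*% dH1, b1 = colSums(dH1),
       W2 = t(fw$H1) %*% dZpre, b2 = colSums(dZpre),
       Wa = t(fw$Z) %*% dUpre, ba = colSums(dUpre))
}

ae_backward <- function(X, fw, p) {
  n <- nrow(X); d <- ncol(X)
  dXh <- 2 * (fw$Xh - X) / (n * d)
  dH2 <- (dXh %*% t(p$W4)) * (fw$H2 > 0)
  dZp <- dH2 %*% t(p$W3)
  enc <- ae_backprop_encoder(X, fw, p, dZp)
  c(enc, list(W3 = t(fw$Zp) %*% dH2, b3 = colSums(dH2),
              W4 = t(fw$H2) %*% dXh, b4 = colSums(dXh)))
}

#' Train the attention autoencoder
#'
#' Minimizes mean squared reconstruction error with Adam. Epoch 0 of the
#' returned trace is the loss of the untrained network, so the first row is
#' the pre-training baseline. Deterministic given \code{cfg$seed}.
#'
#' @param X_train Standardized training feature matrix.
#' @param X_val Optional standardized validation matrix (adds a \code{val}
#'   column to the trace).
#' @param cfg A \code{\link{hazchemnet_config}}.
#' @return List with \code{params} (\code{hcn_autoencoder}) and \code{trace}
#'   (data frame epoch / train / val).
#' @export
train_autoencoder <- function(X_train, X_val = NULL, cfg = hazchemnet_config()) {
  X_train <- as.matrix(X_train)
  stopifnot(nrow(X_train) >= 2L)
  p <- autoencoder_init(ncol(X_train), cfg$hidden_dim, cfg$latent_dim,
                        seed = derive_seed(cfg$seed, "ae_init"))
  st <- adam_init(p[ae_weight_names])
  eval_loss <- function(M) reconstruction_loss(M, ae_forward(M, p)$Xh)
  trace <- data.frame(epoch = 0L, train = eval_loss(X_train),
                      val = if (is.null(X_val)) NA_real_ else eval_loss(X_val))
  set.seed(derive_seed(cfg$seed, "ae_shuffle"))
  for (epoch in seq_len(cfg$ae_epochs)) {
    for (batch in minibatches(nrow(X_train), cfg$batch_size)) {
      Xb <- X_train[batch, , drop = FALSE]
      fw <- ae_forward(Xb, p)
      g <- ae_backward(Xb, fw, p)
      upd <- adam_step(p[ae_weight_names], g, st, lr = cfg$learning_rate)
      p[ae_weight_names] <- upd$params
      st <- upd$state
    }
    tr <- eval_loss(X_train)
    if (!is.finite(tr)) {
      stop("autoencoder training diverged (non-finite loss) at epoch ", epoch,
           "; lower the learning rate")
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, train = tr,
      val = if (is.null(X_val)) NA_real_ else eval_loss(X_val)))
  }
  list(params = p, trace = trace)
}
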