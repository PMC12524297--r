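#' Initialize mixture-of-experts parameters
#'
#' M independent feed-forward experts (latent -> hidden ReLU -> sigmoid
#' output, so every expert emits a probability) plus a linear gating network
#' whose softmax over the M scores weights the experts.
#'
#' @param latent_dim Input size (dimension of the weighted latent code z').
#' @param expert_hidden Hidden width of each expert.
#' @param M Number of experts (>= 1).
#' @param seed Seed for initialization.
#' @return Object of class \code{hcn_moe}.
#' @export
moe_init <- function(latent_dim, expert_hidden, M, seed = 1L) {
  stopifnot(M >= 1L)
  set.seed(seed)
  experts <- lapply(seq_len(M), function(m) {
    list(V = glorot(latent_dim, expert_hidden), c = numeric(expert_hidden),
         w = glorot(expert_hidden, 1L), d = 0)
  })
  structure(list(experts = experts,
                 Wg = glorot(latent_dim, M), bg = numeric(M),
                 M = as.integer(M), latent_dim = as.integer(latent_dim),
                 expert_hidden = as.integer(expert_hidden)),
            class = "hcn_moe")
}

#' Gating weights
#'
#' Softmax over the M gating scores: strictly positive, summing to 1 per
#' sample.
#'
#' @param z_prime Weighted latent vector or matrix (rows = samples).
#' @param p An \code{hcn_moe}.
#' @return Matrix n x M of gating weights.
#' @export
gate <- function(z_prime, p) {
  stopifnot(inherits(p, "hcn_moe"))
  Zp <- as_row_matrix(z_prime)
  if (ncol(Zp) != p$latent_dim) stop("latent dimension mismatch in gating")
  softmax_rows(sweep(Zp %*% p$Wg, 2L, p$bg, "+"))
}

moe_forward <- function(Zp, p) {
  n <- nrow(Zp)
  G <- gate(Zp, p)
  H <- vector("list", p$M)
  Y <- matrix(0, n, p$M)
  for (m in seq_len(p$M)) {
    e <- p$experts[[m]]
    H[[m]] <- relu(sweep(Zp %*% e$V, 2L, e$c, "+"))
    Y[, m] <- sigmoid(H[[m]] %*% e$w + e$d)
  }
  list(G = G, H = H, Y = Y, y = rowSums(G * Y))
}

#' Mixture-of-experts prediction
#'
#' \code{y = sum_m g_m y_m}: a convex combination of the expert
#' probabilities, hence always in [0, 1] and between the minimum and maximum
#' expert output.
#'
#' @param z_prime Weighted latent vector or matrix.
#' @param p An \code{hcn_moe}.
#' @param detail Return gating weights and per-expert outputs as well.
#' @return Numeric vector of probabilities (or a list when
#'   \code{detail = TRUE}).
#' @export
moe_predict <- function(z_prime, p, detail = FALSE) {
  stopifnot(inherits(p, "hcn_moe"))
  fw <- moe_forward(as_row_matrix(z_prime), p)
  if (detail) list(y = fw$y, gating = fw$G, experts = fw$Y) else fw$y
}

#' Binary cross-entropy of mixture predictions
#'
#' @param y_true 0/1 labels.
#' @param y_prob Predicted probabilities.
#' @param eps Clamp width to keep the logs finite.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y_true, y_prob, eps = 1e-12) {
  if (length(y_true) != length(y_prob)) stop("length mismatch in BCE")
  yp <- pmin(pmax(y_prob, eps), 1 - eps)
  -mean(y_true * log(yp) + (1 - y_true) * log(1 - yp))
}

# Gradients of BCE wrt all MoE parameters; also returns dL/dZp for joint
# fine-tuning of the encoder.
moe_backward <- function(Zp, tgt, fw, p, eps = 1e-12) {
  n <- nrow(Zp)
  yp <- pmin(pmax(fw$y, eps), 1 - eps)
  dy <- (-(tgt / yp) + (1 - tgt) / (1 - yp)) / n
  dY <- dy * fw$G
  dG <- dy * fw$Y
  dS <- fw$G * (dG - rowSums(dG * fw$G))
  grads <- list(Wg = t(Zp) %*% dS, bg = colSums(dS))
  dZp <- dS %*% t(p$Wg)
  for (m in seq_len(p$M)) {
    e <- p$experts[[m]]
    ym <- fw$Y[, m]
    dpre <- dY[, m] * ym * (1 - ym)
    dH <- (dpre %*% t(e$w)) * (fw$H[[m]] > 0)
    grads[[paste0("V", m)]] <- t(Zp) %*% dH
    grads[[paste0("c", m)]] <- colSums(dH)
    grads[[paste0("w", m)]] <- t(fw$H[[m]]) %*% dpre
    grads[[paste0("d", m)]] <- sum(dpre)
    dZp <- dZp + dH %*% t(e$V)
  }
  list(grads = grads, dZp = dZp)
}

moe_flatten <- function(p) {
  out <- list(Wg = p$Wg, bg = p$bg)
  for (m in seq_len(p$M)) {
    e <- p$experts[[m]]
    out[[paste0("V", m)]] <- e$V
    out[[paste0("c", m)]] <- e$c
    out[[paste0("w", m)]] <- e$w
    out[[paste0("d", m)]] <- e$d
  }
  out
}

moe_unflatten <- function(flat, p) {
  p$Wg <- flat$Wg; p$bg <- flat$bg
  for (m in seq_len(p$M)) {
    p$experts[[m]] <- list(V = flat[[paste0("V", m)]],
                           c = flat[[paste0("c", m)]],
                           w = flat[[paste0("w", m)]],
                           d = flat[[paste0("d", m)]])
  }
  p
}

#' Train the mixture-of-experts classifier
#'
#' Minimizes binary cross-entropy of the mixture output with Adam on the
#' (frozen) attention-weighted latent codes. Epoch 0 of the trace is the
#' untrained loss. Deterministic given \code{cfg$seed}.
#'
#' @param Zp_train Latent training codes (n x latent_dim).
#' @param y_train Binary labels (both classes must be present).
#' @param Zp_val,y_val Optional validation data for the trace.
#' @param cfg A \code{\link{hazchemnet_config}}.
#' @return List with \code{params} (\code{hcn_moe}) and \code{trace}.
#' @export
train_moe <- function(Zp_train, y_train, Zp_val = NULL, y_val = NULL,
                      cfg = hazchemnet_config()) {
  Zp_train <- as.matrix(Zp_train)
  y_train <- as.numeric(y_train)
  if (!all(y_train %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y_train)) < 2L) {
    stop("training labels contain a single class; cannot train a classifier")
  }
  p <- moe_init(ncol(Zp_train), cfg$expert_hidden, cfg$M,
                seed = derive_seed(cfg$seed, "moe_init"))
  st <- adam_init(moe_flatten(p))
  eval_loss <- function(Z, y) bce_loss(y, moe_forward(Z, p)$y)
  trace <- data.frame(
    epoch = 0L, train = eval_loss(Zp_train, y_train),
    val = if (is.null(Zp_val)) NA_real_ else eval_loss(Zp_val, y_val))
  set.seed(derive_seed(cfg$seed, "moe_shuffle"))
  for (epoch in seq_len(cfg$moe_epochs)) {
    for (batch in minibatches(nrow(Zp_train), cfg$batch_size)) {
      Zb <- Zp_train[batch, , drop = FALSE]
      tb <- y_train[batch]
      fw <- moe_forward(Zb, p)
      bk <- moe_backward(Zb, tb, fw, p)
      upd <- adam_step(moe_flatten(p), bk$grads, st, lr = cfg$learning_rate)
      p <- moe_unflatten(upd$params, p)
      st <- upd$state
    }
    tr <- eval_loss(Zp_train, y_train)
    if (!is.finite(tr)) {
      stop("mixture-of-experts training diverged (non-finite loss) at epoch ",
           epoch)
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, train = tr,
      val = if (is.null(Zp_val)) NA_real_ else eval_loss(Zp_val, y_val)))
  }
  list(params = p, trace = trace)
}
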