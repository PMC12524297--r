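# Attention autoencoder and mixture-of-experts: exact unit behavior,
# softmax normalization, gradient correctness against finite differences,
# and training-level properties (descent, determinism, capacity).

test_that("encoder maps zero weights to zero and clamps negatives", {
  p <- autoencoder_init(1, 1, 1, seed = 1)
  p$W1[] <- 1; p$b1[] <- 0; p$W2[] <- 1; p$b2[] <- 0
  expect_equal(as.numeric(encode(3, p)), 3)   # ReLU of a positive
  expect_equal(as.numeric(encode(-5, p)), 0)  # ReLU clamps

  pz <- autoencoder_init(6, 4, 3, seed = 2)
  for (k in c("W1", "b1", "W2", "b2")) pz[[k]][] <- 0
  expect_true(all(encode(rnorm(6), pz) == 0))
  expect_error(encode(rnorm(5), pz), "features")
})

test_that("attention weights are a softmax: positive, sum to 1, uniform when scores tie", {
  Wa <- matrix(0, 4, 4); ba <- rep(0, 4)
  att <- attention_weights(c(1, 2, 3, 4), Wa, ba)
  expect_equal(as.numeric(att$alpha), rep(0.25, 4))

  att2 <- attention_weights(c(4, 2), matrix(0, 2, 2), c(0, 0))
  expect_equal(as.numeric(att2$z_prime), c(2, 1))

  set.seed(3)
  for (i in 1:25) {
    d <- sample(2:16, 1)
    Wa <- matrix(rnorm(d * d), d, d)
    att <- attention_weights(rnorm(d, sd = 5), Wa, rnorm(d))
    expect_lt(abs(sum(att$alpha) - 1), 1e-12)
    expect_true(all(att$alpha > 0))
  }
  # overflow-free for extreme inputs
  big <- attention_weights(c(1e6, -1e6, 0), diag(3) * 1e3, rep(0, 3))
  expect_true(all(is.finite(big$alpha)))
  expect_lt(abs(sum(big$alpha) - 1), 1e-12)
})

test_that("decoder and reconstruction loss behave as specified", {
  p <- autoencoder_init(4, 3, 2, seed = 4)
  for (k in c("W3", "b3", "W4", "b4")) p[[k]][] <- 0
  expect_true(all(decode(c(1, 2), p) == 0))
  expect_error(decode(c(1, 2, 3), p), "latent")

  expect_equal(reconstruction_loss(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(reconstruction_loss(c(1, 0), c(0, 0)), 0.5)
  expect_error(reconstruction_loss(matrix(0, 2, 3), matrix(0, 3, 2)), "shape")

  # brute-force double-loop oracle
  set.seed(5)
  X <- matrix(rnorm(8 * 5), 8, 5)
  Xh <- matrix(rnorm(8 * 5), 8, 5)
  acc <- 0
  for (i in 1:8) for (j in 1:5) acc <- acc + (X[i, j] - Xh[i, j])^2
  expect_lt(abs(reconstruction_loss(X, Xh) - acc / 40), 1e-12)
})

test_that("an identity-like network reconstructs its input exactly", {
  # latent_dim = input_dim = 1: attention over a single dimension is forced
  # to alpha = 1, so the identity weights round-trip x
  p <- autoencoder_init(1, 1, 1, seed = 6)
  p$W1[] <- 1; p$W2[] <- 1; p$W3[] <- 1; p$W4[] <- 1
  p$b1[] <- 0; p$b2[] <- 0; p$b3[] <- 0; p$b4[] <- 0
  p$Wa[] <- 0; p$ba[] <- 0
  att <- attention_weights(encode(3, p), p$Wa, p$ba)
  expect_equal(as.numeric(decode(att$z_prime, p)), 3)
})

test_that("gating is a softmax over experts", {
  p1 <- moe_init(3, 4, 1, seed = 7)
  expect_equal(as.numeric(gate(c(1, -2, 0.5), p1)), 1)

  p <- moe_init(3, 4, 5, seed = 8)
  p$Wg[] <- 0; p$bg[] <- 0
  expect_equal(as.numeric(gate(c(1, 2, 3), p)), rep(0.2, 5))

  set.seed(9)
  for (i in 1:25) {
    g <- gate(rnorm(3, sd = 4), p <- moe_init(3, 4, sample(1:6, 1),
                                              seed = i))
    expect_lt(abs(sum(g) - 1), 1e-12)
    expect_true(all(g > 0))
  }
})

test_that("mixture output is a convex combination of expert outputs", {
  set.seed(10)
  for (i in 1:20) {
    p <- moe_init(4, 3, sample(1:5, 1), seed = 100 + i)
    z <- rnorm(4, sd = 3)
    out <- moe_predict(z, p, detail = TRUE)
    expect_gte(out$y + 1e-12, min(out$experts))
    expect_lte(out$y - 1e-12, max(out$experts))
    expect_gte(out$y, 0); expect_lte(out$y, 1)
  }
  # equal expert outputs pass through unchanged whatever the gating
  p <- moe_init(2, 3, 4, seed = 11)
  for (m in 2:4) p$experts[[m]] <- p$experts[[1]]
  out <- moe_predict(c(0.3, -1.2), p, detail = TRUE)
  expect_equal(unname(out$y), unname(out$experts[1]), tolerance = 1e-12)
})

test_that("autoencoder gradients match central finite differences", {
  ns <- asNamespace("hazchemnet")
  set.seed(42)
  X <- matrix(rnorm(5 * 7), 5, 7)
  p <- random_ae()
  g <- ns$ae_backward(X, ns$ae_forward(X, p), p)
  loss_at <- function(p) reconstruction_loss(X, ns$ae_forward(X, p)$Xh)
  for (k in c("W1", "b1", "W2", "b2", "Wa", "ba", "W3", "b3", "W4", "b4")) {
    for (i in seq_along(p[[k]])) {
      e <- 1e-5
      p1 <- p; p1[[k]][i] <- p1[[k]][i] + e
      p2 <- p; p2[[k]][i] <- p2[[k]][i] - e
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * e)
      expect_lt(abs(fd - g[[k]][i]) / max(1e-8, abs(fd) + abs(g[[k]][i])),
                1e-4, label = paste("AE grad", k, i))
    }
  }
})

test_that("mixture-of-experts gradients match central finite differences", {
  ns <- asNamespace("hazchemnet")
  set.seed(43)
  Zp <- matrix(rnorm(6 * 3), 6, 3)
  tgt <- c(0, 1, 1, 0, 1, 0)
  p <- moe_init(3, 4, 3, seed = 11)
  set.seed(44)
  for (m in 1:3) p$experts[[m]]$c <- rnorm(4, sd = 0.3)
  fw <- ns$moe_forward(Zp, p)
  bk <- ns$moe_backward(Zp, tgt, fw, p)
  flat <- ns$moe_flatten(p)
  loss_at <- function(f) bce_loss(tgt, ns$moe_forward(Zp, ns$moe_unflatten(f, p))$y)
  for (k in names(flat)) {
    for (i in seq_along(flat[[k]])) {
      e <- 1e-5
      f1 <- flat; f1[[k]][i] <- f1[[k]][i] + e
      f2 <- flat; f2[[k]][i] <- f2[[k]][i] - e
      fd <- (loss_at(f1) - loss_at(f2)) / (2 * e)
      expect_lt(abs(fd - bk$grads[[k]][i]) /
                  max(1e-8, abs(fd) + abs(bk$grads[[k]][i])),
                1e-4, label = paste("MoE grad", k, i))
    }
  }
  # gradient wrt the latent input (used by joint fine-tuning)
  for (i in seq_along(Zp)) {
    e <- 1e-5
    Z1 <- Zp; Z1[i] <- Z1[i] + e
    Z2 <- Zp; Z2[i] <- Z2[i] - e
    fd <- (bce_loss(tgt, ns$moe_forward(Z1, p)$y) -
             bce_loss(tgt, ns$moe_forward(Z2, p)$y)) / (2 * e)
    expect_lt(abs(fd - bk$dZp[i]) / max(1e-8, abs(fd) + abs(bk$dZp[i])), 1e-4)
  }
})

test_that("loss functions match brute-force loop oracles", {
  set.seed(45)
  y <- rbinom(30, 1, 0.5)
  prob <- runif(30)
  acc <- 0
  for (i in 1:30) {
    acc <- acc - (y[i] * log(prob[i]) + (1 - y[i]) * log(1 - prob[i]))
  }
  expect_lt(abs(bce_loss(y, prob) - acc / 30), 1e-12)
})

test_that("autoencoder training descends and is seed-deterministic", {
  syn <- separable_features(n_per_class = 40, seed = 12)
  std <- fit_standardizer(syn$X)
  Xs <- apply_standardizer(syn$X, std)
  cfg <- tiny_config(ae_epochs = 8L)
  r1 <- train_autoencoder(Xs, cfg = cfg)
  r2 <- train_autoencoder(Xs, cfg = cfg)
  expect_lt(tail(r1$trace$train, 1), r1$trace$train[1])
  expect_identical(r1$params, r2$params)
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), cfg$ae_epochs + 1L)  # epoch 0 baseline
  expect_true(all(r1$trace$train >= 0))
})

test_that("autoencoder captures low-rank structure well below data variance", {
  # 5 latent factors in 40 dimensions, latent_dim 8
  set.seed(13)
  n <- 200
  F5 <- matrix(rnorm(n * 5), n, 5)
  L <- matrix(rnorm(5 * 40), 5, 40)
  X <- F5 %*% L + matrix(rnorm(n * 40, sd = 0.1), n, 40)
  std <- fit_standardizer(X[1:150, ])
  Xs_tr <- apply_standardizer(X[1:150, ], std)
  Xs_va <- apply_standardizer(X[151:200, ], std)
  cfg <- tiny_config(hidden_dim = 32L, latent_dim = 8L, ae_epochs = 60L,
                     batch_size = 16L)
  r <- train_autoencoder(Xs_tr, Xs_va, cfg)
  val_var <- mean(Xs_va^2)  # reconstruction-by-zero baseline
  expect_lt(tail(r$trace$val, 1), 0.5 * val_var)
})

test_that("mixture-of-experts training fits separable latent data and is deterministic", {
  set.seed(14)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  Zp <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  Zp[y == 1, 1:2] <- Zp[y == 1, 1:2] + 3
  cfg <- tiny_config(moe_epochs = 60L, expert_hidden = 8L)
  r1 <- train_moe(Zp, y, cfg = cfg)
  r2 <- train_moe(Zp, y, cfg = cfg)
  expect_identical(r1$params, r2$params)
  acc <- mean((moe_predict(Zp, r1$params) >= 0.5) == y)
  expect_gte(acc, 0.98)
  expect_error(train_moe(Zp, rep(1, n), cfg = cfg), "single class")
  expect_error(train_moe(Zp, rep(2, n), cfg = cfg), "0/1")
})

test_that("full fit predicts its own separable training set almost perfectly", {
  syn <- separable_features(n_per_class = 100, seed = 15)
  cfg <- learn_config(seed = 15L)
  fit <- hazchemnet_fit(syn$X, syn$y, cfg = cfg)
  pred <- predict(fit, syn$X)
  expect_gte(mean(pred$predictions$class == syn$y), 0.98)
  expect_true(all(pred$predictions$probability >= 0 &
                    pred$predictions$probability <= 1))
  # empty input gives empty output
  e <- predict(fit, syn$X[0, , drop = FALSE])
  expect_equal(nrow(e$predictions), 0L)
})

test_that("probability exactly at the threshold is classified hazardous", {
  syn <- separable_features(n_per_class = 20, seed = 16)
  fit <- hazchemnet_fit(syn$X, syn$y, cfg = tiny_config())
  # thresholding contract is >=
  probs <- c(0.4999999, 0.5, 0.5000001)
  cls <- as.integer(probs >= fit$config$decision_threshold)
  expect_equal(cls, c(0L, 1L, 1L))
})

test_that("attention concentrates on label-informative latent dimensions after fine-tuning", {
  syn <- separable_features(n_per_class = 80, seed = 17)
  cfg <- learn_config(seed = 17L, fine_tune = TRUE, fine_tune_epochs = 15L)
  fit <- hazchemnet_fit(syn$X, syn$y, cfg = cfg)
  Xs <- apply_standardizer(syn$X, fit$standardizer)
  ns <- asNamespace("hazchemnet")
  fw <- ns$ae_forward(Xs, fit$autoencoder)
  # rank latent dimensions by |correlation of z with the label|
  cors <- abs(apply(fw$Z, 2, function(z) {
    if (stats::sd(z) == 0) 0 else stats::cor(z, syn$y)
  }))
  informative <- cors >= stats::median(cors)
  mean_alpha <- colMeans(fw$A)
  expect_gt(mean(mean_alpha[informative]), mean(mean_alpha[!informative]))
})
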