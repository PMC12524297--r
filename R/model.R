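#' Fit the full hazard classifier
#'
#' Two-stage training on a raw (unstandardized) feature matrix: (1) fit the
#' standardizer on the training rows only and train the attention
#' autoencoder on reconstruction error; (2) freeze encoder + attention and
#' train the mixture-of-experts on the attention-weighted latent codes.
#' With \code{cfg$fine_tune = TRUE}, a third stage jointly updates encoder,
#' attention and experts on the classification loss.
#'
#' @param X_train Raw feature matrix (rows = compounds), e.g. from
#'   \code{\link{featurize_dataset}} or
#'   \code{\link{generate_synthetic_features}}.
#' @param y_train Binary labels (1 = hazardous).
#' @param X_val,y_val Optional validation data (used for loss traces only;
#'   no early stopping).
#' @param cfg A \code{\link{hazchemnet_config}}.
#' @return Object of class \code{hazchemnet_model}: standardizer,
#'   autoencoder, mixture-of-experts, config, loss traces and feature names.
#' @examples
#' \donttest{
#' syn <- generate_synthetic_features(n_per_class = 60, seed = 7)
#' cfg <- hazchemnet_config(hidden_dim = 32, latent_dim = 8,
#'                          expert_hidden = 8, M = 2,
#'                          ae_epochs = 10, moe_epochs = 20, seed = 7)
#' fit <- hazchemnet_fit(syn$X, syn$y, cfg = cfg)
#' pred <- predict(fit, syn$X)
#' mean(pred$class == syn$y)
#' }
#' @export
hazchemnet_fit <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                           cfg = hazchemnet_config()) {
  stopifnot(inherits(cfg, "hazchemnet_config"))
  X_train <- as.matrix(X_train)
  y_train <- as.numeric(y_train)
  if (nrow(X_train) != length(y_train)) stop("X_train/y_train length mismatch")

  std <- fit_standardizer(X_train, fit_on = "train")
  Xs <- apply_standardizer(X_train, std)
  Xs_val <- if (is.null(X_val)) NULL else apply_standardizer(as.matrix(X_val), std)

  ae <- train_autoencoder(Xs, Xs_val, cfg)
  Zp <- ae_forward(Xs, ae$params)$Zp
  Zp_val <- if (is.null(Xs_val)) NULL else ae_forward(Xs_val, ae$params)$Zp

  moe <- train_moe(Zp, y_train, Zp_val, if (is.null(X_val)) NULL else
    as.numeric(y_val), cfg)

  model <- structure(list(
    standardizer = std,
    autoencoder = ae$params,
    moe = moe$params,
    config = cfg,
    traces = list(autoencoder = ae$trace, moe = moe$trace),
    feature_names = colnames(X_train),
    schema_hash = hcn_digest(colnames(X_train))),
    class = "hazchemnet_model")

  if (cfg$fine_tune) model <- fine_tune(model, X_train, y_train)
  model
}

# Joint fine-tuning: propagate the classification gradient through the
# (previously frozen) encoder and attention as well as the experts.
fine_tune <- function(model, X_train, y_train) {
  cfg <- model$config
  Xs <- apply_standardizer(as.matrix(X_train), model$standardizer)
  y <- as.numeric(y_train)
  ae <- model$autoencoder
  moe <- model$moe
  enc_names <- c("W1", "b1", "W2", "b2", "Wa", "ba")
  st_ae <- adam_init(ae[enc_names])
  st_moe <- adam_init(moe_flatten(moe))
  set.seed(derive_seed(cfg$seed, "fine_tune"))
  for (epoch in seq_len(cfg$fine_tune_epochs)) {
    for (batch in minibatches(nrow(Xs), cfg$batch_size)) {
      Xb <- Xs[batch, , drop = FALSE]
      tb <- y[batch]
      fw_ae <- ae_forward(Xb, ae)
      fw_moe <- moe_forward(fw_ae$Zp, moe)
      bk <- moe_backward(fw_ae$Zp, tb, fw_moe, moe)
      g_enc <- ae_backprop_encoder(Xb, fw_ae, ae, bk$dZp)
      upd <- adam_step(ae[enc_names], g_enc, st_ae, lr = cfg$learning_rate)
      ae[enc_names] <- upd$params; st_ae <- upd$state
      upd <- adam_step(moe_flatten(moe), bk$grads, st_moe,
                       lr = cfg$learning_rate)
      moe <- moe_unflatten(upd$params, moe); st_moe <- upd$state
    }
  }
  model$autoencoder <- ae
  model$moe <- moe
  model
}

#' @export
print.hazchemnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<hazchemnet_model> %d features -> %d hidden -> %d latent, %d experts\n",
    "  trained %d + %d epochs (seed %d)%s\n"),
    length(x$feature_names), cfg$hidden_dim, cfg$latent_dim, cfg$M,
    cfg$ae_epochs, cfg$moe_epochs, cfg$seed,
    if (cfg$fine_tune) ", fine-tuned" else ""))
  invisible(x)
}

#' Predict hazard probability and class
#'
#' Accepts either a raw feature matrix (same columns as training) or a data
#' frame of records with id/smiles columns, which is featurized first.
#' The class is 1 (hazardous) iff probability >= the configured decision
#' threshold, so an exact tie goes to the hazardous class.
#'
#' @param object A \code{hazchemnet_model}.
#' @param newdata Feature matrix or record data frame.
#' @param ... Unused.
#' @return List with \code{predictions} (data frame id, probability, class)
#'   and \code{rejects} (records that could not be featurized; empty for
#'   matrix input).
#' @export
predict.hazchemnet_model <- function(object, newdata, ...) {
  empty_rejects <- data.frame(id = character(0), smiles = character(0),
                              reason = character(0), stringsAsFactors = FALSE)
  if (is.data.frame(newdata) && "smiles" %in% names(newdata)) {
    n_bits <- length(object$feature_names) # full model: 516 -> 512 bits
    feat <- featurize_dataset(newdata, n_bits = n_bits - 4L)
    X <- feat$X
    rejects <- feat$rejects
    ids <- rownames(X)
  } else {
    X <- as.matrix(newdata)
    if (!is.null(colnames(X)) &&
        !identical(colnames(X), object$feature_names)) {
      stop("feature columns do not match the model's feature schema")
    }
    rejects <- empty_rejects
    ids <- if (is.null(rownames(X))) as.character(seq_len(nrow(X))) else
      rownames(X)
  }
  if (nrow(X) == 0L) {
    return(list(predictions = data.frame(id = character(0),
                                         probability = numeric(0),
                                         class = integer(0),
                                         stringsAsFactors = FALSE),
                rejects = rejects))
  }
  if (ncol(X) != length(object$feature_names)) {
    stop("input has ", ncol(X), " features, model expects ",
         length(object$feature_names))
  }
  Xs <- apply_standardizer(X, object$standardizer)
  Zp <- ae_forward(Xs, object$autoencoder)$Zp
  prob <- moe_predict(Zp, object$moe)
  list(predictions = data.frame(
    id = ids, probability = prob,
    class = as.integer(prob >= object$config$decision_threshold),
    stringsAsFactors = FALSE),
    rejects = rejects)
}

#' Save a fitted model as a directory bundle
#'
#' Writes plain-text JSON artifacts: config, standardizer, all network
#' weights, and a manifest with the seed, feature schema and its hash, and
#' the package version.
#'
#' @param model A \code{hazchemnet_model}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
save_hazchemnet <- function(model, dir) {
  stopifnot(inherits(model, "hazchemnet_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, null = "null")
  wj(unclass(model$config), "config.json")
  wj(list(mean = model$standardizer$mean, sd = model$standardizer$sd,
          constant = model$standardizer$constant,
          fit_on = model$standardizer$fit_on,
          names = model$standardizer$names), "standardizer.json")
  ae <- model$autoencoder
  wj(lapply(ae[ae_weight_names], as.numeric), "ae_weights.json")
  wj(list(input_dim = ae$input_dim, hidden_dim = ae$hidden_dim,
          latent_dim = ae$latent_dim), "ae_dims.json")
  wj(lapply(moe_flatten(model$moe), as.numeric), "moe_weights.json")
  wj(list(M = model$moe$M, latent_dim = model$moe$latent_dim,
          expert_hidden = model$moe$expert_hidden), "moe_dims.json")
  wj(list(package_version = as.character(utils::packageVersion("hazchemnet")),
          seed = model$config$seed,
          feature_names = model$feature_names,
          schema_hash = model$schema_hash), "manifest.json")
  invisible(dir)
}

#' Load a model bundle saved by \code{\link{save_hazchemnet}}
#'
#' @param dir Bundle directory.
#' @return A \code{hazchemnet_model}.
#' @export
load_hazchemnet <- function(dir) {
  rj <- function(f) jsonlite::read_json(file.path(dir, f),
                                        simplifyVector = TRUE)
  cfg <- do.call(hazchemnet_config, rj("config.json")[
    names(formals(hazchemnet_config))])
  s <- rj("standardizer.json")
  std <- structure(list(mean = s$mean, sd = s$sd, constant = s$constant,
                        fit_on = s$fit_on, names = s$names),
                   class = "hcn_standardizer")
  dims <- rj("ae_dims.json")
  ae <- autoencoder_init(dims$input_dim, dims$hidden_dim, dims$latent_dim)
  w <- rj("ae_weights.json")
  for (k in ae_weight_names) {
    ae[[k]] <- if (is.matrix(ae[[k]])) matrix(w[[k]], nrow(ae[[k]]),
                                              ncol(ae[[k]])) else w[[k]]
  }
  mdims <- rj("moe_dims.json")
  moe <- moe_init(mdims$latent_dim, mdims$expert_hidden, mdims$M)
  mw <- rj("moe_weights.json")
  flat <- moe_flatten(moe)
  for (k in names(flat)) {
    flat[[k]] <- if (is.matrix(flat[[k]])) matrix(mw[[k]], nrow(flat[[k]]),
                                                  ncol(flat[[k]])) else mw[[k]]
  }
  moe <- moe_unflatten(flat, moe)
  man <- rj("manifest.json")
  structure(list(standardizer = std, autoencoder = ae, moe = moe,
                 config = cfg, traces = NULL,
                 feature_names = man$feature_names,
                 schema_hash = man$schema_hash),
            class = "hazchemnet_model")
}
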