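#' Training configuration
#'
#' Collects every tunable hyperparameter of the two-stage training schedule
#' with validated defaults. The autoencoder is trained first on
#' reconstruction error (120 epochs by default, where its loss curve has
#' stabilized); the encoder and attention are then frozen and the
#' mixture-of-experts is trained on the attention-weighted latent codes.
#' Optional joint fine-tuning of encoder + attention + experts is available
#' but off by default.
#'
#' @param hidden_dim Width of the encoder/decoder hidden layer (default 256).
#' @param latent_dim Size of the latent code z (default 64).
#' @param expert_hidden Hidden width of each expert network (default 32).
#' @param M Number of experts (default 4).
#' @param ae_epochs Autoencoder training epochs (default 120).
#' @param moe_epochs Mixture-of-experts training epochs (default 100).
#' @param fine_tune Jointly fine-tune encoder, attention and experts after
#'   the two stages (default FALSE).
#' @param fine_tune_epochs Epochs of joint fine-tuning (default 20).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param optimizer Only "adam" is implemented.
#' @param decision_threshold Probability cutoff; class 1 iff probability >=
#'   threshold, so an exact tie is classified hazardous (default 0.5).
#' @param seed Master seed driving all randomness (default 1).
#' @return Object of class \code{hazchemnet_config} (a validated named list).
#' @export
hazchemnet_config <- function(hidden_dim = 256L, latent_dim = 64L,
                              expert_hidden = 32L, M = 4L,
                              ae_epochs = 120L, moe_epochs = 100L,
                              fine_tune = FALSE, fine_tune_epochs = 20L,
                              batch_size = 64L, learning_rate = 1e-3,
                              optimizer = "adam",
                              decision_threshold = 0.5, seed = 1L) {
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              latent_dim = as.integer(latent_dim),
              expert_hidden = as.integer(expert_hidden),
              M = as.integer(M),
              ae_epochs = as.integer(ae_epochs),
              moe_epochs = as.integer(moe_epochs),
              fine_tune = isTRUE(fine_tune),
              fine_tune_epochs = as.integer(fine_tune_epochs),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              optimizer = match.arg(optimizer, "adam"),
              decision_threshold = as.numeric(decision_threshold),
              seed = as.integer(seed))
  counts <- c("hidden_dim", "latent_dim", "expert_hidden", "M", "ae_epochs",
              "moe_epochs", "fine_tune_epochs", "batch_size", "seed")
  for (k in counts) {
    if (is.na(cfg[[k]]) || cfg[[k]] < if (k == "seed") 0L else 1L) {
      stop("config field '", k, "' must be a positive integer")
    }
  }
  if (!is.finite(cfg$learning_rate) || cfg$learning_rate <= 0) {
    stop("learning_rate must be positive")
  }
  if (!is.finite(cfg$decision_threshold) || cfg$decision_threshold <= 0 ||
      cfg$decision_threshold >= 1) {
    stop("decision_threshold must lie in (0, 1)")
  }
  structure(cfg, class = "hazchemnet_config")
}

#' @export
print.hazchemnet_config <- function(x, ...) {
  cat("<hazchemnet_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load a training configuration from YAML or JSON
#'
#' Unknown keys are an error (no silent typo absorption); missing keys take
#' the documented defaults of \code{\link{hazchemnet_config}}.
#'
#' @param path Path to a .yaml/.yml or .json file. May be empty.
#' @return A \code{hazchemnet_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(hazchemnet_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(hazchemnet_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config A \code{hazchemnet_config}.
#' @param path Output path (.yaml).
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "hazchemnet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable hash of an R object (used for config hashes and feature-schema
# hashes in run logs and model manifests).
hcn_digest <- function(object) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(object, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
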