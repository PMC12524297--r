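#' Names of the supported ablation variants
#'
#' "full" keeps all 516 features; each "-<descriptor>" variant drops one
#' descriptor column (515 features); "-MorganFingerprint" drops the whole
#' fingerprint block (4 features).
#'
#' @return Character vector of variant names.
#' @export
ablation_variants <- function() {
  c("full", "-MolLogP", "-MolWt", "-NumHDonors", "-NumHAcceptors",
    "-MorganFingerprint")
}

ablate_columns <- function(feature_names, variant) {
  keep <- switch(variant,
    "full" = rep(TRUE, length(feature_names)),
    "-MolLogP" = feature_names != "MolLogP",
    "-MolWt" = feature_names != "MolWt",
    "-NumHDonors" = feature_names != "NumHDonors",
    "-NumHAcceptors" = feature_names != "NumHAcceptors",
    "-MorganFingerprint" = !grepl("^fp_", feature_names),
    stop("unknown ablation variant: ", variant))
  keep
}

#' Feature ablation study
#'
#' Retrains the full pipeline once per variant with identical seeds and
#' configuration, differing only in the dropped feature block, and evaluates
#' every variant on the same held-out test split (7:2:1 by default, made
#' from the master seed). Because everything except the feature set is held
#' fixed, metric differences isolate the contribution of the ablated
#' feature.
#'
#' @param X Raw feature matrix with named columns (fingerprint bits
#'   \code{fp_*} and the four descriptor names).
#' @param y Binary labels.
#' @param cfg A \code{\link{hazchemnet_config}}.
#' @param variants Subset of \code{\link{ablation_variants}()}.
#' @param ratios Train/validation/test split ratios.
#' @return Object of class \code{hcn_ablation}: a list of per-variant
#'   results (variant, n_features, dropped columns, \code{hcn_metrics}) plus
#'   a summary data frame \code{table}.
#' @export
ablate <- function(X, y, cfg = hazchemnet_config(),
                   variants = ablation_variants(),
                   ratios = c(0.7, 0.2, 0.1)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(colnames(X))) stop("X must have feature column names")
  unknown <- setdiff(variants, ablation_variants())
  if (length(unknown)) {
    stop("unknown ablation variant(s): ", paste(unknown, collapse = ", "))
  }
  sp <- split_dataset(nrow(X), ratios = ratios, labels = y,
                      seed = derive_seed(cfg$seed, "split"))

  results <- list()
  rows <- list()
  for (v in variants) {
    keep <- ablate_columns(colnames(X), v)
    Xv <- X[, keep, drop = FALSE]
    model <- hazchemnet_fit(Xv[sp$train, , drop = FALSE], y[sp$train],
                            Xv[sp$validation, , drop = FALSE],
                            y[sp$validation], cfg = cfg)
    pred <- predict(model, Xv[sp$test, , drop = FALSE])
    m <- compute_metrics(y[sp$test], pred$predictions$probability,
                         threshold = cfg$decision_threshold)
    results[[v]] <- list(variant = v, n_features = ncol(Xv),
                         dropped = colnames(X)[!keep], metrics = m)
    rows[[v]] <- cbind(data.frame(variant = v, n_features = ncol(Xv)),
                       metrics_row(m))
  }
  structure(list(results = results, table = do.call(rbind, rows),
                 split = sp, seed = cfg$seed),
            class = "hcn_ablation")
}

#' @export
print.hcn_ablation <- function(x, ...) {
  cat("<hcn_ablation> seed", x$seed, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
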