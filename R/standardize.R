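#' Fit a feature standardizer (z-score)
#'
#' Computes per-column mean and population standard deviation (denominator
#' n). Standardization parameters must be fitted on the training split only
#' and then applied unchanged to validation, test and external data, so the
#' object records a provenance tag. Zero-variance columns (common for rarely
#' set fingerprint bits) get sigma = 1 so they standardize to a constant 0
#' instead of NaN; their positions are recorded.
#'
#' @param X Numeric feature matrix (rows = samples), at least 2 rows.
#' @param fit_on Provenance tag naming the split the parameters come from.
#' @return Object of class \code{hcn_standardizer}: list with \code{mean},
#'   \code{sd}, \code{constant} (logical per column), \code{fit_on}.
#' @export
fit_standardizer <- function(X, fit_on = "train") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a standardizer")
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  constant <- sdev == 0
  sdev[constant] <- 1
  structure(list(mean = mu, sd = sdev, constant = constant,
                 fit_on = fit_on, names = colnames(X)),
            class = "hcn_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param X Numeric matrix with the same number of columns the standardizer
#'   was fitted on.
#' @param p An \code{hcn_standardizer}.
#' @return Standardized matrix \code{(X - mean) / sd} with attribute
#'   \code{standardized = TRUE}.
#' @export
apply_standardizer <- function(X, p) {
  stopifnot(inherits(p, "hcn_standardizer"))
  X <- as.matrix(X)
  if (ncol(X) != length(p$mean)) {
    stop("column mismatch: matrix has ", ncol(X), " columns, standardizer has ",
         length(p$mean))
  }
  out <- sweep(sweep(X, 2L, p$mean), 2L, p$sd, "/")
  attr(out, "standardized") <- TRUE
  out
}

#' Invert a standardization
#'
#' @param X_std Standardized matrix.
#' @param p The \code{hcn_standardizer} used to produce it.
#' @return The original-scale matrix \code{X_std * sd + mean}.
#' @export
invert_standardizer <- function(X_std, p) {
  stopifnot(inherits(p, "hcn_standardizer"))
  X_std <- as.matrix(X_std)
  if (ncol(X_std) != length(p$mean)) stop("column mismatch")
  out <- sweep(sweep(X_std, 2L, p$sd, "*"), 2L, p$mean, "+")
  attr(out, "standardized") <- NULL
  out
}

#' @export
print.hcn_standardizer <- function(x, ...) {
  cat(sprintf("<hcn_standardizer> %d columns, fitted on '%s' (%d constant)\n",
              length(x$mean), x$fit_on, sum(x$constant)))
  invisible(x)
}
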