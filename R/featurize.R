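#' Concatenate fingerprint and descriptors into one feature vector
#'
#' The model input is the fingerprint block followed by the descriptor block:
#' 512 + 4 = 516 values by default. Entry 513 is therefore MolWt.
#'
#' @param fp Binary fingerprint vector from \code{\link{morgan_fingerprint}}.
#' @param d Length-4 descriptor vector from \code{\link{compute_descriptors}}.
#' @return Named numeric vector of length \code{length(fp) + 4} with
#'   attribute \code{standardized = FALSE}.
#' @export
build_feature_vector <- function(fp, d) {
  if (length(d) != 4L) {
    stop("descriptor block must have exactly 4 entries, got ", length(d))
  }
  if (!all(fp %in% c(0, 1))) {
    stop("fingerprint block must be binary")
  }
  x <- c(as.numeric(fp), as.numeric(d))
  names(x) <- feature_names(length(fp))
  attr(x, "standardized") <- FALSE
  x
}

#' Featurize a single SMILES string
#'
#' @param smiles A SMILES string.
#' @param n_bits,radius Fingerprint settings.
#' @return A feature vector (see \code{\link{build_feature_vector}}), or an
#'   \code{hcn_reject} if the SMILES does not parse.
#' @examples
#' length(featurize_smiles("CCO"))  # 516
#' @export
featurize_smiles <- function(smiles, n_bits = 512L, radius = 2L) {
  mol <- parse_smiles(smiles)
  if (inherits(mol, "hcn_reject")) return(mol)
  build_feature_vector(morgan_fingerprint(mol, n_bits = n_bits,
                                          radius = radius),
                       compute_descriptors(mol))
}

#' Featurize a table of molecule records
#'
#' Converts records (id, smiles, optionally label) into a feature matrix,
#' one row per successfully featurized record in input order. Failures never
#' abort the run: every unparseable or otherwise unfeaturizable record is
#' routed to a reject report carrying its id and the reason. Multi-fragment
#' inputs (e.g. salts) are featurized as given and flagged in the output.
#'
#' @param records Data frame with columns \code{id}, \code{smiles} and
#'   optionally \code{label} (0/1), e.g. from \code{\link{read_dataset}}.
#' @param n_bits,radius Fingerprint settings.
#' @param verbose Print a message per rejected record.
#' @return List with elements \code{X} (numeric matrix, n_ok x (n_bits+4),
#'   rownames = ids, colnames = \code{\link{feature_names}}), \code{labels}
#'   (aligned numeric vector or NULL), \code{rejects} (data frame id, smiles,
#'   reason) and \code{multi_fragment} (ids of multi-fragment inputs).
#' @export
featurize_dataset <- function(records, n_bits = 512L, radius = 2L,
                              verbose = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(list(
      X = matrix(numeric(0), nrow = 0, ncol = n_bits + 4L,
                 dimnames = list(NULL, feature_names(n_bits))),
      labels = if ("label" %in% names(records)) numeric(0) else NULL,
      rejects = data.frame(id = character(0), smiles = character(0),
                           reason = character(0), stringsAsFactors = FALSE),
      multi_fragment = character(0)))
  }
  if (!all(c("id", "smiles") %in% names(records))) {
    stop("records must have columns 'id' and 'smiles'")
  }
  has_label <- "label" %in% names(records)

  n <- nrow(records)
  rows <- vector("list", n)
  ok <- logical(n)
  rej <- list()
  multi <- character(0)
  for (i in seq_len(n)) {
    id_i <- as.character(records$id[i])
    mol <- parse_smiles(as.character(records$smiles[i]), id = id_i)
    if (inherits(mol, "hcn_reject")) {
      rej[[length(rej) + 1L]] <- data.frame(
        id = id_i, smiles = mol$smiles, reason = mol$reason,
        stringsAsFactors = FALSE)
      if (verbose) message("reject ", id_i, ": ", mol$reason)
      next
    }
    if (mol$n_fragments > 1L) multi <- c(multi, id_i)
    x <- tryCatch(
      build_feature_vector(
        morgan_fingerprint(mol, n_bits = n_bits, radius = radius),
        compute_descriptors(mol)),
      error = function(e) NULL)
    if (is.null(x)) {
      rej[[length(rej) + 1L]] <- data.frame(
        id = id_i, smiles = as.character(records$smiles[i]),
        reason = "descriptor or fingerprint computation failed",
        stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- x
    ok[i] <- TRUE
  }

  X <- if (any(ok)) do.call(rbind, rows[ok]) else
    matrix(numeric(0), nrow = 0, ncol = n_bits + 4L)
  colnames(X) <- feature_names(n_bits)
  rownames(X) <- as.character(records$id[ok])
  rejects <- if (length(rej)) do.call(rbind, rej) else
    data.frame(id = character(0), smiles = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(X = X,
       labels = if (has_label) as.numeric(records$label[ok]) else NULL,
       rejects = rejects,
       multi_fragment = multi)
}
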