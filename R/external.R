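#' External validation on held-out compound lists
#'
#' Runs a trained model on two lists of compounds with known class (one
#' hazardous, one non-hazardous) that were never seen in training, and
#' reports per-class accuracy (correct / evaluated), the false-negative rate
#' on the hazardous list, and a per-compound verdict table. Compounds are
#' featurized with the model's own training-set standardizer. Compounds that
#' cannot be featurized are reported and excluded from the denominators with
#' a warning.
#'
#' @param model A \code{hazchemnet_model}.
#' @param hazardous Data frame of records (id, smiles) known to be hazardous.
#' @param nonhazardous Data frame of records known to be non-hazardous.
#' @return Object of class \code{hcn_external}: \code{hazardous_accuracy},
#'   \code{nonhazardous_accuracy}, \code{false_negative_rate},
#'   \code{verdicts} (per-compound table), \code{rejects}.
#' @export
external_validate <- function(model, hazardous, nonhazardous) {
  stopifnot(inherits(model, "hazchemnet_model"))
  if (!is.data.frame(hazardous) || nrow(hazardous) == 0L ||
      !is.data.frame(nonhazardous) || nrow(nonhazardous) == 0L) {
    stop("both compound lists must be non-empty data frames")
  }
  run_list <- function(records, true_label) {
    pred <- predict(model, records)
    v <- pred$predictions
    if (nrow(pred$rejects) > 0L) {
      warning(nrow(pred$rejects), " compound(s) could not be featurized and ",
              "were excluded: ",
              paste(pred$rejects$id, collapse = ", "))
    }
    v$true_label <- true_label
    v$correct <- v$class == true_label
    list(verdicts = v, rejects = pred$rejects)
  }
  haz <- run_list(hazardous, 1L)
  non <- run_list(nonhazardous, 0L)
  verdicts <- rbind(haz$verdicts, non$verdicts)
  n_haz <- nrow(haz$verdicts)
  n_non <- nrow(non$verdicts)
  if (n_haz == 0L || n_non == 0L) {
    stop("no evaluable compounds in one of the lists")
  }
  structure(list(
    hazardous_accuracy = sum(haz$verdicts$correct) / n_haz,
    nonhazardous_accuracy = sum(non$verdicts$correct) / n_non,
    false_negative_rate = sum(!haz$verdicts$correct) / n_haz,
    n_hazardous = n_haz, n_nonhazardous = n_non,
    verdicts = verdicts,
    rejects = rbind(haz$rejects, non$rejects)),
    class = "hcn_external")
}

#' @export
print.hcn_external <- function(x, ...) {
  cat(sprintf(paste0(
    "<hcn_external> hazardous: %d/%d correct (%.1f%%), FNR %.1f%%\n",
    "               non-hazardous: %d/%d correct (%.1f%%)\n"),
    round(x$hazardous_accuracy * x$n_hazardous), x$n_hazardous,
    100 * x$hazardous_accuracy, 100 * x$false_negative_rate,
    round(x$nonhazardous_accuracy * x$n_nonhazardous), x$n_nonhazardous,
    100 * x$nonhazardous_accuracy))
  invisible(x)
}
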