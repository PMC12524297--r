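#' Physicochemical descriptors of a molecule
#'
#' Computes the four global descriptors used alongside the fingerprint, in
#' fixed order: molecular weight (g/mol), Wildman-Crippen logP (octanol-water
#' partition coefficient, unitless), number of hydrogen-bond donors and
#' number of hydrogen-bond acceptors. Values are computed by OpenBabel via
#' \pkg{ChemmineOB} from the canonical SMILES.
#'
#' @param mol An \code{hcn_mol} from \code{\link{parse_smiles}}.
#' @return Named numeric vector \code{c(MolWt, MolLogP, NumHDonors,
#'   NumHAcceptors)}.
#' @examples
#' compute_descriptors(parse_smiles("CCO"))
#' @export
compute_descriptors <- function(mol) {
  if (inherits(mol, "hcn_reject")) {
    stop("cannot compute descriptors for a rejected molecule: ", mol$reason)
  }
  stopifnot(inherits(mol, "hcn_mol"))
  props <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(mol$cansmi, "\tmol\n"),
                           ChemmineOB::prop_OB)[[1]],
    error = function(e) NULL)
  if (is.null(props) || !all(c("MW", "logP", "HBD", "HBA1") %in% names(props))) {
    stop("descriptor computation failed for SMILES: ", mol$cansmi)
  }
  out <- c(MolWt = as.numeric(props$MW),
           MolLogP = as.numeric(props$logP),
           NumHDonors = as.numeric(props$HBD),
           NumHAcceptors = as.numeric(props$HBA1))
  if (anyNA(out) || out["MolWt"] <= 0 ||
      out["NumHDonors"] < 0 || out["NumHAcceptors"] < 0) {
    stop("descriptor computation returned invalid values for SMILES: ",
         mol$cansmi)
  }
  out
}

#' Names of the feature-vector columns
#'
#' @param n_bits Fingerprint length (default 512).
#' @return Character vector of length \code{n_bits + 4}: \code{fp_0001} ...
#'   followed by the four descriptor names.
#' @export
feature_names <- function(n_bits = 512L) {
  c(sprintf("fp_%04d", seq_len(n_bits)),
    "MolWt", "MolLogP", "NumHDonors", "NumHAcceptors")
}
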