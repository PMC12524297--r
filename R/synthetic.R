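# Synthetic fixtures: a numeric feature generator with controllable class
# separation for model tests that bypass chemistry, and a SMILES table
# generator drawing from a curated pool of real molecules so the full
# featurization pipeline can run without any external download.

#' Generate a synthetic 516-dimensional feature matrix
#'
#' Two Gaussian classes that differ by \code{class_separation} (in units of
#' \code{noise_sd}) on \code{n_informative} dimensions; all other dimensions
#' are pure noise. To mimic fingerprint bits, the first \code{n_bits}
#' columns are binarized by thresholding (the raw Gaussian is compared
#' against \code{bit_threshold}, so a shifted class mean changes the
#' bit-on probability); the descriptor columns stay continuous.
#'
#' The defaults (250 per class, separation 3 on 20 dimensions, unit noise)
#' give a clearly separable but not trivial problem sized for minutes-scale
#' training; separation 0 gives an exact no-signal control.
#'
#' @param n_per_class Samples per class.
#' @param class_separation Mean shift of class 1 on informative dimensions.
#' @param n_informative Number of informative dimensions (ignored when
#'   \code{informative_dims} is given).
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param informative_dims Optional explicit informative column indices
#'   (1-based, in 1..n_bits+4), e.g. \code{515} to plant the signal on the
#'   NumHDonors column only.
#' @param binarize_bits Threshold the fingerprint block to {0,1}
#'   (default TRUE; FALSE keeps the raw Gaussians, useful for checking the
#'   generator's class-separation calibration directly).
#' @param bit_threshold Binarization threshold (default 1, i.e. one noise SD
#'   above the background mean, so background bits are on ~16% of the time).
#' @param n_bits Size of the fingerprint block (default 512; total dimension
#'   is n_bits + 4).
#' @param seed Seed; identical seeds give identical matrices.
#' @return List with \code{X} (matrix with \code{\link{feature_names}}
#'   columns), \code{y} (0/1 labels), \code{informative_dims} and
#'   \code{spec} (the generating parameters).
#' @export
generate_synthetic_features <- function(n_per_class = 250L,
                                        class_separation = 3,
                                        n_informative = 20L,
                                        noise_sd = 1,
                                        informative_dims = NULL,
                                        binarize_bits = TRUE,
                                        bit_threshold = 1,
                                        n_bits = 512L,
                                        seed = 1L) {
  stopifnot(n_per_class >= 1L, class_separation >= 0, noise_sd > 0)
  d <- n_bits + 4L
  set.seed(derive_seed(seed, "synth"))
  if (is.null(informative_dims)) {
    if (n_informative > d) stop("n_informative exceeds the feature dimension")
    informative_dims <- sort(sample.int(d, n_informative))
  } else {
    informative_dims <- sort(unique(as.integer(informative_dims)))
    if (any(informative_dims < 1L | informative_dims > d)) {
      stop("informative_dims out of range")
    }
  }
  n <- 2L * n_per_class
  y <- rep(c(0, 1), each = n_per_class)
  X <- matrix(stats::rnorm(n * d, sd = noise_sd), n, d)
  X[y == 1, informative_dims] <- X[y == 1, informative_dims] +
    class_separation * noise_sd
  if (binarize_bits && n_bits > 0L) {
    X[, seq_len(n_bits)] <- as.numeric(X[, seq_len(n_bits)] >
                                         bit_threshold * noise_sd)
  }
  colnames(X) <- feature_names(n_bits)
  rownames(X) <- sprintf("syn_%04d", seq_len(n))
  list(X = X, y = y, informative_dims = informative_dims,
       spec = list(n_per_class = n_per_class,
                   class_separation = class_separation,
                   n_informative = length(informative_dims),
                   noise_sd = noise_sd, binarize_bits = binarize_bits,
                   bit_threshold = bit_threshold, n_bits = n_bits,
                   seed = seed))
}

# Curated pool of real, parseable SMILES with plausible hazard labels:
# industrial solvents, reactive intermediates and recognized toxics as the
# positive class; sugars, polyols, amino acids and mild metabolites as the
# negative class.
.hcn_smiles_pool <- list(
  hazardous = c(
    methanol = "CO",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    aniline = "Nc1ccccc1",
    formaldehyde = "C=O",
    chloroform = "C(Cl)(Cl)Cl",
    carbon_tetrachloride = "ClC(Cl)(Cl)Cl",
    acrylonitrile = "C=CC#N",
    nitrobenzene = "O=[N+]([O-])c1ccccc1",
    hydrazine = "NN",
    acetonitrile = "CC#N",
    epichlorohydrin = "ClCC1CO1",
    dichloroethane = "ClCCCl",
    pyridine = "c1ccncc1",
    nitromethane = "C[N+](=O)[O-]",
    acrolein = "C=CC=O",
    carbon_disulfide = "S=C=S",
    dimethyl_sulfate = "COS(=O)(=O)OC",
    chlorobenzene = "Clc1ccccc1",
    trichloroethylene = "ClC=C(Cl)Cl",
    ethylene_oxide = "C1CO1",
    ethanol = "CCO",
    naphthalene = "c1ccc2ccccc2c1"),
  nonhazardous = c(
    glucose = "OCC(O)C(O)C(O)C(O)C=O",
    citric_acid = "OC(=O)CC(O)(C(=O)O)CC(=O)O",
    glycerol = "OCC(O)CO",
    ascorbic_acid = "OCC(O)C1OC(=O)C(O)=C1O",
    glycine = "NCC(=O)O",
    alanine = "CC(N)C(=O)O",
    leucine = "CC(C)CC(N)C(=O)O",
    lactic_acid = "CC(O)C(=O)O",
    urea = "NC(=O)N",
    sorbitol = "OCC(O)C(O)C(O)C(O)CO",
    caffeine = "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    fructose = "OCC(=O)C(O)C(O)C(O)CO",
    succinic_acid = "OC(=O)CCC(=O)O",
    fumaric_acid = "OC(=O)/C=C/C(=O)O",
    malic_acid = "OC(C(=O)O)CC(=O)O",
    tartaric_acid = "OC(=O)C(O)C(O)C(=O)O",
    serine = "OCC(N)C(=O)O",
    threonine = "CC(O)C(N)C(=O)O",
    valine = "CC(C)C(N)C(=O)O",
    proline = "OC(=O)C1CCCN1",
    niacin = "OC(=O)c1cccnc1",
    inositol = "OC1C(O)C(O)C(O)C(O)C1O",
    xylitol = "OCC(O)C(O)C(O)CO",
    betaine = "C[N+](C)(C)CC(=O)[O-]"))

#' The built-in SMILES fixture pool
#'
#' @return Data frame with columns name, smiles, label (1 = hazardous).
#' @export
smiles_pool <- function() {
  p <- .hcn_smiles_pool
  data.frame(
    name = c(names(p$hazardous), names(p$nonhazardous)),
    smiles = c(unname(p$hazardous), unname(p$nonhazardous)),
    label = rep(c(1, 0), c(length(p$hazardous), length(p$nonhazardous))),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic (id, smiles, label) table
#'
#' Samples with replacement from the curated pool, by class. The default
#' positive:negative ratio of 0.9 mirrors a mildly imbalanced hazard
#' screening dataset. All pool molecules are valid, so featurizing the table
#' yields zero rejects.
#'
#' @param n_per_class Number of negative (non-hazardous) rows; the number of
#'   positive rows is \code{round(ratio * n_per_class)}.
#' @param seed Seed; identical seeds give identical tables.
#' @param ratio Positive:negative ratio (default 0.9).
#' @param replace Sample with replacement (default TRUE; with
#'   \code{replace = FALSE}, requesting more rows than the pool holds is an
#'   error).
#' @param path Optional CSV output path.
#' @return Data frame with columns id, smiles, label (and the CSV written
#'   when \code{path} is given).
#' @export
generate_synthetic_smiles_table <- function(n_per_class = 50L, seed = 1L,
                                            ratio = 0.9, replace = TRUE,
                                            path = NULL) {
  n_neg <- as.integer(n_per_class)
  n_pos <- as.integer(round(ratio * n_per_class))
  stopifnot(n_neg >= 1L, n_pos >= 1L)
  pool <- .hcn_smiles_pool
  if (!replace && (n_pos > length(pool$hazardous) ||
                   n_neg > length(pool$nonhazardous))) {
    stop("requested more rows than the pool holds and replace = FALSE")
  }
  set.seed(derive_seed(seed, "synth_smiles"))
  pos <- sample(seq_along(pool$hazardous), n_pos, replace = replace)
  neg <- sample(seq_along(pool$nonhazardous), n_neg, replace = replace)
  tab <- data.frame(
    id = sprintf("syn_%04d", seq_len(n_pos + n_neg)),
    smiles = c(unname(pool$hazardous[pos]), unname(pool$nonhazardous[neg])),
    label = rep(c(1, 0), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  tab
}
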