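#' Circular (Morgan-style) molecular fingerprint
#'
#' Encodes the topological neighborhood of every heavy atom up to a fixed
#' bond radius into a fixed-length binary vector by iterative neighborhood
#' hashing: each atom starts from an identifier derived from its chemical
#' properties (atomic number, heavy-atom degree, attached hydrogens, formal
#' charge, ring membership) and is repeatedly updated by hashing its own
#' identifier together with the sorted (bond order, identifier) pairs of its
#' neighbors. Every identifier produced at any radius sets one bit
#' (identifier mod \code{n_bits}).
#'
#' Because the initial invariants are atom properties and neighbor
#' contributions are sorted, the fingerprint does not depend on the atom
#' order of the input SMILES; \code{\link{parse_smiles}} additionally
#' canonicalizes the molecule first. Bit positions are internally consistent
#' and deterministic but, as with any hashed fingerprint, not comparable
#' across unrelated implementations.
#'
#' @param mol An \code{hcn_mol} from \code{\link{parse_smiles}}.
#' @param n_bits Fingerprint length in bits (default 512).
#' @param radius Maximum bond radius of the encoded neighborhoods (default 2).
#' @return Integer vector of length \code{n_bits} with entries in {0, 1},
#'   with attributes \code{radius} and \code{n_bits}.
#' @examples
#' fp <- morgan_fingerprint(parse_smiles("CCO"))
#' sum(fp)
#' @export
morgan_fingerprint <- function(mol, n_bits = 512L, radius = 2L) {
  if (inherits(mol, "hcn_reject")) {
    stop("cannot fingerprint a rejected molecule: ", mol$reason)
  }
  stopifnot(inherits(mol, "hcn_mol"))
  n_bits <- as.integer(n_bits); radius <- as.integer(radius)
  if (is.na(n_bits) || n_bits <= 0L) stop("n_bits must be a positive integer")
  if (is.na(radius) || radius < 0L) stop("radius must be a non-negative integer")

  atoms <- mol$atoms
  n <- nrow(atoms)
  bits <- integer(n_bits)
  if (n == 0L) {
    return(structure(bits, radius = radius, n_bits = n_bits))
  }

  # adjacency: list of (neighbor index, bond order) per atom
  nbr <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (b in seq_len(nrow(mol$bonds))) {
      a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]; o <- mol$bonds$order[b]
      nbr[[a1]] <- rbind(nbr[[a1]], c(a2, o))
      nbr[[a2]] <- rbind(nbr[[a2]], c(a1, o))
    }
  }

  ids <- vapply(seq_len(n), function(i) {
    hcn_hash(c(atoms$z[i], atoms$degree[i], atoms$n_h[i],
               atoms$charge[i] + 16, as.integer(atoms$in_ring[i])))
  }, numeric(1))

  seen <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- nbr[[i]]
        if (is.null(nb)) {
          hcn_hash(c(r, ids[i]))
        } else {
          pair_ids <- ids[nb[, 1]]
          ord <- order(nb[, 2], pair_ids)
          hcn_hash(c(r, ids[i], as.numeric(rbind(nb[ord, 2], pair_ids[ord]))))
        }
      }, numeric(1))
      ids <- new_ids
      seen <- c(seen, ids)
    }
  }

  for (v in unique(seen)) {
    bits[(v %% n_bits) + 1L] <- 1L
  }
  structure(bits, radius = radius, n_bits = n_bits)
}

# Deterministic polynomial hash over non-negative numeric tuples.
# Modulus is the largest prime below 2^25 so every intermediate product
# stays well inside the exactly-representable double range (< 2^53).
hcn_hash <- function(values) {
  m <- 33554393
  h <- 17
  for (v in values) {
    h <- (h * 1000003 + (v %% m)) %% m
  }
  h
}
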