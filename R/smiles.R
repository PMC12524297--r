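#' Parse a SMILES string into a molecule graph
#'
#' Validates and canonicalizes a SMILES string through OpenBabel (via
#' \pkg{ChemmineOB}) and extracts the heavy-atom graph used for
#' fingerprinting: one row per heavy atom with element, formal charge,
#' attached-hydrogen count, heavy-atom degree and ring membership, plus a
#' bond table with Kekulé bond orders. Canonicalization is applied first so
#' that two SMILES spellings of the same molecule yield the same graph (and
#' therefore the same fingerprint).
#'
#' Invalid SMILES are not errors at the R level: they return an object of
#' class \code{hcn_reject} carrying the reason, so that dataset-level
#' featurization can continue past failures and report them.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier carried through to rejection reports.
#' @return An object of class \code{hcn_mol} (a list with elements
#'   \code{smiles}, \code{cansmi}, \code{atoms}, \code{bonds},
#'   \code{n_fragments}) or an \code{hcn_reject} with elements \code{id},
#'   \code{smiles}, \code{reason}.
#' @examples
#' mol <- parse_smiles("CCO")
#' mol$atoms
#' parse_smiles("C1CC")  # unmatched ring bond -> rejection
#' @export
parse_smiles <- function(smiles, id = NA_character_) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(hcn_reject(id, smiles, "empty or non-string SMILES"))
  }
  smiles <- trimws(smiles)
  cansmi <- canonical_smiles(smiles)
  if (is.na(cansmi)) {
    return(hcn_reject(id, smiles, "SMILES failed to parse"))
  }
  # explicit hydrogens for per-atom H counts; 2D coordinates are irrelevant
  # to the graph but keep the MDL writer from warning about their absence
  sdf_txt <- ob_convert_quiet("SMI", "SDF", paste0(cansmi, "\tmol\n"),
                              options = data.frame(names = c("h", "gen2D"),
                                                   args = c("", ""),
                                                   stringsAsFactors = FALSE))
  if (!nzchar(trimws(sdf_txt))) {
    return(hcn_reject(id, smiles, "SMILES parsed but SDF conversion failed"))
  }
  graph <- tryCatch(molgraph_from_sdf(sdf_txt),
                    error = function(e) NULL)
  if (is.null(graph)) {
    return(hcn_reject(id, smiles, "could not extract molecule graph"))
  }
  structure(list(smiles = smiles, cansmi = cansmi,
                 atoms = graph$atoms, bonds = graph$bonds,
                 n_fragments = graph$n_fragments),
            class = "hcn_mol")
}

hcn_reject <- function(id, smiles, reason) {
  structure(list(id = id,
                 smiles = if (is.character(smiles) && length(smiles) == 1L)
                   smiles else NA_character_,
                 reason = reason),
            class = "hcn_reject")
}

#' @export
print.hcn_mol <- function(x, ...) {
  cat(sprintf("<hcn_mol> %s  (%d heavy atoms, %d bonds, %d fragment%s)\n",
              x$cansmi, nrow(x$atoms), nrow(x$bonds), x$n_fragments,
              if (x$n_fragments == 1L) "" else "s"))
  invisible(x)
}

#' @export
print.hcn_reject <- function(x, ...) {
  cat(sprintf("<hcn_reject> id=%s smiles=%s : %s\n",
              x$id, x$smiles, x$reason))
  invisible(x)
}

#' Canonicalize a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES, or \code{NA_character_} if it does not parse.
#' @export
canonical_smiles <- function(smiles) {
  out <- ob_convert_quiet("SMI", "CAN", paste0(smiles, "\tmol\n"))
  out <- sub("\t.*$", "", sub("\n$", "", out))
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

# Error-tolerant wrapper around ChemmineOB::convertFormat. An unparseable
# input yields an empty string (OpenBabel reports the parse problem on
# stderr from C++, which R cannot intercept; the empty result is the
# machine-readable signal).
ob_convert_quiet <- function(from, to, source, options = NULL) {
  res <- suppressWarnings(tryCatch({
    if (is.null(options)) ChemmineOB::convertFormat(from, to, source)
    else ChemmineOB::convertFormat(from, to, source, options = options)
  }, error = function(e) ""))
  if (!is.character(res) || length(res) != 1L) "" else res
}

# Old-style molfile charge codes (field used by OpenBabel output).
.molfile_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                     `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# Parse an explicit-hydrogen SDF text block into a heavy-atom graph.
molgraph_from_sdf <- function(sdf_txt) {
  con <- textConnection(sdf_txt)
  on.exit(close(con), add = TRUE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con)))
  ab <- ChemmineR::atomblock(sdf[[1]])
  elem <- sub("_\\d+$", "", rownames(ab))
  n_all <- length(elem)
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds_all <- matrix(integer(0), ncol = 3)
  } else {
    bonds_all <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                       as.integer(bb[, 3]))
  }
  charge_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    rep(0L, n_all)
  charge <- .molfile_charge[as.character(pmin(pmax(charge_code, 0L), 7L))]
  charge[is.na(charge)] <- 0L

  heavy <- which(elem != "H")
  if (length(heavy) == 0L) {
    # e.g. "[H][H]"; treat the hydrogens themselves as the graph
    heavy <- seq_len(n_all)
  }
  idx_map <- rep(NA_integer_, n_all)
  idx_map[heavy] <- seq_along(heavy)

  n_h <- integer(length(heavy))
  keep <- logical(nrow(bonds_all))
  if (nrow(bonds_all) > 0L) {
    for (b in seq_len(nrow(bonds_all))) {
      a1 <- bonds_all[b, 1]; a2 <- bonds_all[b, 2]
      h1 <- elem[a1] == "H"; h2 <- elem[a2] == "H"
      if (h1 && !h2 && !is.na(idx_map[a2])) {
        n_h[idx_map[a2]] <- n_h[idx_map[a2]] + 1L
      } else if (h2 && !h1 && !is.na(idx_map[a1])) {
        n_h[idx_map[a1]] <- n_h[idx_map[a1]] + 1L
      } else if (!h1 && !h2) {
        keep[b] <- TRUE
      }
    }
  }
  bonds <- bonds_all[keep, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds <- data.frame(a1 = idx_map[bonds[, 1]], a2 = idx_map[bonds[, 2]],
                        order = bonds[, 3])
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  elem_h <- elem[heavy]
  z <- atomic_numbers(elem_h)
  degree <- integer(length(heavy))
  if (nrow(bonds) > 0L) {
    tab <- table(factor(c(bonds$a1, bonds$a2), levels = seq_along(heavy)))
    degree <- as.integer(tab)
  }

  g <- igraph::graph_from_data_frame(
    d = if (nrow(bonds) > 0L) bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy)))
  in_ring <- rep(FALSE, length(heavy))
  if (nrow(bonds) > 0L) {
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      if (length(comp) >= 3L) {
        in_ring[as.integer(igraph::V(g)$name[comp])] <- TRUE
      }
    }
  }
  n_fragments <- igraph::count_components(g)

  atoms <- data.frame(elem = elem_h, z = z, charge = charge[heavy],
                      n_h = n_h, degree = degree, in_ring = in_ring,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds, n_fragments = n_fragments)
}

atomic_numbers <- function(symbols) {
  tbl <- hcn_atomprop()
  z <- tbl$Number[match(symbols, tbl$Symbol)]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

# Periodic-table lookup from ChemmineR, cached per session.
hcn_atomprop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("atomprop", package = "ChemmineR", envir = e)
      cache <<- e$atomprop
    }
    cache
  }
})
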