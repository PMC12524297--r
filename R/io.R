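#' Read a molecule dataset
#'
#' Accepts CSV/TSV with a header containing columns \code{id},
#' \code{smiles} and optionally \code{label}, or a bare \code{.smi} file
#' ("SMILES whitespace id" per line, no labels, prediction mode). Labels
#' must be exactly 0 or 1 (1 = hazardous); any other value is an error
#' naming the offending rows, as are duplicate ids. Duplicate SMILES with
#' conflicting labels are reported with a warning and the first occurrence
#' is kept.
#'
#' @param path File path.
#' @param format "auto" (by extension), "csv", "tsv" or "smi".
#' @return List with \code{records} (data frame id, smiles, label) and
#'   \code{manifest} (see \code{\link{dataset_manifest}}).
#' @export
read_dataset <- function(path, format = c("auto", "csv", "tsv", "smi")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     smi = "smi",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty dataset file: ", path)
    parts <- strsplit(trimws(lines), "[ \t]+")
    records <- data.frame(
      id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) >= 2L) parts[[i]][2] else
          paste0("mol_", i), character(1)),
      smiles = vapply(parts, `[[`, character(1), 1L),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            colClasses = "character", quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    missing_cols <- setdiff(c("id", "smiles"), names(df))
    if (length(missing_cols)) {
      stop("dataset is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (nrow(df) == 0L) stop("empty dataset file: ", path)
    records <- data.frame(id = df$id, smiles = df$smiles,
                          stringsAsFactors = FALSE)
    if ("label" %in% names(df)) {
      bad <- which(!df$label %in% c("0", "1"))
      if (length(bad)) {
        stop("non-binary label(s) at row(s) ",
             paste(utils::head(bad, 10), collapse = ", "),
             " (values: ", paste(utils::head(df$label[bad], 10),
                                 collapse = ", "), ")")
      }
      records$label <- as.numeric(df$label)
    }
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup)) {
    stop("duplicate id(s): ", paste(utils::head(unique(dup), 10),
                                    collapse = ", "))
  }
  if ("label" %in% names(records)) {
    # duplicate structures with conflicting labels: keep first, report
    key <- records$smiles
    conflict <- character(0)
    seen <- list()
    keep <- rep(TRUE, nrow(records))
    for (i in seq_len(nrow(records))) {
      prev <- seen[[key[i]]]
      if (is.null(prev)) {
        seen[[key[i]]] <- records$label[i]
      } else if (prev != records$label[i]) {
        conflict <- c(conflict, records$id[i])
        keep[i] <- FALSE
      }
    }
    if (length(conflict)) {
      warning("duplicate SMILES with conflicting labels; kept first ",
              "occurrence, dropped: ", paste(conflict, collapse = ", "))
      records <- records[keep, , drop = FALSE]
    }
  }
  list(records = records,
       manifest = dataset_manifest(records, path = path))
}

#' Dataset manifest
#'
#' Class counts and positive:negative ratio are recomputed from the labels,
#' never trusted from the input; the file checksum ties the manifest to its
#' source.
#'
#' @param records Data frame with optional \code{label} column.
#' @param path Optional source file (for the checksum).
#' @param source Provenance tag: "supplementary", "synthetic" or "user".
#' @return List with \code{source}, \code{n}, \code{n_positive},
#'   \code{n_negative}, \code{ratio}, \code{checksum}.
#' @export
dataset_manifest <- function(records, path = NULL, source = "user") {
  has_label <- "label" %in% names(records)
  n_pos <- if (has_label) sum(records$label == 1) else NA_integer_
  n_neg <- if (has_label) sum(records$label == 0) else NA_integer_
  list(source = source,
       n = nrow(records),
       n_positive = n_pos,
       n_negative = n_neg,
       ratio = if (has_label && n_neg > 0) n_pos / n_neg else NA_real_,
       checksum = if (is.null(path)) NA_character_ else
         unname(tools::md5sum(path)))
}

#' Write a feature matrix with a sidecar manifest
#'
#' @param X Feature matrix (from \code{\link{featurize_dataset}}).
#' @param path Output CSV path; a JSON manifest with the column names is
#'   written next to it.
#' @param labels Optional label vector appended as a \code{label} column.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(X, path, labels = NULL) {
  df <- as.data.frame(X)
  df <- cbind(id = rownames(X), df)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(columns = colnames(X), n = nrow(X),
         has_labels = !is.null(labels)),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by \code{\link{write_features}}
#'
#' @param path CSV path.
#' @return List with \code{X} (matrix with rownames = ids) and \code{labels}
#'   (or NULL).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- df$id
  df$id <- NULL
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.numeric(df$label)
    df$label <- NULL
  }
  X <- as.matrix(df)
  rownames(X) <- ids
  list(X = X, labels = labels)
}

#' Set up a JSONL run log
#'
#' Subsequent calls to \code{\link{log_event}} append one JSON object per
#' line (timestamp, event, payload) to the file. Every training entry point
#' logs its seed, config hash, dataset manifest and package version, so runs
#' are auditable.
#'
#' @param path Log file path, or NULL to disable logging.
#' @return Previous log path, invisibly.
#' @export
setup_logging <- function(path) {
  old <- getOption("hazchemnet.log")
  options(hazchemnet.log = path)
  invisible(old)
}

#' Append an event to the run log
#'
#' No-op unless \code{\link{setup_logging}} has set a log file.
#'
#' @param event Short event name.
#' @param ... Named payload fields (must be JSON-serializable).
#' @return Invisibly, TRUE if a line was written.
#' @export
log_event <- function(event, ...) {
  path <- getOption("hazchemnet.log")
  if (is.null(path)) return(invisible(FALSE))
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                event = event,
                package_version = as.character(
                  utils::packageVersion("hazchemnet")))
  payload <- list(...)
  entry[names(payload)] <- payload
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
  invisible(TRUE)
}
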