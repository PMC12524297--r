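#' Repeated stratified k-fold cross-validation
#'
#' Evaluation protocol: records are partitioned once into k stratified folds
#' (from the master seed); each fold is then used as the held-out set for
#' \code{repeats} fully independent trainings of the whole pipeline, each
#' with a fresh seed derived from the master. Reported are the run-level
#' metrics, per-fold mean +/- SD over the repeats, and the overall
#' mean +/- SD over all k x repeats runs (so the overall mean equals the
#' arithmetic mean of the run-level values).
#'
#' @param X Raw feature matrix.
#' @param y Binary labels.
#' @param cfg A \code{\link{hazchemnet_config}}; its seed is the master seed.
#' @param k Number of folds (default 5).
#' @param repeats Independent trainings per fold (default 5).
#' @param verbose Print progress.
#' @return Object of class \code{hcn_cv}: \code{runs} (data frame with fold,
#'   repeat id, seed and the five metrics), \code{per_fold}, \code{overall},
#'   \code{folds} (fold assignment), \code{k}, \code{repeats}.
#' @export
cross_validate <- function(X, y, cfg = hazchemnet_config(), k = 5L,
                           repeats = 5L, verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (k > nrow(X)) stop("k exceeds the number of records")
  folds <- stratified_folds(y, k = k, seed = derive_seed(cfg$seed, "folds"))

  runs <- list()
  for (fold in seq_len(k)) {
    test_idx <- which(folds == fold)
    train_idx <- which(folds != fold)
    if (length(unique(y[test_idx])) < 2L && verbose) {
      message("fold ", fold, " has a single class in its test set")
    }
    for (rep_i in seq_len(repeats)) {
      run_seed <- derive_seed(cfg$seed, "cv_run", fold * 1000L + rep_i)
      run_cfg <- cfg
      run_cfg$seed <- run_seed
      model <- hazchemnet_fit(X[train_idx, , drop = FALSE], y[train_idx],
                              cfg = run_cfg)
      pred <- predict(model, X[test_idx, , drop = FALSE])
      m <- compute_metrics(y[test_idx], pred$predictions$probability,
                           threshold = cfg$decision_threshold)
      runs[[length(runs) + 1L]] <- cbind(
        data.frame(fold = fold, rep = rep_i, seed = run_seed),
        metrics_row(m))
      if (verbose) {
        message(sprintf("fold %d rep %d: acc %.3f", fold, rep_i, m$accuracy))
      }
    }
  }
  runs <- do.call(rbind, runs)

  agg <- function(df) {
    row <- list()
    for (mn in metric_names) {
      ms <- mean_sd(df[[mn]])
      row[[paste0(mn, "_mean")]] <- ms[["mean"]]
      row[[paste0(mn, "_sd")]] <- ms[["sd"]]
    }
    as.data.frame(row)
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    cbind(data.frame(fold = f), agg(runs[runs$fold == f, ]))
  }))
  overall <- agg(runs)

  structure(list(runs = runs, per_fold = per_fold, overall = overall,
                 folds = folds, k = k, repeats = repeats, seed = cfg$seed),
            class = "hcn_cv")
}

#' @export
print.hcn_cv <- function(x, ...) {
  cat(sprintf("<hcn_cv> %d-fold x %d repeats (%d runs), master seed %d\n",
              x$k, x$repeats, nrow(x$runs), x$seed))
  tab <- cbind(fold = c(as.character(x$per_fold$fold), "overall"),
               rbind(format_percent_table(x$per_fold),
                     format_percent_table(x$overall)))
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report
#'
#' Emits the run-level metrics, the per-fold and overall mean +/- SD tables
#' as CSV, and a human-readable text table. Byte-identical across runs with
#' the same master seed.
#'
#' @param cv An \code{hcn_cv}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  stopifnot(inherits(cv, "hcn_cv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cv$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(cv$per_fold, file.path(dir, "per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$overall, file.path(dir, "overall.csv"),
                   row.names = FALSE)
  txt <- c(sprintf("%d-fold cross-validation, %d repeats, master seed %d",
                   cv$k, cv$repeats, cv$seed),
           "", "fold  " , utils::capture.output({
             tab <- cbind(fold = c(as.character(cv$per_fold$fold), "overall"),
                          rbind(format_percent_table(cv$per_fold),
                                format_percent_table(cv$overall)))
             print(as.data.frame(tab), row.names = FALSE)
           }))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
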