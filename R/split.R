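#' Split a dataset into train / validation / test sets
#'
#' Default ratios are 7:2:1. Set sizes are fixed by largest-remainder
#' rounding of \code{n * ratio} so they always sum to \code{n} (e.g. 5140
#' records give exactly 3598 / 1028 / 514). With \code{stratified = TRUE}
#' (the default, recommended for the mildly imbalanced 0.9 hazard ratio),
#' records are allocated per class by the same largest-remainder scheme,
#' constrained so the global set sizes still hold exactly.
#'
#' @param n Number of records, or a vector/data frame from which it is taken.
#' @param ratios Length-3 positive vector summing to 1 (train, validation,
#'   test).
#' @param labels Binary label vector, required when \code{stratified}.
#' @param stratified Stratify by label (default TRUE when labels given).
#' @param seed Seed for the shuffle.
#' @return List of integer index vectors \code{train}, \code{validation},
#'   \code{test}: disjoint and exhaustive.
#' @examples
#' sp <- split_dataset(5140, labels = rep(c(1, 0), c(2428, 2712)))
#' lengths(sp)  # 3598 1028 514
#' @export
split_dataset <- function(n, ratios = c(0.7, 0.2, 0.1), labels = NULL,
                          stratified = !is.null(labels), seed = 1L) {
  if (is.data.frame(n)) {
    if (is.null(labels) && "label" %in% names(n)) labels <- n$label
    n <- nrow(n)
  } else if (length(n) > 1L) {
    n <- length(n)
  }
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 records to split")
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be 3 positive numbers")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (stratified && is.null(labels)) {
    stop("stratified split requires labels")
  }
  sizes <- largest_remainder(n, ratios)

  set.seed(seed)
  if (!stratified) {
    idx <- sample.int(n)
    assign <- rep.int(1:3, sizes)
  } else {
    labels <- as.numeric(labels)
    if (length(labels) != n) stop("labels length must equal n")
    classes <- sort(unique(labels))
    # per-(class, set) quota: start from floors of the fractional targets,
    # then fill remaining slots greedily by fractional part, constrained so
    # each set reaches exactly its global largest-remainder size
    quota <- matrix(0L, length(classes), 3L)
    frac <- matrix(0, length(classes), 3L)
    for (ci in seq_along(classes)) {
      target <- sum(labels == classes[ci]) * ratios
      quota[ci, ] <- floor(target)
      frac[ci, ] <- target - floor(target)
    }
    set_left <- sizes - colSums(quota)
    class_left <- vapply(classes, function(cl) sum(labels == cl),
                         numeric(1)) - rowSums(quota)
    ord <- order(-as.vector(frac))
    for (cell in ord) {
      ci <- (cell - 1L) %% length(classes) + 1L
      si <- (cell - 1L) %/% length(classes) + 1L
      if (class_left[ci] > 0L && set_left[si] > 0L) {
        quota[ci, si] <- quota[ci, si] + 1L
        class_left[ci] <- class_left[ci] - 1L
        set_left[si] <- set_left[si] - 1L
      }
    }
    idx <- integer(n)
    assign <- integer(n)
    pos <- 1L
    for (ci in seq_along(classes)) {
      members <- sample(which(labels == classes[ci]))
      a <- rep.int(1:3, quota[ci, ])
      span <- pos:(pos + length(members) - 1L)
      idx[span] <- members
      assign[span] <- a
      pos <- pos + length(members)
    }
  }
  list(train = sort(idx[assign == 1L]),
       validation = sort(idx[assign == 2L]),
       test = sort(idx[assign == 3L]))
}

# integer apportionment: floor everything, hand out the remainder to the
# largest fractional parts (earlier position wins ties)
largest_remainder <- function(n, ratios) {
  target <- n * ratios
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(-(target - sizes), seq_along(ratios))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Stratified fold assignment for k-fold cross-validation
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per record; every record
#'   is in exactly one fold and both classes appear in every fold whenever
#'   counts allow.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (k > n) stop("k exceeds the number of records")
  set.seed(seed)
  folds <- integer(n)
  for (cl in unique(labels)) {
    members <- sample(which(labels == cl))
    folds[members] <- rep_len(seq_len(k), length(members))
  }
  folds
}
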