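# Splitting, metrics, cross-validation, ablation, external validation.

test_that("7:2:1 split of 5140 stratified records gives exactly 3598/1028/514", {
  labels <- rep(c(1, 0), c(2428, 2712))
  sp <- split_dataset(5140, labels = labels, seed = 1)
  expect_equal(lengths(sp)[["train"]], 3598L)
  expect_equal(lengths(sp)[["validation"]], 1028L)
  expect_equal(lengths(sp)[["test"]], 514L)
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, 1:5140)
  # stratification keeps the class ratio in every set
  for (s in sp) {
    expect_equal(mean(labels[s] == 1), 2428 / 5140, tolerance = 0.01)
  }
})

test_that("split sizes follow largest-remainder rounding and partition the data", {
  sp <- split_dataset(10, seed = 2, stratified = FALSE)
  expect_equal(unname(lengths(sp)), c(7L, 2L, 1L))
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    labels <- rbinom(n, 1, 0.45)
    sp <- split_dataset(n, labels = labels, seed = i)
    expect_equal(sum(lengths(sp)), n)
    expect_identical(sort(c(sp$train, sp$validation, sp$test)), 1:n)
    expect_equal(length(intersect(sp$train, sp$test)), 0L)
    expect_equal(length(intersect(sp$train, sp$validation)), 0L)
  }
  expect_identical(split_dataset(100, seed = 9, stratified = FALSE),
                   split_dataset(100, seed = 9, stratified = FALSE))
})

test_that("split argument validation", {
  expect_error(split_dataset(5), "at least 10")
  expect_error(split_dataset(100, ratios = c(0.5, 0.3), stratified = FALSE),
               "3 positive")
  expect_error(split_dataset(100, ratios = c(0.5, 0.3, 0.3),
                             stratified = FALSE), "sum to 1")
  expect_error(split_dataset(100, stratified = TRUE), "labels")
})

test_that("stratified folds partition records with both classes per fold", {
  y <- rep(c(0, 1), c(60, 54))
  f <- stratified_folds(y, k = 5, seed = 4)
  expect_equal(length(f), 114L)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_gt(sum(y[f == k] == 0), 0)
    expect_gt(sum(y[f == k] == 1), 0)
  }
  expect_error(stratified_folds(y, k = 200), "exceeds")
})

test_that("metric formulas reproduce hand-computed confusion arithmetic", {
  m <- metrics_from_confusion(tp = 225, tn = 208, fp = 25, fn = 10)
  expect_equal(m$accuracy, 433 / 468)
  expect_equal(m$precision, 225 / 250)
  expect_equal(m$recall, 225 / 235)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$n, 468L)
  expect_error(metrics_from_confusion(-1, 0, 0, 2), "non-negative")
})

test_that("probability metrics: perfect, chance and degenerate cases", {
  y <- c(0, 0, 1, 1)
  perfect <- compute_metrics(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  const <- compute_metrics(y, rep(0.7, 4))
  expect_equal(const$auc, 0.5)  # midrank tie convention

  nopos <- compute_metrics(c(0, 0, 0), c(0.1, 0.2, 0.3))
  expect_true(is.na(nopos$recall))
  expect_true("recall" %in% nopos$undefined)
  expect_true(is.na(nopos$auc))

  nopred <- compute_metrics(c(0, 1), c(0.1, 0.2))
  expect_true(is.na(nopred$precision))
  expect_true("precision" %in% nopred$undefined)
})

test_that("metrics agree with brute-force counting on random instances", {
  set.seed(5)
  has_proc <- requireNamespace("pROC", quietly = TRUE)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    prob <- round(runif(n), 2)  # rounding forces ties
    thr <- runif(1, 0.2, 0.8)
    m <- compute_metrics(y, prob, threshold = thr)
    pred <- ifelse(prob >= thr, 1, 0)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == 1 && y[j] == 1) tp <- tp + 1
      if (pred[j] == 0 && y[j] == 0) tn <- tn + 1
      if (pred[j] == 1 && y[j] == 0) fp <- fp + 1
      if (pred[j] == 0 && y[j] == 1) fn <- fn + 1
    }
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    # pairwise-comparison AUC oracle with half credit for ties
    pos <- which(y == 1); neg <- which(y == 0)
    wins <- 0
    for (a in pos) for (b in neg) {
      wins <- wins + (prob[a] > prob[b]) + 0.5 * (prob[a] == prob[b])
    }
    expect_lt(abs(m$auc - wins / (length(pos) * length(neg))), 1e-12)
    if (has_proc && i <= 25) {
      proc_auc <- suppressMessages(as.numeric(
        pROC::auc(pROC::roc(y, prob, quiet = TRUE, direction = "<"))))
      expect_lt(abs(m$auc - proc_auc), 1e-12)
    }
  }
})

test_that("cross-validation aggregates run-level metrics exactly", {
  syn <- separable_features(n_per_class = 45, seed = 6)
  cv <- cross_validate(syn$X, syn$y, tiny_config(), k = 3, repeats = 2)
  expect_equal(nrow(cv$runs), 6L)
  # pooled mean is the arithmetic mean of run-level metrics
  for (mn in c("accuracy", "precision", "recall", "f1", "auc")) {
    expect_lt(abs(cv$overall[[paste0(mn, "_mean")]] - mean(cv$runs[[mn]])),
              1e-12)
  }
  # per-fold SD is over the repeats of that fold
  f1_acc <- cv$runs$accuracy[cv$runs$fold == 1]
  expect_equal(cv$per_fold$accuracy_sd[1], stats::sd(f1_acc))
  # every record is in exactly one test fold
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_equal(length(cv$folds), nrow(syn$X))
  # F1 identity holds in every emitted row
  with(cv$runs, expect_equal(f1, 2 * precision * recall / (precision + recall),
                             tolerance = 1e-9))
})

test_that("single-repeat cross-validation reports zero SD", {
  syn <- separable_features(n_per_class = 30, seed = 7)
  cv <- cross_validate(syn$X, syn$y, tiny_config(), k = 3, repeats = 1)
  expect_true(all(cv$per_fold$accuracy_sd == 0))
  expect_true(all(cv$per_fold$auc_sd == 0))
  expect_error(cross_validate(syn$X, syn$y, tiny_config(), k = 1000),
               "exceeds")
})

test_that("ablation variants drop the right columns", {
  syn <- separable_features(n_per_class = 30, seed = 8)
  expect_error(ablate(syn$X, syn$y, tiny_config(), variants = "-Bogus"),
               "unknown")
  ab <- ablate(syn$X, syn$y, tiny_config(),
               variants = c("full", "-MolWt", "-MorganFingerprint"))
  expect_equal(ab$results[["full"]]$n_features, 516L)
  expect_equal(ab$results[["-MolWt"]]$n_features, 515L)
  expect_equal(ab$results[["-MolWt"]]$dropped, "MolWt")
  expect_equal(ab$results[["-MorganFingerprint"]]$n_features, 4L)
  expect_equal(nrow(ab$table), 3L)
})

test_that("external validation reports per-class accuracy and excludes rejects", {
  tab <- generate_synthetic_smiles_table(n_per_class = 30, seed = 9)
  feat <- featurize_dataset(tab)
  fit <- hazchemnet_fit(feat$X, feat$labels, cfg = learn_config(seed = 9L))
  pool <- smiles_pool()
  haz <- data.frame(id = pool$name[pool$label == 1],
                    smiles = pool$smiles[pool$label == 1])
  non <- data.frame(id = pool$name[pool$label == 0],
                    smiles = pool$smiles[pool$label == 0])
  ext <- external_validate(fit, haz, non)
  expect_equal(ext$n_hazardous, nrow(haz))
  expect_equal(ext$hazardous_accuracy,
               sum(ext$verdicts$correct[ext$verdicts$true_label == 1]) /
                 nrow(haz))
  expect_equal(ext$false_negative_rate, 1 - ext$hazardous_accuracy)
  expect_equal(nrow(ext$verdicts), nrow(haz) + nrow(non))
  expect_error(external_validate(fit, haz[0, ], non), "non-empty")

  # a bad SMILES is excluded from the denominator with a warning
  haz_bad <- rbind(haz, data.frame(id = "broken", smiles = "C1CC"))
  expect_warning(ext2 <- external_validate(fit, haz_bad, non), "excluded")
  expect_equal(ext2$n_hazardous, nrow(haz))
})
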