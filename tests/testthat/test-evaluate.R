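test_that("pooled ROC/AUC matches hand cases and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(50:400, 1)
    s <- round(runif(n), sample(c(1, 2, 7), 1))   # induce ties sometimes
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.3, 0.4), c(1, 1)), "single-class")
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(62)
  r <- roc_auc(runif(300), rbinom(300, 1, 0.5))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("AUC is near 1/2 under a permutation null and invariant to monotone maps", {
  set.seed(63)
  n <- 4000
  s <- runif(n)
  y <- rbinom(n, 1, 0.5)
  n1 <- sum(y); n0 <- n - n1
  null_sd <- sqrt((n + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 3 * null_sd)
  # strictly increasing transforms leave the AUC unchanged
  set.seed(64)
  s2 <- runif(500); y2 <- rbinom(500, 1, 0.3)
  a <- roc_auc(s2, y2)$auc
  expect_equal(roc_auc(qlogis(pmin(pmax(s2, 1e-9), 1 - 1e-9)), y2)$auc, a)
  expect_equal(roc_auc(s2^3 + 2 * s2, y2)$auc, a)
})

test_that("ROC agrees with an established implementation on pooled scores", {
  skip_if_not_installed("pROC")
  set.seed(65)
  s <- runif(600)
  y <- rbinom(600, 1, 0.35)
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion matrices tabulate and normalize correctly", {
  cf <- confusion_at_threshold(c(0.9, 0.95, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(cf$percent), matrix(c(100, 0, 0, 100), 2, 2, byrow = TRUE))
  cf_all1 <- confusion_at_threshold(rep(1, 6), c(1, 1, 0, 0, 0, 0), 0.75)
  expect_equal(unname(cf_all1$percent[2, ]), c(100, 0))
  expect_true(all(abs(rowSums(cf$percent) - 100) < 1e-9))
  # FP rate is non-increasing in the threshold
  set.seed(66)
  s <- runif(500); y <- rbinom(500, 1, 0.5)
  fp <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    confusion_at_threshold(s, y, th)$percent[2, 1]
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))
  expect_error(confusion_at_threshold(numeric(0), numeric(0)), "empty")
})

test_that("cross-validation pools held-out scores and is perfect on noiseless data", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds)
  r2f <- crossval_auc(ds, "cbc", folds = 2, seed = 3, features = fe)
  r4f <- crossval_auc(ds, "cbc", folds = 4, seed = 3, features = fe)
  expect_gte(r2f$auc, 0.9)   # smaller training splits, mildly weaker
  expect_gte(r4f$auc, 0.97)
  expect_false(anyNA(r4f$scores))
  # stratification: every graph class present in every training split
  fold <- grangerlearn:::stratified_folds(fe$graph_index, 4, seed = 3)
  for (f in 1:4) {
    expect_setequal(unique(fe$graph_index[fold != f]), 0:3)
  }
  # gca route needs no training data
  rg <- crossval_auc(tiny_noisy(), "gca")
  expect_true(rg$auc > 0 && rg$auc <= 1)
})

test_that("mismatch evaluation trains once and scores the other dataset", {
  clean <- tiny_noiseless()
  noisy <- tiny_noisy()
  fe_c <- featurize_dataset(clean)
  fe_n <- featurize_dataset(noisy)
  mm <- mismatch_auc(clean, noisy, "cbc", train_features = fe_c,
                     test_features = fe_n)
  expect_s3_class(mm, "experiment_report")
  expect_true(mm$auc > 0.5)
  # training and testing on the same data bounds the held-out AUC
  ins <- mismatch_auc(noisy, noisy, "cbc", train_features = fe_n,
                      test_features = fe_n)
  cv <- crossval_auc(noisy, "cbc", folds = 4, seed = 1, features = fe_n)
  expect_gte(ins$auc + 1e-9, cv$auc)
  # reverse direction runs without error
  rev <- mismatch_auc(noisy, clean, "cbc", train_features = fe_n,
                      test_features = fe_c)
  expect_true(is.finite(rev$auc))
  expect_error(mismatch_auc(clean, tiny_m3_stub()), "share M and p")
})

test_that("experiment replication emits the documented report shapes", {
  rep3 <- replicate_experiment("table3", M = 2, p = 3, N = 250,
                               trials_per_graph = 8, folds = 2, seed = 9)
  expect_length(rep3, 6)
  expect_true(all(vapply(rep3, function(r) is.finite(r$auc), logical(1))))
  rep5 <- replicate_experiment("table5", M = 2, p = 3, N = 250,
                               trials_per_graph = 8, folds = 2, seed = 9)
  expect_length(rep5, 3)
  expect_true(all(vapply(rep5, function(r) !is.null(r$confusion), logical(1))))
})
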