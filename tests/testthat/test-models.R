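test_that("CBC trains one probabilistic model per off-diagonal cell", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds)
  m <- train_cbc(fe)
  expect_s3_class(m, "trained_cbc")
  expect_length(m$models, 2)                 # M(M-1) for M = 2
  sc <- predict_cell_scores(m, fe)
  expect_true(all(sc >= 0 & sc <= 1))
  # noiseless labeled data are separable: in-sample ranking is perfect
  truths <- dataset_truth(ds)
  expect_equal(roc_auc(sc, truths)$auc, 1)
  # determinism
  m2 <- train_cbc(fe)
  expect_identical(predict_cell_scores(m2, fe), sc)
})

test_that("single-class cells fall back to a constant predictor", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds, engineered = FALSE)
  keep <- fe$graph_index %in% c(0, 1)        # cell 2 (x2->x1) always 0
  sub <- fe
  sub$X <- fe$X[keep, , drop = FALSE]
  sub$graph_index <- fe$graph_index[keep]
  expect_warning(m <- train_cbc(sub), "single training class")
  sc <- predict_cell_scores(m, sub)
  expect_true(all(sc[, 2] == sc[1, 2]))
  expect_gt(length(unique(sc[, 1])), 1)
})

test_that("MBC posteriors normalize and marginalize into cell scores", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds)
  m <- train_mbc(fe)
  expect_s3_class(m, "trained_mbc")
  post <- predict_class_posteriors(m, fe)
  expect_equal(dim(post), c(64, 4))
  expect_equal(unname(rowSums(post)), rep(1, 64), tolerance = 1e-9)
  sc <- predict_cell_scores(m, fe)
  expect_equal(roc_auc(sc, dataset_truth(ds))$auc, 1)
  # marginal consistency: cell score + mass on entry-0 graphs = 1
  bits <- grangerlearn:::graph_bits(m$classes, 2)
  expect_equal(drop(sc[, 1] + post %*% (1 - bits[, 1])),
               rep(1, 64), tolerance = 1e-9)
  expect_error(train_mbc(subset_one_class(fe)), "two distinct")
})

test_that("degenerate MBC posteriors reproduce the graph entries exactly", {
  # posterior mass 1 on one graph -> cell scores equal that graph's bits;
  # uniform posterior over all graphs -> every cell score is 1/2
  fake <- structure(
    list(a0 = c(0, 0, 0, 0), beta = matrix(0, 3, 4), classes = 0:3,
         standardizer = list(center = rep(0, 3), scale = rep(1, 3)),
         feature_names = c("f1", "f2", "f3"), M = 2,
         config = list(method = "mbc")),
    class = "trained_mbc")
  fe <- structure(list(X = matrix(0, 5, 3, dimnames = list(NULL, c("f1", "f2", "f3"))),
                       graph_index = rep(NA_real_, 5), M = 2, p = 1,
                       mode = "complete", engineered = FALSE),
                  class = "trial_features")
  expect_equal(unname(predict_cell_scores(fake, fe)),
               matrix(0.5, 5, 2))
  fake$a0 <- c(0, 50, 0, 0)                  # graph index 1: cell (1,2) = 1
  sc <- predict_cell_scores(fake, fe)
  expect_equal(unname(sc[1, ]), c(1, 0), tolerance = 1e-12)
})

test_that("thresholding yields monotone graphs and honors the cost threshold", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds)
  m <- train_cbc(fe)
  g50 <- predict_graph(m, fe, threshold = 0.5)
  g75 <- predict_graph(m, fe, threshold = 0.75)
  g100 <- predict_graph(m, fe, threshold = 1)
  for (k in seq_along(g50)) {
    expect_true(all(g75[[k]] <= g50[[k]]))   # raising threshold removes edges
    expect_true(all(diag(g75[[k]]) == 1))
    expect_true(all(g100[[k]][off_diag_cells(2)] == 0 |
                      predict_cell_scores(m, fe)[k, ] == 1))
  }
  expect_error(predict_graph(m, fe, threshold = 2), "threshold")
})

test_that("the ridge logistic cores agree with an independent solver", {
  # the binomial core, the two-class multinomial core and glmnet's
  # coordinate-descent binomial ridge all solve the same objective up to
  # parameterization; their probabilities must match closely
  skip_if_not_installed("glmnet")
  set.seed(51)
  n <- 300
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(n, 1, plogis(X %*% c(1.2, -0.8, 0.5, rep(0, 5))))
  fit <- grangerlearn:::ridge_multinomial(scale(X), cbind(1 - y, y),
                                          lambda = 1 / n)
  lin <- sweep(scale(X) %*% fit$beta, 2, fit$a0, "+")
  p_own <- grangerlearn:::softmax_rows(lin)[, 2]
  g <- glmnet::glmnet(scale(X), y, family = "binomial", alpha = 0,
                      lambda = 1 / n, standardize = FALSE, thresh = 1e-10)
  p_glm <- drop(predict(g, newx = scale(X), type = "response"))
  expect_gt(cor(p_own, p_glm), 0.9999)
  expect_lt(max(abs(p_own - p_glm)), 0.02)
  fb <- grangerlearn:::ridge_binomial(scale(X), y, lambda = 1 / n,
                                      maxit = 1000)
  p_bin <- plogis(drop(scale(X) %*% fb$beta) + fb$a0)
  expect_gt(cor(p_bin, p_glm), 0.9999)
  expect_lt(max(abs(p_bin - p_glm)), 0.02)
})

test_that("models round-trip through the JSON container", {
  ds <- tiny_noiseless()
  fe <- featurize_dataset(ds, engineered = FALSE)
  dir <- withr::local_tempdir()
  mc <- train_cbc(fe)
  write_model(mc, file.path(dir, "cbc.json"))
  mc2 <- read_model(file.path(dir, "cbc.json"))
  expect_equal(predict_cell_scores(mc2, fe), predict_cell_scores(mc, fe),
               tolerance = 1e-12)
  mm <- train_mbc(fe)
  write_model(mm, file.path(dir, "mbc.json"))
  mm2 <- read_model(file.path(dir, "mbc.json"))
  expect_equal(predict_cell_scores(mm2, fe), predict_cell_scores(mm, fe),
               tolerance = 1e-12)
})
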