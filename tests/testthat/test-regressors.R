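# Smaller-than-default epochs keep unit runs quick; the defaults are
# exercised by the linear-target convergence check and the acceptance suite.
fastConfig <- function(...) regressorConfig(epochs = 80, ...)

test_that("a linear target is fit to low training error with defaults", {
  set.seed(1)
  X <- matrix(rnorm(2000 * 5), 2000, 5)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, -1)) + 0.7
  m <- trainRegressor(X, y, regressorConfig(seed = 0))
  expect_lt(m@loss_history[length(m@loss_history)], 0.05)
})

test_that("a constant target is reproduced almost exactly", {
  set.seed(2)
  X <- matrix(rnorm(300), 60, 5)
  m <- trainRegressor(X, rep(2.5, 60), fastConfig(seed = 0))
  expect_lt(max(abs(predict(m, X) - 2.5)), 1e-3)
})

test_that("training is deterministic given seed, config and data", {
  set.seed(3)
  X <- matrix(rnorm(400), 80, 5)
  y <- rnorm(80)
  m1 <- trainRegressor(X, y, fastConfig(seed = 9))
  m2 <- trainRegressor(X, y, fastConfig(seed = 9))
  expect_identical(m1@loss_history, m2@loss_history)
  expect_identical(m1@params, m2@params)
  # minibatch path is seeded too
  m3 <- trainRegressor(X, y, fastConfig(seed = 9, batch_size = 16))
  m4 <- trainRegressor(X, y, fastConfig(seed = 9, batch_size = 16))
  expect_identical(m3@loss_history, m4@loss_history)
})

test_that("attention gating normalizes and gates as defined", {
  d <- 5
  res <- attentionGate(matrix(0, d, d), c(1, 2, 3, 4, 5))
  expect_equal(res$A, rep(1 / d, d))
  expect_equal(res$h_A, c(1, 2, 3, 4, 5) / d)

  res2 <- attentionGate(diag(2), c(log(2), 0))
  expect_equal(res2$A, c(2 / 3, 1 / 3))

  set.seed(5)
  for (i in 1:20) {
    d <- sample(2:50, 1)
    W <- matrix(rnorm(d * d, sd = 2), d, d)
    h <- rnorm(d, sd = 3)
    out <- attentionGate(W, h)
    expect_lt(abs(sum(out$A) - 1), 1e-9)
    expect_equal(out$h_A, out$A * h)
  }
  expect_error(attentionGate(matrix(0, 2, 3), c(1, 2)), "d x d")
})

# A hand-built two-stage model with a zeroed correction net.
zeroCorrectionModel <- function(kcat_m, km_m, d, h = 8, a = 1, b = 1) {
  new("TwoStageRatioModel", kcat_model = kcat_m, km_model = km_m,
      correction = list(Wd = matrix(0, d, h), bd = numeric(h),
                        Wa = matrix(0, h, h), wo = matrix(0, h, 1), bo = 0),
      blend = c(a, b), config = list())
}

test_that("ratio prediction is the exact submodel log-difference when the correction is zero", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6)
  kc <- trainRegressor(X, rnorm(40), fastConfig(seed = 1, hidden_dim = 16))
  km <- trainRegressor(X, rnorm(40), fastConfig(seed = 2, hidden_dim = 16))
  m <- zeroCorrectionModel(kc, km, d = 6)
  expect_identical(ratioPredict(m, X), predict(kc, X) - predict(km, X))

  # a = 0, b = 1 isolates the correction term
  m2 <- zeroCorrectionModel(kc, km, d = 6, a = 0, b = 1)
  m2@correction$bo <- 1.25
  expect_equal(ratioPredict(m2, X), rep(1.25, 40))
})

test_that("two-stage training freezes submodels and does not hurt the raw difference", {
  fams <- simulateFamilies(12, 6, seq_len = 60, within_rate = 0.05, seed = 4)
  sim <- simulateKinetics(fams, substratePool(6), param = "both", seed = 4)
  ent <- sim$records
  ds <- new("KineticDataset", param = "ratio",
            entries = ent[, c("enzyme_id", "sequence", "smiles", "label",
                              "kcat_label", "km_label", "enzyme_type")])
  pp <- syntheticProvider(32, 1, mode = "kmer_composition")
  mp <- syntheticProvider(16, 2, mode = "kmer_composition", k = 2)
  X <- featurizeDataset(ds, pp, mp)
  fa <- randomPartition(entries(ds), k = 3, seed = 0)
  cfg <- regressorConfig(epochs = 120, hidden_dim = 64, seed = 0)
  fit <- trainTwoStage(ds, X, fa, cfg, cfg)

  # freeze contract: stage 2 returned models embed the stage-1 parameters
  # (trainTwoStage asserts identity internally; check the blend learned)
  expect_length(fit$models, 3)
  for (m in fit$models) expect_length(blendWeights(m), 2)

  oof <- fit$oof
  expect_true(all(is.finite(oof$two_stage)))
  rmse_two <- rmse(oof$two_stage, oof$label)
  rmse_raw <- rmse(oof$raw_diff, oof$label)
  expect_lte(rmse_two, rmse_raw + 0.02)
})

test_that("the attention correction recovers a learnable residual", {
  # residual after the submodel difference is a linear function of the
  # features, so the corrected model must beat the raw difference
  set.seed(8)
  n <- 600; d <- 10
  X <- matrix(rnorm(n * d), n, d)
  rownames(X) <- paste0("r", 1:n)
  kcat_y <- as.numeric(X %*% rnorm(d, sd = 0.3))
  km_y <- as.numeric(X %*% rnorm(d, sd = 0.3))
  residual <- as.numeric(X %*% c(rep(1, 3), rep(0, d - 3)))
  ent <- data.frame(enzyme_id = rownames(X), sequence = rownames(X),
                    smiles = paste0("s", 1:n), label = kcat_y - km_y + residual,
                    kcat_label = kcat_y, km_label = km_y,
                    enzyme_type = "wild_type", stringsAsFactors = FALSE)
  ds <- new("KineticDataset", param = "ratio", entries = ent)
  rownames(X) <- paste(ent$sequence, ent$smiles, sep = "\r")
  fa <- randomPartition(ent, k = 2, seed = 1)
  cfg <- regressorConfig(epochs = 150, hidden_dim = 64, seed = 0)
  fit <- trainTwoStage(ds, X, fa, cfg, cfg)
  oof <- fit$oof
  expect_lt(rmse(oof$two_stage, oof$label), rmse(oof$raw_diff, oof$label))
})

test_that("cross-validation predicts every record exactly once, reproducibly", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  rownames(X) <- paste0("k", 1:n)
  y <- setNames(rnorm(n), rownames(X))
  recs <- data.frame(sequence = rownames(X), smiles = "CCO",
                     stringsAsFactors = FALSE)
  fa <- new("FoldAssignment", k = 2L,
            fold_of = setNames(rep(0:1, n / 2), rownames(X)),
            mode = "random", seed = 0L)
  cv <- crossValidate(X, y, fa, fastConfig(seed = 3, hidden_dim = 8))
  expect_true(all(is.finite(cv$oof)))
  expect_identical(names(cv$oof), rownames(X))
  cv2 <- crossValidate(X, y, fa, fastConfig(seed = 3, hidden_dim = 8))
  expect_identical(cv$oof, cv2$oof)
  expect_equal(nrow(cv$fold_metrics), 2)
})

test_that("grid search is exhaustive with deterministic selection", {
  set.seed(12)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  rownames(X) <- paste0("g", 1:n)
  y <- setNames(as.numeric(X %*% c(1, 1, 1)), rownames(X))
  fa <- new("FoldAssignment", k = 2L,
            fold_of = setNames(rep(0:1, n / 2), rownames(X)),
            mode = "random", seed = 0L)
  single <- gridSearch(X, y, fa, list(hidden_dim = 32),
                       base_config = fastConfig(seed = 0))
  expect_equal(single$best_config$hidden_dim, 32L)
  expect_equal(nrow(single$table), 1)

  # a near-zero learning rate is strictly dominated on a learnable target
  two <- gridSearch(X, y, fa, list(learning_rate = c(1e-7, 0.01)),
                    base_config = fastConfig(seed = 0, hidden_dim = 32))
  expect_equal(two$best_config$learning_rate, 0.01)
  expect_equal(nrow(two$table), 2)
})

test_that("ensembling and multi-substrate prediction average arithmetically", {
  set.seed(13)
  X <- matrix(rnorm(20), 4, 5)
  m1 <- trainRegressor(X, rep(1, 4), fastConfig(seed = 1, hidden_dim = 4))
  m2 <- trainRegressor(X, rep(3, 4), fastConfig(seed = 1, hidden_dim = 4))
  expect_equal(ensemblePredict(list(m1, m1), X), predict(m1, X))
  expect_equal(ensemblePredict(list(m1, m2), X),
               (predict(m1, X) + predict(m2, X)) / 2)
  # constant models predict their constants; the ensemble of 1 and 3 gives 2
  expect_equal(unname(ensemblePredict(list(m1, m2), X[1, ])), 2,
               tolerance = 1e-6)
  # one substrate row: averaging over rows is the single-row prediction
  expect_equal(ensemblePredict(m1, X[2, , drop = FALSE], average_rows = TRUE),
               unname(predict(m1, X[2, , drop = FALSE])[1]))
  expect_error(ensemblePredict(list(), X), "empty model list")
})

test_that("the extra-trees backend honors the same contract and fits steps", {
  set.seed(14)
  n <- 300
  X <- matrix(runif(n), n, 1)
  rownames(X) <- paste0("t", 1:n)
  y <- ifelse(X[, 1] > 0.5, 2, -2)   # step function
  t1 <- trainTreeEnsemble(X, y, regressorConfig(seed = 0, num_trees = 100))
  t2 <- trainTreeEnsemble(X, y, regressorConfig(seed = 0, num_trees = 100))
  expect_identical(predict(t1, X), predict(t2, X))
  tree_rmse <- rmse(predict(t1, X), y)
  linear_rmse <- rmse(predict(lm(y ~ X[, 1])), y)
  expect_lt(tree_rmse, linear_rmse)
  expect_length(predict(t1, X[1:3, , drop = FALSE]), 3)
})
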