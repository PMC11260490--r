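test_that("one-hot encoding follows the padding and N rules", {
  m <- encode_onehot("ACGT", 6L)
  expect_equal(dim(m), c(4L, 6L))
  expect_equal(m[, 1:4], diag(4), ignore_attr = TRUE)
  expect_true(all(m[, 5:6] == 0))                 # right padding
  expect_true(all(colSums(m[, 1:4]) == 1))        # one 1 per position
  expect_true(all(encode_onehot("NNN", 3L) == 0)) # N -> all-zero
  expect_error(encode_onehot("ACGTA", 4L), "exceeds")
  expect_error(encode_onehot("ACGX", 4L), "invalid nucleotide")
})

test_that("a +/-2 kb promoter encodes to exactly 4000 positions", {
  genes <- mk_genes(10000, chrom_len = 1e5)
  expect_equal(width(genes$promoter), 4000L)
  seq4k <- paste(rep("ACGT", 1000), collapse = "")
  v <- encode_features(seq4k, "ACGT", distance = 123,
                       L_p = 4000L, L_t = 10L)
  expect_length(v, 4 * 4000 + 4 * 10 + 1)
  expect_equal(unname(v[["distance"]]), 123)
  expect_equal(sum(v[1:16000]), 4000)            # one hot bit per position
})

test_that("train/test split is 80/20, disjoint, exhaustive, seeded", {
  rec <- data.frame(id = 1:100, x = rnorm(100))
  sp1 <- split_dataset(rec, seed = 5)
  sp2 <- split_dataset(rec, seed = 5)
  expect_equal(nrow(sp1$train), 80L)
  expect_equal(nrow(sp1$test), 20L)
  expect_identical(sp1$train_idx, sp2$train_idx)
  expect_length(intersect(sp1$train_idx, sp1$test_idx), 0L)
  expect_setequal(c(sp1$train_idx, sp1$test_idx), 1:100)
  expect_error(split_dataset(rec[1:5, ], seed = 1), "at least 10")
})

test_that("pooled training set respects the per-stage resampling rule", {
  stage_df <- function(n) data.frame(v = seq_len(n))
  sp <- list(s1 = stage_df(40), s2 = stage_df(40), s3 = stage_df(40))
  pooled <- build_pooled_training_set(list(spA = sp), 300L, seed = 2)
  expect_equal(nrow(pooled), 300L)
  # 300 / 3 = 100 per stage, no remainder
  expect_equal(as.vector(table(pooled$stage)), rep(100L, 3))
  # non-divisible: remainder goes to the first stage
  sp7 <- stats::setNames(replicate(7, stage_df(20), simplify = FALSE),
                         paste0("t", 1:7))
  pooled7 <- build_pooled_training_set(list(spB = sp7), 300L, seed = 3)
  counts <- table(factor(pooled7$stage, levels = paste0("t", 1:7)))
  expect_equal(as.vector(counts), c(42L + 6L, rep(42L, 6)))
  expect_equal(nrow(pooled7), 300L)
  # single species, single stage: plain with-replacement draw
  p1 <- build_pooled_training_set(list(spC = list(only = stage_df(5))),
                                  50L, seed = 4)
  expect_equal(nrow(p1), 50L)
  expect_error(build_pooled_training_set(list(), 10L), "no species")
})

test_that("the registry lists eleven methods and rejects unknowns", {
  reg <- ml_method_registry()
  expect_equal(nrow(reg), 11L)
  expect_error(model_spec("gradient_unicorn"), "unknown method")
  expect_error(
    train_regressor(model_spec("cnn"), matrix(rnorm(20), 10), rnorm(10)),
    "no offline backend")
})

test_that("constant targets are fit exactly by the tree engine", {
  X <- matrix(rnorm(200), 50, 4)
  m <- train_regressor(model_spec("gbdt", list(iterations = 5), seed = 1),
                       X, rep(2.5, 50))
  expect_equal(predict(m, X), rep(2.5, 50))
  expect_warning(ev <- evaluate_regressor(m, X, rep(2.5, 50)), "constant")
  expect_equal(ev$rmse, 0)
})

test_that("boosted trees recover a pure distance signal", {
  withr::local_seed(83)
  n <- 800
  X <- cbind(matrix(rbinom(n * 12, 1, 0.5), n, 12), runif(n, 0, 5e4))
  colnames(X) <- c(sprintf("seq_%02d", 1:12), "distance")
  y <- exp(-X[, 13] / 15000)
  sp <- split_dataset(as.data.frame(X), seed = 1)
  spec <- model_spec("gb_trees",
                     list(iterations = 150, depth = 4, subsample = 1,
                          colsample = 1), seed = 9)
  m <- train_regressor(spec, X[sp$train_idx, ], y[sp$train_idx])
  ev <- evaluate_regressor(m, X[sp$test_idx, ], y[sp$test_idx])
  expect_gt(ev$r_squared, 0.9)
  # determinism under seed
  m2 <- train_regressor(spec, X[sp$train_idx, ], y[sp$train_idx])
  expect_identical(predict(m, X[sp$test_idx, ]),
                   predict(m2, X[sp$test_idx, ]))
})

test_that("all supported methods train and predict finitely", {
  withr::local_seed(89)
  n <- 120
  X <- cbind(matrix(rbinom(n * 6, 1, 0.5), n, 6), runif(n))
  colnames(X) <- c(sprintf("b%d", 1:6), "distance")
  y <- 0.5 * X[, 7] + 0.1 * X[, 1] + rnorm(n, 0, 0.05)
  small <- list(iterations = 20L, n_trees = 20L, epochs = 50L)
  for (method in c("gb_trees", "gbdt", "xgb", "lgbm", "dtree", "rforest",
                   "adaboost", "knn", "mlp", "svr")) {
    hp <- small[intersect(names(small),
                          names(model_spec(method)$hyperparams))]
    m <- train_regressor(model_spec(method, hp, seed = 2), X, y)
    p <- predict(m, X)
    expect_length(p, n)
    expect_true(all(is.finite(p)), info = method)
    # every method must beat predicting far off the target scale
    expect_lt(evaluate_regressor(m, X, y)$rmse, stats::sd(y) * 2,
              label = method)
  }
})

test_that("evaluation metrics match their definitions", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_regressor(y, NULL, y)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$spearman_R, 1)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  shifted <- evaluate_regressor(y + 1, NULL, y)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$mae, 1)
  expect_equal(shifted$rmse, 1)
  expect_equal(shifted$r_squared, 1 - 5 / sum((y - 3)^2))
  withr::local_seed(97)
  rnd <- evaluate_regressor(rnorm(1000), NULL, rnorm(1000))
  expect_lt(abs(rnd$pearson_r), 0.1)
})

test_that("5-fold cross-validation returns one score row per fold", {
  withr::local_seed(101)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- X[, 1] + rnorm(50, 0, 0.1)
  cv <- cross_validate(model_spec("dtree", seed = 3), X, y, k = 5)
  expect_equal(nrow(cv), 5L)
  expect_equal(cv$fold, 1:5)
  expect_true(all(is.finite(cv$rmse)))
})

test_that("TreeSHAP satisfies local accuracy on every tree method", {
  withr::local_seed(103)
  n <- 150
  X <- cbind(matrix(rbinom(n * 8, 1, 0.5), n, 8), runif(n))
  colnames(X) <- c(sprintf("b%d", 1:8), "distance")
  y <- X[, 9] + 0.3 * X[, 2] + rnorm(n, 0, 0.05)
  for (method in c("gbdt", "dtree", "rforest", "adaboost")) {
    hp <- if (method == "rforest") list(n_trees = 15L) else
      list(iterations = 15L)
    hp <- hp[intersect(names(hp), names(model_spec(method)$hyperparams))]
    m <- train_regressor(model_spec(method, hp, seed = 5), X, y)
    att <- attribute_shap(m, X[1:30, ])
    expect_lt(max(abs(att$prediction - predict(m, X[1:30, ]))), 1e-6,
              label = method)
  }
  # non-tree models refuse attribution
  mk <- train_regressor(model_spec("knn"), X, y)
  expect_error(attribute_shap(mk, X), "tree-ensemble")
})

test_that("TreeSHAP equals the exponential-time Shapley oracle", {
  withr::local_seed(107)
  n <- 200
  X <- cbind(matrix(rbinom(n * 5, 1, 0.5), n, 5), runif(n))
  colnames(X) <- c(sprintf("b%d", 1:5), "distance")
  y <- X[, 6] + X[, 1] * 0.5 - X[, 3] * 0.2 + rnorm(n, 0, 0.02)
  m <- train_regressor(model_spec("dtree", list(depth = 4), seed = 7), X, y)
  tree <- m$fit$trees[[1L]]
  att <- attribute_shap(m, X[1:10, ])
  for (i in 1:10) {
    expect_equal(unname(att$phi[i, ]), bf_shapley(tree, X[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("a depth-1 distance stump gives distance all the attribution", {
  withr::local_seed(109)
  X <- cbind(b1 = rbinom(100, 1, 0.5), distance = runif(100))
  y <- as.numeric(X[, 2] > 0.5)
  m <- train_regressor(model_spec("dtree", list(depth = 1)), X, y)
  expect_equal(m$fit$trees[[1L]]$feature[1L], 1L)   # split on distance
  att <- attribute_shap(m, X)
  expect_equal(unname(att$importance[["b1"]]), 0)
  expect_gt(att$importance[["distance"]], 0)
  # closed form for a stump: phi = v_leaf - cover-weighted leaf mean;
  # the base adds the boosting offset (mean of y) the tree was fit on
  tr <- m$fit$trees[[1L]]
  ev <- (tr$cover[2] * tr$value[2] + tr$cover[3] * tr$value[3]) /
    tr$cover[1]
  leaf <- ifelse(X[, 2] <= tr$threshold[1], tr$value[2], tr$value[3])
  expect_equal(unname(att$phi[, 2]), leaf - ev)
  expect_equal(att$base, mean(y) + ev)
})

test_that("permutation importance flags the informative feature", {
  withr::local_seed(113)
  n <- 300
  X <- cbind(constant = rep(1, n), noise = rnorm(n), signal = runif(n))
  y <- 2 * X[, "signal"]
  m <- train_regressor(model_spec("gbdt", list(iterations = 50, depth = 3),
                                  seed = 1), X, y)
  imp <- importance_by_permutation(m, X, y, n_repeats = 3, seed = 5)
  expect_equal(names(imp)[1L], "signal")
  expect_equal(unname(imp[["constant"]]), 0)
  imp2 <- importance_by_permutation(m, X, y, n_repeats = 3, seed = 5)
  expect_identical(imp, imp2)
  expect_error(importance_by_permutation(m, X, y, n_repeats = 0), ">= 1")
})
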