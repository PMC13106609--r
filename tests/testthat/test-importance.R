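test_that("a planted perfect predictor is ranked first and a constant scores zero", {
  set.seed(1)
  n <- 60
  x <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n),
                  flat = rep(1, n))
  y <- x$signal
  imp <- hl_importance(x, y, n_trees = 150, seed = 2)
  expect_equal(imp$importance$predictor[1], "signal")
  expect_gt(imp$importance$inc_mse_percent[1], 20)
  expect_equal(imp$importance$inc_mse_percent[imp$importance$predictor == "flat"], 0)
})

test_that("importance is deterministic given the seed", {
  set.seed(2)
  x <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- x$a + rnorm(30, sd = 0.5)
  i1 <- hl_importance(x, y, n_trees = 80, seed = 7)
  i2 <- hl_importance(x, y, n_trees = 80, seed = 7)
  expect_identical(i1$importance, i2$importance)
})

test_that("with a response independent of every predictor, importance straddles zero", {
  set.seed(3)
  n <- 50
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  imps <- vapply(1:12, function(s) {
    set.seed(700 + s)
    y <- rnorm(n)    # independent of all predictors
    res <- hl_importance(x, y, n_trees = 100, seed = 100 + s)
    res$importance$inc_mse_percent[res$importance$predictor == "a"]
  }, numeric(1))
  # sign test: a useless predictor's OOB importance is centred near zero
  expect_gt(sum(imps <= 0), 0)
  expect_gt(sum(imps >= 0), 0)
  expect_lt(abs(mean(imps)), 5)
})

test_that("ranking is invariant to affine rescaling of a predictor", {
  set.seed(4)
  n <- 50
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * x$a + x$b + rnorm(n, sd = 0.4)
  r1 <- hl_importance(x, y, n_trees = 120, seed = 9)
  x2 <- transform(x, a = 1000 * a + 5)
  r2 <- hl_importance(x2, y, n_trees = 120, seed = 9)
  expect_equal(r1$importance$predictor, r2$importance$predictor)
  expect_equal(r1$importance$inc_mse_percent, r2$importance$inc_mse_percent,
               tolerance = 1e-8)
})

test_that("response-permutation significance hits the floor for strong signal", {
  set.seed(5)
  n <- 40
  x <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- x$signal + rnorm(n, sd = 0.1)
  imp <- hl_importance(x, y, n_trees = 60, seed = 11, n_null = 99)
  p_sig <- imp$importance$p[imp$importance$predictor == "signal"]
  expect_equal(p_sig, 0.01)   # (1 + 0) / (99 + 1): minimum achievable
  expect_equal(imp$importance$stars[imp$importance$predictor == "signal"], "**")
  # noise predictors never reach the permutation floor
  expect_true(all(imp$importance$p[imp$importance$predictor != "signal"] > 0.01))
})

test_that("null p-values for noise predictors are not systematically small", {
  set.seed(6)
  n <- 30
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  ps <- vapply(1:10, function(s) {
    set.seed(50 + s)
    y <- rnorm(n)   # response independent of every predictor
    imp <- hl_importance(x, y, n_trees = 40, seed = 500 + s, n_null = 19)
    imp$importance$p[imp$importance$predictor == "a"]
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.9)
})

test_that("ranking agrees with randomForest's own importance on clear signal", {
  set.seed(8)
  n <- 60
  x <- data.frame(strong = rnorm(n), weak = rnorm(n), noise = rnorm(n))
  y <- 2 * x$strong + 0.5 * x$weak + rnorm(n, sd = 0.3)
  ours <- hl_importance(x, y, n_trees = 200, seed = 15)
  set.seed(15)
  rf <- randomForest::randomForest(x = x, y = y, ntree = 200,
                                   importance = TRUE)
  ref_rank <- rownames(rf$importance)[order(-rf$importance[, "%IncMSE"])]
  expect_equal(ours$importance$predictor, ref_rank)
})

test_that("degenerate inputs are rejected", {
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_error(hl_importance(x, rep(1, 20), seed = 1), "constant response")
  expect_error(hl_importance(x["a"], rnorm(20), seed = 1), ">= 2 predictors")
  expect_error(hl_importance(x, rnorm(20), seed = 1, n_null = 5), "n_null")
  expect_error(hl_importance(x[1:5, ], rnorm(5), seed = 1), ">= 10 observations")
})

test_that("generator-coupled structural traits top the biomass importance ranking", {
  co <- simulate_cohort(cohort_params(n_genotypes = 40), seed = 19)
  X <- trait_mean_matrix(co, "pooled")
  feats <- as.data.frame(X[, setdiff(colnames(X), c("afw", "adw"))])
  imp <- hl_importance(feats, X[, "afw"], n_trees = 200, seed = 21)
  top3 <- imp$importance$predictor[1:3]
  expect_true(any(c("stem_diameter", "spad") %in% top3))
})
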