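test_that("entropy weights match hand-evaluated arithmetic", {
  # frozen from the step-by-step min-max/entropy formula on [[1,2],[2,2],[3,6]]
  X <- matrix(c(1, 2, 3, 2, 2, 6), 3, 2, dimnames = list(NULL, c("c1", "c2")))
  w <- entropy_weights(X)
  expect_equal(unname(w$entropy), c(0.5793801643, 0), tolerance = 1e-9)
  expect_equal(unname(w$weights), c(0.2960819110, 0.7039180890), tolerance = 1e-9)
  expect_equal(unname(w$weights), oracle_entropy(X), tolerance = 1e-12)

  # perfect anti-symmetric 2x2: equal split
  w2 <- entropy_weights(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(unname(w2$entropy), c(0, 0))
  expect_equal(unname(w2$weights), c(0.5, 0.5))
})

test_that("entropy weights sum to 1, zero out constant criteria, and match the oracle on random matrices", {
  set.seed(42)
  for (i in 1:20) {
    X <- matrix(runif(5 * 3, 0.2, 2), 5, 3)
    dirs <- sample(c("benefit", "cost"), 3, replace = TRUE)
    w <- entropy_weights(X, dirs)
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_true(all(w$weights >= 0))
    expect_true(all(w$entropy >= 0 & w$entropy <= 1 + 1e-12))
    expect_equal(unname(w$weights), oracle_entropy(X, dirs), tolerance = 1e-10)
  }
  Xc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(wc <- entropy_weights(Xc), "constant criterion")
  expect_equal(unname(wc$weights), c(1, 0))
  expect_error(entropy_weights(matrix(1, 3, 2)), "degenerate")
})

test_that("TOPSIS closeness matches the spreadsheet oracle and its bounds", {
  X <- matrix(c(1, 2, 3, 4, 3, 1), 3, 2)
  res <- topsis_ci(X, weights = c(0.5, 0.5))
  expect_equal(res$scores$ci,
               c(0.5239679923, 0.5887789464, 0.4760320077), tolerance = 1e-9)
  expect_equal(res$scores$ci, oracle_topsis(X, c(0.5, 0.5)), tolerance = 1e-12)

  # dominating alternative on a single-criterion-style problem
  two <- topsis_ci(matrix(c(2, 1, 5, 5), 2, 2), weights = c(1, 0))
  expect_equal(two$scores$ci, c(1, 0))
  expect_equal(two$scores$rank, c(1L, 2L))

  # alternative equal to the positive ideal has CI 1 and rank 1
  X3 <- matrix(c(5, 1, 2, 9, 3, 4), 3, 2)
  r3 <- topsis_ci(X3, weights = c(0.4, 0.6))
  expect_equal(r3$scores$ci[1], 1)
  expect_equal(r3$scores$rank[1], 1L)
  expect_true(all(r3$scores$ci >= 0 & r3$scores$ci <= 1))
})

test_that("CI is scale-invariant and monotone in single-criterion improvement", {
  set.seed(7)
  X <- matrix(runif(6 * 4, 0.5, 1.5), 6, 4)
  w <- rep(0.25, 4)
  base <- topsis_ci(X, w)$scores$ci
  # multiplying a column by a positive constant is absorbed by normalisation
  X2 <- X; X2[, 2] <- X2[, 2] * 137
  expect_equal(topsis_ci(X2, w)$scores$ci, base, tolerance = 1e-12)
  # improving alternative 3 on a benefit criterion never lowers its CI
  for (delta in c(0.05, 0.3, 1)) {
    X3 <- X; X3[3, 1] <- X3[3, 1] + delta
    expect_gte(topsis_ci(X3, w)$scores$ci[3], base[3] - 1e-12)
  }
  # every dominating 2-alternative pair wins
  for (i in 1:10) {
    a <- runif(3, 0.5, 1); b <- a + runif(3, 0.01, 0.5)
    ci <- topsis_ci(rbind(b, a), weights = rep(1 / 3, 3))$scores$ci
    expect_gt(ci[1], ci[2])
  }
})

test_that("competition ranking shares the minimum rank on ties", {
  expect_equal(rank_alternatives(c(0.9, 0.5, 0.5, 0.1)), c(1L, 2L, 2L, 4L))
  ci <- c(0.3, 0.9, 0.6)
  expect_equal(rank_alternatives(ci), c(3L, 1L, 2L))
})

test_that("cost criteria reverse the ideal and the evaluation respects directions", {
  X <- matrix(c(1, 2, 3, 4, 3, 1), 3, 2)
  ben <- topsis_ci(X, weights = c(0.5, 0.5))$scores$ci
  cst <- topsis_ci(X, weights = c(0.5, 0.5), directions = c("cost", "cost"))$scores$ci
  expect_equal(order(ben), rev(order(cst)))
  expect_equal(cst, oracle_topsis(X, c(0.5, 0.5), c("cost", "cost")),
               tolerance = 1e-12)
})

test_that("the screen recovers the generator's latent tolerance gradient", {
  p_weak <- cohort_params(tolerance_effect = 0.05)
  p_strong <- cohort_params(tolerance_effect = 0.25)
  rc <- function(p, seed) {
    co <- simulate_cohort(p, seed = seed)
    ev <- hl_eval(co, directions = c(proline = "cost",
                                     setNames(rep("benefit", 8),
                                              setdiff(hl_traits(), "proline"))))
    tol <- attr(co, "latent_tolerance")
    cor(coef(ev)[names(tol)], tol, method = "spearman")
  }
  weak <- rc(p_weak, 31)
  strong <- rc(p_strong, 31)
  expect_gt(weak, 0)
  expect_gt(strong, weak)
  expect_gt(strong, 0.8)
})

test_that("a dominant latent-tolerance genotype ranks first", {
  p <- cohort_params(n_genotypes = 24, tolerance_effect = 0.4,
                     residual_cv = 0.02)
  co <- simulate_cohort(p, seed = 13)
  tol <- attr(co, "latent_tolerance")
  ev <- hl_eval(co, directions = c(proline = "cost",
                                   setNames(rep("benefit", 8),
                                            setdiff(hl_traits(), "proline"))))
  expect_equal(ev$table$genotype[ev$table$rank == 1L],
               names(which.max(tol)))
})
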