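test_that("DAG parsing validates structure and finds the terminal response", {
  dag <- path_dag(c("# comment", "A -> B", "B -> C"))
  expect_equal(dag$response, "C")
  expect_equal(dag$exogenous, "A")
  expect_error(path_dag(c("A -> B", "B -> A")), "cycle")
  expect_error(path_dag(c("A -> B", "A -> C")), "ambiguous")
  dag2 <- path_dag(c("A -> B", "A -> C"), response = "C")
  expect_equal(dag2$response, "C")

  d <- default_dag()
  expect_equal(sort(d$exogenous), c("G", "LI", "LIxG"))
  expect_equal(d$response, "AFW")
  expect_equal(nrow(d$edges), 22L)
})

test_that("basis set matches textbook cases", {
  chain <- path_dag(c("X -> M", "M -> Y"))
  bs <- basis_set(chain)
  expect_length(bs, 1L)
  expect_setequal(c(bs[[1]]$x, bs[[1]]$y), c("X", "Y"))
  expect_equal(bs[[1]]$conditioning, "M")

  full <- path_dag(c("A -> B", "A -> C", "B -> C"))
  expect_length(basis_set(full), 0L)

  # two exogenous variables are never claimed independent of each other
  vee <- path_dag(c("A -> C", "B -> C"))
  expect_length(basis_set(vee), 0L)
})

test_that("basis set equals the brute-force oracle on random small DAGs", {
  set.seed(8)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    nodes <- LETTERS[1:k]
    adj <- matrix(0L, k, k, dimnames = list(nodes, nodes))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      adj[i, j] <- rbinom(1, 1, 0.45)   # upper-triangular => acyclic
    }
    # an edge list cannot represent isolated nodes; restrict to used ones
    used <- rowSums(adj) + colSums(adj) > 0
    if (sum(used) < 2) next
    adj <- adj[used, used, drop = FALSE]
    nodes <- rownames(adj)
    edges <- which(adj == 1, arr.ind = TRUE)
    dag <- path_dag(data.frame(parent = nodes[edges[, 1]],
                               child = nodes[edges[, 2]]),
                    response = nodes[max(edges[, 2])])
    expect_equal(claims_to_strings(basis_set(dag)), oracle_basis_strings(adj))
  }
})

test_that("Fisher's C follows the closed form and the published anchor", {
  expect_equal(fishers_c(1), list(C = 0, df = 2L, p = 1))
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, exp(-fc$C / 2) * (1 + fc$C / 2), tolerance = 1e-12)
  expect_equal(fc$p, 0.5966, tolerance = 1e-4)
  # empty basis set: saturated model
  expect_equal(fishers_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  expect_error(fishers_c(c(0.5, 0)), "out of")
})

test_that("single-edge and single-parent fits recover exact closed forms", {
  set.seed(9)
  x <- rnorm(40)
  d_exact <- data.frame(X = x, Y = x)
  # lm warns about the perfect fit; the exact coefficient is the point
  fit <- suppressWarnings(hl_psem(path_dag("X -> Y"), d_exact))
  expect_equal(unname(coef(fit)["X -> Y"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$r2["Y"]), 1, tolerance = 1e-12)

  y <- 0.6 * x + rnorm(40, sd = 0.8)
  fit2 <- hl_psem(path_dag("X -> Y"), data.frame(X = x, Y = y))
  expect_equal(unname(coef(fit2)["X -> Y"]), cor(x, y), tolerance = 1e-12)
})

test_that("standardized coefficients are recovered from data simulated off a known DAG", {
  set.seed(12)
  truth <- c("X1 -> M" = 0.5, "X2 -> M" = 0.3, "M -> Y" = 0.5, "X1 -> Y" = 0.3)
  reps <- t(vapply(1:20, function(i) {
    d <- simulate_dag_data(500, a = 0.5, b = 0.3, c = 0.5, d = 0.3)
    coef(hl_psem(recovery_dag(), d))[names(truth)]
  }, truth))
  # consistency: mean recovered coefficients within +/-0.05 of truth, and
  # every single n=500 fit within ordinary sampling error of it
  expect_true(all(abs(colMeans(reps) - truth) < 0.05))
  expect_true(all(abs(t(reps) - truth) < 0.15))
})

test_that("model p-values are approximately uniform under the true DAG", {
  set.seed(14)
  ps <- vapply(1:500, function(i) {
    d <- simulate_dag_data(200)
    hl_psem(recovery_dag(), d)$p_model
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.10)   # type-I control of the d-sep test
})

test_that("effects decompose exactly along enumerated paths", {
  # chain LI -> SD -> AFW: total = product, direct = 0
  set.seed(15)
  li <- rnorm(300)
  sd_ <- 0.7 * li + rnorm(300, sd = sqrt(1 - 0.49))
  afw <- 0.6 * sd_ + rnorm(300, sd = 0.5)
  fit <- hl_psem(path_dag(c("LI -> SD", "SD -> AFW")),
                 data.frame(LI = li, SD = sd_, AFW = afw))
  eff <- path_effects(fit)
  cf <- coef(fit)
  li_row <- eff[eff$node == "LI", ]
  expect_equal(li_row$direct, 0)
  expect_equal(li_row$total, unname(cf["LI -> SD"] * cf["SD -> AFW"]),
               tolerance = 1e-12)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-10)

  # brute-force path enumeration oracle on a denser DAG
  d <- simulate_dag_data(400)
  fit2 <- hl_psem(recovery_dag(), d)
  cf2 <- coef(fit2)
  eff2 <- path_effects(fit2)
  # X1 -> Y paths: direct, and X1 -> M -> Y
  expect_equal(eff2$total[eff2$node == "X1"],
               unname(cf2["X1 -> Y"] + cf2["X1 -> M"] * cf2["M -> Y"]),
               tolerance = 1e-12)
  expect_equal(eff2$total[eff2$node == "X2"],
               unname(cf2["X2 -> M"] * cf2["M -> Y"]), tolerance = 1e-12)
})

test_that("the cohort-level path model fits end to end with the default diagram", {
  co <- simulate_cohort(cohort_params(), seed = 25)
  st <- sem_table(co)
  expect_equal(nrow(st), 96L)
  expect_equal(colnames(st), c("LI", "G", "LIxG", "FPC", "PH", "LT", "SPAD", "SD", "AFW"))
  fit <- hl_psem(default_dag(), st)
  expect_equal(fit$df, 2L * length(basis_set(default_dag())))
  expect_true(all(abs(fit$coefficients$beta) < 1.5))
  eff <- path_effects(fit)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-10)
  # stress lowers biomass; the light-intensity total effect must be negative
  expect_lt(eff$total[eff$node == "LI"], 0)
})

test_that("missing columns and degenerate data are diagnosed", {
  expect_error(hl_psem(path_dag("X -> Y"), data.frame(X = rnorm(10))),
               "lacks DAG node")
  expect_error(hl_psem(path_dag("X -> Y"),
                       data.frame(X = rep(1, 10), Y = rnorm(10))),
               "non-finite|constant")
})
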