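# Builders and independent oracles shared across test files.

# Small long-format trait table: one value per (genotype, treatment,
# replicate) for a subset of traits.
make_tt <- function(genotypes, traits = c("plant_height", "proline"),
                    n_rep = 2, value_fun = function(g, trt, tr, r) 10 + r) {
  grid <- expand.grid(genotype = genotypes, treatment = c("control", "stress"),
                      replicate = seq_len(n_rep), trait = traits,
                      stringsAsFactors = FALSE)
  grid$value <- mapply(value_fun, grid$genotype, grid$treatment,
                       grid$trait, grid$replicate)
  trait_table(grid)
}

# Step-by-step entropy-weight arithmetic, written independently of the
# package implementation (explicit loops, no shared helpers).
oracle_entropy <- function(X, directions = rep("benefit", ncol(X))) {
  n <- nrow(X)
  e <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    lo <- min(X[, j]); hi <- max(X[, j])
    xp <- if (directions[j] == "benefit") (X[, j] - lo) / (hi - lo)
          else (hi - X[, j]) / (hi - lo)
    p <- xp / sum(xp)
    s <- 0
    for (i in seq_len(n)) if (p[i] > 0) s <- s + p[i] * log(p[i])
    e[j] <- -s / log(n)
  }
  (1 - e) / sum(1 - e)
}

# Spreadsheet-style TOPSIS arithmetic.
oracle_topsis <- function(X, w, directions = rep("benefit", ncol(X))) {
  v <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    v[, j] <- w[j] * X[, j] / sqrt(sum(X[, j]^2))
  }
  ci <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    dp <- dm <- 0
    for (j in seq_len(ncol(X))) {
      best <- if (directions[j] == "benefit") max(v[, j]) else min(v[, j])
      worst <- if (directions[j] == "benefit") min(v[, j]) else max(v[, j])
      dp <- dp + (v[i, j] - best)^2
      dm <- dm + (v[i, j] - worst)^2
    }
    ci[i] <- sqrt(dm) / (sqrt(dp) + sqrt(dm))
  }
  ci
}

# Brute-force d-separation basis set from an adjacency matrix: every
# non-adjacent unordered pair, conditioned on the union of parents, pairs of
# two parentless nodes excluded. Returns sorted "x|y|cond" strings.
oracle_basis_strings <- function(adj) {
  nodes <- rownames(adj)
  out <- character(0)
  for (a in nodes) for (b in nodes) {
    if (a >= b) next
    if (adj[a, b] == 1 || adj[b, a] == 1) next
    pa_a <- nodes[adj[, a] == 1]
    pa_b <- nodes[adj[, b] == 1]
    if (length(pa_a) == 0 && length(pa_b) == 0) next
    cond <- sort(setdiff(union(pa_a, pa_b), c(a, b)))
    out <- c(out, paste(sort(c(a, b))[1], sort(c(a, b))[2],
                        paste(cond, collapse = ","), sep = "|"))
  }
  sort(out)
}

claims_to_strings <- function(claims) {
  sort(vapply(claims, function(cl) {
    ab <- sort(c(cl$x, cl$y))
    paste(ab[1], ab[2], paste(sort(cl$conditioning), collapse = ","), sep = "|")
  }, character(1)))
}

# Data simulated exactly from a small standardized DAG:
# X1, X2 exogenous N(0,1); M = a*X1 + b*X2 + e; Y = c*M + d*X1 + e,
# error variances chosen so every variable has unit variance.
simulate_dag_data <- function(n, a = 0.5, b = 0.3, c = 0.5, d = 0.3) {
  X1 <- rnorm(n); X2 <- rnorm(n)
  M <- a * X1 + b * X2 + rnorm(n, sd = sqrt(1 - a^2 - b^2))
  vy <- c^2 + d^2 + 2 * c * d * a   # var of c*M + d*X1
  Y <- c * M + d * X1 + rnorm(n, sd = sqrt(max(1 - vy, 0.05)))
  data.frame(X1 = X1, X2 = X2, M = M, Y = Y)
}

recovery_dag <- function() {
  path_dag(c("X1 -> M", "X2 -> M", "M -> Y", "X1 -> Y"))
}
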