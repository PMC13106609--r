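#' Pearson correlation matrix across traits
#'
#' Correlations over genotype-level means. By default the control and stress
#' tables are pooled (one row per genotype x treatment), which captures both
#' inter-genotype and stress-induced co-variation; per-treatment modes
#' restrict to one light level. Two-sided p-values come from the
#' t-distribution transform of r.
#'
#' @param means a `genotype_means` table from [aggregate_replicates()] or a
#'   [trait_table()].
#' @param mode `"pooled"` (default), `"control"` or `"stress"`.
#' @return List with `r` (trait x trait correlations, unit diagonal), `p`
#'   (two-sided p-values, NA on the diagonal) and `n` (rows used).
#' @export
pearson_matrix <- function(means, mode = c("pooled", "control", "stress")) {
  mode <- match.arg(mode)
  X <- trait_mean_matrix(means, mode)
  if (nrow(X) < 3L) stop("need >= 3 genotypes for correlations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s) reported as NA: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X))
  n <- nrow(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Genotype x trait matrix of replicate means
#'
#' @param means `genotype_means` or [trait_table()].
#' @param mode `"pooled"` stacks control and stress rows (rownames
#'   `genotype.treatment`); otherwise one treatment's rows.
#' @return Numeric matrix, rows = genotypes (x treatment if pooled),
#'   columns = traits.
#' @export
trait_mean_matrix <- function(means, mode = c("pooled", "control", "stress")) {
  mode <- match.arg(mode)
  if (inherits(means, "trait_table")) means <- aggregate_replicates(means)
  keep <- if (mode == "pooled") means else means[means$treatment == mode, ]
  traits <- intersect(hl_traits(), unique(keep$trait))
  key <- if (mode == "pooled") paste(keep$genotype, keep$treatment, sep = ".")
         else keep$genotype
  rows <- sort(unique(key))
  M <- matrix(NA_real_, length(rows), length(traits),
              dimnames = list(rows, traits))
  M[cbind(match(key, rows), match(keep$trait, traits))] <- keep$mean
  if (anyNA(M)) stop("incomplete genotype x trait mean matrix")
  M
}

#' Euclidean distance between genotypes on standardized traits
#'
#' Columns are z-standardized so traits with different units contribute
#' comparably; for a single trait this reduces to |difference| of z-scores.
#'
#' @param X numeric matrix (rows = genotypes) or vector.
#' @return A `dist` object.
#' @export
trait_dist <- function(X) {
  X <- as.matrix(X)
  Z <- scale(X)
  if (any(!is.finite(Z))) stop("zero-variance column: distance undefined after standardization")
  stats::dist(Z)
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle entries;
#' the null is generated by simultaneous row/column permutation of the second
#' matrix. The one-sided (greater) p-value is
#' `(1 + #[r_perm >= r_obs]) / (n_perm + 1)`, never below `1/(n_perm + 1)`.
#' With `exact = TRUE` all n! relabelings are enumerated and the p-value is
#' the exact fraction of permutations (identity included) attaining
#' `r_perm >= r_obs`.
#'
#' @param D1,D2 `dist` objects or square symmetric matrices of equal size
#'   (n >= 4).
#' @param n_perm number of random permutations (default 9999; ignored when
#'   `exact`).
#' @param seed integer seed for the permutation stream (required unless
#'   `exact`).
#' @param exact enumerate all permutations (only sensible for n <= 8).
#' @return Object of class `mantel_result`: `r`, `p`, `n_perm`, `exact`,
#'   `strength` (see [classify_mantel_strength()]).
#' @export
mantel_test <- function(D1, D2, n_perm = 9999L, seed = NULL, exact = FALSE) {
  M1 <- as.matrix(D1)
  M2 <- as.matrix(D2)
  n <- nrow(M1)
  if (!all(dim(M1) == dim(M2))) stop("distance matrices must have equal size")
  if (n < 4L) stop("Mantel test needs n >= 4 objects")
  low <- lower.tri(M1)
  v1 <- M1[low]
  if (stats::sd(v1) == 0 || stats::sd(M2[low]) == 0) {
    stop("constant off-diagonal distances: Mantel r undefined")
  }
  r_of <- function(perm) stats::cor(v1, M2[perm, perm][low])
  r_obs <- r_of(seq_len(n))
  if (exact) {
    perms <- .permutations(n)
    r_all <- apply(perms, 1, r_of)
    p <- mean(r_all >= r_obs - 1e-12)
    B <- nrow(perms) - 1L
  } else {
    if (is.null(seed)) stop("mantel_test requires a seed for random permutations")
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (r_of(sample.int(n)) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    B <- as.integer(n_perm)
  }
  structure(list(r = r_obs, p = p, n_perm = B, exact = exact,
                 strength = classify_mantel_strength(r_obs)),
            class = "mantel_result")
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) # insert i, shift the rest
  }))
}

#' Strength class of a Mantel correlation
#'
#' Conventional edge-weight classes for association networks:
#' r < 0.2 weak, 0.2 <= r < 0.4 moderate, r >= 0.4 strong.
#'
#' @param r Mantel correlation(s).
#' @return Character vector in {"weak", "moderate", "strong"}.
#' @export
classify_mantel_strength <- function(r) {
  stopifnot(all(is.finite(r)))
  ifelse(r >= 0.4, "strong", ifelse(r >= 0.2, "moderate", "weak"))
}

#' Mantel association of each trait with hub responses
#'
#' Runs [mantel_test()] of every single trait's genotype distance matrix
#' against the distance matrices of the two hub variables of the screen's
#' association network: aboveground fresh weight and net photosynthetic rate.
#'
#' @param means `genotype_means` or [trait_table()].
#' @param mode pooling mode passed to [trait_mean_matrix()].
#' @param n_perm,seed permutation settings (see [mantel_test()]).
#' @param hubs response traits to test against (default `c("afw", "pn")`).
#' @return data.frame: hub, trait, r, p, strength, n_perm.
#' @export
mantel_screen <- function(means, mode = "pooled", n_perm = 999L, seed,
                          hubs = c("afw", "pn")) {
  if (missing(seed)) stop("mantel_screen requires a seed")
  X <- trait_mean_matrix(means, mode)
  rows <- list()
  i <- 0L
  for (hub in hubs) {
    Dh <- trait_dist(X[, hub])
    for (tr in setdiff(colnames(X), hub)) {
      i <- i + 1L
      mt <- mantel_test(trait_dist(X[, tr]), Dh, n_perm = n_perm,
                        seed = as.integer(seed) + i)
      rows[[i]] <- data.frame(hub = hub, trait = tr, r = mt$r, p = mt$p,
                              strength = mt$strength, n_perm = mt$n_perm,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f (%s), p = %.4g (%s, %d permutations)\n",
              x$r, x$strength, x$p,
              if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}
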