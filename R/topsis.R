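#' Entropy weights for a decision matrix
#'
#' Objective criterion weights from Shannon entropy of each criterion's
#' min-max-normalised value distribution: criteria on which the alternatives
#' hardly differ carry high entropy and receive near-zero weight. Cost
#' criteria are reversed before normalisation (`(max - x) / (max - min)`).
#' With proportions `p_ij = x'_ij / sum_i x'_ij`, the entropy of criterion j
#' is `e_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`, the exact
#' limit) and the weight is `w_j = (1 - e_j) / sum_k (1 - e_k)`.
#'
#' @param X numeric decision matrix, alternatives x criteria (n >= 2 rows),
#'   complete.
#' @param directions `"benefit"` or `"cost"` per criterion; recycled if
#'   length 1.
#' @return List of class `entropy_weights` with components `weights`
#'   (non-negative, summing to 1), `entropy`, `proportions` and `directions`,
#'   retained for audit.
#' @export
entropy_weights <- function(X, directions = "benefit") {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2L) stop("entropy weights need >= 2 alternatives")
  if (anyNA(X) || any(!is.finite(X))) stop("decision matrix must be complete and finite")
  directions <- .check_directions(directions, m, colnames(X))
  Xn <- X
  for (j in seq_len(m)) {
    rng <- range(X[, j])
    if (rng[1] == rng[2]) {
      Xn[, j] <- 0   # constant criterion: no information, entropy forced to 1
    } else if (directions[j] == "benefit") {
      Xn[, j] <- (X[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      Xn[, j] <- (rng[2] - X[, j]) / (rng[2] - rng[1])
    }
  }
  csum <- colSums(Xn)
  P <- sweep(Xn, 2, ifelse(csum > 0, csum, 1), "/")
  plogp <- ifelse(P > 0, P * log(P), 0)
  e <- ifelse(csum > 0, -colSums(plogp) / log(n), 1)
  if (all(1 - e == 0)) {
    stop("degenerate entropy weights: every criterion is constant")
  }
  if (any(e == 1)) {
    warning("constant criterion receives zero weight: ",
            paste(colnames(X)[e == 1], collapse = ", "))
  }
  w <- (1 - e) / sum(1 - e)
  structure(list(weights = stats::setNames(w, colnames(X)),
                 entropy = stats::setNames(e, colnames(X)),
                 proportions = P, directions = directions),
            class = "entropy_weights")
}

.check_directions <- function(directions, m, crit_names) {
  if (length(directions) == 1L) directions <- rep(directions, m)
  if (!is.null(names(directions)) && !is.null(crit_names) &&
      all(crit_names %in% names(directions))) {
    directions <- directions[crit_names]
  }
  if (length(directions) != m) {
    stop("need one direction per criterion (or a single direction)")
  }
  if (!all(directions %in% c("benefit", "cost"))) {
    stop('criterion directions must be "benefit" or "cost"')
  }
  directions
}

#' TOPSIS closeness coefficients
#'
#' Ranks alternatives by relative closeness to the ideal solution. Columns
#' are vector-normalised (`r_ij = x_ij / sqrt(sum_i x_ij^2)`), weighted, and
#' each alternative's Euclidean distances to the positive ideal (per-column
#' max for benefit criteria, min for cost) and negative ideal (the reverse)
#' are combined into `CI = D- / (D+ + D-)`, in [0, 1], higher = closer to
#' ideal. Ties in CI share the minimum (competition) rank.
#'
#' @param X numeric decision matrix, alternatives x criteria.
#' @param weights an [entropy_weights()] object or a non-negative numeric
#'   vector summing to 1; if omitted, entropy weights are computed from `X`.
#' @param directions `"benefit"`/`"cost"` per criterion (recycled).
#' @return Object of class `hl_topsis`: data.frame `scores` (alternative,
#'   d_plus, d_minus, ci, rank) plus `weights` and `directions`.
#' @export
topsis_ci <- function(X, weights = NULL, directions = "benefit") {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  if (anyNA(X) || any(!is.finite(X))) stop("decision matrix must be complete and finite")
  directions <- .check_directions(directions, m, colnames(X))
  if (is.null(weights)) weights <- entropy_weights(X, directions)
  w <- if (inherits(weights, "entropy_weights")) weights$weights else weights
  if (length(w) != m || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1, one per criterion")
  }
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) {
    stop("zero column norm: criterion ",
         paste(colnames(X)[norms == 0], collapse = ", "),
         " cannot be vector-normalised")
  }
  V <- sweep(sweep(X, 2, norms, "/"), 2, w, "*")
  pos <- ifelse(directions == "benefit", apply(V, 2, max), apply(V, 2, min))
  neg <- ifelse(directions == "benefit", apply(V, 2, min), apply(V, 2, max))
  d_plus <- sqrt(rowSums(sweep(V, 2, pos)^2))
  d_minus <- sqrt(rowSums(sweep(V, 2, neg)^2))
  denom <- d_plus + d_minus
  ci <- ifelse(denom > 0, d_minus / denom, 0.5)
  if (any(denom == 0)) {
    warning("all alternatives identical on the weighted matrix; CI set to 0.5")
  }
  scores <- data.frame(
    alternative = if (is.null(rownames(X))) as.character(seq_len(n)) else rownames(X),
    d_plus = d_plus, d_minus = d_minus, ci = ci,
    rank = rank_alternatives(ci), stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 weights = stats::setNames(w, colnames(X)),
                 directions = stats::setNames(directions, colnames(X))),
            class = "hl_topsis")
}

#' Competition ranks for closeness coefficients
#'
#' Descending-CI ranks; tied values share the minimum rank (1 = best).
#'
#' @param ci numeric vector of closeness coefficients.
#' @return Integer ranks.
#' @export
rank_alternatives <- function(ci) {
  as.integer(rank(-ci, ties.method = "min"))
}

#' @export
print.hl_topsis <- function(x, ...) {
  cat("TOPSIS evaluation of", nrow(x$scores), "alternatives on",
      length(x$weights), "criteria\n")
  cat("CI range:", sprintf("%.3f", min(x$scores$ci)), "-",
      sprintf("%.3f", max(x$scores$ci)), "\n")
  top <- x$scores[order(x$scores$rank), ][1:min(5L, nrow(x$scores)), ]
  cat("Top alternatives:\n")
  print(top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("Entropy weights (", length(x$weights), " criteria )\n", sep = "")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}
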