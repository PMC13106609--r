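#' Cluster closeness coefficients into tolerance groups
#'
#' Agglomerative hierarchical clustering of the 1-dimensional CI values on
#' Euclidean distance, cut at `k` groups. The default linkage is complete:
#' on the reference screen's printed CI values it reproduces the published
#' four-level partition (1/27/11/9 genotypes), which Ward linkage does not --
#' the II/III boundary is linkage-sensitive, so the linkage is an explicit
#' argument rather than a constant.
#'
#' @param ci numeric vector of closeness coefficients (finite).
#' @param k number of clusters (default 4; must be <= length(ci)).
#' @param linkage `"complete"` (default), `"ward"` (hclust `ward.D2`) or
#'   `"average"`.
#' @return Integer cluster ids (arbitrary labels) with the dendrogram
#'   attached as attribute `tree`.
#' @export
cluster_ci <- function(ci, k = 4L, linkage = c("complete", "ward", "average")) {
  linkage <- match.arg(linkage)
  if (any(!is.finite(ci))) stop("CI values must be finite")
  if (k > length(ci)) stop("k (", k, ") exceeds number of genotypes (", length(ci), ")")
  method <- switch(linkage, ward = "ward.D2", linkage)
  # cluster on the sorted values so the partition is invariant to input
  # order (tied CI values otherwise make hclust order-dependent)
  ord <- order(ci)
  tree <- stats::hclust(stats::dist(ci[ord]), method = method)
  ids <- integer(length(ci))
  ids[ord] <- stats::cutree(tree, k = k)
  attr(ids, "tree") <- tree
  ids
}

#' Label clusters as tolerance levels I..IV
#'
#' Orders clusters by descending mean CI and assigns Roman-numeral levels:
#' level I is the most tolerant group, the last level the most sensitive.
#' Tied cluster means are broken by the cluster maximum (with a warning).
#'
#' @param ids integer cluster ids from [cluster_ci()].
#' @param ci the CI vector the ids were computed from.
#' @param genotype optional genotype names (defaults to names of `ci` or
#'   indices).
#' @return Object of class `level_assignment`: data.frame `assignment`
#'   (genotype, ci, cluster, level) and data.frame `levels` (level, n,
#'   mean_ci, min_ci, max_ci) ordered I..IV.
#' @export
label_levels <- function(ids, ci, genotype = NULL) {
  stopifnot(length(ids) == length(ci))
  if (is.null(genotype)) {
    genotype <- if (!is.null(names(ci))) names(ci) else as.character(seq_along(ci))
  }
  cl <- sort(unique(ids))
  mu <- vapply(cl, function(c) mean(ci[ids == c]), numeric(1))
  mx <- vapply(cl, function(c) max(ci[ids == c]), numeric(1))
  if (anyDuplicated(mu)) warning("tied cluster means; ties broken by maximum CI")
  ord <- order(-mu, -mx)
  lvl_names <- as.character(utils::as.roman(seq_along(cl)))
  level_of <- stats::setNames(lvl_names, cl[ord])
  level <- factor(unname(level_of[as.character(ids)]), levels = lvl_names)
  assignment <- data.frame(genotype = genotype, ci = ci,
                           cluster = ids, level = level,
                           stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  levels_df <- data.frame(
    level = lvl_names,
    n = as.integer(table(level)[lvl_names]),
    mean_ci = mu[ord], min_ci = vapply(cl[ord], function(c) min(ci[ids == c]), numeric(1)),
    max_ci = mx[ord], stringsAsFactors = FALSE)
  rownames(levels_df) <- NULL
  structure(list(assignment = assignment, levels = levels_df),
            class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat("Tolerance levels over", nrow(x$assignment), "genotypes\n")
  print(transform(x$levels, mean_ci = round(mean_ci, 3),
                  min_ci = round(min_ci, 3), max_ci = round(max_ci, 3)),
        row.names = FALSE)
  invisible(x)
}
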