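#' Comprehensive high-light tolerance evaluation
#'
#' The one-stop estimator of the package: from replicate-level trait
#' measurements to a ranked, level-classified tolerance screen. Stages:
#' replicate aggregation, per-genotype stress/control tolerance coefficients,
#' entropy weighting of the nine trait criteria, TOPSIS closeness
#' coefficients (CI), and hierarchical clustering of the CI values into
#' tolerance levels I (most tolerant) to `k`.
#'
#' All nine tolerance coefficients are treated as benefit criteria by
#' default (a higher stress/control ratio = greater stability under stress).
#' Proline's role is genuinely ambiguous -- its accumulation marks stress
#' intensity, and its total effect on biomass is negative -- so the
#' direction is overridable per trait via `directions`.
#'
#' @param data a [trait_table()] (or a data.frame coercible to one).
#' @param directions `"benefit"`/`"cost"` per trait, or a single value;
#'   named vectors are matched to trait columns.
#' @param k number of tolerance levels (default 4).
#' @param linkage clustering linkage for [cluster_ci()].
#' @return Object of class `hl_eval` with components `tolerance` (genotype x
#'   trait coefficient matrix), `weights` ([entropy_weights()]), `topsis`
#'   ([topsis_ci()] result), `levels` ([label_levels()] result) and `table`
#'   (genotype, ci, rank, level -- the screen's summary table).
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_genotypes = 12), seed = 1)
#' ev <- hl_eval(cohort)
#' head(ev$table)
#' @export
hl_eval <- function(data, directions = "benefit", k = 4L,
                    linkage = c("complete", "ward", "average")) {
  linkage <- match.arg(linkage)
  if (!inherits(data, "trait_table")) data <- trait_table(data)
  tol <- tolerance_coefficients(data)
  w <- entropy_weights(tol, directions)
  ts <- topsis_ci(tol, w, w$directions)
  ci <- stats::setNames(ts$scores$ci, ts$scores$alternative)
  ids <- cluster_ci(ci, k = k, linkage = linkage)
  lv <- label_levels(ids, ci)
  tab <- merge(ts$scores[, c("alternative", "ci", "rank")],
               lv$assignment[, c("genotype", "level")],
               by.x = "alternative", by.y = "genotype")
  names(tab)[1] <- "genotype"
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(tolerance = tol, weights = w, topsis = ts, levels = lv,
                 table = tab, k = as.integer(k), linkage = linkage),
            class = "hl_eval")
}

#' @export
print.hl_eval <- function(x, ...) {
  cat("High-light tolerance evaluation:", nrow(x$table), "genotypes,",
      ncol(x$tolerance), "traits\n")
  cat("Entropy weights:\n")
  print(round(x$weights$weights, 3))
  cat("CI range:", sprintf("%.3f - %.3f", min(x$table$ci), max(x$table$ci)),
      "\nLevels (", x$linkage, " linkage, k = ", x$k, "):\n", sep = "")
  print(transform(x$levels$levels, mean_ci = round(mean_ci, 3),
                  min_ci = round(min_ci, 3), max_ci = round(max_ci, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.hl_eval <- function(object, ...) {
  cat("Top genotypes by closeness coefficient:\n")
  print(utils::head(object$table, 5), row.names = FALSE)
  cat("...\n")
  print(utils::tail(object$table, 3), row.names = FALSE)
  invisible(object$table)
}

#' @export
coef.hl_eval <- function(object, ...) {
  stats::setNames(object$table$ci, object$table$genotype)
}

#' @export
plot.hl_eval <- function(x, ...) {
  ci <- coef(x)
  lvl <- x$levels$assignment$level[match(names(ci), x$levels$assignment$genotype)]
  cols <- grDevices::hcl.colors(nlevels(lvl), "Zissou 1")
  graphics::barplot(sort(ci, decreasing = TRUE),
                    col = cols[as.integer(lvl)][order(-ci)],
                    las = 2, ylab = "Closeness coefficient (CI)",
                    cex.names = 0.6, ...)
  graphics::legend("topright", legend = levels(lvl), fill = cols,
                   title = "Tolerance level", bty = "n")
  invisible(x)
}
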