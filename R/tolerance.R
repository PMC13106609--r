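#' Per-genotype high-light tolerance coefficients
#'
#' The tolerance coefficient of genotype g for trait t is the ratio of g's
#' replicate-mean value under stress to its replicate-mean value under
#' control. Values near 1 indicate stability under stress; proline routinely
#' exceeds 1 (stress-induced accumulation). The resulting genotype x trait
#' matrix is the TOPSIS decision matrix; no rescaling or capping is applied
#' here -- normalisation belongs to the evaluation stage.
#'
#' @param means a `genotype_means` table from [aggregate_replicates()], or a
#'   [trait_table()] (aggregated internally).
#' @param on_incomplete `"error"` (default) fails on any missing
#'   (genotype, treatment, trait) cell -- the decision matrix must be
#'   complete; `"drop"` removes affected genotypes everywhere, with a
#'   warning naming them.
#' @return Numeric matrix, genotypes x traits, all entries finite and > 0.
#' @export
tolerance_coefficients <- function(means, on_incomplete = c("error", "drop")) {
  on_incomplete <- match.arg(on_incomplete)
  if (inherits(means, "trait_table")) means <- aggregate_replicates(means)
  stopifnot(is.data.frame(means),
            all(c("genotype", "treatment", "trait", "mean") %in% names(means)))
  traits <- intersect(hl_traits(), unique(means$trait))
  gids <- sort(unique(means$genotype))
  get <- function(trt) {
    sub <- means[means$treatment == trt, ]
    m <- matrix(NA_real_, length(gids), length(traits),
                dimnames = list(gids, traits))
    m[cbind(match(sub$genotype, gids), match(sub$trait, traits))] <- sub$mean
    m
  }
  ctrl <- get("control")
  strs <- get("stress")
  if (anyNA(ctrl) || anyNA(strs)) {
    miss <- which(is.na(ctrl) | is.na(strs), arr.ind = TRUE)
    if (on_incomplete == "error") {
      stop("incomplete decision matrix: missing mean for genotype ",
           gids[miss[1L, 1L]], ", trait ", traits[miss[1L, 2L]],
           " (", nrow(miss), " missing cell(s) in total)")
    }
    bad <- unique(gids[miss[, 1L]])
    warning("dropping incomplete genotype(s): ", paste(bad, collapse = ", "))
    keep <- !(gids %in% bad)
    if (!any(keep)) stop("no complete genotypes remain")
    ctrl <- ctrl[keep, , drop = FALSE]
    strs <- strs[keep, , drop = FALSE]
    gids <- gids[keep]
  }
  if (any(ctrl <= 0)) {
    bad <- which(ctrl <= 0, arr.ind = TRUE)
    stop("control mean <= 0 for genotype ", gids[bad[1L, 1L]],
         ", trait ", traits[bad[1L, 2L]], ": tolerance ratio undefined")
  }
  strs / ctrl
}
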