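#' Out-of-bag permutation importance for trait predictors
#'
#' Ranks predictors of a response (typically aboveground fresh weight) by the
#' percent increase in out-of-bag mean squared error when the predictor is
#' permuted. The tree ensemble is a standard bootstrap regression forest
#' (\pkg{randomForest}); the importance statistic is computed here from the
#' per-tree out-of-bag predictions:
#' `imp_j = mean_b 100 * (MSE_oob(b, X with column j permuted) - MSE_oob(b, X)) / MSE_oob(b, X)`
#' with one seeded global permutation of column j per forest. A predictor the
#' trees never use (e.g. a constant) scores exactly 0.
#'
#' Optional significance attaches a response-permutation null: the forest and
#' importances are recomputed on `n_null` permutations of `y`, and
#' `p_j = (1 + #[null_j >= imp_j]) / (n_null + 1)`.
#'
#' @param x data.frame or matrix of predictors (>= 2 columns).
#' @param y numeric response (length = nrow(x), >= 10 observations,
#'   non-constant).
#' @param n_trees ensemble size (default 500).
#' @param mtry predictors tried per split (default `ceiling(p/3)`).
#' @param seed integer seed covering the forest and all permutations.
#' @param n_null response permutations for p-values; 0 (default) skips the
#'   null, otherwise must be >= 19.
#' @return Object of class `hl_importance`: data.frame `importance`
#'   (predictor, inc_mse_percent, p, stars) sorted by decreasing importance,
#'   plus `n_trees`, `mtry`, `n_null`, `seed`.
#' @export
hl_importance <- function(x, y, n_trees = 500L, mtry = NULL, seed,
                          n_null = 0L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need >= 2 predictors")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nrow(x) < 10L) stop("need >= 10 observations")
  if (stats::sd(y) == 0) stop("constant response: model degenerate")
  if (missing(seed)) stop("hl_importance requires a seed")
  if (n_null != 0L && n_null < 19L) {
    stop("n_null must be 0 or >= 19 for a meaningful permutation null")
  }
  if (is.null(mtry)) mtry <- ceiling(ncol(x) / 3)
  imp <- .oob_perm_importance(x, y, n_trees, mtry, seed)
  p <- rep(NA_real_, ncol(x))
  if (n_null > 0L) {
    null_mat <- matrix(NA_real_, n_null, ncol(x))
    for (b in seq_len(n_null)) {
      set.seed(as.integer(seed) + 100003L * b)
      y_perm <- y[sample.int(length(y))]
      null_mat[b, ] <- .oob_perm_importance(x, y_perm, n_trees, mtry,
                                            seed = as.integer(seed) + 200003L * b)
    }
    p <- vapply(seq_len(ncol(x)), function(j) {
      (1 + sum(null_mat[, j] >= imp[j])) / (n_null + 1)
    }, numeric(1))
  }
  stars <- ifelse(is.na(p), "",
           ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
  out <- data.frame(predictor = colnames(x), inc_mse_percent = imp,
                    p = p, stars = stars, stringsAsFactors = FALSE)
  out <- out[order(-out$inc_mse_percent), ]
  rownames(out) <- NULL
  structure(list(importance = out, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), n_null = as.integer(n_null),
                 seed = as.integer(seed)),
            class = "hl_importance")
}

.oob_perm_importance <- function(x, y, n_trees, mtry, seed) {
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = mtry, keep.inbag = TRUE,
                                   keep.forest = TRUE)
  base_pred <- stats::predict(rf, newdata = x, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  mse_tree <- function(pred) {
    vapply(seq_len(ncol(pred)), function(b) {
      idx <- oob[, b]
      if (!any(idx)) return(NA_real_)
      mean((pred[idx, b] - y[idx])^2)
    }, numeric(1))
  }
  mse_base <- mse_tree(base_pred)
  usable <- !is.na(mse_base) & mse_base > 0
  vapply(seq_len(ncol(x)), function(j) {
    set.seed(as.integer(seed) + 1009L * j)
    xp <- x
    xp[[j]] <- xp[[j]][sample.int(nrow(x))]
    if (identical(xp[[j]], x[[j]])) return(0)
    perm_pred <- stats::predict(rf, newdata = xp, predict.all = TRUE)$individual
    mse_perm <- mse_tree(perm_pred)
    mean(100 * (mse_perm[usable] - mse_base[usable]) / mse_base[usable])
  }, numeric(1))
}

#' @export
print.hl_importance <- function(x, ...) {
  cat("Permutation importance (", x$n_trees, " trees, mtry ", x$mtry, ")\n",
      sep = "")
  df <- x$importance
  df$inc_mse_percent <- round(df$inc_mse_percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
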