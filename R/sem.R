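#' Declare a directed acyclic path diagram
#'
#' @param edges character vector of `"parent -> child"` declarations, or a
#'   two-column data.frame/matrix (parent, child).
#' @param response terminal response node; defaults to the unique node
#'   without children.
#' @return Object of class `path_dag`: `nodes`, `edges` (data.frame parent,
#'   child), `exogenous` (nodes without parents), `response`.
#' @export
path_dag <- function(edges, response = NULL) {
  if (is.character(edges)) {
    lines <- sub("#.*$", "", edges)
    lines <- trimws(lines[trimws(lines) != ""])
    parts <- strsplit(lines, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("each edge must be written as 'parent -> child'")
    }
    edges <- data.frame(parent = trimws(vapply(parts, `[`, "", 1L)),
                        child = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("parent", "child")
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) stop("duplicate edge")
  nodes <- unique(c(edges$parent, edges$child))
  order <- .topo_sort(nodes, edges)   # errors on a cycle
  exo <- setdiff(nodes, edges$child)
  childless <- setdiff(nodes, edges$parent)
  if (is.null(response)) {
    if (length(childless) != 1L) {
      stop("terminal response ambiguous (childless nodes: ",
           paste(childless, collapse = ", "), "); pass `response`")
    }
    response <- childless
  }
  if (!response %in% nodes) stop("response node not in DAG")
  if (response %in% edges$parent) stop("terminal response must have no children")
  structure(list(nodes = order, edges = edges, exogenous = exo,
                 response = response),
            class = "path_dag")
}

#' Read a path diagram from an edge-list file
#'
#' Plain-text format: one `parent -> child` per line, `#` comments allowed.
#'
#' @param path file path.
#' @param response optional terminal response (see [path_dag()]).
#' @return A [path_dag()].
#' @export
read_dag <- function(path, response = NULL) {
  path_dag(readLines(path), response = response)
}

#' Default path diagram of the high-light biomass model
#'
#' Light intensity (LI), genotype score (G) and their interaction (LIxG)
#' drive the intermediate traits (free proline FPC, plant height PH, leaf
#' thickness LT, SPAD, stem diameter SD); the intermediates plus LI and G
#' feed aboveground fresh weight (AFW), the terminal response.
#'
#' @return A [path_dag()].
#' @export
default_dag <- function() {
  read_dag(system.file("extdata", "default_dag.txt", package = "heliotol"))
}

.topo_sort <- function(nodes, edges) {
  order <- character(0)
  remaining <- nodes
  eds <- edges
  while (length(remaining) > 0L) {
    roots <- setdiff(remaining, eds$child)
    if (length(roots) == 0L) stop("graph contains a cycle")
    order <- c(order, sort(roots))
    remaining <- setdiff(remaining, roots)
    eds <- eds[!(eds$parent %in% roots), , drop = FALSE]
  }
  order
}

.parents <- function(dag, node) dag$edges$parent[dag$edges$child == node]

#' d-separation basis set of a DAG
#'
#' The independence claims implied by the diagram: every non-adjacent node
#' pair, conditioned on the union of both nodes' parents. Pairs of two
#' exogenous variables are excluded (their association is not modeled).
#' Each claim is oriented so that the regression response is the pair member
#' occurring later in topological order.
#'
#' @param dag a [path_dag()].
#' @return List of claims, each `list(x, y, conditioning)` meaning
#'   `y _||_ x | conditioning`; length k gives Fisher's C its 2k df.
#' @export
basis_set <- function(dag) {
  stopifnot(inherits(dag, "path_dag"))
  nodes <- dag$nodes   # topologically sorted
  adj <- paste(dag$edges$parent, dag$edges$child)
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      if (a %in% dag$exogenous && b %in% dag$exogenous) next
      cond <- setdiff(unique(c(.parents(dag, a), .parents(dag, b))), c(a, b))
      claims[[length(claims) + 1L]] <- list(x = a, y = b, conditioning = cond)
    }
  }
  claims
}

#' Fisher's C statistic for a set of independence-claim p-values
#'
#' `C = -2 sum(ln p_i)` compared to a chi-square with `2k` degrees of
#' freedom; a large model p-value means the data are consistent with the
#' claimed conditional independencies, i.e. the causal structure is not
#' rejected.
#'
#' @param p_values numeric vector in (0, 1], one per independence claim
#'   (may be empty for a saturated model: C = 0, df = 0, p = 1).
#' @return List `C`, `df`, `p`.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0L) return(list(C = 0, df = 0L, p = 1))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    bad <- which(!is.finite(p_values) | p_values <= 0 | p_values > 1)[1L]
    stop("independence-claim p-value out of (0, 1] at claim ", bad,
         " (p = ", p_values[bad], ")")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = stats::pchisq(C, df = df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' One ordinary least-squares regression per endogenous node on its declared
#' parents, fit on z-standardized columns so every coefficient is a
#' standardized path coefficient (for a single-parent node it equals the
#' Pearson correlation of the pair). Goodness of fit is Shipley's
#' d-separation test: each basis-set claim `y _||_ x | pa` is tested by the
#' t-test on x's partial coefficient in `lm(y ~ pa + x)`, and the claim
#' p-values are combined by [fishers_c()].
#'
#' @param dag a [path_dag()].
#' @param data data.frame containing every DAG node as a numeric column.
#' @param standardize z-standardize columns before fitting (default TRUE;
#'   set FALSE only if `data` is already standardized).
#' @return Object of class `hl_psem`: `coefficients` (parent, child, beta,
#'   se, p), `r2` per endogenous node, `claims` (x, y, conditioning, p),
#'   `C`, `df`, `p_model`, `n`, `dag`, and the per-node `lm` fits in
#'   `models`.
#' @export
hl_psem <- function(dag, data, standardize = TRUE) {
  stopifnot(inherits(dag, "path_dag"))
  data <- as.data.frame(data)
  miss <- setdiff(dag$nodes, names(data))
  if (length(miss) > 0L) {
    stop("data lacks DAG node column(s): ", paste(miss, collapse = ", "))
  }
  Z <- data[, dag$nodes, drop = FALSE]
  if (standardize) Z <- as.data.frame(scale(Z))
  if (any(!is.finite(as.matrix(Z)))) {
    stop("non-finite values after standardization (constant column?)")
  }
  endo <- setdiff(dag$nodes, dag$exogenous)
  max_parents <- max(vapply(endo, function(nd) length(.parents(dag, nd)), 0L))
  if (nrow(Z) <= max_parents + 1L) stop("too few rows for the largest parent set")
  models <- list()
  coefs <- list()
  r2 <- numeric(0)
  for (nd in endo) {
    pa <- .parents(dag, nd)
    fm <- stats::lm(stats::reformulate(pa, response = nd), data = Z)
    models[[nd]] <- fm
    sm <- summary(fm)
    ct <- sm$coefficients[pa, , drop = FALSE]
    kappa_x <- kappa(stats::model.matrix(fm))
    if (kappa_x > 1e6) {
      warning("near-collinear parents for ", nd,
              " (condition number ", format(kappa_x, digits = 3), ")")
    }
    coefs[[nd]] <- data.frame(parent = pa, child = nd,
                              beta = ct[, "Estimate"],
                              se = ct[, "Std. Error"],
                              p = ct[, "Pr(>|t|)"],
                              stringsAsFactors = FALSE)
    r2[nd] <- sm$r.squared
  }
  coefs <- do.call(rbind, coefs)
  rownames(coefs) <- NULL
  claims <- basis_set(dag)
  claim_p <- numeric(length(claims))
  for (i in seq_along(claims)) {
    cl <- claims[[i]]
    fm <- stats::lm(stats::reformulate(c(cl$conditioning, cl$x), response = cl$y),
                    data = Z)
    claim_p[i] <- summary(fm)$coefficients[cl$x, "Pr(>|t|)"]
  }
  fc <- fishers_c(claim_p)
  claims_df <- if (length(claims) > 0L) {
    data.frame(x = vapply(claims, `[[`, "", "x"),
               y = vapply(claims, `[[`, "", "y"),
               conditioning = vapply(claims, function(cl)
                 paste(cl$conditioning, collapse = "+"), ""),
               p = claim_p, stringsAsFactors = FALSE)
  } else {
    data.frame(x = character(0), y = character(0),
               conditioning = character(0), p = numeric(0))
  }
  structure(list(coefficients = coefs, r2 = r2, claims = claims_df,
                 C = fc$C, df = fc$df, p_model = fc$p, n = nrow(Z),
                 dag = dag, models = models),
            class = "hl_psem")
}

#' Direct, indirect and total standardized effects on the response
#'
#' The direct effect of a node is its edge coefficient into the terminal
#' response (0 if absent); the indirect effect sums, over every directed
#' path of length >= 2 from the node to the response, the product of the
#' path's edge coefficients (exact enumeration; the DAG is small); total =
#' direct + indirect.
#'
#' @param fit an [hl_psem()] fit.
#' @return data.frame: node, direct, indirect, total, for every node except
#'   the response.
#' @export
path_effects <- function(fit) {
  stopifnot(inherits(fit, "hl_psem"))
  dag <- fit$dag
  beta <- fit$coefficients
  edge_beta <- function(p, ch) {
    b <- beta$beta[beta$parent == p & beta$child == ch]
    if (length(b) == 0L) 0 else b
  }
  memo <- new.env()
  total_to <- function(node) {
    if (node == dag$response) return(1)
    if (!is.null(memo[[node]])) return(memo[[node]])
    kids <- dag$edges$child[dag$edges$parent == node]
    tot <- 0
    for (ch in kids) tot <- tot + edge_beta(node, ch) * total_to(ch)
    memo[[node]] <- tot
    tot
  }
  nodes <- setdiff(dag$nodes, dag$response)
  out <- data.frame(node = nodes,
                    direct = vapply(nodes, function(nd) edge_beta(nd, dag$response), numeric(1)),
                    total = vapply(nodes, total_to, numeric(1)),
                    stringsAsFactors = FALSE)
  out$indirect <- out$total - out$direct
  out <- out[, c("node", "direct", "indirect", "total")]
  rownames(out) <- NULL
  out
}

#' @export
print.hl_psem <- function(x, ...) {
  cat("Piecewise SEM:", length(x$models), "component regressions, n =", x$n, "\n")
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.3f\n", x$C, x$df, x$p_model))
  cat("Standardized path coefficients:\n")
  df <- x$coefficients
  df$beta <- round(df$beta, 3); df$se <- round(df$se, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hl_psem <- function(object, ...) {
  eff <- path_effects(object)
  out <- list(fit = object, effects = eff, r2 = object$r2)
  class(out) <- "summary.hl_psem"
  out
}

#' @export
print.summary.hl_psem <- function(x, ...) {
  print(x$fit)
  cat("\nR-squared per endogenous node:\n")
  print(round(x$r2, 3))
  cat("\nEffects on ", x$fit$dag$response, ":\n", sep = "")
  eff <- x$effects
  eff[, -1] <- round(eff[, -1], 3)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hl_psem <- function(object, ...) {
  stats::setNames(object$coefficients$beta,
                  paste(object$coefficients$parent, "->",
                        object$coefficients$child))
}

#' @export
fitted.hl_psem <- function(object, ...) lapply(object$models, stats::fitted)

#' @export
residuals.hl_psem <- function(object, ...) lapply(object$models, stats::residuals)

#' Genotype x treatment table for the path model
#'
#' Builds the node columns of [default_dag()] from a cohort: replicate means
#' per genotype x treatment for PH, LT, SPAD, SD, FPC and AFW; LI coded as a
#' standardized control/stress indicator; G as a standardized per-genotype
#' score (by default the generator's latent tolerance attribute, on real
#' data a user-supplied vector); LIxG the re-standardized product.
#'
#' @param cohort a [trait_table()]; if it carries a `latent_tolerance`
#'   attribute (see [simulate_cohort()]) that is the default genotype score.
#' @param genotype_score optional named numeric vector of per-genotype
#'   scores overriding the attribute.
#' @return data.frame with columns LI, G, LIxG, FPC, PH, LT, SPAD, SD, AFW,
#'   one row per genotype x treatment.
#' @export
sem_table <- function(cohort, genotype_score = NULL) {
  means <- aggregate_replicates(cohort)
  X <- trait_mean_matrix(means, "pooled")
  key <- do.call(rbind, strsplit(rownames(X), ".", fixed = TRUE))
  if (is.null(genotype_score)) {
    genotype_score <- attr(cohort, "latent_tolerance")
    if (is.null(genotype_score)) {
      stop("no latent_tolerance attribute; supply genotype_score")
    }
  }
  g_missing <- setdiff(unique(key[, 1]), names(genotype_score))
  if (length(g_missing) > 0L) {
    stop("genotype_score lacks: ", paste(g_missing, collapse = ", "))
  }
  li <- as.numeric(key[, 2] == "stress")
  out <- data.frame(
    LI = as.numeric(scale(li)),
    G = as.numeric(scale(genotype_score[key[, 1]])),
    FPC = X[, "proline"], PH = X[, "plant_height"],
    LT = X[, "leaf_thickness"], SPAD = X[, "spad"],
    SD = X[, "stem_diameter"], AFW = X[, "afw"])
  out$LIxG <- as.numeric(scale(out$LI * out$G))
  rownames(out) <- rownames(X)
  out[, c("LI", "G", "LIxG", "FPC", "PH", "LT", "SPAD", "SD", "AFW")]
}
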