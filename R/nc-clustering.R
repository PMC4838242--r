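#' Fit the nest-group linear discriminant model
#'
#' Dimension-reduction step of nest-centroid clustering: a linear
#' discriminant analysis on the raw trait values (micrometres; no
#' standardization is required) with nest samples as groups. Solves the
#' generalized eigenproblem of the between-nest scatter against the pooled
#' within-nest covariance and retains every axis whose discriminant
#' eigenvalue exceeds `tol`, so that distances downstream use the full
#' discriminant morphospace, not just the first two axes.
#'
#' With many singleton nests the pooled within-nest covariance can be
#' ill-conditioned; `shrinkage = "auto"` then conditions it by shrinking
#' toward its diagonal with a Ledoit-Wolf-style data-driven intensity
#' (applied — and recorded in the model — only when needed). A
#' pseudo-inverse fallback guards against exactly singular conditioned
#' matrices. With `shrinkage = "none"` a singular within-scatter is an
#' error advising the shrinkage option.
#'
#' Axes are normalized to unit pooled within-nest variance and their sign
#' fixed so the largest-magnitude loading is positive, making output
#' deterministic across runs and platforms.
#'
#' @param table A [MorphoTable-class]; specimens with missing traits are
#'   excluded with a warning.
#' @param grouping Nest grouping as returned by [groupByNest()].
#' @param shrinkage `"auto"` (default), `"none"`, or a numeric intensity in
#'   `[0, 1]` applied unconditionally.
#' @param tol Eigenvalue tolerance for retaining axes (default 1e-10).
#' @return A [NestLDA-class] model.
#' @export
fitNestLDA <- function(table, grouping = groupByNest(table),
                       shrinkage = "auto", tol = 1e-10) {
  table <- completeTraitTable(table)
  X <- traitMatrix(table)
  grouping <- lapply(grouping, intersect, rownames(X))
  grouping <- grouping[lengths(grouping) > 0]
  g <- length(grouping)
  if (g < 2) stop("at least 2 nest groups required")
  p <- ncol(X)
  n <- nrow(X)
  grandMean <- colMeans(X)
  Sw <- matrix(0, p, p)
  gm <- matrix(NA_real_, g, p, dimnames = list(names(grouping), colnames(X)))
  Sb <- matrix(0, p, p)
  for (i in seq_len(g)) {
    Xi <- X[grouping[[i]], , drop = FALSE]
    mi <- colMeans(Xi)
    gm[i, ] <- mi
    ci <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(ci)
    dm <- mi - grandMean
    Sb <- Sb + nrow(Xi) * tcrossprod(dm)
  }
  dfw <- max(1L, n - g)
  S <- Sw / dfw

  lambda <- 0
  applied <- FALSE
  if (identical(shrinkage, "none")) {
    if (rcond(S) < 1e-12)
      stop("pooled within-nest scatter is singular; refit with ",
           "shrinkage = \"auto\" or a numeric shrinkage intensity")
  } else if (is.numeric(shrinkage)) {
    lambda <- shrinkage
    applied <- lambda > 0
  } else {
    if (rcond(S) < 1e-8) {
      lambda <- .ledoitWolfLambda(X, grouping, S, dfw)
      applied <- TRUE
      warning("within-scatter conditioning applied (shrinkage lambda = ",
              signif(lambda, 3), ")")
    }
  }
  Sreg <- if (applied) (1 - lambda) * S + lambda * diag(diag(S), p) else S

  es <- eigen(Sreg, symmetric = TRUE)
  pos <- es$values > max(es$values) * 1e-12
  pseudo <- !all(pos)
  Wih <- es$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(es$values[pos]), sum(pos)) %*%
    t(es$vectors[, pos, drop = FALSE])
  A <- Wih %*% Sb %*% Wih
  A <- (A + t(A)) / 2
  ea <- eigen(A, symmetric = TRUE)
  keep <- which(ea$values > tol)
  keep <- keep[seq_len(min(length(keep), p, g - 1L))]
  V <- Wih %*% ea$vectors[, keep, drop = FALSE]
  # unit pooled within-nest variance per axis, canonical sign
  for (j in seq_along(keep)) {
    v <- V[, j]
    v <- v / sqrt(drop(t(v) %*% Sreg %*% v))
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, j] <- v
  }
  dimnames(V) <- list(colnames(X), paste0("LD", seq_along(keep)))
  model <- new("NestLDA", loadings = V, eigenvalues = ea$values[keep],
               traitOrder = colnames(X), center = grandMean,
               groupMeans = sweep(gm, 2, grandMean) %*% V,
               regularization = list(applied = applied, lambda = lambda,
                                     pseudoInverse = pseudo))
  validObject(model)
  model
}

# Ledoit-Wolf-style shrinkage intensity toward the diagonal target,
# estimated from the within-nest residuals.
.ledoitWolfLambda <- function(X, grouping, S, dfw) {
  res <- do.call(rbind, lapply(grouping, function(ids) {
    Xi <- X[ids, , drop = FALSE]
    if (nrow(Xi) < 2) return(NULL)
    sweep(Xi, 2, colMeans(Xi))
  }))
  if (is.null(res) || nrow(res) < 2) return(1)
  n <- nrow(res)
  phi <- 0
  for (i in seq_len(n)) {
    zi <- tcrossprod(res[i, ])
    phi <- phi + sum((zi - S)^2)
  }
  phi <- phi / n^2
  target <- diag(diag(S), ncol(S))
  gamma <- sum((S - target)^2)
  if (gamma <= 0) return(1)
  max(0, min(1, phi / gamma))
}

#' Project specimens into the discriminant morphospace
#'
#' @param model A [NestLDA-class].
#' @param table A [MorphoTable-class] whose traits match the model's trait
#'   order. Projecting the training table reproduces the training scores.
#' @return Numeric matrix of discriminant scores, specimens x axes, rows
#'   named by specimen id.
#' @export
projectScores <- function(model, table) {
  stopifnot(is(model, "NestLDA"))
  X <- traitMatrix(completeTraitTable(table))
  if (!all(model@traitOrder %in% colnames(X)))
    stop("table traits do not match the model's trait order")
  X <- X[, model@traitOrder, drop = FALSE]
  sweep(X, 2, model@center) %*% model@loadings
}

#' Nest centroids in discriminant space
#'
#' @param scores Specimen scores from [projectScores()].
#' @param grouping Nest grouping; every member specimen must have a score
#'   row.
#' @return Matrix of per-nest mean scores, one row per nest.
#' @export
nestCentroids <- function(scores, grouping) {
  miss <- setdiff(unlist(grouping), rownames(scores))
  if (length(miss))
    stop("no score row for specimen(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- t(vapply(grouping,
                  function(ids) colMeans(scores[ids, , drop = FALSE]),
                  numeric(ncol(scores))))
  colnames(out) <- colnames(scores)
  out
}

#' Agglomerative dendrogram of nest centroids
#'
#' Hierarchical clustering of Euclidean distances between nest centroids in
#' discriminant space; the dendrogram visualizes the morphospace structure
#' but carries no phylogenetic meaning.
#'
#' @param centroids Matrix of centroid scores (rows = nests or specimens).
#' @param linkage Agglomeration method: `"ward"` (minimum variance, the
#'   default), `"complete"`, `"average"` (UPGMA) or `"single"`.
#' @param labels Optional display labels per leaf, conventionally
#'   `"<species-or-?>-<CASENT>"`; defaults to the centroid row names.
#' @return An object of class [stats::hclust] with `labels` set.
#' @export
buildDendrogram <- function(centroids, linkage = "ward", labels = NULL) {
  if (nrow(centroids) < 2) stop("at least 2 observations required")
  method <- switch(linkage,
                   ward = "ward.D2", complete = "complete",
                   average = "average", single = "single",
                   stop("unknown linkage: ", linkage))
  hc <- stats::hclust(stats::dist(centroids), method = method)
  hc$labels <- if (is.null(labels)) rownames(centroids) else labels
  hc
}

#' Merge table of a dendrogram
#'
#' @param hc An [stats::hclust] object.
#' @return data.frame with one row per merge: `left`, `right` (negative =
#'   leaf index, positive = earlier merge), `height` and `size` of the
#'   merged cluster.
#' @export
mergeTable <- function(hc) {
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
             height = hc$height, size = sizes)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from merge heights (ultrametric display heights).
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
exportNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
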