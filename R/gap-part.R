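#' Pooled within-cluster dispersion
#'
#' The dispersion underlying the Gap statistic:
#' `W = sum over clusters r of D_r / (2 n_r)` with `D_r` the sum of squared
#' pairwise Euclidean distances within cluster `r` (equivalently the sum of
#' squared deviations from the cluster centroid), returned on the log
#' scale. `-Inf` is the sentinel for `W = 0` (every cluster a single or
#' duplicated point) and is handled by the selection rule downstream.
#'
#' @param X Numeric score matrix, observations in rows.
#' @param labels Cluster labels, one per row; every cluster non-empty.
#' @return `log(W)`.
#' @export
withinDispersion <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) stop("one label per observation required")
  labels <- as.character(labels)
  if (any(table(labels) < 1)) stop("empty cluster")
  W <- 0
  for (l in unique(labels)) {
    Xi <- X[labels == l, , drop = FALSE]
    W <- W + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  log(W)
}

# Cluster X into k groups with the named base engine. kmeans uses
# multi-start Lloyd iterations; hclust is Ward agglomeration cut at k.
.clusterEngine <- function(X, k, engine, nstart = 25) {
  n <- nrow(X)
  if (k <= 1) return(rep(1L, n))
  if (k >= n) return(seq_len(n))
  if (engine == "hclust") {
    return(stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"),
                         k = k))
  }
  if (engine == "kmeans") {
    fit <- tryCatch(
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50),
      error = function(e)  # fewer distinct points than centers, etc.
        NULL)
    if (is.null(fit))
      return(stats::cutree(stats::hclust(stats::dist(X),
                                         method = "ward.D2"), k = k))
    return(fit$cluster)
  }
  stop("unknown engine: ", engine)
}

# Uniform reference draw over the data range in the principal-axes frame.
.referenceDraw <- function(Xc, V, lo, hi) {
  n <- nrow(Xc)
  Zp <- vapply(seq_along(lo),
               function(j) stats::runif(n, lo[j], hi[j]),
               numeric(n))
  Zp %*% t(V)
}

#' Gap statistic over 1..kMax clusters
#'
#' Compares the observed log within-cluster dispersion to its expectation
#' under `B` reference datasets drawn uniformly over the range of the data
#' in its principal-axes frame (rotation-aware uniform reference; a simple
#' per-variable range reference is available via `reference = "range"`).
#' The number of clusters is the smallest `k` with
#' `gap(k) >= gap(k+1) - se(k+1)`, falling back to `kMax` when no `k`
#' satisfies the rule; the simulation standard error includes the
#' `sqrt(1 + 1/B)` factor.
#'
#' @param X Numeric score matrix, observations in rows (n >= 2).
#' @param kMax Maximum number of clusters examined (clipped with a warning
#'   to n - 1 when `kMax >= n`).
#' @param B Number of reference datasets (>= 2).
#' @param engine `"hclust"` or `"kmeans"`.
#' @param seed Integer seed driving the reference draws (and k-means
#'   restarts).
#' @param nstart Multi-start count for the k-means engine.
#' @param reference `"pca"` (default) or `"range"`.
#' @param firstMax If `TRUE`, select the first local maximum of the gap
#'   curve instead of the standard-error rule.
#' @return A [GapProfile-class].
#' @export
gapStatistic <- function(X, kMax = 10, B = 100, engine = "hclust",
                         seed = 1L, nstart = 25, reference = "pca",
                         firstMax = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("at least 2 observations required")
  if (B < 2) stop("B must be >= 2 (simulation standard error undefined)")
  if (kMax >= n) {
    warning("kMax >= number of observations; clipped to ", n - 1L)
    kMax <- n - 1L
  }
  kMax <- max(1L, as.integer(kMax))
  withLocalSeed(seed, {
    ks <- seq_len(kMax)
    logW <- vapply(ks, function(k)
      withinDispersion(X, .clusterEngine(X, k, engine, nstart)), numeric(1))
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    V <- if (identical(reference, "pca") && n > 1)
      svd(Xc, nu = 0)$v else diag(ncol(X))
    Zp <- Xc %*% V
    lo <- apply(Zp, 2, min)
    hi <- apply(Zp, 2, max)
    logWstar <- matrix(NA_real_, B, kMax)
    for (b in seq_len(B)) {
      Z <- .referenceDraw(Xc, V, lo, hi)
      logWstar[b, ] <- vapply(ks, function(k)
        withinDispersion(Z, .clusterEngine(Z, k, engine, nstart)),
        numeric(1))
    }
    gap <- colMeans(logWstar) - logW
    se <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / B)
    chosen <- kMax
    if (kMax > 1) {
      if (firstMax) {
        ok <- which(diff(gap) < 0)
        if (length(ok)) chosen <- ok[1]
      } else {
        ok <- which(gap[-kMax] >= gap[-1] - se[-1])
        if (length(ok)) chosen <- ok[1]
      }
    } else chosen <- 1L
    new("GapProfile", k = ks, logW = logW, logWstar = colMeans(logWstar),
        gap = gap, se = se, B = as.integer(B),
        chosenK = as.integer(chosen), engine = engine)
  })
}

#' Recursive Gap-statistic partitioning (PART)
#'
#' Estimates the number of clusters and assigns observations by recursive
#' application of the Gap statistic: the gap rule is applied at the top
#' level; every resulting cluster is re-examined on its own subset of
#' cases, recursing until the rule returns one cluster or the subset has
#' fewer than `2 * minSize` cases. This discovers both top-level clusters
#' and sub-clusters nested within them.
#'
#' When the gap rule returns one cluster on a subset, a tentative binary
#' split guards against halting the recursion prematurely. If one side of
#' the split holds fewer than `minSize` cases, those cases are set aside as
#' outliers, the remainder is re-examined, and the set-aside cases are
#' finally attached to the nearest resulting cluster (by centroid
#' Euclidean distance). If both sides are at least `minSize`, both are
#' examined recursively: the tentative split is kept only when the Gap
#' statistic confirms a genuine split somewhere below it, and is reverted
#' (the subset stays one cluster) otherwise — so single homogeneous
#' clusters are never fragmented, while flat arrangements of many equally
#' spaced clusters, where the gap curve is ambiguous at `k = 2`, are still
#' resolved.
#'
#' @param X Numeric score matrix (typically nest-centroid discriminant
#'   scores), observations in rows, rows named.
#' @param engine `"hclust"` or `"kmeans"`.
#' @param B Reference datasets per Gap run (the study protocol uses 500).
#' @param minSize Minimum cluster size (default 3).
#' @param kMax Maximum clusters per split (default 10).
#' @param seed Integer seed; all Gap runs and engine restarts derive from
#'   it deterministically.
#' @param nstart Multi-start count for the k-means engine.
#' @return A [PartPartition-class]; the recursion record is in `@tree`.
#' @export
partRecursive <- function(X, engine = "hclust", B = 100, minSize = 3,
                          kMax = 10, seed = 1L, nstart = 25) {
  X <- as.matrix(X)
  if (minSize < 1) stop("minSize must be >= 1")
  if (nrow(X) < 2) stop("at least 2 observations required")
  if (is.null(rownames(X))) rownames(X) <- paste0("obs", seq_len(nrow(X)))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  nextSeed <- function() {
    counter$i <- counter$i + 1L
    (as.integer(seed) + 7919L * counter$i) %% .Machine$integer.max
  }

  # Each call reports whether a genuine (gap-confirmed) split happened in
  # its subtree; unconfirmed tentative splits are reverted.
  recurse <- function(ids) {
    node <- list(ids = ids, profile = NULL, outliers = character(),
                 tentative = FALSE, children = list())
    n <- length(ids)
    if (n < 2L * minSize)
      return(list(clusters = list(ids), node = node, confirmed = FALSE))
    prof <- gapStatistic(X[ids, , drop = FALSE],
                         kMax = min(kMax, n - 1L), B = B, engine = engine,
                         seed = nextSeed(), nstart = nstart)
    node$profile <- prof
    k <- prof@chosenK
    if (k > 1L) {
      labs <- withLocalSeed(nextSeed(),
                            .clusterEngine(X[ids, , drop = FALSE], k,
                                           engine, nstart))
      clusters <- list()
      for (l in sort(unique(labs))) {
        sub <- recurse(ids[labs == l])
        clusters <- c(clusters, sub$clusters)
        node$children <- c(node$children, list(sub$node))
      }
      return(list(clusters = clusters, node = node, confirmed = TRUE))
    }
    # gap says one cluster: probe with a tentative binary split
    labs2 <- withLocalSeed(nextSeed(),
                           .clusterEngine(X[ids, , drop = FALSE], 2L,
                                          engine, nstart))
    sizes <- table(labs2)
    node$tentative <- TRUE
    if (min(sizes) < minSize) {
      # a tiny side would halt the recursion: set it aside, re-test the
      # rest, and reattach the outliers to the nearest resulting cluster
      small <- names(sizes)[which.min(sizes)]
      outliers <- ids[labs2 == small]
      rest <- ids[labs2 != small]
      node$outliers <- outliers
      sub <- recurse(rest)
      node$children <- list(sub$node)
      clusters <- sub$clusters
      cents <- lapply(clusters, function(cl)
        colMeans(X[cl, , drop = FALSE]))
      for (o in outliers) {
        dd <- vapply(cents, function(ce) sum((X[o, ] - ce)^2), numeric(1))
        j <- which.min(dd)
        clusters[[j]] <- c(clusters[[j]], o)
      }
      return(list(clusters = clusters, node = node,
                  confirmed = sub$confirmed))
    }
    # both sides substantial: keep the split only if the gap statistic
    # confirms genuine structure deeper down, otherwise revert
    sub1 <- recurse(ids[labs2 == names(sizes)[1]])
    sub2 <- recurse(ids[labs2 == names(sizes)[2]])
    if (sub1$confirmed || sub2$confirmed) {
      node$children <- list(sub1$node, sub2$node)
      return(list(clusters = c(sub1$clusters, sub2$clusters), node = node,
                  confirmed = TRUE))
    }
    list(clusters = list(ids), node = node, confirmed = FALSE)
  }

  res <- recurse(rownames(X))
  labels <- integer(nrow(X))
  names(labels) <- rownames(X)
  for (i in seq_along(res$clusters)) labels[res$clusters[[i]]] <- i
  part <- new("PartPartition", labels = labels, engine = engine,
              B = as.integer(B), minSize = as.integer(minSize),
              kMax = as.integer(kMax), seed = as.integer(seed),
              tree = res$node)
  validObject(part)
  part
}

#' Propagate a nest-level partition to specimens
#'
#' Nest-centroid clustering assigns nests; member specimens inherit their
#' nest's label.
#'
#' @param partition A [PartPartition-class] over nest ids.
#' @param grouping Nest grouping from [groupByNest()].
#' @return Named integer vector of labels per specimen.
#' @export
propagateToSpecimens <- function(partition, grouping) {
  labs <- partitionLabels(partition)
  miss <- setdiff(names(grouping), names(labs))
  if (length(miss))
    stop("partition lacks label for nest(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- integer(0)
  for (nest in names(grouping)) {
    v <- rep(labs[[nest]], length(grouping[[nest]]))
    names(v) <- grouping[[nest]]
    out <- c(out, v)
  }
  out
}
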