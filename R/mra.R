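#' Isometric size
#'
#' Projection of the log trait vector onto the isometric axis (all traits
#' growing in proportion), reported as the mean of the log trait values per
#' specimen — the projection up to the constant `1/sqrt(p)` factor, which
#' is omitted so the value reads as a log of geometric-mean size.
#'
#' @param x A [MorphoTable-class] or a specimens x traits positive matrix.
#' @return Named numeric vector of isometric size per specimen.
#' @export
isosize <- function(x) {
  m <- if (is(x, "MorphoTable")) traitMatrix(x) else as.matrix(x)
  if (any(m <= 0, na.rm = TRUE)) stop("all traits must be positive")
  rowMeans(log(m))
}

#' Isometry-free shape scores
#'
#' Log traits are column-centered and each specimen's vector projected onto
#' the orthogonal complement of the isometric axis in trait space (removing
#' proportional size variation); the principal components of the projected
#' data are the shape scores. Multiplying every trait of a specimen by a
#' common factor leaves its shape scores unchanged. Shape may still
#' co-vary with size across specimens — that residual covariation is
#' allometry, which this decomposition exposes rather than removes.
#'
#' @param x A [MorphoTable-class] or specimens x traits positive matrix
#'   with at least 2 specimens.
#' @return Specimens x components matrix of shape scores.
#' @export
shapeProjection <- function(x) {
  m <- if (is(x, "MorphoTable")) traitMatrix(x) else as.matrix(x)
  if (nrow(m) < 2) stop("at least 2 specimens required")
  if (any(m <= 0, na.rm = TRUE)) stop("all traits must be positive")
  L <- log(m)
  Lc <- sweep(L, 2, colMeans(L))
  S <- Lc - rowMeans(Lc)  # project out the isometric (all-ones) direction
  pc <- stats::prcomp(S, center = FALSE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  scores <- pc$x[, keep, drop = FALSE]
  rownames(scores) <- rownames(m)
  scores
}

# Optimal single-threshold classification error of a 1-D score (oriented so
# group 1 has the larger mean): fraction misclassified by the best cut.
.thresholdError <- function(v, grp) {
  o <- order(v)
  v <- v[o]; grp <- grp[o]
  n <- length(v)
  # cut after position i: predict group 2 below, group 1 above
  g1 <- cumsum(grp == 1)          # group-1 count at or below i
  g2 <- sum(grp == 2) - cumsum(grp == 2)  # group-2 count above i
  errs <- g1 + g2                 # misclassified for cut after i
  errs <- c(sum(grp == 2), errs)  # cut below everything
  i <- which.min(errs) - 1L
  thr <- if (i == 0) v[1] - abs(v[1]) * 1e-6 - 1e-9
         else if (i == n) v[n] + abs(v[n]) * 1e-6 + 1e-9
         else (v[i] + v[i + 1]) / 2
  list(error = errs[i + 1L] / n, threshold = thr)
}

# Leave-one-out error of the optimal-threshold rule on a 1-D score.
.thresholdErrorLoo <- function(v, grp) {
  n <- length(v)
  wrong <- 0L
  for (i in seq_len(n)) {
    fit <- .thresholdError(v[-i], grp[-i])
    pred <- if (v[i] > fit$threshold) 1L else 2L
    if (pred != grp[i]) wrong <- wrong + 1L
  }
  wrong / n
}

#' LDA ratio extractor: best diagnostic trait ratios between taxa
#'
#' Scores every unordered pair of traits as a candidate diagnostic ratio
#' between groups. The log-ratio `log(numerator) - log(denominator)` is
#' scored by the standardized group-mean difference (two groups; pooled
#' within-group SD) or the one-dimensional discriminant criterion
#' (between-group over within-group sum of squares; more groups).
#' Candidates are ranked by score, ties broken lexicographically by trait
#' codes, and each two-group candidate carries the misclassification error
#' of the optimal single-threshold rule on the ratio (resubstitution, plus
#' a leave-one-out estimate) and the decision boundary on the ratio scale.
#' Ratios are oriented so the first group has the larger mean ratio; A/B
#' and B/A are the same candidate.
#'
#' @param table A [MorphoTable-class] (or specimens x traits matrix).
#' @param labels Named group labels covering the specimens to contrast (2+
#'   groups, each with at least 2 members); specimens not named are
#'   ignored.
#' @param topN Number of ranked candidates to return (default 10).
#' @param loo Also compute the leave-one-out threshold error (two groups
#'   only; default `TRUE`).
#' @return List with `candidates` (data.frame: `numerator`, `denominator`,
#'   `score`, `error`, `errorLOO`, `threshold`), `plottingPair` (the two
#'   top-ranked candidates, to plot one against the other), `isosize`, and
#'   `groups` (the group levels, first = reference for orientation).
#' @export
ldaRatioExtract <- function(table, labels, topN = 10, loo = TRUE) {
  m <- if (is(table, "MorphoTable")) traitMatrix(table) else as.matrix(table)
  labels <- labels[!is.na(labels)]
  ids <- intersect(rownames(m), names(labels))
  m <- m[ids, , drop = FALSE]
  labels <- labels[ids]
  grp <- factor(labels)
  if (nlevels(grp) < 2) stop("at least 2 groups required")
  if (any(table(grp) < 2)) stop("every group needs at least 2 members")
  L <- log(m)
  codes <- colnames(m)
  two <- nlevels(grp) == 2
  gi <- as.integer(grp)
  rows <- list()
  dropped <- character()
  for (i in seq_len(length(codes) - 1)) {
    for (j in (i + 1):length(codes)) {
      r <- L[, i] - L[, j]
      if (two) {
        m1 <- mean(r[gi == 1]); m2 <- mean(r[gi == 2])
        v1 <- stats::var(r[gi == 1]); v2 <- stats::var(r[gi == 2])
        n1 <- sum(gi == 1); n2 <- sum(gi == 2)
        sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
        if (sp == 0) {
          if (m1 == m2) {
            dropped <- c(dropped, paste0(codes[i], "/", codes[j]))
            next
          }
          sp <- .Machine$double.eps  # perfectly separated, zero spread
        }
        sc <- abs(m1 - m2) / sp
        num <- i; den <- j; rr <- r
        if (m1 < m2) { num <- j; den <- i; rr <- -r }
        fit <- .thresholdError(rr, gi)
        rows[[length(rows) + 1L]] <- data.frame(
          numerator = codes[num], denominator = codes[den],
          score = sc, error = fit$error,
          errorLOO = if (loo) .thresholdErrorLoo(rr, gi) else NA_real_,
          threshold = exp(fit$threshold), stringsAsFactors = FALSE)
      } else {
        gm <- tapply(r, grp, mean)
        tot <- mean(r)
        ssb <- sum(tapply(r, grp, length) * (gm - tot)^2)
        ssw <- sum((r - gm[grp])^2)
        if (ssw == 0 && ssb == 0) {
          dropped <- c(dropped, paste0(codes[i], "/", codes[j]))
          next
        }
        sc <- if (ssw == 0) Inf else ssb / ssw
        num <- i; den <- j
        if (gm[1] < gm[nlevels(grp)]) { num <- j; den <- i }
        rows[[length(rows) + 1L]] <- data.frame(
          numerator = codes[num], denominator = codes[den],
          score = sc, error = NA_real_, errorLOO = NA_real_,
          threshold = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(dropped))
    warning("degenerate ratio(s) excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$score, cand$numerator, cand$denominator), ]
  rownames(cand) <- NULL
  list(candidates = utils::head(cand, topN),
       plottingPair = utils::head(cand, 2),
       isosize = isosize(m),
       groups = levels(grp))
}
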