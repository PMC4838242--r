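# O(n^3) Hungarian algorithm (potentials formulation); returns, per row of
# the square cost matrix, the assigned column of the minimum-cost perfect
# matching. Used to match cluster labels across partitions; no assignment
# solver is available among the package's dependencies.
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j + 1] = row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) out[p[j + 1]] <- j
  out
}

#' Align two partitions and flag incongruently classified observations
#'
#' Finds the cluster-label bijection between two partitions that maximizes
#' the number of agreeing observations (optimal assignment on the
#' contingency table). Observations whose matched labels agree are
#' congruent; the rest are wildcards — they receive no prior species
#' hypothesis and will be classified purely by LDA posterior.
#'
#' @param p1,p2 [PartPartition-class] objects (or named label vectors) over
#'   the same observation set.
#' @return List with `mapping` (named vector: cluster of `p1` -> matched
#'   cluster of `p2`), `congruent` and `wildcard` (character vectors of
#'   observation ids), and `agreement` (fraction congruent).
#' @export
alignPartitions <- function(p1, p2) {
  l1 <- if (is(p1, "PartPartition")) partitionLabels(p1) else p1
  l2 <- if (is(p2, "PartPartition")) partitionLabels(p2) else p2
  if (!setequal(names(l1), names(l2)))
    stop("partitions cover different observation sets")
  l2 <- l2[names(l1)]
  c1 <- sort(unique(l1))
  c2 <- sort(unique(l2))
  k <- max(length(c1), length(c2))
  cont <- matrix(0, k, k)
  tab <- table(factor(l1, levels = c1), factor(l2, levels = c2))
  cont[seq_along(c1), seq_along(c2)] <- tab
  asg <- .hungarian(max(cont) - cont)
  mapping <- vapply(seq_along(c1), function(i) {
    j <- asg[i]
    if (j <= length(c2)) c2[j] else NA_integer_
  }, c2[1])
  names(mapping) <- as.character(c1)
  agree <- !is.na(mapping[as.character(l1)]) &
    mapping[as.character(l1)] == l2
  list(mapping = mapping,
       congruent = names(l1)[agree],
       wildcard = names(l1)[!agree],
       agreement = mean(agree))
}

#' Build the prior species hypothesis from two engine partitions
#'
#' Observations congruently classified by the two partitioning runs get a
#' prior cluster label; incongruently classified observations become
#' wildcards with no prior imposed on their classification.
#'
#' @param p1,p2 [PartPartition-class] objects (or named label vectors) over
#'   the same observations; `p1` supplies the label space.
#' @return A [SpeciesHypothesis-class] with priors and wildcard flags set
#'   and no final labels yet.
#' @export
priorHypothesis <- function(p1, p2) {
  l1 <- if (is(p1, "PartPartition")) partitionLabels(p1) else p1
  al <- alignPartitions(p1, p2)
  prior <- paste0("C", l1)
  names(prior) <- names(l1)
  prior[al$wildcard] <- NA_character_
  wc <- is.na(prior)
  prov <- ifelse(wc, "wildcard: engines disagreed", "prior: congruent")
  names(prov) <- names(prior)
  new("SpeciesHypothesis", prior = prior, wildcard = wc,
      final = character(), provenance = prov, classification = list())
}

#' A hypothesis from known labels (no wildcards)
#'
#' Convenience constructor used when priors come from deposited species
#' labels or simulation ground truth rather than from partition congruence.
#'
#' @param labels Named character vector of class labels per specimen; `NA`
#'   marks a wildcard.
#' @return A [SpeciesHypothesis-class].
#' @export
labelHypothesis <- function(labels) {
  wc <- is.na(labels)
  prov <- ifelse(wc, "wildcard", "prior: given label")
  names(prov) <- names(labels)
  new("SpeciesHypothesis", prior = labels, wildcard = wc,
      final = character(), provenance = prov, classification = list())
}

# MASS::lda emits a collinearity warning on trait sets that are strongly
# size-correlated by design; muffle only that warning.
.ldaQuiet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("collinear", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Confirm a species hypothesis by leave-one-out cross-validated LDA
#'
#' For every non-wildcard specimen, a linear discriminant classifier is
#' trained on all other non-wildcard specimens (raw trait values) and the
#' held-out specimen is predicted; the confusion of priors against LOOCV
#' predictions measures how well the hypothesized clusters separate.
#' Wildcard specimens take the class with the highest posterior under the
#' model trained on all non-wildcard specimens; they never enter training.
#' LOOCV-misclassified specimens keep their prior label in the final
#' labeling (misclassification counts against the success rate, it does not
#' reassign), so success rates are computed over non-wildcard specimens.
#'
#' @param table A [MorphoTable-class] with complete traits for all
#'   specimens named in the hypothesis.
#' @param hypothesis A [SpeciesHypothesis-class]; every prior class needs
#'   at least 2 members.
#' @param equalPriors If `TRUE`, equal class prior probabilities; default
#'   proportional to class sizes.
#' @return The updated [SpeciesHypothesis-class]: final labels set and
#'   `classificationSummary()` carrying `confusion` (prior x predicted),
#'   `perClass`, `overall` and `misclassified` specimen ids.
#' @export
loocvLda <- function(table, hypothesis, equalPriors = FALSE) {
  stopifnot(is(hypothesis, "SpeciesHypothesis"))
  ids <- names(priorLabels(hypothesis))
  X <- traitMatrix(table)[ids, , drop = FALSE]
  if (any(!stats::complete.cases(X)))
    stop("complete trait vectors required for LOOCV-LDA")
  prior <- priorLabels(hypothesis)
  wild <- isWildcard(hypothesis)
  cls <- factor(prior[!wild])
  if (nlevels(cls) < 2) stop("at least 2 prior classes required")
  sizes <- table(cls)
  if (any(sizes < 2))
    stop("prior class(es) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  Xt <- X[!wild, , drop = FALSE]
  pr <- if (equalPriors) rep(1 / nlevels(cls), nlevels(cls))
        else as.vector(sizes) / sum(sizes)
  cv <- .ldaQuiet(MASS::lda(Xt, grouping = cls, prior = pr, CV = TRUE))
  confusion <- table(prior = cls, predicted = cv$class)
  perClass <- diag(confusion) / rowSums(confusion)
  overall <- sum(diag(confusion)) / sum(confusion)
  mis <- rownames(Xt)[as.character(cv$class) != as.character(cls)]

  final <- prior
  prov <- hypothesis@provenance
  prov[mis] <- "prior kept; LOOCV-LDA disagreed"
  if (any(wild)) {
    model <- .ldaQuiet(MASS::lda(Xt, grouping = cls, prior = pr))
    pred <- stats::predict(model, X[wild, , drop = FALSE])
    final[wild] <- as.character(pred$class)
    prov[wild] <- "wildcard: assigned by LDA posterior"
  }
  new("SpeciesHypothesis", prior = prior, wildcard = wild, final = final,
      provenance = prov,
      classification = list(confusion = confusion, perClass = perClass,
                            overall = overall, misclassified = mis))
}

#' Merge prior clusters not confirmed by LOOCV-LDA
#'
#' A pair of prior clusters whose separation is not convincingly confirmed
#' — either member's per-class LOOCV success falls below `threshold` with
#' its errors concentrated in the other member — is lumped into one class,
#' and the LOOCV is re-run; this repeats until every class meets the
#' threshold or no error-concentrated pair remains.
#'
#' @param table A [MorphoTable-class].
#' @param hypothesis A confirmed [SpeciesHypothesis-class] (run through
#'   [loocvLda()] first; it is re-run here after each merge).
#' @param threshold Per-class success below which a cluster pair is a merge
#'   candidate, in `(0, 1]` (default 0.90).
#' @param equalPriors Passed to [loocvLda()].
#' @return The stabilized [SpeciesHypothesis-class] after merging; merged
#'   classes get the concatenated label `"a+b"`.
#' @export
mergeUnconfirmed <- function(table, hypothesis, threshold = 0.90,
                             equalPriors = FALSE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  hyp <- if (length(hypothesis@classification)) hypothesis
         else loocvLda(table, hypothesis, equalPriors)
  repeat {
    cs <- classificationSummary(hyp)
    conf <- cs$confusion
    perClass <- cs$perClass
    weak <- names(perClass)[perClass < threshold]
    if (!length(weak)) break
    merged <- FALSE
    for (a in weak[order(perClass[weak])]) {
      row <- conf[a, ]
      row[a] <- 0
      if (sum(row) == 0) next
      b <- colnames(conf)[which.max(row)]
      # errors concentrated in b: b absorbs the majority of a's errors
      if (row[b] <= sum(row) / 2) next
      prior <- priorLabels(hyp)
      newlab <- paste(sort(c(a, b)), collapse = "+")
      prior[!is.na(prior) & prior %in% c(a, b)] <- newlab
      hyp2 <- labelHypothesis(prior)
      hyp2@provenance[prior %in% newlab & !is.na(prior)] <-
        paste0("merged cluster pair ", a, ", ", b)
      if (nlevels(factor(prior[!is.na(prior)])) < 2) {
        hyp2@final <- ifelse(is.na(prior), prior, prior)
        hyp2@final[is.na(hyp2@final)] <- unique(prior[!is.na(prior)])[1]
        names(hyp2@final) <- names(prior)
        return(hyp2)
      }
      hyp <- loocvLda(table, hyp2, equalPriors)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  hyp
}
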