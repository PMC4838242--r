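#' Run the full species-delimitation pipeline
#'
#' Orchestrates the complete protocol on a specimen-level trait table:
#' nest grouping, nest-group LDA and centroid scores, the dendrogram,
#' recursive Gap partitioning with one or two base engines, congruence /
#' wildcard reconciliation into a prior species hypothesis, confirmatory
#' LOOCV-LDA with wildcard posterior assignment, merging of unconfirmed
#' sibling clusters, diagnostic-ratio extraction between the final
#' classes, an optional key-consistency check against deposited species
#' labels, and the per-class summary. Any stage error aborts with the
#' stage name; when `outputDir` is given every intermediate artifact is
#' written there as plain text/CSV.
#'
#' @param table A [MorphoTable-class] (e.g. from [readSpecimenTable()] or
#'   [simulateDataset()]).
#' @param unit Clustering unit, `"nest"` (default; partitions nest
#'   centroids and propagates labels to member specimens) or
#'   `"specimen"`.
#' @param linkage Dendrogram linkage (see [buildDendrogram()]).
#' @param engines Base engines for PART (default both `"hclust"` and
#'   `"kmeans"`; with a single engine every congruent specimen keeps its
#'   label and there are no wildcards).
#' @param B Gap reference datasets per split (study protocol: 500).
#' @param minSize,kMax PART recursion controls (see [partRecursive()]).
#' @param mergeThreshold LOOCV per-class success below which
#'   error-concentrated cluster pairs are lumped (see
#'   [mergeUnconfirmed()]).
#' @param seed Integer seed; all stochastic stages derive their seeds from
#'   it.
#' @param outputDir Optional directory for stage outputs.
#' @return List with `config`, `table`, `grouping`, `ldaModel`, `scores`,
#'   `centroids`, `dendrogram`, `partitions` (per engine),
#'   `priorHypothesis`, `hypothesis` (final, after merge), `ratioResults`
#'   (per final class pair), `keyCheck` (or `NULL`), `summary`,
#'   `specimenIds`.
#' @export
runPipeline <- function(table, unit = c("nest", "specimen"),
                        linkage = "ward", engines = c("hclust", "kmeans"),
                        B = 500, minSize = 3, kMax = 10,
                        mergeThreshold = 0.90, seed = 1L,
                        outputDir = NULL) {
  unit <- match.arg(unit)
  config <- list(unit = unit, linkage = linkage, engines = engines, B = B,
                 minSize = minSize, kMax = kMax,
                 mergeThreshold = mergeThreshold, seed = as.integer(seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  table <- stage("validate", {
    stopifnot(is(table, "MorphoTable"))
    completeTraitTable(table)
  })
  grouping <- stage("nest-grouping", groupByNest(table))
  model <- stage("nest-lda", fitNestLDA(table, grouping))
  scores <- stage("scores", projectScores(model, table))
  centroids <- stage("centroids", nestCentroids(scores, grouping))
  X <- if (unit == "nest") centroids else scores
  dendro <- stage("dendrogram", {
    labs <- if (unit == "nest") rownames(centroids) else rownames(scores)
    sp <- speciesLabels(table)
    if (unit == "specimen" && any(!is.na(sp)))
      labs <- paste0(ifelse(is.na(sp), "?", sp), "-", colnames(table))
    buildDendrogram(X, linkage = linkage, labels = labs)
  })

  partitions <- list()
  for (i in seq_along(engines)) {
    eng <- engines[i]
    partitions[[eng]] <- stage(paste0("part-", eng),
                               partRecursive(X, engine = eng, B = B,
                                             minSize = minSize,
                                             kMax = kMax,
                                             seed = seed + 101L * i))
  }

  specLabels <- stage("propagate", {
    lapply(partitions, function(p) {
      if (unit == "nest") propagateToSpecimens(p, grouping)
      else partitionLabels(p)
    })
  })

  prior <- stage("congruence", {
    if (length(specLabels) >= 2)
      priorHypothesis(specLabels[[1]], specLabels[[2]])
    else {
      v <- paste0("C", specLabels[[1]])
      names(v) <- names(specLabels[[1]])
      labelHypothesis(v)
    }
  })
  prior <- stage("congruence", {
    # a prior imposed on fewer than 2 specimens cannot be cross-validated;
    # such specimens are demoted to wildcards and assigned by posterior
    p <- priorLabels(prior)
    sizes <- table(p[!is.na(p)])
    tooSmall <- names(sizes)[sizes < 2]
    if (length(tooSmall)) {
      warning("prior class(es) with a single member demoted to wildcard: ",
              paste(tooSmall, collapse = ", "))
      p[!is.na(p) & p %in% tooSmall] <- NA
      h <- labelHypothesis(p)
      h@provenance[is.na(p) & !isWildcard(prior)] <-
        "wildcard: singleton prior class"
      h
    } else prior
  })
  confirmed <- stage("loocv-lda", loocvLda(table, prior))
  final <- stage("merge", mergeUnconfirmed(table, confirmed,
                                           threshold = mergeThreshold))

  ratioResults <- stage("mra", {
    labs <- finalLabels(final)
    cls <- sort(unique(labs))
    out <- list()
    if (length(cls) >= 2) {
      for (i in seq_len(length(cls) - 1)) {
        for (j in (i + 1):length(cls)) {
          sel <- labs[labs %in% c(cls[i], cls[j])]
          if (min(table(sel)) < 2) next
          nm <- paste0(cls[i], " vs ", cls[j])
          out[[nm]] <- ldaRatioExtract(table, sel, topN = 3, loo = FALSE)
        }
      }
    }
    out
  })

  keyCheck <- stage("key", {
    sp <- speciesLabels(table)
    if (any(!is.na(sp))) keyConsistency(table) else NULL
  })

  summaryTab <- stage("summary", {
    labs <- finalLabels(final)
    speciesSummary(table, labels = labs)
  })

  result <- list(config = config, table = table, grouping = grouping,
                 ldaModel = model, scores = scores, centroids = centroids,
                 dendrogram = dendro, partitions = partitions,
                 priorHypothesis = prior, hypothesis = final,
                 ratioResults = ratioResults, keyCheck = keyCheck,
                 summary = summaryTab, specimenIds = colnames(table))

  if (!is.null(outputDir)) stage("write-outputs", {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeSpecimenTable(table, file.path(outputDir, "table.csv"))
    exportNewick(dendro, file.path(outputDir, "dendrogram.nwk"))
    utils::write.csv(mergeTable(dendro),
                     file.path(outputDir, "merges.csv"),
                     row.names = FALSE)
    for (eng in names(partitions)) {
      p <- partitions[[eng]]
      utils::write.csv(
        data.frame(observation = names(partitionLabels(p)),
                   cluster = partitionLabels(p), engine = eng,
                   B = p@B, minSize = p@minSize, seed = p@seed),
        file.path(outputDir, paste0("partition-", eng, ".csv")),
        row.names = FALSE)
    }
    labs <- finalLabels(final)
    utils::write.csv(
      data.frame(specimen = names(labs),
                 prior = priorLabels(final)[names(labs)],
                 final = labs,
                 provenance = final@provenance[names(labs)]),
      file.path(outputDir, "final-labels.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(classificationSummary(final)$confusion),
                     file.path(outputDir, "confusion.csv"),
                     row.names = FALSE)
    utils::write.csv(summaryTab, file.path(outputDir, "summary.csv"),
                     row.names = FALSE)
    writeLines(renderRunReport(result), file.path(outputDir, "report.md"))
  })
  result
}
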