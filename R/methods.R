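#' @include AllClasses.R
NULL

#' Accessors for MorphoTable and friends
#'
#' `traitMatrix` returns the specimens x traits matrix (micrometres);
#' `specimenIds`, `nestIds`, `speciesLabels` and `elevations` return the
#' corresponding per-specimen metadata; `speciesLabels<-` replaces the
#' species labels.
#'
#' @param x A [MorphoTable-class].
#' @param value Replacement character vector (length one or n specimens).
#' @return `traitMatrix`: numeric matrix; the others: vectors named by
#'   specimen id.
#' @name morphotable-accessors
NULL

#' @rdname morphotable-accessors
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))

#' @rdname morphotable-accessors
#' @export
setMethod("traitMatrix", "MorphoTable", function(x)
  t(SummarizedExperiment::assay(x, "traits")))

#' @rdname morphotable-accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname morphotable-accessors
#' @export
setMethod("specimenIds", "MorphoTable", function(x) colnames(x))

#' @rdname morphotable-accessors
#' @export
setGeneric("nestIds", function(x) standardGeneric("nestIds"))

#' @rdname morphotable-accessors
#' @export
setMethod("nestIds", "MorphoTable", function(x) {
  v <- as.character(SummarizedExperiment::colData(x)$nest_id)
  names(v) <- colnames(x)
  v
})

#' @rdname morphotable-accessors
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname morphotable-accessors
#' @export
setMethod("speciesLabels", "MorphoTable", function(x) {
  v <- as.character(SummarizedExperiment::colData(x)$species)
  names(v) <- colnames(x)
  v
})

#' @rdname morphotable-accessors
#' @export
setGeneric("speciesLabels<-",
           function(x, value) standardGeneric("speciesLabels<-"))

#' @rdname morphotable-accessors
#' @export
setMethod("speciesLabels<-", "MorphoTable", function(x, value) {
  SummarizedExperiment::colData(x)$species <- as.character(value)
  validObject(x)
  x
})

#' @rdname morphotable-accessors
#' @export
setGeneric("elevations", function(x) standardGeneric("elevations"))

#' @rdname morphotable-accessors
#' @export
setMethod("elevations", "MorphoTable", function(x) {
  v <- as.numeric(SummarizedExperiment::colData(x)$elevation_m)
  names(v) <- colnames(x)
  v
})

#' Partition accessors
#'
#' `partitionLabels` returns the final cluster labels named by observation
#' id; `gapProfile` extracts the top-level [GapProfile-class] of a
#' partition; `chosenK` the selected number of clusters of a profile.
#'
#' @param x A [PartPartition-class] or [GapProfile-class].
#' @name partition-accessors
NULL

#' @rdname partition-accessors
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' @rdname partition-accessors
#' @export
setMethod("partitionLabels", "PartPartition", function(x) x@labels)

#' @rdname partition-accessors
#' @export
setGeneric("gapProfile", function(x) standardGeneric("gapProfile"))

#' @rdname partition-accessors
#' @export
setMethod("gapProfile", "PartPartition", function(x) x@tree$profile)

#' @rdname partition-accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname partition-accessors
#' @export
setMethod("chosenK", "GapProfile", function(x) x@chosenK)

#' SpeciesHypothesis accessors
#'
#' `priorLabels`/`finalLabels` return per-specimen labels (`NA` prior marks
#' a wildcard); `isWildcard` the wildcard flags; `classificationSummary`
#' the latest LOOCV confusion matrix and success rates.
#'
#' @param x A [SpeciesHypothesis-class].
#' @name hypothesis-accessors
NULL

#' @rdname hypothesis-accessors
#' @export
setGeneric("priorLabels", function(x) standardGeneric("priorLabels"))

#' @rdname hypothesis-accessors
#' @export
setMethod("priorLabels", "SpeciesHypothesis", function(x) x@prior)

#' @rdname hypothesis-accessors
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))

#' @rdname hypothesis-accessors
#' @export
setMethod("finalLabels", "SpeciesHypothesis", function(x) x@final)

#' @rdname hypothesis-accessors
#' @export
setGeneric("isWildcard", function(x) standardGeneric("isWildcard"))

#' @rdname hypothesis-accessors
#' @export
setMethod("isWildcard", "SpeciesHypothesis", function(x) x@wildcard)

#' @rdname hypothesis-accessors
#' @export
setGeneric("classificationSummary",
           function(x) standardGeneric("classificationSummary"))

#' @rdname hypothesis-accessors
#' @export
setMethod("classificationSummary", "SpeciesHypothesis",
          function(x) x@classification)

setMethod("show", "MorphoTable", function(object) {
  cat("MorphoTable:", ncol(object), "specimens x", nrow(object),
      "traits (micrometres)\n")
  cat("  nests:", length(unique(nestIds(object))), "\n")
  sp <- speciesLabels(object)
  if (any(!is.na(sp)))
    cat("  species labels:", length(unique(sp[!is.na(sp)])), "distinct,",
        sum(is.na(sp)), "unlabeled\n")
  else cat("  species labels: none\n")
})

setMethod("show", "NestLDA", function(object) {
  cat("NestLDA:", ncol(object@loadings), "discriminant axes over",
      nrow(object@groupMeans), "nest groups\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 4), 4), collapse = ", "),
      "\n")
  if (isTRUE(object@regularization$applied))
    cat("  within-scatter shrinkage applied, lambda =",
        signif(object@regularization$lambda, 3), "\n")
})

setMethod("show", "GapProfile", function(object) {
  cat("GapProfile (", object@engine, ", B = ", object@B, "): chosen k = ",
      object@chosenK, "\n", sep = "")
  print(data.frame(k = object@k, gap = signif(object@gap, 4),
                   se = signif(object@se, 4)), row.names = FALSE)
})

setMethod("show", "PartPartition", function(object) {
  tab <- table(object@labels)
  cat("PartPartition (", object@engine, ", B = ", object@B,
      ", minSize = ", object@minSize, "): ", length(tab),
      " clusters over ", length(object@labels), " observations\n", sep = "")
  cat("  sizes:", paste(as.integer(tab), collapse = ", "), "\n")
})

setMethod("show", "SpeciesHypothesis", function(object) {
  cat("SpeciesHypothesis:", length(object@prior), "specimens,",
      sum(object@wildcard), "wildcards\n")
  if (length(object@final))
    cat("  final classes:",
        paste(names(table(object@final)), collapse = ", "), "\n")
  if (length(object@classification))
    cat("  LOOCV overall success:",
        sprintf("%.2f%%", 100 * object@classification$overall), "\n")
})
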