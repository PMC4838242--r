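#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' MorphoTable: a specimen-level morphometric trait table
#'
#' S4 container for continuous morphometric data with nested sampling
#' structure, extending [SummarizedExperiment::SummarizedExperiment]. The
#' single assay `"traits"` holds the 22 measured traits (rows, canonical
#' order of [traitCodes()], micrometres) by specimens (columns, unique
#' CASENT-style identifiers). Column data carries at least `nest_id`
#' (collection/nest series code) and optionally `species`, `longitude`,
#' `latitude`, `elevation_m` and `dendro_name`.
#'
#' Trait values must be positive; `NA` is tolerated (such specimens are
#' excluded from multivariate stages with a warning but remain usable by the
#' identification key when the ratios it needs are computable).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases MorphoTable-class
#' @export
setClass("MorphoTable", contains = "SummarizedExperiment")

setValidity("MorphoTable", function(object) {
  msg <- character()
  if (!"traits" %in% SummarizedExperiment::assayNames(object))
    return("assay 'traits' is missing")
  a <- SummarizedExperiment::assay(object, "traits")
  codes <- traitCodes()
  if (!identical(rownames(a), codes))
    msg <- c(msg, paste0("assay rows must be exactly the 22 canonical ",
                         "trait codes in order; got: ",
                         paste(utils::head(rownames(a), 5), collapse = ", "),
                         " ..."))
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    msg <- c(msg, "specimen identifiers (column names) must be unique")
  if (any(!is.na(a) & a <= 0))
    msg <- c(msg, "trait values must be strictly positive (in micrometres)")
  cd <- SummarizedExperiment::colData(object)
  if (!"nest_id" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'nest_id'")
  } else if (any(is.na(cd$nest_id) | !nzchar(as.character(cd$nest_id)))) {
    msg <- c(msg, "nest_id must be non-empty for every specimen")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MorphoTable
#'
#' @param traits Numeric matrix of trait values in micrometres, specimens in
#'   rows and the 22 canonical trait codes in columns (any column order;
#'   reordered internally), or the transposed orientation.
#' @param specimenId Character vector of unique specimen identifiers
#'   (defaults to the matrix row names).
#' @param nestId Character vector of nest/collection series codes, one per
#'   specimen; specimens sharing a code form one nest sample.
#' @param species Optional character vector of species labels (`NA` for
#'   undetermined material).
#' @param longitude,latitude Optional decimal-degree coordinates.
#' @param elevation Optional collection elevation in metres.
#' @param dendroName Optional display label used on dendrogram leaves.
#' @param extra Optional data.frame of additional per-specimen metadata.
#' @return A validated [MorphoTable-class] object.
#' @examples
#' tr <- matrix(rep(sikoraiTraitMeans()["sikorai", ], 3), nrow = 3,
#'              byrow = TRUE, dimnames = list(paste0("CASENT", 1:3),
#'                                            traitCodes()))
#' MorphoTable(tr, nestId = c("BLF001", "BLF001", "BLF002"))
#' @export
MorphoTable <- function(traits, specimenId = rownames(traits), nestId,
                        species = NULL, longitude = NULL, latitude = NULL,
                        elevation = NULL, dendroName = NULL, extra = NULL) {
  codes <- traitCodes()
  if (!is.matrix(traits)) traits <- as.matrix(traits)
  if (all(codes %in% rownames(traits)) && !all(codes %in% colnames(traits)))
    traits <- t(traits)
  missing_codes <- setdiff(codes, colnames(traits))
  if (length(missing_codes))
    stop("missing trait column(s): ", paste(missing_codes, collapse = ", "))
  if (is.null(specimenId))
    specimenId <- paste0("specimen", seq_len(nrow(traits)))
  specimenId <- as.character(specimenId)
  a <- t(traits[, codes, drop = FALSE])
  storage.mode(a) <- "double"
  colnames(a) <- specimenId
  if (missing(nestId)) nestId <- specimenId  # singleton nests by default
  cd <- S4Vectors::DataFrame(
    nest_id = as.character(nestId),
    species = if (is.null(species)) NA_character_ else as.character(species),
    longitude = if (is.null(longitude)) NA_real_ else as.numeric(longitude),
    latitude = if (is.null(latitude)) NA_real_ else as.numeric(latitude),
    elevation_m = if (is.null(elevation)) NA_real_ else as.numeric(elevation),
    dendro_name = if (is.null(dendroName)) NA_character_
                  else as.character(dendroName),
    row.names = specimenId)
  if (!is.null(extra)) {
    for (nm in colnames(extra)) cd[[nm]] <- extra[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(traits = a), colData = cd)
  new("MorphoTable", se)
}

#' NestLDA: discriminant model fitted with nest samples as groups
#'
#' Result of the dimension-reduction step of nest-centroid clustering: a
#' linear discriminant basis obtained from the between-nest / pooled
#' within-nest generalized eigenproblem on raw trait values.
#'
#' @slot loadings Traits x retained-axes matrix of discriminant vectors.
#' @slot eigenvalues Non-increasing discriminant eigenvalues, one per axis.
#' @slot traitOrder Trait codes, the row order expected by the loadings.
#' @slot center Grand mean trait vector subtracted before projection.
#' @slot groupMeans Groups x axes matrix of nest-mean discriminant scores.
#' @slot regularization List describing within-scatter conditioning
#'   (`lambda`, shrinkage intensity toward the diagonal; `pseudoInverse`,
#'   whether a pseudo-inverse fallback was used).
#' @aliases NestLDA-class
#' @export
setClass("NestLDA", representation(
  loadings = "matrix", eigenvalues = "numeric", traitOrder = "character",
  center = "numeric", groupMeans = "matrix", regularization = "list"))

setValidity("NestLDA", function(object) {
  k <- ncol(object@loadings)
  if (length(object@eigenvalues) != k)
    return("one eigenvalue per retained axis required")
  if (k > 1 && any(diff(object@eigenvalues) > 1e-8))
    return("eigenvalues must be non-increasing")
  if (nrow(object@loadings) != length(object@traitOrder))
    return("loadings rows must match traitOrder")
  TRUE
})

#' GapProfile: the Gap statistic over a range of cluster numbers
#'
#' @slot k Candidate cluster numbers 1..kMax.
#' @slot logW Observed log within-cluster dispersion per k.
#' @slot logWstar Mean reference log dispersion per k over B draws.
#' @slot gap Gap values, `logWstar - logW`.
#' @slot se Simulation standard errors s_k (include the sqrt(1+1/B) factor).
#' @slot B Number of reference datasets.
#' @slot chosenK Selected number of clusters.
#' @slot engine Clustering engine used ("hclust" or "kmeans").
#' @aliases GapProfile-class
#' @export
setClass("GapProfile", representation(
  k = "integer", logW = "numeric", logWstar = "numeric", gap = "numeric",
  se = "numeric", B = "integer", chosenK = "integer", engine = "character"))

setValidity("GapProfile", function(object) {
  n <- length(object@k)
  if (length(object@gap) != n || length(object@se) != n ||
      length(object@logW) != n || length(object@logWstar) != n)
    return("k, logW, logWstar, gap and se must have equal length")
  if (!object@chosenK %in% object@k) return("chosenK must be among k")
  TRUE
})

#' PartPartition: cluster assignment from recursive Gap partitioning
#'
#' @slot labels Named integer vector, final cluster id per observation.
#' @slot engine Base clustering engine ("hclust" or "kmeans").
#' @slot B Reference datasets per Gap run.
#' @slot minSize Minimum cluster size; recursion stops below `2 * minSize`.
#' @slot kMax Maximum clusters considered per split.
#' @slot seed Integer seed that drove all randomness.
#' @slot tree Nested list recording the recursion: each node holds the
#'   observation ids examined, the node's [GapProfile-class], any outliers
#'   set aside by a tentative split, and child nodes.
#' @aliases PartPartition-class
#' @export
setClass("PartPartition", representation(
  labels = "integer", engine = "character", B = "integer",
  minSize = "integer", kMax = "integer", seed = "integer", tree = "list"))

setValidity("PartPartition", function(object) {
  if (is.null(names(object@labels)))
    return("labels must be named by observation id")
  if (any(table(object@labels) < 1)) return("clusters must be non-empty")
  TRUE
})

#' SpeciesHypothesis: prior and confirmed specimen classification
#'
#' Carries the prior species hypothesis produced by reconciling the two PART
#' engine partitions (congruent specimens get a prior label, incongruent
#' ones are wildcards), and, after confirmatory LOOCV-LDA, the final label
#' per specimen with provenance notes.
#'
#' @slot prior Named character vector; `NA` for wildcard specimens.
#' @slot wildcard Named logical vector, `TRUE` where no prior was imposed.
#' @slot final Named character vector of confirmed labels (may be empty
#'   before confirmation).
#' @slot provenance Named character notes ("prior", "wildcard: assigned by
#'   LDA posterior", "merged ...", ...).
#' @slot classification List with the latest LOOCV summary: `confusion`
#'   (prior x predicted table), `perClass`, `overall`, `misclassified`.
#' @aliases SpeciesHypothesis-class
#' @export
setClass("SpeciesHypothesis", representation(
  prior = "character", wildcard = "logical", final = "character",
  provenance = "character", classification = "list"))

setValidity("SpeciesHypothesis", function(object) {
  if (is.null(names(object@prior)) || is.null(names(object@wildcard)))
    return("prior and wildcard must be named by specimen id")
  if (!identical(names(object@prior), names(object@wildcard)))
    return("prior and wildcard must cover the same specimens")
  if (any(object@wildcard != is.na(object@prior)))
    return("wildcard flag must match NA priors")
  if (length(object@final) &&
      !identical(sort(names(object@final)), sort(names(object@prior))))
    return("final labels must cover exactly the specimens of the prior")
  TRUE
})
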