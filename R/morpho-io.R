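#' Read a specimen-level morphometric CSV
#'
#' Reads and validates a trait table in the revision's supplementary
#' dialect: metadata columns `casent` (unique specimen id), `species`,
#' `long`, `lat`, `dendro-name`, followed by the 22 trait columns in
#' micrometres. Additional columns are preserved as opaque per-specimen
#' metadata; in particular a `nest` (or `collection-code`) column, when
#' present, supplies nest membership. Otherwise the nest series is taken
#' from `dendro-name` (one dendrogram leaf per nest sample) and, failing
#' that, each specimen forms a singleton nest.
#'
#' @param path Path to a CSV file (UTF-8, comma separator, decimal point).
#' @param registry Trait registry governing the expected trait columns;
#'   defaults to [traitRegistry()].
#' @return A validated [MorphoTable-class]; the source path and parse notes
#'   are stored in `metadata(x)$provenance`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeSpecimenTable(simulateDataset(simulationConfig(seed = 1))$table, tf)
#' tab <- readSpecimenTable(tf)
#' @export
readSpecimenTable <- function(path, registry = traitRegistry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  codes <- registry$code
  missing_codes <- setdiff(codes, colnames(raw))
  if (length(missing_codes))
    stop("missing trait column(s): ", paste(missing_codes, collapse = ", "))
  idcol <- if ("casent" %in% colnames(raw)) "casent" else colnames(raw)[1]
  ids <- as.character(raw[[idcol]])
  if (anyDuplicated(ids))
    stop("duplicate specimen id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tr <- as.matrix(raw[, codes, drop = FALSE])
  if (!is.numeric(tr)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, codes], 2, as.numeric))) &
                   !is.na(raw[, codes]), arr.ind = TRUE)
    stop("non-numeric trait value at row ", bad[1, 1], ", column ",
         codes[bad[1, 2]])
  }
  nonpos <- which(!is.na(tr) & tr <= 0, arr.ind = TRUE)
  if (nrow(nonpos))
    stop("non-positive trait value at row ", nonpos[1, 1], ", column ",
         codes[nonpos[1, 2]])
  rownames(tr) <- ids
  getcol <- function(nm) if (nm %in% colnames(raw)) raw[[nm]] else NULL
  nest <- getcol("nest")
  if (is.null(nest)) nest <- getcol("collection-code")
  notes <- character()
  if (is.null(nest)) {
    nest <- getcol("dendro-name")
    if (!is.null(nest)) {
      notes <- c(notes, "nest membership derived from dendro-name")
    } else {
      nest <- ids
      notes <- c(notes, "no nest information; singleton nests assumed")
    }
  }
  extra_cols <- setdiff(colnames(raw),
                        c(idcol, metadataColumns(), "nest",
                          "collection-code", "elevation", codes))
  tab <- MorphoTable(
    tr, specimenId = ids, nestId = nest,
    species = getcol("species"), longitude = getcol("long"),
    latitude = getcol("lat"), elevation = getcol("elevation"),
    dendroName = getcol("dendro-name"),
    extra = if (length(extra_cols)) raw[, extra_cols, drop = FALSE])
  S4Vectors::metadata(tab)$provenance <- list(path = path, notes = notes)
  tab
}

#' Write a MorphoTable as a specimen-level CSV
#'
#' Inverse of [readSpecimenTable()]: emits the metadata columns `casent`,
#' `species`, `long`, `lat`, `dendro-name`, a `nest` column, an `elevation`
#' column when any elevation is recorded, then the 22 trait columns.
#' Round-tripping preserves trait values bit-exactly (values are printed at
#' full precision) and row order.
#'
#' @param x A [MorphoTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpecimenTable <- function(x, path) {
  stopifnot(is(x, "MorphoTable"))
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(
    casent = colnames(x),
    species = as.character(cd$species),
    long = as.numeric(cd$longitude),
    lat = as.numeric(cd$latitude),
    `dendro-name` = as.character(cd$dendro_name),
    nest = as.character(cd$nest_id),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (any(!is.na(cd$elevation_m))) df$elevation <- as.numeric(cd$elevation_m)
  df <- cbind(df, as.data.frame(traitMatrix(x)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive absolute cephalic size (CS)
#'
#' CS is the arithmetic mean of cephalic length `CL` and head-capsule width
#' `CWb`; it is the size denominator of most diagnostic ratios and is
#' derived, never measured.
#'
#' @param x A [MorphoTable-class], or a numeric vector/matrix containing
#'   `CL` and `CWb` entries (named vector or trait-named columns).
#' @return Numeric vector of CS values in micrometres, named by specimen
#'   where available.
#' @examples
#' deriveCS(c(CL = 500, CWb = 522))
#' @export
deriveCS <- function(x) {
  if (is(x, "MorphoTable")) {
    m <- traitMatrix(x)
    return((m[, "CL"] + m[, "CWb"]) / 2)
  }
  if (is.matrix(x) || is.data.frame(x)) {
    if (!all(c("CL", "CWb") %in% colnames(x)))
      stop("CL and CWb required to derive CS")
    return((x[, "CL"] + x[, "CWb"]) / 2)
  }
  if (!all(c("CL", "CWb") %in% names(x)))
    stop("CL and CWb required to derive CS")
  unname((x[["CL"]] + x[["CWb"]]) / 2)
}

#' Group specimens into nest samples
#'
#' Individuals collected from the same nest (shared collection code) are
#' assumed to be close kin and form the grouping unit of the nest-group
#' discriminant analysis.
#'
#' @param x A [MorphoTable-class].
#' @return Named list mapping nest id to the character vector of member
#'   specimen ids; the groups partition the specimen set.
#' @export
groupByNest <- function(x) {
  stopifnot(is(x, "MorphoTable"))
  if (ncol(x) == 0L) stop("empty table: no specimens to group")
  nid <- nestIds(x)
  split(names(nid), factor(nid, levels = unique(nid)))
}

#' Measurement repeatability by intraclass correlation
#'
#' Average-measure intraclass correlation coefficient for a trait measured
#' twice on the same specimens (two-way random-effects ANOVA mean squares,
#' average of the two measurements). Negative estimates are clamped to 0.
#'
#' @param first,second Numeric vectors: first and second measurement of the
#'   same specimens, equal length, n >= 3.
#' @return Repeatability R in `[0, 1]`.
#' @examples
#' set.seed(1)
#' spec <- rnorm(50, 700, 30)
#' iccRepeatability(spec + rnorm(50, 0, 2), spec + rnorm(50, 0, 2))
#' @export
iccRepeatability <- function(first, second) {
  if (length(first) != length(second))
    stop("measurement vectors must have equal length")
  n <- length(first)
  if (n < 3) stop("at least 3 specimens required")
  y <- cbind(first, second)
  if (stats::var(as.vector(y)) == 0)
    stop("zero total variance: repeatability undefined")
  k <- 2
  rowm <- rowMeans(y); colm <- colMeans(y); gm <- mean(y)
  msr <- k * sum((rowm - gm)^2) / (n - 1)           # between specimens
  msc <- n * sum((colm - gm)^2) / (k - 1)           # between measurements
  sse <- sum((y - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))                  # residual
  r <- (msr - mse) / (msr + (msc - mse) / n)
  max(0, min(1, r))
}

#' Screen traits for error variance by pairwise Pearson correlation
#'
#' Traits measured with high repeatability on size-correlated structures
#' should correlate strongly with at least one other trait; a trait whose
#' maximum absolute Pearson correlation with every other trait falls below
#' the threshold is flagged as possibly dominated by measurement error or a
#' morphological artifact. The report is advisory: no rows or columns are
#' dropped automatically.
#'
#' @param x A [MorphoTable-class] with at least 3 complete records.
#' @param threshold Correlation below which a trait is flagged (default 0.5).
#' @return List with `maxAbsCorrelation` (named per trait; `NA` for a
#'   constant trait, reported as undefined), `flagged` (character vector)
#'   and `undefined` (constant traits).
#' @export
screenTraitCorrelations <- function(x, threshold = 0.5) {
  m <- traitMatrix(x)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("at least 3 complete records required")
  const <- apply(m, 2, function(v) stats::var(v) == 0)
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- NA
  maxabs <- apply(abs(r), 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  })
  maxabs[const] <- NA_real_
  list(maxAbsCorrelation = maxabs,
       flagged = names(maxabs)[!is.na(maxabs) & maxabs < threshold],
       undefined = names(const)[const])
}

# Specimens with any missing trait cannot enter the multivariate stages;
# drop them with a warning, keeping the original column order.
completeTraitTable <- function(x) {
  keep <- stats::complete.cases(traitMatrix(x))
  if (!all(keep)) {
    warning(sum(!keep), " specimen(s) with missing trait values excluded ",
            "from multivariate analysis: ",
            paste(utils::head(colnames(x)[!keep], 5), collapse = ", "))
    x <- x[, keep]
  }
  x
}
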