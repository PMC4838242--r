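#' Per-species summary statistics of size and shape indices
#'
#' Computes, per species over individuals, the statistics of the published
#' summary-table layout: absolute cephalic size CS (micrometres) and the 21
#' ratio indices (PoOC/CL, CL/CW, CL/CWb, and 18 trait/CS ratios), each
#' with mean, sample (n-1) SD, minimum, maximum and n. Display columns
#' round ratios to three decimals and CS to the nearest micrometre; full
#' precision is retained in the numeric columns.
#'
#' @param table A [MorphoTable-class].
#' @param labels Named species labels per specimen (default: the table's
#'   species column). Unlabeled specimens are excluded with a warning.
#' @return data.frame with columns `species`, `statistic`, `n`, `mean`,
#'   `sd`, `min`, `max`, `display` (a mean, SD and range string at
#'   published precision).
#' @export
speciesSummary <- function(table, labels = speciesLabels(table)) {
  m <- traitMatrix(table)
  if (any(is.na(labels))) {
    warning(sum(is.na(labels)), " unlabeled specimen(s) excluded from the ",
            "summary")
    labels <- labels[!is.na(labels)]
  }
  ids <- intersect(rownames(m), names(labels))
  m <- m[ids, , drop = FALSE]
  labels <- labels[ids]
  idx <- cbind(CS = deriveCS(m))
  idx <- cbind(idx,
               `PoOC/CL` = m[, "PoOC"] / m[, "CL"],
               `CL/CW` = m[, "CL"] / m[, "CW"],
               `CL/CWb` = m[, "CL"] / m[, "CWb"])
  cs <- idx[, "CS"]
  for (tc in c("FRS", "SL", "EL", "MW", "PSTI", "PEW", "PPW", "SPBA",
               "SPTI", "ML", "PEL", "NOL", "MPST", "PEH", "NOH", "PPH",
               "SPST", "PPL")) {
    v <- m[, tc] / cs
    idx <- cbind(idx, v)
    colnames(idx)[ncol(idx)] <- paste0(tc, "/CS")
  }
  out <- list()
  for (sp in unique(labels)) {
    sub <- idx[labels == sp, , drop = FALSE]
    for (st in colnames(idx)) {
      v <- sub[, st]
      vsd <- if (length(v) > 1) stats::sd(v) else 0
      digits <- if (st == "CS") 0 else 3
      disp <- sprintf("%s±%s [%s, %s]",
                      round(mean(v), digits),
                      signif(vsd, 3),
                      round(min(v), digits), round(max(v), digits))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, statistic = st, n = nrow(sub),
        mean = mean(v), sd = vsd, min = min(v), max = max(v),
        display = disp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Annotate a dendrogram with partition label tracks
#'
#' Emits the dendrogram (Newick plus merge table) together with one label
#' track per partition, aligned to the dendrogram's leaf order — the
#' structure of the published figure where prior partitions from both
#' engines and the final species hypothesis are drawn as colored bars under
#' the tree.
#'
#' @param hc A dendrogram from [buildDendrogram()].
#' @param partitions Named list of label vectors (each named by leaf
#'   identifier); every leaf must have a label in each partition.
#' @param leafIds Identifiers keying the partitions, in leaf-index order
#'   (defaults to `hc$labels`).
#' @return List with `newick`, `mergeTable` and `tracks` (data.frame: leaf
#'   order, leaf id, one column per partition).
#' @export
annotateDendrogram <- function(hc, partitions, leafIds = hc$labels) {
  ord <- hc$order
  tracks <- data.frame(position = seq_along(ord), leaf = leafIds[ord],
                       stringsAsFactors = FALSE)
  for (nm in names(partitions)) {
    labs <- partitions[[nm]]
    miss <- setdiff(tracks$leaf, names(labs))
    if (length(miss))
      stop("partition '", nm, "' lacks label for leaf: ",
           paste(utils::head(miss, 5), collapse = ", "))
    tracks[[nm]] <- unname(labs[tracks$leaf])
  }
  list(newick = exportNewick(hc), mergeTable = mergeTable(hc),
       tracks = tracks)
}

#' Render a plain-text run report
#'
#' @param result A pipeline result from [runPipeline()].
#' @return Character vector of report lines (also usable with
#'   [writeLines()]).
#' @export
renderRunReport <- function(result) {
  cfg <- result$config
  lines <- c(
    "# Species-delimitation run report", "",
    paste0("seed: ", cfg$seed),
    paste0("clustering unit: ", cfg$unit),
    paste0("linkage: ", cfg$linkage),
    paste0("engines: ", paste(cfg$engines, collapse = ", ")),
    paste0("gap bootstrap B: ", cfg$B),
    paste0("minSize: ", cfg$minSize, "  kMax: ", cfg$kMax),
    paste0("LOOCV merge threshold: ", cfg$mergeThreshold), "",
    paste0("specimens: ", length(result$specimenIds),
           "  nests: ", length(result$grouping)))
  for (eng in names(result$partitions))
    lines <- c(lines, paste0("PART (", eng, "): ",
                             length(unique(partitionLabels(
                               result$partitions[[eng]]))), " clusters"))
  hyp <- result$hypothesis
  lines <- c(lines,
             paste0("wildcards: ", sum(isWildcard(hyp))),
             paste0("final classes: ",
                    length(unique(finalLabels(hyp)))),
             sprintf("LOOCV overall success: %.2f%%",
                     100 * classificationSummary(hyp)$overall))
  lines
}
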