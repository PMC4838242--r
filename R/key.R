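#' The published dichotomous key to the sikorai group
#'
#' Hard-coded encoding of the published worker key to the eight species:
#' seven couplets whose decisive predicates are printed trait-ratio
#' thresholds, with the printed qualitative character states (sculpture,
#' color, eye protrusion) and the elevation predicate of the final couplet
#' carried as advisory evidence. The key graph is a binary tree whose
#' leaves are the eight species.
#'
#' Each couplet is a list with `id` and two `arms`; an arm holds `quant`
#' (list of predicates `list(num, den, op, value)` — the first is decisive,
#' any others advisory), optional `qual` (named character states), optional
#' `elevation` (`list(op, value)` in metres, advisory), and `outcome`
#' (species name or the id of the next couplet). A ratio exactly at a
#' threshold follows the arm whose printed inequality is non-strict where
#' the wording determines one (a pronotal/propodeal spine-distance ratio of
#' exactly 2.5 keys to *sikorai*); elsewhere ties route to the second arm.
#'
#' @return Named list of 7 couplets, ids `"c1"`..`"c7"`.
#' @export
buildSikoraiKey <- function() {
  cpl <- function(id, ...) { a <- list(...); list(id = id, arms = a) }
  arm <- function(outcome, quant, qual = NULL, elevation = NULL)
    list(quant = quant, qual = qual, elevation = elevation,
         outcome = outcome)
  q <- function(num, den, op, value) list(num = num, den = den, op = op,
                                          value = value)
  key <- list(
    cpl("c1",
        arm("reticulatus",
            list(q("SL", "CS", "<", 0.73), q("NOL", "CS", "<", 0.3))),
        arm("c2",
            list(q("SL", "CS", ">=", 0.73), q("NOL", "CS", ">=", 0.3)))),
    cpl("c2",
        arm("c3", list(q("SPST", "CS", ">", 0.36)),
            qual = c(spine_shape = "curving downward, blunt, very long")),
        arm("c4", list(q("SPST", "CS", "<=", 0.36)),
            qual = c(spine_shape = "triangular, acute, shorter"))),
    cpl("c3",
        arm("retusispinosus", list(q("PoOC", "CL", ">", 0.455)),
            qual = c(vertex_sculpture = "rugose, ground areolate, dull")),
        arm("tamatavensis", list(q("PoOC", "CL", "<=", 0.455)),
            qual = c(vertex_sculpture = "smooth, shiny"))),
    cpl("c4",
        arm("c5", list(q("CW", "ML", ">", 0.73)),
            qual = c(body_color = "black", eyes = "protuberant")),
        arm("c7", list(q("CW", "ML", "<=", 0.73)),
            qual = c(body_color = "yellow to light brown",
                     eyes = "non-protuberant"))),
    cpl("c5",
        arm("modestus", list(q("CL", "CW", ">", 1.09)),
            qual = c(vertex_sculpture =
                       "inconspicuously areolate or absent, shiny")),
        arm("c6", list(q("CL", "CW", "<=", 1.09)),
            qual = c(vertex_sculpture = "coarse areolate or costate"))),
    cpl("c6",
        arm("sikorai", list(q("PSTI", "SPTI", "<=", 2.5)),
            qual = c(vertex_sculpture = "coarse areolate",
                     petiole_dorsum = "rugoso-reticulate, dull")),
        arm("striatus", list(q("PSTI", "SPTI", ">", 2.5)),
            qual = c(vertex_sculpture = "longitudinally costate",
                     petiole_dorsum = "smooth, shiny"))),
    cpl("c7",
        arm("excelsior", list(q("PSTI", "PPW", "<", 1.84)),
            elevation = list(op = ">", value = 500)),
        arm("rugosus", list(q("PSTI", "PPW", ">=", 1.84)),
            elevation = list(op = "<", value = 500))))
  names(key) <- vapply(key, `[[`, character(1), "id")
  key
}

.ratioValue <- function(traits, num, den) {
  getv <- function(code) {
    if (code == "CS") return(deriveCS(traits))
    if (!code %in% names(traits)) return(NA_real_)
    unname(traits[[code]])
  }
  getv(num) / getv(den)
}

.cmp <- function(x, op, value) switch(op,
  "<" = x < value, "<=" = x <= value,
  ">" = x > value, ">=" = x >= value,
  stop("bad comparator: ", op))

#' Run one specimen through an identification key
#'
#' Walks the key from the first couplet, deciding each couplet by its
#' arms' decisive ratio predicate. Secondary quantitative predicates,
#' qualitative character states and the elevation predicate are consulted
#' only as advisory evidence: disagreement with the decisive ratio is
#' reported as a note, never an override.
#'
#' @param traits Named numeric vector of trait values in micrometres (CS is
#'   derived internally from CL and CWb); ratios required along the taken
#'   path must be computable.
#' @param qualitative Optional named character vector of observed character
#'   states (matched by name against the couplets' advisory states).
#' @param elevation Optional collection elevation in metres.
#' @param key A key as built by [buildSikoraiKey()] (the default).
#' @return List with `species`, `path` (couplet ids taken), `values`
#'   (data.frame of evaluated decisive ratios) and `notes` (advisory
#'   disagreements, possibly empty).
#' @examples
#' applyKey(c(CL = 540, CWb = 482, SL = 360, NOL = 138,
#'            setNames(rep(200, 18), setdiff(traitCodes(),
#'                                           c("CL", "CWb", "SL", "NOL")))))
#' @export
applyKey <- function(traits, qualitative = NULL, elevation = NA_real_,
                     key = buildSikoraiKey()) {
  traits <- as.list(traits)
  path <- character()
  notes <- character()
  vals <- list()
  at <- key[[1]]$id
  for (step in seq_len(length(key) + 1L)) {
    cp <- key[[at]]
    path <- c(path, at)
    p1 <- cp$arms[[1]]$quant[[1]]
    r <- .ratioValue(traits, p1$num, p1$den)
    if (is.na(r))
      stop("ratio ", p1$num, "/", p1$den, " not computable at couplet ",
           at)
    takeFirst <- .cmp(r, p1$op, p1$value)
    arm <- cp$arms[[if (takeFirst) 1 else 2]]
    vals[[at]] <- data.frame(couplet = at,
                             ratio = paste0(p1$num, "/", p1$den),
                             value = r, threshold = p1$value,
                             arm = if (takeFirst) 1L else 2L)
    # advisory checks on the chosen arm
    if (length(arm$quant) > 1) {
      for (p in arm$quant[-1]) {
        rv <- .ratioValue(traits, p$num, p$den)
        if (!is.na(rv) && !.cmp(rv, p$op, p$value))
          notes <- c(notes, paste0(at, ": advisory ratio ", p$num, "/",
                                   p$den, " = ", signif(rv, 4),
                                   " disagrees with arm (", p$op, " ",
                                   p$value, ")"))
      }
    }
    if (!is.null(arm$qual) && !is.null(qualitative)) {
      for (nm in intersect(names(arm$qual), names(qualitative))) {
        if (!identical(unname(qualitative[nm]), unname(arm$qual[nm])))
          notes <- c(notes, paste0(at, ": qualitative '", nm,
                                   "' = '", qualitative[nm],
                                   "' disagrees with arm ('",
                                   arm$qual[nm], "')"))
      }
    }
    if (!is.null(arm$elevation) && !is.na(elevation)) {
      if (!.cmp(elevation, arm$elevation$op, arm$elevation$value))
        notes <- c(notes, paste0(at, ": elevation ", elevation,
                                 " m disagrees with arm (",
                                 arm$elevation$op, " ",
                                 arm$elevation$value, " m)"))
    }
    if (!arm$outcome %in% names(key)) {
      return(list(species = arm$outcome, path = path,
                  values = do.call(rbind, vals), notes = notes))
    }
    at <- arm$outcome
  }
  stop("key did not terminate (cyclic outcomes?)")
}

#' Check key output against assigned species labels
#'
#' Applies the key to every specimen of a labeled table and reports, per
#' species, the fraction keying out to its assigned species, with the
#' couplet paths of mismatching specimens.
#'
#' @param table A [MorphoTable-class]; elevations are used when recorded.
#' @param labels Named character vector of species labels per specimen
#'   (defaults to the table's species column); unlabeled specimens are
#'   skipped.
#' @param key The key to apply (default [buildSikoraiKey()]).
#' @return List with `agreement` (named per-species fractions; `overall`
#'   attribute-free element named `"overall"` included), `mismatches`
#'   (data.frame: specimen, assigned, keyed, path).
#' @export
keyConsistency <- function(table, labels = speciesLabels(table),
                           key = buildSikoraiKey()) {
  m <- traitMatrix(table)
  el <- elevations(table)
  labels <- labels[!is.na(labels)]
  ids <- intersect(rownames(m), names(labels))
  if (!length(ids))
    return(list(agreement = c(overall = NA_real_),
                mismatches = data.frame(specimen = character(),
                                        assigned = character(),
                                        keyed = character(),
                                        path = character())))
  keyed <- character(length(ids))
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    res <- applyKey(m[ids[i], ], elevation = el[[ids[i]]], key = key)
    keyed[i] <- res$species
    paths[i] <- paste(res$path, collapse = ">")
  }
  ok <- keyed == labels[ids]
  per <- tapply(ok, labels[ids], mean)
  mism <- data.frame(specimen = ids[!ok], assigned = labels[ids][!ok],
                     keyed = keyed[!ok], path = paths[!ok],
                     stringsAsFactors = FALSE)
  list(agreement = c(per, overall = mean(ok)), mismatches = mism)
}

#' Serialize / load a key as structured text
#'
#' Plain-text round-trippable representation (one line per arm:
#' `couplet TAB arm TAB decisive TAB advisory TAB qual TAB elevation TAB
#' outcome`) so alternative keys can be stored and loaded.
#'
#' @param key A key list as from [buildSikoraiKey()].
#' @param path File path to write to / read from.
#' @return `writeKey`: `path` invisibly; `readKey`: a key list.
#' @export
writeKey <- function(key, path) {
  fmtq <- function(p) paste0(p$num, "/", p$den, p$op, p$value)
  lines <- c("couplet\tarm\tdecisive\tadvisory\tqual\televation\toutcome")
  for (cp in key) {
    for (a in 1:2) {
      arm <- cp$arms[[a]]
      adv <- if (length(arm$quant) > 1)
        paste(vapply(arm$quant[-1], fmtq, character(1)), collapse = ";")
      else ""
      qual <- if (is.null(arm$qual)) "" else
        paste(paste0(names(arm$qual), "=", arm$qual), collapse = ";")
      elev <- if (is.null(arm$elevation)) "" else
        paste0(arm$elevation$op, arm$elevation$value)
      lines <- c(lines, paste(cp$id, a, fmtq(arm$quant[[1]]), adv, qual,
                              elev, arm$outcome, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeKey
#' @export
readKey <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  parseq <- function(s) {
    m <- regmatches(s, regexec("^([A-Za-z]+)/([A-Za-z]+)(<=|>=|<|>)(.+)$",
                               s))[[1]]
    list(num = m[2], den = m[3], op = m[4], value = as.numeric(m[5]))
  }
  key <- list()
  for (id in unique(df$couplet)) {
    arms <- lapply(1:2, function(a) {
      row <- df[df$couplet == id & df$arm == a, ]
      quant <- c(list(parseq(row$decisive)),
                 if (nzchar(row$advisory))
                   lapply(strsplit(row$advisory, ";")[[1]], parseq))
      qual <- NULL
      if (nzchar(row$qual)) {
        kv <- strsplit(strsplit(row$qual, ";")[[1]], "=")
        qual <- stats::setNames(vapply(kv, `[`, character(1), 2),
                                vapply(kv, `[`, character(1), 1))
      }
      elev <- NULL
      if (nzchar(row$elevation)) {
        m <- regmatches(row$elevation,
                        regexec("^(<=|>=|<|>)(.+)$", row$elevation))[[1]]
        elev <- list(op = m[2], value = as.numeric(m[3]))
      }
      list(quant = quant, qual = qual, elevation = elev,
           outcome = row$outcome)
    })
    key[[id]] <- list(id = id, arms = arms)
  }
  key
}
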