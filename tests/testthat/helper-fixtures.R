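# Shared fixture builders. Everything is generated in code; no data files.

# A MorphoTable from a specimens x traits matrix with minimal metadata.
makeTable <- function(traits, nestId = NULL, species = NULL,
                      elevation = NULL) {
  if (is.null(rownames(traits)))
    rownames(traits) <- sprintf("CASENT%06d", seq_len(nrow(traits)))
  if (is.null(nestId)) nestId <- rownames(traits)
  MorphoTable(traits, nestId = nestId, species = species,
              elevation = elevation)
}

# n specimens at a species' published mean trait vector, with multiplicative
# log-normal jitter of sd `noise` (0 = exact copies).
speciesMeanSpecimens <- function(species, n = 1, noise = 0, seed = 1) {
  mu <- sikoraiTraitMeans()[species, ]
  set.seed(seed)
  m <- matrix(rep(mu, each = n), n, length(mu),
              dimnames = list(sprintf("%s%03d", toupper(species), seq_len(n)),
                              names(mu)))
  if (noise > 0) m <- m * exp(matrix(rnorm(length(m), 0, noise), nrow = n))
  m
}

# A labeled table holding all eight species at (or near) their published
# trait means; optionally several specimens per species.
allSpeciesTable <- function(n = 1, noise = 0, seed = 1, withElevation = TRUE) {
  sp <- sikoraiSpecies()
  mats <- lapply(seq_along(sp), function(i)
    speciesMeanSpecimens(sp[i], n, noise, seed + i))
  traits <- do.call(rbind, mats)
  labels <- rep(sp, each = n)
  elev <- if (withElevation) rep(unname(sikoraiElevations()[sp]), each = n)
  makeTable(traits, species = labels, elevation = elev)
}

# Full-rank random 22-trait fixture with a few multi-member nests, suitable
# for exact (unregularized) discriminant algebra: n - #nests > 22.
fullRankNestFixture <- function(nNests = 10, perNest = 4, seed = 42,
                                spread = 0.05) {
  set.seed(seed)
  p <- length(traitCodes())
  base <- log(sikoraiTraitMeans()["sikorai", ])
  rows <- list(); nid <- character()
  for (g in seq_len(nNests)) {
    shift <- rnorm(p, 0, 0.08)
    for (w in seq_len(perNest)) {
      rows[[length(rows) + 1L]] <- exp(base + shift + rnorm(p, 0, spread))
      nid <- c(nid, sprintf("NEST%02d", g))
    }
  }
  traits <- do.call(rbind, rows)
  colnames(traits) <- traitCodes()
  rownames(traits) <- sprintf("FX%04d", seq_len(nrow(traits)))
  makeTable(traits, nestId = nid)
}

# Two well-separated synthetic classes in 22 traits (about `sds` pooled SDs
# apart on the log scale along every trait).
twoClassTable <- function(n1 = 20, n2 = 20, sds = 10, sd = 0.01,
                          seed = 7) {
  set.seed(seed)
  p <- length(traitCodes())
  base <- log(sikoraiTraitMeans()["sikorai", ])
  m1 <- t(replicate(n1, exp(base + rnorm(p, 0, sd))))
  m2 <- t(replicate(n2, exp(base + sds * sd + rnorm(p, 0, sd))))
  traits <- rbind(m1, m2)
  colnames(traits) <- traitCodes()
  rownames(traits) <- sprintf("TC%04d", seq_len(n1 + n2))
  list(table = makeTable(traits),
       labels = setNames(rep(c("A", "B"), c(n1, n2)), rownames(traits)))
}

# Independent re-implementation of the gap selection rule (test oracle).
oracleGapRule <- function(gap, se, kMax = length(gap)) {
  for (k in seq_len(kMax - 1)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) return(k)
  }
  kMax
}
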