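test_that("CSV round-trip is lossless and preserves row order", {
  sim <- simulateDataset(simulationConfig(nSpecies = 2, nestsPerSpecies = 3,
                                          seed = 5))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeSpecimenTable(sim$table, tf)
  back <- readSpecimenTable(tf)
  expect_identical(specimenIds(back), specimenIds(sim$table))
  expect_identical(traitMatrix(back), traitMatrix(sim$table))
  expect_identical(nestIds(back), nestIds(sim$table))
})

test_that("reader validates columns, ids and positivity", {
  sim <- simulateDataset(simulationConfig(nSpecies = 1, nestsPerSpecies = 3,
                                          seed = 2))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeSpecimenTable(sim$table, tf)
  df <- read.csv(tf, check.names = FALSE)

  t2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(colnames(df), "PoOC")], t2, row.names = FALSE)
  expect_error(readSpecimenTable(t2), "PoOC")

  df2 <- df; df2$casent[2] <- df2$casent[1]
  write.csv(df2, t2, row.names = FALSE)
  expect_error(readSpecimenTable(t2), "duplicate")

  df3 <- df; df3$SL[2] <- -1
  write.csv(df3, t2, row.names = FALSE)
  expect_error(readSpecimenTable(t2), "non-positive.*SL")

  df4 <- df; df4$EL <- as.character(df4$EL); df4$EL[1] <- "big"
  write.csv(df4, t2, row.names = FALSE)
  expect_error(readSpecimenTable(t2), "non-numeric")
})

test_that("CS derivation is the CL/CWb mean and symmetric in its operands", {
  expect_equal(deriveCS(c(CL = 700, CWb = 700)), 700)
  expect_equal(deriveCS(c(CL = 500, CWb = 522)), 511)
  expect_error(deriveCS(c(CL = 500)), "CWb")
  m <- speciesMeanSpecimens("sikorai", n = 6, noise = 0.05, seed = 3)
  cs <- deriveCS(m)
  expect_true(all(cs >= pmin(m[, "CL"], m[, "CWb"]) &
                    cs <= pmax(m[, "CL"], m[, "CWb"])))
  swapped <- m
  swapped[, c("CL", "CWb")] <- m[, c("CWb", "CL")]
  expect_equal(unname(deriveCS(swapped)), unname(cs))
})

test_that("nest grouping partitions the specimen set", {
  sim <- simulateDataset(simulationConfig(nSpecies = 3, nestsPerSpecies = 4,
                                          seed = 9))
  g <- groupByNest(sim$table)
  expect_equal(sum(lengths(g)), ncol(sim$table))
  expect_false(any(duplicated(unlist(g))))
  expect_setequal(unlist(g), specimenIds(sim$table))

  tab <- makeTable(speciesMeanSpecimens("sikorai", n = 4))  # singleton nests
  expect_equal(length(groupByNest(tab)), 4L)
  expect_error(groupByNest(tab[, 0]), "empty")
})

test_that("ICC repeatability matches an independent ANOVA oracle", {
  expect_equal(iccRepeatability(1:10, 1:10), 1)
  set.seed(31)
  n <- 200
  spec <- rnorm(n, 0, 3)                     # specimen effect, var 9
  y1 <- 700 + spec + rnorm(n, 0, 1)
  y2 <- 700 + spec + rnorm(n, 0, 1)
  r <- iccRepeatability(y1, y2)
  # oracle: two-way ANOVA mean squares via lm/anova on the long layout
  long <- data.frame(y = c(y1, y2),
                     specimen = factor(rep(seq_len(n), 2)),
                     meas = factor(rep(1:2, each = n)))
  a <- anova(lm(y ~ specimen + meas, data = long))
  msr <- a["specimen", "Mean Sq"]; msc <- a["meas", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  expect_equal(r, (msr - mse) / (msr + (msc - mse) / n), tolerance = 1e-9)
  expect_gt(r, 0.8)

  set.seed(32)
  noise <- iccRepeatability(rnorm(200), rnorm(200))
  expect_lt(abs(noise), 0.15)

  expect_error(iccRepeatability(1:5, 1:4), "equal length")
  expect_error(iccRepeatability(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("error-variance screening flags only uncorrelated traits", {
  set.seed(8)
  base <- speciesMeanSpecimens("sikorai", n = 100, noise = 0, seed = 1)
  size <- exp(rnorm(100, 0, 0.08))
  m <- base * size                           # all traits share the size factor
  m[, "EL"] <- runif(100, 100, 200)          # one independent noise trait
  tab <- makeTable(m)
  rep <- screenTraitCorrelations(tab, threshold = 0.5)
  expect_identical(rep$flagged, "EL")

  m2 <- m
  m2[, "EL"] <- 2 * m2[, "CL"]
  rep2 <- screenTraitCorrelations(makeTable(m2), threshold = 0.5)
  expect_equal(unname(rep2$maxAbsCorrelation["EL"]), 1)
  expect_length(rep2$flagged, 0)
})

test_that("pairwise Pearson screening agrees with the explicit formula", {
  m <- speciesMeanSpecimens("modestus", n = 3, noise = 0.1, seed = 4)
  rep <- screenTraitCorrelations(makeTable(m), threshold = 0)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  byHand <- vapply(colnames(m), function(a) {
    max(abs(vapply(setdiff(colnames(m), a),
                   function(b) pearson(m[, a], m[, b]), numeric(1))))
  }, numeric(1))
  expect_equal(rep$maxAbsCorrelation, byHand, tolerance = 1e-12)
})

test_that("specimens with missing traits are excluded from multivariate use", {
  m <- speciesMeanSpecimens("sikorai", n = 6, noise = 0.02, seed = 6)
  m[2, "PPH"] <- NA
  tab <- makeTable(m)
  expect_warning(out <- MorphoPart:::completeTraitTable(tab), "excluded")
  expect_equal(ncol(out), 5L)
  expect_false(rownames(m)[2] %in% specimenIds(out))
})
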