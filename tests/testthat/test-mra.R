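test_that("isometric size is the log-scale mean and shifts under scaling", {
  m <- matrix(150, 2, 22, dimnames = list(c("u", "v"), traitCodes()))
  expect_equal(unname(isosize(m)), c(log(150), log(150)))
  m2 <- speciesMeanSpecimens("rugosus", n = 4, noise = 0.03, seed = 2)
  iso <- isosize(m2)
  expect_equal(iso, rowMeans(log(m2)), tolerance = 1e-12)
  expect_equal(unname(isosize(m2 * 3)), unname(iso) + log(3),
               tolerance = 1e-12)
  expect_error(isosize(m2 - 1e6), "positive")
})

test_that("shape scores ignore isometric size", {
  base <- speciesMeanSpecimens("excelsior", n = 1)[1, ]
  factors <- c(0.5, 0.8, 1, 1.3, 2)
  m <- t(vapply(factors, function(f) base * f, base))
  rownames(m) <- paste0("i", seq_along(factors))
  sh <- shapeProjection(m)
  for (i in 2:nrow(sh))
    expect_equal(unname(sh[i, ]), unname(sh[1, ]), tolerance = 1e-10)
})

test_that("shape projection matches a brute-force computation", {
  m <- speciesMeanSpecimens("striatus", n = 6, noise = 0.05, seed = 10)
  sh <- shapeProjection(m)
  # oracle: explicit centering, projection matrix, eigen-decomposition
  L <- log(m)
  Lc <- sweep(L, 2, colMeans(L))
  p <- ncol(L)
  P <- diag(p) - matrix(1 / p, p, p)     # complement of the all-ones axis
  S <- Lc %*% P
  ev <- eigen(crossprod(S), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-8
  oracle <- S %*% ev$vectors[, keep, drop = FALSE]
  expect_equal(ncol(sh), sum(keep))
  for (j in seq_len(ncol(sh))) {
    agree <- min(max(abs(sh[, j] - oracle[, j])),
                 max(abs(sh[, j] + oracle[, j])))
    expect_lt(agree, 1e-8)               # up to component sign
  }
  # projected data are orthogonal to the isometric direction
  expect_lt(max(abs(rowSums(S))), 1e-10)
  expect_error(shapeProjection(m[1, , drop = FALSE]), "at least 2")
})

test_that("ratio extraction finds a planted diagnostic pair", {
  set.seed(12)
  n <- 30
  p <- length(traitCodes())
  # traits are size * noisy baselines; only SL/EL carries a group contrast
  logm <- matrix(rnorm(2 * n * p, log(300), 0.2), 2 * n, p)
  colnames(logm) <- traitCodes()
  size <- rnorm(2 * n, 0, 0.3)
  logm <- logm + size
  logm[(n + 1):(2 * n), "SL"] <- logm[(n + 1):(2 * n), "SL"] + 2
  m <- exp(logm)
  rownames(m) <- sprintf("R%02d", seq_len(2 * n))
  labels <- setNames(rep(c("g1", "g2"), each = n), rownames(m))
  res <- ldaRatioExtract(makeTable(m), labels, topN = 5)
  expect_true("SL" %in% c(res$candidates$numerator[1],
                          res$candidates$denominator[1]))
  expect_lt(res$candidates$error[1], 0.05)
})

test_that("candidate scores equal brute-force pair enumeration", {
  fx <- twoClassTable(n1 = 12, n2 = 12, sds = 3, sd = 0.05, seed = 9)
  res <- ldaRatioExtract(fx$table, fx$labels, topN = 400, loo = FALSE)
  m <- log(traitMatrix(fx$table))
  g <- fx$labels[rownames(m)]
  codes <- colnames(m)
  # oracle: explicit double loop over unordered pairs
  oracle <- list()
  for (i in seq_len(length(codes) - 1)) {
    for (j in (i + 1):length(codes)) {
      r <- m[, i] - m[, j]
      r1 <- r[g == "A"]; r2 <- r[g == "B"]
      sp <- sqrt(((length(r1) - 1) * var(r1) + (length(r2) - 1) * var(r2)) /
                   (length(r1) + length(r2) - 2))
      key <- paste(sort(c(codes[i], codes[j])), collapse = "|")
      oracle[[key]] <- abs(mean(r1) - mean(r2)) / sp
    }
  }
  got <- setNames(res$candidates$score,
                  vapply(seq_len(nrow(res$candidates)), function(k)
                    paste(sort(c(res$candidates$numerator[k],
                                 res$candidates$denominator[k])),
                          collapse = "|"), character(1)))
  expect_setequal(names(got), names(oracle))
  expect_equal(got[names(oracle)], unlist(oracle)[names(oracle)],
               tolerance = 1e-10, ignore_attr = TRUE)
  # ranked by score, ties lexicographic
  expect_true(all(diff(res$candidates$score) <= 1e-12))
})

test_that("scores are invariant to positive trait rescaling", {
  fx <- twoClassTable(n1 = 10, n2 = 10, sds = 2, sd = 0.05, seed = 4)
  res1 <- ldaRatioExtract(fx$table, fx$labels, topN = 3, loo = FALSE)
  m <- traitMatrix(fx$table)
  m[, "NOH"] <- m[, "NOH"] * 500
  res2 <- ldaRatioExtract(makeTable(m), fx$labels, topN = 3, loo = FALSE)
  expect_equal(res1$candidates$score, res2$candidates$score,
               tolerance = 1e-10)
  expect_identical(res1$candidates$numerator, res2$candidates$numerator)
})

test_that("the optimal threshold is no worse than any fixed cut", {
  set.seed(8)
  v <- c(rnorm(25, 1), rnorm(25, 0))
  grp <- rep(c(1L, 2L), each = 25)
  fit <- MorphoPart:::.thresholdError(v, grp)
  for (t in seq(min(v) - 0.1, max(v) + 0.1, length.out = 50)) {
    err <- mean((v > t) != (grp == 1L))
    expect_lte(fit$error, err)
  }
  expect_lte(fit$error, 0.5)
  # the reported boundary reproduces the reported error
  expect_equal(mean((v > fit$threshold) != (grp == 1L)), fit$error)
})
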