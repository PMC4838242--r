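test_that("a single informative trait yields a single-trait axis", {
  set.seed(4)
  mu <- sikoraiTraitMeans()["sikorai", ]
  n <- 8
  traits <- matrix(rep(mu, each = 2 * n), 2 * n, length(mu),
                   dimnames = list(sprintf("S%02d", seq_len(2 * n)),
                                   names(mu)))
  traits[, "CL"] <- c(rnorm(n, 600, 1), rnorm(n, 800, 1))
  tab <- makeTable(traits, nestId = rep(c("N1", "N2"), each = n))
  fit <- suppressWarnings(fitNestLDA(tab, groupByNest(tab)))
  ld1 <- fit@loadings[, 1]
  expect_gt(abs(ld1["CL"]), 0)
  expect_lt(max(abs(ld1[setdiff(names(ld1), "CL")])),
            1e-8 * abs(ld1["CL"]))
})

test_that("discriminant axes solve the generalized eigenproblem", {
  tab <- fullRankNestFixture(nNests = 10, perNest = 4, seed = 42)
  g <- groupByNest(tab)
  fit <- fitNestLDA(tab, g, shrinkage = "none")
  expect_false(fit@regularization$applied)
  expect_lte(ncol(fit@loadings), min(22, length(g) - 1))
  expect_true(all(diff(fit@eigenvalues) <= 1e-8))

  # brute-force oracle: dense between/within scatters and a direct
  # non-symmetric eigensolve of solve(W) %*% B
  X <- traitMatrix(tab)
  grand <- colMeans(X)
  Sw <- matrix(0, 22, 22); Sb <- matrix(0, 22, 22)
  for (ids in g) {
    Xi <- X[ids, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - grand)
  }
  S <- Sw / (nrow(X) - length(g))
  eo <- eigen(solve(S) %*% Sb)
  ord <- order(-Re(eo$values))
  k <- ncol(fit@loadings)
  expect_equal(fit@eigenvalues, Re(eo$values[ord])[seq_len(k)],
               tolerance = 1e-8)
  for (j in seq_len(k)) {
    v <- Re(eo$vectors[, ord[j]])
    v <- v / sqrt(drop(t(v) %*% S %*% v))
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(fit@loadings[, j]), unname(v), tolerance = 1e-8)
  }
})

test_that("an exactly singular within-scatter errors without shrinkage", {
  # duplicated specimens within nests: zero within-nest scatter
  m <- speciesMeanSpecimens("sikorai", n = 4, noise = 0.05, seed = 9)
  m <- m[rep(1:4, each = 2), ]
  rownames(m) <- sprintf("D%02d", 1:8)
  tab <- makeTable(m, nestId = rep(c("N1", "N1", "N2", "N2"), 2))
  expect_error(fitNestLDA(tab, shrinkage = "none"), "shrinkage")
  expect_warning(fit <- fitNestLDA(tab), "conditioning")
  expect_true(fit@regularization$applied)
})

test_that("projection is the centered linear map and respects group means", {
  tab <- fullRankNestFixture(seed = 3)
  g <- groupByNest(tab)
  fit <- fitNestLDA(tab, g, shrinkage = "none")
  sc <- projectScores(fit, tab)
  # hand matrix product
  X <- traitMatrix(tab)[, fit@traitOrder]
  expect_equal(sc, sweep(X, 2, fit@center) %*% fit@loadings,
               tolerance = 1e-10)
  # a specimen equal to a nest's mean vector scores at the group mean
  nest1 <- g[[1]]
  mvec <- colMeans(traitMatrix(tab)[nest1, ])
  one <- makeTable(matrix(mvec, 1, dimnames = list("MEAN", names(mvec))))
  expect_equal(unname(projectScores(fit, one)[1, ]),
               unname(fit@groupMeans[names(g)[1], ]), tolerance = 1e-8)
  expect_error(projectScores(fit, tab[1:3, ]), "trait")
})

test_that("nest centroids are member means", {
  sc <- matrix(c(1, 2, -1, -2, 3, 4, 5, 6, 7, 8), 5, 2,
               dimnames = list(paste0("s", 1:5), c("LD1", "LD2")))
  g <- list(single = "s1", pair = c("s2", "s3"), rest = c("s4", "s5"))
  ce <- nestCentroids(sc, g)
  expect_equal(ce["single", ], sc["s1", ])
  expect_equal(unname(ce["rest", ]),
               colMeans(sc[c("s4", "s5"), ]), ignore_attr = TRUE)
  # symmetric pair at +v/-v lands on the origin
  sc2 <- rbind(v = c(2, -3), w = c(-2, 3))
  expect_equal(unname(nestCentroids(sc2, list(n = c("v", "w")))[1, ]),
               c(0, 0))
  expect_error(nestCentroids(sc, list(bad = "nope")), "no score row")
})

test_that("Ward dendrogram matches the Lance-Williams recurrence by hand", {
  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0), d = c(10.5, 4))
  hc <- buildDendrogram(pts, linkage = "ward")
  expect_equal(nrow(hc$merge), 3L)
  d <- as.matrix(dist(pts))
  # merge 1: a,b at Euclidean distance 1
  expect_equal(hc$height[1], d["a", "b"])
  # Lance-Williams ward.D2 update for the cluster {a,b} against c and d
  lw <- function(dki, dkj, dij, ni, nj, nk)
    sqrt(((ni + nk) * dki^2 + (nj + nk) * dkj^2 - nk * dij^2) /
           (ni + nj + nk))
  dab_c <- lw(d["a", "c"], d["b", "c"], d["a", "b"], 1, 1, 1)
  dab_d <- lw(d["a", "d"], d["b", "d"], d["a", "b"], 1, 1, 1)
  # merge 2: c,d (closer than either is to {a,b})
  expect_equal(hc$height[2], d["c", "d"])
  dcd_ab <- lw(dab_c, dab_d, d["c", "d"], 1, 1, 2)
  expect_equal(hc$height[3], dcd_ab, tolerance = 1e-10)
  expect_error(buildDendrogram(pts[1, , drop = FALSE]), "at least 2")
})

test_that("centroid distances are invariant to trait rescaling", {
  tab <- fullRankNestFixture(seed = 6)
  g <- groupByNest(tab)
  ce1 <- nestCentroids(projectScores(fitNestLDA(tab, g, shrinkage = "none"),
                                     tab), g)
  m2 <- traitMatrix(tab)
  m2[, "SL"] <- m2[, "SL"] * 1000
  tab2 <- makeTable(m2, nestId = nestIds(tab))
  ce2 <- nestCentroids(projectScores(fitNestLDA(tab2, groupByNest(tab2),
                                                shrinkage = "none"), tab2),
                       groupByNest(tab2))
  expect_equal(as.matrix(dist(ce1)), as.matrix(dist(ce2)),
               tolerance = 1e-6)
})

test_that("specimen order does not affect the model or the dendrogram", {
  tab <- fullRankNestFixture(seed = 12)
  set.seed(1)
  perm <- sample(ncol(tab))
  tab2 <- tab[, perm]
  f1 <- fitNestLDA(tab, shrinkage = "none")
  f2 <- fitNestLDA(tab2, shrinkage = "none")
  expect_equal(f1@loadings, f2@loadings, tolerance = 1e-8)
  g1 <- groupByNest(tab); g2 <- groupByNest(tab2)
  c1 <- nestCentroids(projectScores(f1, tab), g1)
  c2 <- nestCentroids(projectScores(f2, tab2), g2)
  expect_equal(c1[rownames(c2), ], c2, tolerance = 1e-8)
})

test_that("Newick export round-trips topology and heights", {
  tab <- fullRankNestFixture(nNests = 8, perNest = 4, seed = 8)
  g <- groupByNest(tab)
  ce <- nestCentroids(projectScores(fitNestLDA(tab, g, shrinkage = "none"),
                                    tab), g)
  hc <- buildDendrogram(ce)
  expect_equal(nrow(mergeTable(hc)), nrow(ce) - 1L)
  expect_equal(mergeTable(hc)$size[nrow(ce) - 1L], nrow(ce))
  nwk <- exportNewick(hc)
  phy <- ape::read.tree(text = nwk)
  coph <- as.matrix(stats::cophenetic(hc))
  cophPhy <- as.matrix(ape::cophenetic.phylo(phy))[rownames(coph),
                                                   colnames(coph)]
  expect_equal(cophPhy, coph, tolerance = 1e-9)
})
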