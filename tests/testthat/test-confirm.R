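test_that("the assignment solver finds the minimum-cost matching", {
  set.seed(14)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  for (rep in 1:5) {
    cost <- matrix(runif(25), 5, 5)
    asg <- MorphoPart:::.hungarian(cost)
    got <- sum(cost[cbind(1:5, asg)])
    best <- min(vapply(perms(1:5),
                       function(p) sum(cost[cbind(1:5, p)]), numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("partition alignment flags exactly the disagreeing observations", {
  ids <- sprintf("s%02d", 1:40)
  l1 <- setNames(rep(1:5, each = 8), ids)
  # same partition with permuted label names
  l2 <- setNames(c(3L, 5L, 1L, 2L, 4L)[l1], ids)
  al <- alignPartitions(l1, l2)
  expect_length(al$wildcard, 0)
  expect_equal(al$agreement, 1)

  l2b <- l2
  l2b["s09"] <- l2[["s01"]]  # move one observation across clusters
  al2 <- alignPartitions(l1, l2b)
  expect_identical(al2$wildcard, "s09")

  expect_error(alignPartitions(l1, l2[-1]), "different observation sets")
})

test_that("alignment equals exhaustive search over label bijections", {
  set.seed(6)
  ids <- sprintf("t%02d", 1:40)
  l1 <- setNames(sample(1:5, 40, replace = TRUE), ids)
  l2 <- setNames(sample(1:5, 40, replace = TRUE), ids)
  al <- alignPartitions(l1, l2)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- max(vapply(perms(1:5),
                     function(p) sum(p[l1] == l2), numeric(1)))
  expect_equal(length(al$congruent), best)
})

test_that("LOOCV-LDA separates distant classes perfectly", {
  fx <- twoClassTable(sds = 10)
  hyp <- loocvLda(fx$table, labelHypothesis(fx$labels))
  cs <- classificationSummary(hyp)
  expect_equal(cs$overall, 1)
  expect_equal(unname(cs$perClass), c(1, 1))
  expect_identical(finalLabels(hyp), fx$labels)
  expect_equal(cs$overall,
               sum(diag(cs$confusion)) / sum(cs$confusion))
})

test_that("LOOCV-LDA validates class sizes and completeness", {
  fx <- twoClassTable()
  bad <- fx$labels
  bad[bad == "B"] <- "C"
  bad[which(bad == "C")[-1]] <- "B"   # class C has a single member
  expect_error(loocvLda(fx$table, labelHypothesis(bad)), "C")
})

test_that("LOOCV success is invariant to row order and trait rescaling", {
  fx <- twoClassTable(sds = 4, seed = 3)
  base <- classificationSummary(loocvLda(fx$table,
                                         labelHypothesis(fx$labels)))
  set.seed(2)
  perm <- sample(ncol(fx$table))
  permuted <- loocvLda(fx$table[, perm],
                       labelHypothesis(fx$labels[perm]))
  expect_equal(classificationSummary(permuted)$overall, base$overall)

  m <- traitMatrix(fx$table)
  m[, "PPW"] <- m[, "PPW"] * 1000
  scaled <- loocvLda(makeTable(m), labelHypothesis(fx$labels))
  expect_equal(classificationSummary(scaled)$overall, base$overall)
})

test_that("wildcards are assigned by posterior and never train", {
  fx <- twoClassTable(sds = 10)
  labels <- fx$labels
  wildIds <- c(names(labels)[1], names(labels)[length(labels)])
  labels[wildIds] <- NA
  hyp <- loocvLda(fx$table, labelHypothesis(labels))
  fin <- finalLabels(hyp)
  expect_identical(unname(fin[wildIds]), c("A", "B"))
  expect_match(hyp@provenance[wildIds[1]], "posterior")
  # success rates are computed over non-wildcards only
  expect_equal(sum(classificationSummary(hyp)$confusion),
               sum(!isWildcard(hyp)))
})

test_that("an arbitrarily split Gaussian is lumped back together", {
  set.seed(19)
  p <- length(traitCodes())
  base <- log(sikoraiTraitMeans()["sikorai", ])
  m <- t(replicate(40, exp(base + rnorm(p, 0, 0.05))))
  colnames(m) <- traitCodes()
  rownames(m) <- sprintf("G%02d", 1:40)
  tab <- makeTable(m)
  labels <- setNames(rep(c("half1", "half2"), 20), rownames(m))
  merged <- mergeUnconfirmed(tab, labelHypothesis(labels), threshold = 0.9)
  expect_equal(length(unique(finalLabels(merged))), 1L)
  expect_match(unique(finalLabels(merged)), "half1\\+half2")
})

test_that("well-separated classes are never merged", {
  fx <- twoClassTable(sds = 10)
  hyp <- loocvLda(fx$table, labelHypothesis(fx$labels))
  kept <- mergeUnconfirmed(fx$table, hyp, threshold = 1)
  expect_equal(sort(unique(finalLabels(kept))), c("A", "B"))
  expect_error(mergeUnconfirmed(fx$table, hyp, threshold = 1.5),
               "threshold")
})

test_that("raising the merge threshold never undoes merges", {
  set.seed(23)
  p <- length(traitCodes())
  base <- log(sikoraiTraitMeans()["sikorai", ])
  # three classes: two overlapping halves plus one distant class
  m <- rbind(t(replicate(30, exp(base + rnorm(p, 0, 0.05)))),
             t(replicate(15, exp(base + 1 + rnorm(p, 0, 0.05)))))
  colnames(m) <- traitCodes()
  rownames(m) <- sprintf("M%02d", 1:45)
  tab <- makeTable(m)
  labels <- setNames(c(rep(c("x1", "x2"), 15), rep("far", 15)),
                     rownames(m))
  nClasses <- function(th)
    length(unique(finalLabels(
      mergeUnconfirmed(tab, labelHypothesis(labels), threshold = th))))
  expect_gte(nClasses(0.5), nClasses(0.95))
})
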