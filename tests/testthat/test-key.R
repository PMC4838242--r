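# Build a complete trait vector realizing given ratios, starting from a
# species' published means and overriding selected measurements.
traitVectorWith <- function(base = "sikorai", ...) {
  v <- sikoraiTraitMeans()[base, ]
  over <- list(...)
  for (nm in names(over)) v[nm] <- over[[nm]]
  v
}

test_that("the key is a binary tree over exactly the eight species", {
  key <- buildSikoraiKey()
  expect_length(key, 7)
  outcomes <- unlist(lapply(key, function(cp)
    vapply(cp$arms, `[[`, character(1), "outcome")))
  leaves <- setdiff(outcomes, names(key))
  expect_setequal(leaves, sikoraiSpecies())
  expect_equal(sum(outcomes %in% names(key)), 6)  # 6 internal links
  # each couplet's decisive predicates are mutually exclusive and exhaustive
  for (cp in key) {
    p1 <- cp$arms[[1]]$quant[[1]]
    p2 <- cp$arms[[2]]$quant[[1]]
    expect_identical(p1$num, p2$num)
    expect_identical(p1$value, p2$value)
    for (probe in p1$value + c(-0.01, 0, 0.01)) {
      expect_equal(MorphoPart:::.cmp(probe, p1$op, p1$value),
                   !MorphoPart:::.cmp(probe, p2$op, p2$value))
    }
  }
})

test_that("printed examples key out as published", {
  # very short scape and petiolar node
  cs <- 500
  v1 <- traitVectorWith("reticulatus", CL = cs * 1.08, CWb = cs * 0.92,
                        SL = 0.70 * cs, NOL = 0.27 * cs)
  r1 <- applyKey(v1)
  expect_identical(r1$species, "reticulatus")
  expect_identical(r1$path, "c1")

  # long scape, very long downcurved spines, forward eyes
  v2 <- traitVectorWith("retusispinosus")
  stopifnot(v2[["SL"]] / deriveCS(v2) > 0.73,
            v2[["SPST"]] / deriveCS(v2) > 0.36)
  r2 <- applyKey(v2)
  expect_identical(r2$species, "retusispinosus")
  expect_identical(r2$path, c("c1", "c2", "c3"))
})

test_that("every species' published mean trait vector keys to itself", {
  mu <- sikoraiTraitMeans()
  elev <- sikoraiElevations()
  for (sp in sikoraiSpecies()) {
    res <- applyKey(mu[sp, ], elevation = elev[[sp]])
    expect_identical(res$species, sp)
  }
})

test_that("threshold boundaries follow the documented tie rules", {
  # measurements are chosen so each tested ratio is *exactly* the printed
  # threshold in double precision (integer numerators over powers of ten)
  cs <- 1000
  mk <- function(...) traitVectorWith("sikorai", CL = cs, CWb = cs, ...)
  # scape ratio exactly 0.73: not reticulatus (ties to the second arm)
  at1 <- applyKey(mk(SL = 730))
  expect_false(identical(at1$species, "reticulatus"))
  expect_identical(at1$path[2], "c2")
  # spine length exactly 0.36: shorter-spine arm (couplet 4)
  at2 <- applyKey(mk(SL = 800, SPST = 360))
  expect_identical(at2$path[3], "c4")
  # postocular ratio exactly 0.455: second arm (tamatavensis)
  at3 <- applyKey(mk(SL = 800, SPST = 400, PoOC = 455))
  expect_identical(at3$species, "tamatavensis")
  # head width vs mesosoma exactly 0.73: second arm (couplet 7)
  at4 <- applyKey(mk(SL = 800, SPST = 300, CW = 730, ML = 1000))
  expect_identical(at4$path[4], "c7")
  # CL/CW exactly 1.09: second arm (couplet 6)
  at5 <- applyKey(traitVectorWith("sikorai", CL = 1090, CWb = 1090,
                                  CW = 1000, SL = 880, SPST = 320,
                                  ML = 1250))
  expect_identical(at5$path[5], "c6")
  # pronotal/propodeal spine-distance ratio exactly 2.5 keys to sikorai
  at6 <- applyKey(mk(SL = 800, SPST = 300, CW = 950, ML = 1200,
                     PSTI = 500, SPTI = 200))
  expect_identical(at6$species, "sikorai")
  # petiole ratio exactly 1.84 keys to rugosus
  at7 <- applyKey(mk(SL = 800, SPST = 300, CW = 700, ML = 1000,
                     PSTI = 460, PPW = 250))
  expect_identical(at7$species, "rugosus")
})

test_that("advisory evidence warns but never overrides the decisive ratio", {
  mu <- sikoraiTraitMeans()
  res <- applyKey(mu["excelsior", ], elevation = 100)  # lowland record
  expect_identical(res$species, "excelsior")
  expect_true(any(grepl("elevation", res$notes)))
  res2 <- applyKey(mu["modestus", ],
                   qualitative = c(body_color = "yellow to light brown"))
  expect_identical(res2$species, "modestus")
  expect_true(any(grepl("body_color", res2$notes)))
})

test_that("a missing measurement on the path is a named error", {
  v <- sikoraiTraitMeans()["sikorai", ]
  v2 <- v[setdiff(names(v), "SPST")]
  expect_error(applyKey(v2), "SPST.*c2|c2.*SPST")
})

test_that("key consistency reports per-species agreement", {
  tab <- allSpeciesTable(n = 3, noise = 0.002, seed = 5)
  kc <- keyConsistency(tab)
  expect_equal(unname(kc$agreement["overall"]), 1)
  expect_equal(nrow(kc$mismatches), 0)

  empty <- keyConsistency(allSpeciesTable(n = 1)[, 0])
  expect_true(is.na(empty$agreement["overall"]))

  one <- allSpeciesTable(n = 1)[, 1]
  kc1 <- keyConsistency(one)
  expect_equal(unname(kc1$agreement["overall"]), 1)
})

test_that("keys serialize and reload without behavioral change", {
  key <- buildSikoraiKey()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeKey(key, tf)
  back <- readKey(tf)
  mu <- sikoraiTraitMeans()
  for (sp in sikoraiSpecies()) {
    expect_identical(applyKey(mu[sp, ], key = back)$species,
                     applyKey(mu[sp, ], key = key)$species)
  }
})
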