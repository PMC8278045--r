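test_that("equal-total normalization equalizes sample totals", {
  m <- matrix(c(4, 6, 10, 20), 2,
              dimnames = list(c("A", "B"), c("PSI_r1", "PSI_r2")))
  pe <- normalizeTotal(PulldownExperiment(m))
  expect_equal(unname(colSums(SummarizedExperiment::assay(pe))),
               c(20, 20))
  expect_identical(scaleTag(pe), "total_normalized")

  # already-equal totals: values unchanged
  m2 <- matrix(c(1, 9, 6, 4), 2,
               dimnames = list(c("A", "B"), c("PSI_r1", "PSI_r2")))
  pe2 <- normalizeTotal(PulldownExperiment(m2))
  expect_equal(unname(SummarizedExperiment::assay(pe2)), unname(m2))

  set.seed(3)
  m3 <- matrix(runif(60, 0.1, 5), 6,
               dimnames = list(letters[1:6],
                               sprintf("PSI_r%d", 1:10)))
  tot <- colSums(SummarizedExperiment::assay(
    normalizeTotal(PulldownExperiment(m3))))
  expect_equal(unname(tot), rep(mean(colSums(m3)), 10))

  m4 <- m2; m4[, 2] <- 0
  expect_error(normalizeTotal(PulldownExperiment(m4)), "PSI_r2")
})

test_that("bait normalization divides by each sample's GFP value", {
  map <- smallMap()
  m <- matrix(c(8, 2, 4, 9, 3, 1), 3,
              dimnames = list(c("PsaA", "PsaB", "GFP"),
                              c("PSI_r1", "WT_r1")))
  pe <- normalizeToBait(PulldownExperiment(m), map)
  a <- SummarizedExperiment::assay(pe)
  expect_equal(unname(a[, "PSI_r1"]), c(2, 0.5, 1))
  expect_equal(unname(a[, "WT_r1"]), c(9, 3, 1))  # WT passed through
  expect_identical(scaleTag(pe), "bait_normalized")
  expect_identical(unname(SummarizedExperiment::colData(pe)$baitNormalized),
                   c(TRUE, FALSE))

  set.seed(8)
  m2 <- matrix(runif(30, 0.5, 9), 5,
               dimnames = list(c("PsaA", "PsaB", "PsbA", "PsbB", "GFP"),
                               sprintf("PSI_r%d", 1:6)))
  a2 <- SummarizedExperiment::assay(
    normalizeToBait(PulldownExperiment(m2), map))
  expect_equal(a2, sweep(m2, 2, m2["GFP", ], "/"))  # division oracle
  expect_true(all(a2["GFP", ] == 1))

  m3 <- m; m3["GFP", 1] <- 0
  expect_error(normalizeToBait(PulldownExperiment(m3), map), "PSI_r1")
  expect_error(normalizeToBait(PulldownExperiment(m[1:2, , drop = FALSE]),
                               map), "missing")
})

test_that("bait normalization is invariant to per-sample scaling", {
  map <- smallMap()
  set.seed(9)
  m <- matrix(runif(15, 0.5, 4), 5,
              dimnames = list(c("PsaA", "PsaB", "PsbA", "PsbB", "GFP"),
                              sprintf("PSI_r%d", 1:3)))
  scaled <- sweep(m, 2, c(7, 0.2, 3.5), "*")
  n1 <- SummarizedExperiment::assay(
    normalizeToBait(PulldownExperiment(m), map))
  n2 <- SummarizedExperiment::assay(
    normalizeToBait(PulldownExperiment(scaled), map))
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("complex abundance sums mapped subunits", {
  map <- smallMap()
  m <- matrix(c(2, 3, 5, 1), 4,
              dimnames = list(c("PsaA", "PsaB", "PsbA", "GFP"),
                              "PSI_r1"))
  pe <- baitNormTable(m)
  expect_equal(unname(complexAbundance(pe, map, "PSI", "PSI_r1")), 5)
  expect_equal(unname(complexAbundance(pe, map, "PSII", "PSI_r1")), 5)
  expect_error(complexAbundance(pe, map, "NOSUCH", "PSI_r1"),
               "no mapped")
  expect_error(complexAbundance(pe, map, "PSI", "nope"), "unknown sample")

  # brute-force oracle on a random table, including unmapped rows
  set.seed(10)
  m2 <- matrix(runif(40), 8,
               dimnames = list(c("PsaA", "PsaB", "PsbA", "PsbB", "GFP",
                                 "X1", "X2", "X3"),
                               sprintf("PSI_r%d", 1:5)))
  pe2 <- baitNormTable(m2)
  for (s in colnames(m2)) {
    expect_equal(unname(complexAbundance(pe2, map, "PSI", s)),
                 oracleComplexAbundance(m2, map, "PSI", s))
    expect_equal(unname(complexAbundance(pe2, map, "PSII", s)),
                 oracleComplexAbundance(m2, map, "PSII", s))
  }
})

test_that("on clean synthetic data the bait complex abundance counts its subunits", {
  map <- defaultComplexMap()
  pe <- simulatePulldown(noiseFreeTruth(), map)
  bn <- normalizeToBait(pe, map)
  # d = 1, nu = 0: every bait subunit has occupancy 1 per bait copy
  expect_equal(unname(complexAbundance(bn, map, "PSI", "PSI_r1")),
               length(complexSubunits(map, "PSI")))
  expect_equal(unname(complexAbundance(bn, map, "PSII", "PSII_r2")),
               length(complexSubunits(map, "PSII")))
})

test_that("detection counts distinguish mapped and unmapped proteins", {
  map <- smallMap()
  m <- matrix(0, 4, 2, dimnames = list(c("PsaA", "PsaB", "X1", "GFP"),
                                       c("PSI_r1", "WT_r1")))
  expect_equal(detectedSubunitCount(PulldownExperiment(m), map),
               list(total = 0L, mappedToFour = 0L))
  m["PsaA", 1] <- 1; m["X1", 2] <- 2; m["GFP", 1] <- 5
  expect_equal(detectedSubunitCount(PulldownExperiment(m), map),
               list(total = 2L, mappedToFour = 1L))
})
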