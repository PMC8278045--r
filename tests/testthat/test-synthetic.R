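test_that("ground-truth fractions derive from counts and copy numbers", {
  gt <- makeGroundTruth(list(copy_number = list(PSI = 450, PSII = 100),
                             supercomplex_count = list(
                               list(a = "PSI", b = "PSII", n = 10))))
  f <- associationTruth(gt)
  expect_equal(f$fraction[f$bait == "PSII" & f$partner == "PSI"], 0.10)
  expect_equal(f$fraction[f$bait == "PSI" & f$partner == "PSII"],
               10 / 450)

  # no supercomplexes -> all fractions zero
  gt0 <- makeGroundTruth(list(supercomplex_count = list()))
  expect_equal(nrow(associationTruth(gt0)), 0L)

  # counts exceeding a copy number violate the probability constraint
  expect_error(
    makeGroundTruth(list(copy_number = list(PSI = 450, PSII = 100),
                         supercomplex_count = list(
                           list(a = "PSI", b = "PSII", n = 200)))),
    "PSII")
  expect_error(makeGroundTruth(list(nonsense_key = 1)), "nonsense_key")
})

test_that("ground truth is reciprocal by construction", {
  gt <- makeGroundTruth()
  f <- associationTruth(gt)
  n <- gt@copyNumber
  for (i in seq_len(nrow(f))) {
    rev <- f$fraction[f$bait == f$partner[i] & f$partner == f$bait[i]]
    expect_equal(f$fraction[i] * n[[f$bait[i]]], rev * n[[f$partner[i]]],
                 tolerance = 1e-12)
  }
})

test_that("expected abundance follows the observation model", {
  map <- smallMap()
  gt <- makeGroundTruth(list(copy_number = list(PSI = 4, PSII = 1),
                             supercomplex_count = list(
                               list(a = "PSI", b = "PSII", n = 0.25)),
                             background = list(PsaA = 0.7),
                             capture_scale = list(PSII = 2),
                             noise_sd = 0),
                        map = map)
  # WT: background only, GFP absent
  expect_equal(expectedAbundance(gt, "WT", "PsaA", map), 0.7)
  expect_equal(expectedAbundance(gt, "WT", "PsbA", map), 0)
  expect_equal(expectedAbundance(gt, "WT", "GFP", map), 0)
  # home subunit rides along once per captured complex (kappa_PSI = 1)
  expect_equal(expectedAbundance(gt, "PSI", "PsbA", map) /
                 expectedAbundance(gt, "PSI", "GFP", map), 0.25 / 4)
  # co-capture: f[PSII][PSI] = 0.25, kappa = 2 -> 2 * 0.25 = 0.5
  expect_equal(expectedAbundance(gt, "PSII", "PsbA", map), 2)
  expect_equal(expectedAbundance(gt, "PSII", "PsaB", map), 0.5)
  # background adds on top of co-capture
  expect_equal(expectedAbundance(gt, "PSII", "PsaA", map), 0.5 + 0.7)
  expect_error(expectedAbundance(gt, "PSI", "NotAProtein", map),
               "unknown protein")
})

test_that("noise-free simulation reproduces the expectations exactly", {
  map <- defaultComplexMap()
  gt <- noiseFreeTruth()
  pe <- simulatePulldown(gt, map)
  a <- SummarizedExperiment::assay(pe)
  cd <- SummarizedExperiment::colData(pe)
  set.seed(5)
  for (s in sample(colnames(a), 4)) for (p in sample(rownames(a), 8))
    expect_identical(a[p, s],
                     expectedAbundance(gt, cd[s, "bait"], p, map))
  expect_identical(scaleTag(pe), "raw")
  expect_true(all(a[, cd$bait == "WT"][rownames(a) == "GFP", ] == 0))
})

test_that("simulation is deterministic and cell-local in its seeding", {
  gt <- makeGroundTruth(list(noise_sd = 0.3))
  pe1 <- simulatePulldown(gt, seed = 42)
  pe2 <- simulatePulldown(gt, seed = 42)
  expect_identical(SummarizedExperiment::assay(pe1),
                   SummarizedExperiment::assay(pe2))
  pe3 <- simulatePulldown(gt, seed = 43)
  expect_false(identical(SummarizedExperiment::assay(pe1),
                         SummarizedExperiment::assay(pe3)))
  # adding a protein (a background extra) leaves shared cells untouched
  gt2 <- makeGroundTruth(list(noise_sd = 0.3,
                              background = list(Sticky1 = 0.5)))
  pe4 <- simulatePulldown(gt2, seed = 42)
  shared <- rownames(pe1)
  expect_identical(SummarizedExperiment::assay(pe1)[shared, ],
                   SummarizedExperiment::assay(pe4)[shared, ])
})

test_that("noise follows the stated log-normal law", {
  map <- smallMap()
  gt <- makeGroundTruth(list(copy_number = list(PSI = 1),
                             supercomplex_count = list(),
                             noise_sd = 0.1),
                        map = map)
  mu <- expectedAbundance(gt, "PSI", "PsaA", map)
  draws <- vapply(seq_len(1000), function(k) {
    a <- SummarizedExperiment::assay(
      simulatePulldown(gt, map, baits = "PSI", replicates = 1, seed = k))
    a["PsaA", 1]
  }, 0)
  m <- mean(log(draws) - log(mu))
  expect_lt(abs(m), 3 * 0.1 / sqrt(1000))
  expect_equal(sd(log(draws)), 0.1, tolerance = 0.15)
})
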