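test_that("identical partner abundance in both pulldowns gives 100%", {
  map <- smallMap()
  m <- matrix(c(3, 4, 1, 3, 4, 1), 3,
              dimnames = list(c("PsaA", "PsaB", "GFP"),
                              c("PSI_r1", "PSII_r1")))
  est <- associationFraction(baitNormTable(m), map, "PSII", "PSI")
  expect_equal(meanPercent(est), 100)
})

test_that("the estimator is exact on noise-free background-free data", {
  map <- defaultComplexMap()
  gt <- noiseFreeTruth(pairs = list(
    list(a = "PSI", b = "PSII", n = 0.25),   # f[PSII][PSI] = 0.25
    list(a = "PSI", b = "CYTB6F", n = 0.07),
    list(a = "PSII", b = "ATPASE", n = 0.02)))
  bn <- normalizeToBait(simulatePulldown(gt, map), map)
  est <- associationFraction(bn, map, "PSII", "PSI")
  expect_equal(meanPercent(est), 25, tolerance = 1e-9)
  expect_length(replicateRatios(est), 3L)

  # full matrix against ground truth, elementwise
  am <- associationMatrix(bn, map)
  expect_equal(nrow(am$table), 12L)  # 4 baits -> 12 ordered pairs
  tr <- associationTruth(gt)
  m <- merge(am$table, tr, by = c("bait", "partner"), all.x = TRUE)
  m$fraction[is.na(m$fraction)] <- 0
  expect_equal(m$meanPercent / 100, m$fraction, tolerance = 1e-9)
})

test_that("estimates honour stoichiometry and reject self-pairs", {
  map <- defaultComplexMap()
  # s = 2 partner copies per supercomplex doubles the apparent fraction
  gt <- noiseFreeTruth(pairs = list(
    list(a = "PSI", b = "PSII", n = 0.1, s = 2)))
  bn <- normalizeToBait(simulatePulldown(gt, map), map)
  expect_equal(meanPercent(associationFraction(bn, map, "PSII", "PSI")),
               2 * 100 * 0.1, tolerance = 1e-9)
  expect_error(associationFraction(bn, map, "PSI", "PSI"), "distinct")
  expect_error(associationFraction(bn, map, "PSI", "NDH1"),
               "no samples")
})

test_that("background inflates the estimate monotonically", {
  map <- defaultComplexMap()
  ests <- vapply(c(0, 0.005, 0.02, 0.05), function(nu) {
    gt <- noiseFreeTruth(background = nu)
    bn <- normalizeToBait(simulatePulldown(gt, map), map)
    meanPercent(associationFraction(bn, map, "PSII", "PSI"))
  }, 0)
  expect_equal(ests[1], 9.9, tolerance = 1e-9)
  expect_true(all(diff(ests) > 0))
})

test_that("association comparisons follow the Student t-test", {
  e1 <- new("AssociationEstimate", bait = "PSII", partner = "PSI",
            ratios = c(0.10, 0.11, 0.09))
  e2 <- new("AssociationEstimate", bait = "PSII", partner = "CYTB6F",
            ratios = c(0.30, 0.29, 0.31))
  got <- compareAssociations(e1, e2)
  want <- oracleT(c(0.10, 0.11, 0.09), c(0.30, 0.29, 0.31))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_lt(got$p, 0.01)

  # identical ratio lists: degenerate convention t = 0, p = 1
  e3 <- new("AssociationEstimate", bait = "PSII", partner = "PSI",
            ratios = c(0.2, 0.2))
  e4 <- new("AssociationEstimate", bait = "PSII", partner = "ATPASE",
            ratios = c(0.2, 0.2))
  expect_equal(compareAssociations(e3, e4), list(t = 0, p = 1, df = 2L))
})

test_that("reciprocity diagnostics recover consistent and broken pairs", {
  mk <- function(b, p, r) new("AssociationEstimate", bait = b,
                              partner = p, ratios = r)
  # hand-built consistent pair: 0.2 * 1 == 0.1 * 2
  ests <- list(mk("A", "B", 0.2), mk("B", "A", 0.1))
  out <- reciprocityCheck(ests, c(A = 1, B = 2))
  expect_equal(out$absDiff, 0)
  expect_equal(out$relDiff, 0)

  # the published PSI/PSII directions are not reciprocal at N ratio 4.5
  ests2 <- list(mk("PSII", "PSI", 0.099), mk("PSI", "PSII", 0.017))
  out2 <- reciprocityCheck(ests2, c(PSI = 4.5, PSII = 1))
  expect_gt(out2$absDiff, 0)

  expect_warning(reciprocityCheck(list(mk("A", "B", 0.2)),
                                  c(A = 1, B = 2)), "no reverse")

  # noise-free full-matrix estimates are reciprocal to numerical precision
  map <- defaultComplexMap()
  gt <- noiseFreeTruth()
  bn <- normalizeToBait(simulatePulldown(gt, map), map)
  am <- associationMatrix(bn, map)
  chk <- reciprocityCheck(am$estimates, gt@copyNumber)
  expect_true(all(chk$absDiff < 1e-9))
})
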