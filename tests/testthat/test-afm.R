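test_that("topograph synthesis is deterministic and respects geometry", {
  none <- synthTopograph(list(), pixelNm = 0.5, gridSize = c(16, 16))
  expect_true(all(heights(none) == 0))
  # peak on a pixel centre: the grid maximum equals the amplitude
  one <- synthTopograph(list(list(peaks = rbind(c(7.75, 7.75)),
                                  amplitude = 5, width = 1.5)),
                        pixelNm = 0.5, gridSize = c(32, 32))
  expect_equal(max(heights(one)), 5, tolerance = 1e-9)
  t1 <- synthTopograph(list(), pixelNm = 1, gridSize = c(16, 16),
                       noiseSd = 0.3, seed = 9)
  t2 <- synthTopograph(list(), pixelNm = 1, gridSize = c(16, 16),
                       noiseSd = 0.3, seed = 9)
  expect_identical(heights(t1), heights(t2))
  expect_error(synthTopograph(list(list(peaks = rbind(c(99, 1)),
                                        amplitude = 1, width = 1)),
                              pixelNm = 0.5, gridSize = c(16, 16)),
               "outside")
  expect_error(Topograph(matrix(0, 4, 4), 1), "8 x 8")
})

test_that("profiles are sampled by bilinear interpolation", {
  flat <- Topograph(matrix(2.5, 16, 16), 1)
  pr <- extractProfile(flat, c(1, 8), c(14, 8))
  expect_true(all(abs(pr$height - 2.5) < 1e-12))
  expect_equal(pr$position[1], 0)

  g <- synthTopograph(list(list(peaks = rbind(c(8, 8)), amplitude = 4,
                                width = 2)),
                      pixelNm = 0.5, gridSize = c(32, 32))
  pr2 <- extractProfile(g, c(2, 8), c(14, 8))
  expect_equal(max(pr2$height), 4, tolerance = 0.02 * 4)
  expect_error(extractProfile(g, c(2, 8), c(2, 8)), "zero-length")
  expect_error(extractProfile(g, c(-1, 8), c(14, 8)), "outside")
})

test_that("profile measurement recovers heights and vertex distances", {
  # two narrow peaks at 5 and 15 nm on a zero baseline
  pos <- seq(0, 20, by = 0.5)
  h <- 3 * exp(-(pos - 5)^2 / (2 * 0.6^2)) +
    3 * exp(-(pos - 15)^2 / (2 * 0.6^2))
  m <- measureProfile(data.frame(position = pos, height = h))
  expect_equal(m$vertex_distance_nm, 10, tolerance = 1e-9)
  expect_equal(m$height_nm, 3, tolerance = 0.01)

  # two wider Gaussians 12 nm apart, pixel 0.5 nm: within one pixel
  h2 <- 5 * exp(-(pos - 4)^2 / (2 * 1.5^2)) +
    5 * exp(-(pos - 16)^2 / (2 * 1.5^2))
  m2 <- measureProfile(data.frame(position = pos, height = h2))
  expect_lte(abs(m2$vertex_distance_nm - 12), 0.5)

  # single peak: height only
  h3 <- 4 * exp(-(pos - 10)^2 / (2 * 1.5^2))
  m3 <- measureProfile(data.frame(position = pos, height = h3))
  expect_equal(m3$height_nm, 4, tolerance = 0.01)
  expect_true(is.na(m3$vertex_distance_nm))
  expect_equal(m3$n_peaks, 1L)

  # nothing above background + prominence: measurement absent with reason
  m4 <- measureProfile(data.frame(position = pos,
                                  height = rep(0.01, length(pos))))
  expect_true(is.na(m4$height_nm))
  expect_match(m4$reason, "background")
  expect_error(measureProfile(data.frame(position = 1:3, height = 1:3)),
               "short")
})

test_that("height measurement is invariant to a constant grid offset", {
  topo <- synthTopograph(list(list(peaks = rbind(c(11.2, 16), c(20.8, 16)),
                                   amplitude = 5.7, width = 1.5)),
                         pixelNm = 0.5)
  shifted <- Topograph(heights(topo) + 7.3, pixelNm(topo))
  m0 <- measureProfile(extractProfile(topo, c(2, 16), c(30, 16)))
  m1 <- measureProfile(extractProfile(shifted, c(2, 16), c(30, 16)))
  expect_equal(m0$height_nm, m1$height_nm, tolerance = 1e-9)
  expect_equal(m0$vertex_distance_nm, m1$vertex_distance_nm)
})

test_that("measurement summaries use the sample SD and drop NAs", {
  ms <- list(list(height_nm = 1, vertex_distance_nm = NA),
             list(height_nm = 2, vertex_distance_nm = 10),
             list(height_nm = 3, vertex_distance_nm = 9))
  s <- summarizeMeasurements(ms)
  expect_equal(s$mean[s$observable == "height_nm"], 2)
  expect_equal(s$sd[s$observable == "height_nm"], 1)  # (n-1) denominator
  expect_equal(s$n[s$observable == "vertex_distance_nm"], 2L)
  s1 <- summarizeMeasurements(list(list(height_nm = 5,
                                        vertex_distance_nm = 9)))
  expect_true(all(is.na(s1$sd)))  # single value: SD absent
  expect_error(summarizeMeasurements(list()), "no measurements")
})

test_that("reference constants and the CSV reader are available", {
  ref <- afmReference()
  expect_equal(ref$height_mean_nm, c(5.7, 5.6))
  expect_equal(ref$vertex_mean_nm, c(9.6, 10.4))
  expect_equal(ref$n, c(21L, 11L))
  f <- tempfile(fileext = ".csv")
  z <- matrix(round(runif(100), 4), 10)
  write.table(z, f, sep = ",", row.names = FALSE, col.names = FALSE)
  topo <- readTopographCSV(f, pixelNm = 2)
  expect_equal(heights(topo), z, tolerance = 1e-12)
  expect_equal(pixelNm(topo), 2)
})
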