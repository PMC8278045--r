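# Small in-code fixtures shared across test files.

# two-complex map with two PSI and two PSII subunits
smallMap <- function() {
  ComplexMap(c(PsaA = "PSI", PsaB = "PSI", PsbA = "PSII", PsbB = "PSII"))
}

# bait-normalized table built directly (GFP row already 1 in non-WT)
baitNormTable <- function(values, scaleTag = "bait_normalized") {
  PulldownExperiment(values, scaleTag = scaleTag)
}

# noise-free ground truth over the default five-complex map
noiseFreeTruth <- function(pairs = list(list(a = "PSI", b = "PSII",
                                             n = 0.099)),
                           seed = 1, ...) {
  makeGroundTruth(c(list(noise_sd = 0, supercomplex_count = pairs),
                    list(...)), seed = seed)
}

# textbook pooled-variance Student t, independent of stats::t.test
oracleT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2), df = nx + ny - 2)
}

# brute-force complex abundance: explicit loop over the membership map
oracleComplexAbundance <- function(values, map, complex, sample) {
  tot <- 0
  for (p in rownames(values))
    if (p %in% names(membership(map)) &&
        membership(map)[[p]] == complex)
      tot <- tot + values[p, sample]
  tot
}
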