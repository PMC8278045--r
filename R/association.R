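#' Estimate the fraction of a complex engaged with a partner complex
#'
#' Cross-pulldown ratio estimator. After bait (GFP) normalization the
#' captured amount per bait copy is comparable between strains, so the
#' fraction of complex B engaged with partner A is estimated, under the
#' 1:1-stoichiometry assumption, by A's summed subunit abundance in the
#' B-bait pulldown divided by A's summed subunit abundance in A's own
#' pulldown. Each replicate of the B-bait strain yields one ratio; the
#' denominator is the mean complex abundance over the A-bait replicates
#' (replicates are not paired by index — the experiment provides no
#' pairing).
#'
#' If every copy of B were bound to one copy of A, A's abundance would be
#' the same in both pulldowns and the estimate would be 100\%.
#'
#' @param x a bait-normalized \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param bait complex id B whose engaged fraction is estimated.
#' @param partner partner complex id A (must differ from \code{bait}).
#' @return An \linkS4class{AssociationEstimate}.
#' @seealso \code{\link{associationMatrix}},
#'   \code{\link{compareAssociations}}
#' @export
associationFraction <- function(x, map, bait, partner) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  if (scaleTag(x) != "bait_normalized")
    stop("associationFraction expects bait-normalized values; ",
         "run normalizeToBait() first")
  if (bait == partner)
    stop("bait and partner must be distinct complexes")
  cd <- SummarizedExperiment::colData(x)
  bSamples <- colnames(x)[cd$bait == bait]
  aSamples <- colnames(x)[cd$bait == partner]
  if (!length(bSamples)) stop("no samples for bait strain ", bait)
  if (!length(aSamples)) stop("no samples for partner strain ", partner)
  bSamples <- bSamples[order(cd[bSamples, "replicate"])]

  denom <- mean(complexAbundance(x, map, partner, aSamples))
  if (denom <= 0)
    stop("zero abundance of ", partner, " in its own pulldown")
  ratios <- complexAbundance(x, map, partner, bSamples) / denom
  new("AssociationEstimate", bait = bait, partner = partner,
      ratios = unname(ratios))
}

#' Association estimates for every ordered pair of complexes
#'
#' Runs \code{\link{associationFraction}} for each ordered pair of
#' distinct complexes with available bait samples; per-pair failures are
#' collected, not raised.
#'
#' @param x a bait-normalized \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param complexes complex ids to cross; default: complexes with bait
#'   samples in \code{x}.
#' @return list with \code{estimates} (list of
#'   \linkS4class{AssociationEstimate}), \code{table} (data.frame with
#'   columns bait, partner, n, meanPercent, sdPercent) and
#'   \code{failures} (data.frame bait, partner, reason).
#' @export
associationMatrix <- function(x, map, complexes = NULL) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  if (is.null(complexes)) {
    cd <- SummarizedExperiment::colData(x)
    complexes <- intersect(complexIds(map), unique(cd$bait))
  }
  estimates <- list()
  fails <- data.frame(bait = character(0), partner = character(0),
                      reason = character(0))
  rows <- list()
  for (B in complexes) for (A in setdiff(complexes, B)) {
    est <- tryCatch(associationFraction(x, map, B, A), error = identity)
    if (inherits(est, "error")) {
      fails <- rbind(fails, data.frame(bait = B, partner = A,
                                       reason = conditionMessage(est)))
    } else {
      estimates[[paste(B, A, sep = "->")]] <- est
      r <- replicateRatios(est)
      rows[[length(rows) + 1L]] <- data.frame(
        bait = B, partner = A, n = length(r),
        meanPercent = meanPercent(est),
        sdPercent = if (length(r) > 1L) 100 * sd(r) else NA_real_)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(bait = character(0), partner = character(0),
                  n = integer(0), meanPercent = numeric(0),
                  sdPercent = numeric(0))
  rownames(tab) <- NULL
  list(estimates = estimates, table = tab, failures = fails)
}

#' Compare two association estimates
#'
#' Two-sided equal-variance (Student) two-sample t-test on the replicate
#' ratios of two \linkS4class{AssociationEstimate}s, as used for the
#' significance stars between bars of the association panels.
#'
#' @param e1,e2 \linkS4class{AssociationEstimate}s with at least two
#'   replicates each.
#' @return list with \code{t}, \code{p} and \code{df}.
#' @export
compareAssociations <- function(e1, e2) {
  stopifnot(is(e1, "AssociationEstimate"), is(e2, "AssociationEstimate"))
  twoSampleT(replicateRatios(e1), replicateRatios(e2))
}

#' Reciprocity diagnostic for association estimates
#'
#' Under the supercomplex model the estimated fractions of the two
#' directions of a pair both measure the same number of joined complexes:
#' \code{f[B][A] * N_B = f[A][B] * N_A = n_AB}. Given complex copy numbers
#' this reports the absolute and relative discrepancy between the two
#' directions of each unordered pair, a consistency check on real data
#' (where copy-number estimates and the printed fractions need not
#' cohere).
#'
#' @param estimates a list of \linkS4class{AssociationEstimate}s (e.g.
#'   \code{associationMatrix(...)$estimates}).
#' @param copyNumbers named numeric vector of complex copy numbers.
#' @return data.frame with one row per unordered pair: \code{a}, \code{b},
#'   \code{nFromA} (= f[A][B] N_A), \code{nFromB} (= f[B][A] N_B),
#'   \code{absDiff}, \code{relDiff}. Pairs with a missing direction or
#'   copy number are skipped with a warning.
#' @export
reciprocityCheck <- function(estimates, copyNumbers) {
  frac <- lapply(estimates, function(e) mean(replicateRatios(e)))
  key <- t(vapply(estimates, function(e) c(e@bait, e@partner),
                  character(2L)))
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(key))) {
    B <- key[i, 1L]; A <- key[i, 2L]
    uk <- paste(sort(c(A, B)), collapse = "|")
    if (uk %in% seen) next
    seen <- c(seen, uk)
    j <- which(key[, 1L] == A & key[, 2L] == B)
    if (!length(j)) {
      warning("no reverse estimate for pair ", A, "-", B, "; skipped")
      next
    }
    if (!all(c(A, B) %in% names(copyNumbers))) {
      warning("missing copy number for pair ", A, "-", B, "; skipped")
      next
    }
    nFromB <- frac[[i]] * copyNumbers[[B]]
    nFromA <- frac[[j[1L]]] * copyNumbers[[A]]
    s <- nFromA + nFromB
    rows[[length(rows) + 1L]] <- data.frame(
      a = A, b = B, nFromA = nFromA, nFromB = nFromB,
      absDiff = abs(nFromA - nFromB),
      relDiff = if (s > 0) 2 * abs(nFromA - nFromB) / s else 0)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(a = character(0), b = character(0),
                  nFromA = numeric(0), nFromB = numeric(0),
                  absDiff = numeric(0), relDiff = numeric(0))
  rownames(out) <- NULL
  out
}
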