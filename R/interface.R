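#' Relative abundance of one subunit across pulldowns
#'
#' The per-subunit analogue of the association ratio: for a subunit p with
#' home complex C, each replicate of the B-bait strain yields the ratio of
#' p's bait-normalized abundance in that replicate to p's mean abundance
#' over the C-bait (home) replicates. Subunits travelling with the
#' complex-complex interface are dragged into foreign pulldowns more than
#' their complex-mates, so their ratios stand out.
#'
#' @param x a bait-normalized \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param subunit protein id (mapped to some complex C, C != bait).
#' @param bait bait strain B whose samples provide the numerators.
#' @return numeric vector of per-replicate ratios (ordered by replicate).
#' @export
subunitRelativeAbundance <- function(x, map, subunit, bait) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  if (scaleTag(x) != "bait_normalized")
    stop("subunitRelativeAbundance expects bait-normalized values")
  mem <- membership(map)
  if (!subunit %in% names(mem)) stop("unmapped subunit: ", subunit)
  home <- mem[[subunit]]
  if (home == bait)
    stop("subunit ", subunit, " belongs to the bait complex ", bait)
  if (!subunit %in% rownames(x)) stop("subunit not in table: ", subunit)
  cd <- SummarizedExperiment::colData(x)
  hSamples <- colnames(x)[cd$bait == home]
  bSamples <- colnames(x)[cd$bait == bait]
  if (!length(hSamples)) stop("no home (", home, ") samples")
  if (!length(bSamples)) stop("no samples for bait ", bait)
  bSamples <- bSamples[order(cd[bSamples, "replicate"])]
  a <- SummarizedExperiment::assay(x, "abundance")
  homeMean <- mean(a[subunit, hSamples])
  if (homeMean <= 0)
    stop("subunit ", subunit, " undetected in its home pulldown")
  unname(a[subunit, bSamples] / homeMean)
}

#' One-vs-rest interface test for a subunit
#'
#' Tests whether a subunit's relative abundance in a foreign pulldown
#' exceeds that of its complex-mates: Student's equal-variance t-test of
#' the subunit's replicate ratios against the pooled replicate ratios of
#' all other eligible subunits of the same complex in the same pulldown
#' ("as a whole"). Eligible means mapped, present in the table and
#' detected in the home pulldown.
#'
#' @param x a bait-normalized \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param subunit protein id.
#' @param bait foreign bait strain.
#' @return one-row data.frame: \code{subunit}, \code{home}, \code{bait},
#'   \code{n}, \code{meanRatio}, \code{t}, \code{p}.
#' @export
oneVsRestTest <- function(x, map, subunit, bait) {
  ratios <- subunitRelativeAbundance(x, map, subunit, bait)
  home <- membership(map)[[subunit]]
  others <- setdiff(.eligibleSubunits(x, map, home), subunit)
  if (!length(others))
    stop("complex ", home, " has no other eligible subunit")
  pooled <- unlist(lapply(others, function(q)
    subunitRelativeAbundance(x, map, q, bait)))
  tt <- twoSampleT(ratios, pooled)
  data.frame(subunit = subunit, home = home, bait = bait,
             n = length(ratios), meanRatio = mean(ratios),
             t = tt$t, p = tt$p)
}

# subunits of `complex` usable for ratio analysis: in the table and
# detected (mean > 0) in the home pulldown
.eligibleSubunits <- function(x, map, complex) {
  subs <- intersect(complexSubunits(map, complex), rownames(x))
  cd <- SummarizedExperiment::colData(x)
  hSamples <- colnames(x)[cd$bait == complex]
  if (!length(hSamples)) return(character(0))
  a <- SummarizedExperiment::assay(x, "abundance")
  subs[rowMeans(a[subs, hSamples, drop = FALSE]) > 0]
}

#' Interface scores for all subunits and foreign baits
#'
#' Applies \code{\link{oneVsRestTest}} to every eligible subunit in every
#' foreign pulldown. Subunits undetected in their home pulldown are
#' skipped with a warning (their ratio denominator is undefined).
#'
#' @param x a bait-normalized \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param baits bait strains to scan; default all non-WT baits in
#'   \code{x}.
#' @return data.frame, one row per (subunit, bait), columns as in
#'   \code{\link{oneVsRestTest}} plus \code{star}.
#' @export
interfaceScores <- function(x, map, baits = NULL) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  cd <- SummarizedExperiment::colData(x)
  if (is.null(baits)) baits <- setdiff(unique(cd$bait), "WT")
  mem <- membership(map)
  dropped <- character(0)
  rows <- list()
  for (B in baits) {
    foreign <- names(mem)[mem != B & mem %in% unique(cd$bait)]
    for (p in intersect(foreign, rownames(x))) {
      row <- tryCatch(oneVsRestTest(x, map, p, B), error = identity)
      if (inherits(row, "error")) {
        dropped <- c(dropped, paste0(p, " (", B, ")"))
      } else rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(dropped))
    warning("subunit(s) skipped: ",
            paste(unique(dropped), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(subunit = character(0), home = character(0),
                  bait = character(0), n = integer(0),
                  meanRatio = numeric(0), t = numeric(0), p = numeric(0))
  out$star <- starAnnotation(out$p)
  rownames(out) <- NULL
  out
}

#' Nominate interface-subunit candidates
#'
#' A subunit is nominated as a putative binding-site (interface) subunit
#' of its complex in a given pulldown when its one-vs-rest p-value falls
#' below \code{alpha} and its mean ratio is above the median mean ratio of
#' its complex's subunits in that pulldown (elevated, not depressed).
#' Candidates are returned sorted by descending mean ratio with star
#' annotations.
#'
#' @param scores data.frame from \code{\link{interfaceScores}}.
#' @param alpha significance threshold (default 0.05).
#' @return the nominated subset of \code{scores}, ordered by descending
#'   \code{meanRatio}.
#' @export
rankInterfaceCandidates <- function(scores, alpha = 0.05) {
  if (!nrow(scores)) return(scores[0, , drop = FALSE])
  keep <- logical(nrow(scores))
  for (g in split(seq_len(nrow(scores)),
                  paste(scores$home, scores$bait))) {
    med <- median(scores$meanRatio[g])
    keep[g] <- scores$p[g] < alpha & scores$meanRatio[g] > med
  }
  out <- scores[keep, , drop = FALSE]
  out <- out[order(-out$meanRatio), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance stars
#'
#' The conventional three-level annotation: \code{***} for p < 0.001,
#' \code{**} for 0.001 <= p < 0.01, \code{*} for 0.01 <= p < 0.05, and
#' \code{n.s.} otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of annotations.
#' @export
starAnnotation <- function(p) {
  out <- rep("n.s.", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}
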