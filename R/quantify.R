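#' Equal-total normalization across samples
#'
#' Scales every sample so its summed abundance equals the across-sample
#' mean total, emulating the "normalize against all proteins" behaviour of
#' label-free quantification software (which assumes most proteins do not
#' change between runs). This is the scale on which the pulldown-vs-WT
#' volcano comparison operates, since the WT control carries no GFP to
#' normalize against.
#'
#' @param x a raw \linkS4class{PulldownExperiment}.
#' @return the table rescaled, with scale tag \code{"total_normalized"}.
#' @export
normalizeTotal <- function(x) {
  stopifnot(is(x, "PulldownExperiment"))
  if (scaleTag(x) != "raw")
    stop("normalizeTotal expects raw values, got ", scaleTag(x))
  a <- SummarizedExperiment::assay(x, "abundance")
  totals <- colSums(a)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(a)[totals <= 0], collapse = ", "))
  SummarizedExperiment::assay(x, "abundance") <-
    sweep(a, 2L, mean(totals) / totals, "*")
  .scaleTag(x) <- "total_normalized"
  validObject(x)
  x
}

#' Bait (GFP) normalization
#'
#' Divides every value in each GFP-tagged sample by that sample's GFP
#' abundance, making abundances comparable per captured bait copy (the GFP
#' row becomes exactly 1). WT samples, which have no GFP, are passed
#' through unchanged and flagged in \code{colData(x)$baitNormalized}.
#'
#' @param x a \linkS4class{PulldownExperiment} (raw or total-normalized).
#' @param map a \linkS4class{ComplexMap} (supplies the GFP row id).
#' @return the table with scale tag \code{"bait_normalized"}.
#' @export
normalizeToBait <- function(x, map) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  if (scaleTag(x) == "bait_normalized")
    stop("table is already bait-normalized")
  a <- SummarizedExperiment::assay(x, "abundance")
  cd <- SummarizedExperiment::colData(x)
  gfp <- gfpId(map)
  nonWT <- cd$bait != "WT"
  if (any(nonWT)) {
    if (!gfp %in% rownames(a))
      stop("GFP row '", gfp, "' is missing")
    g <- a[gfp, ]
    bad <- nonWT & g <= 0
    if (any(bad))
      stop("zero GFP abundance in non-WT sample(s): ",
           paste(colnames(a)[bad], collapse = ", "))
    a[, nonWT] <- sweep(a[, nonWT, drop = FALSE], 2L, g[nonWT], "/")
  }
  SummarizedExperiment::assay(x, "abundance") <- a
  SummarizedExperiment::colData(x)$baitNormalized <- nonWT
  .scaleTag(x) <- "bait_normalized"
  validObject(x)
  x
}

#' Complex-level abundance by subunit summation
#'
#' The quantity of a multi-subunit complex in a sample is represented by
#' the sum of the abundance scores of all its observed subunits; mapped
#' subunits absent from the table contribute 0.
#'
#' @param x a \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @param complex complex id.
#' @param sample one or more sample ids (default all samples).
#' @return named numeric vector of complex abundances per sample.
#' @export
complexAbundance <- function(x, map, complex, sample = colnames(x)) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  subs <- complexSubunits(map, complex)
  if (!length(subs))
    stop("complex '", complex, "' has no mapped proteins")
  bad <- setdiff(sample, colnames(x))
  if (length(bad))
    stop("unknown sample(s): ", paste(bad, collapse = ", "))
  a <- SummarizedExperiment::assay(x, "abundance")
  present <- intersect(subs, rownames(a))
  if (!length(present))
    return(setNames(rep(0, length(sample)), sample))
  colSums(a[present, sample, drop = FALSE])
}

#' Count detected proteins and photosynthetic-complex subunits
#'
#' A protein counts as detected when its abundance is positive in at least
#' one sample; the GFP marker is excluded. The second count restricts to
#' subunits mapped to the four photosynthetic complexes (PSI, PSII,
#' Cyt b6f, ATP synthase).
#'
#' @param x a \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @return list with elements \code{total} and \code{mappedToFour}.
#' @export
detectedSubunitCount <- function(x, map) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  a <- SummarizedExperiment::assay(x, "abundance")
  det <- rownames(a)[rowSums(a > 0) > 0]
  det <- setdiff(det, gfpId(map))
  mem <- membership(map)
  four <- names(mem)[mem %in% .FOUR_COMPLEXES]
  list(total = length(det), mappedToFour = length(intersect(det, four)))
}
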