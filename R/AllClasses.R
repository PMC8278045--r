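#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats median rnorm sd var t.test p.adjust pt ks.test setNames
#' @importFrom utils read.csv write.csv read.delim
NULL

.BAITS <- c("PSI", "PSII", "CYTB6F", "ATPASE", "WT")
.SCALE_TAGS <- c("raw", "total_normalized", "bait_normalized")
.FOUR_COMPLEXES <- c("PSI", "PSII", "CYTB6F", "ATPASE")

#' PulldownExperiment: pull-down abundance data with replicate design
#'
#' An S4 container for protein-level label-free abundance scores from GFP
#' pull-down experiments, extending
#' \linkS4class{SummarizedExperiment}. Rows are proteins (gene-name
#' identifiers, case-sensitive; the reserved \code{"GFP"} row carries the
#' bait marker), columns are samples. \code{colData} holds the experimental
#' design: \code{bait} (one of \code{PSI}, \code{PSII}, \code{CYTB6F},
#' \code{ATPASE}, \code{WT}) and \code{replicate} (positive integer, unique
#' within bait). The normalization state of the values is tracked by a scale
#' tag (\code{"raw"}, \code{"total_normalized"} or \code{"bait_normalized"})
#' retrievable with \code{\link{scaleTag}}.
#'
#' All abundance values must be finite and non-negative; absent measurements
#' are zeros, not \code{NA} (the aggregate-table convention of label-free
#' quantification software, which reports a dense matrix with no missing
#' cells).
#'
#' @seealso \code{\link{readAbundanceTable}}, \code{\link{simulatePulldown}}
#' @export
setClass("PulldownExperiment", contains = "SummarizedExperiment")

setValidity("PulldownExperiment", function(object) {
  msg <- character(0)
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "abundance values must be finite and non-missing")
    else if (any(a < 0))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("bait", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'bait' and 'replicate'")
  } else {
    if (!all(cd$bait %in% .BAITS))
      msg <- c(msg, sprintf("bait must be one of %s",
                            paste(.BAITS, collapse = ", ")))
    rep <- cd$replicate
    if (anyNA(rep) || any(rep < 1) || any(rep != round(rep)))
      msg <- c(msg, "replicate must be a positive integer")
    if (anyDuplicated(paste(cd$bait, rep)))
      msg <- c(msg, "each (bait, replicate) pair must be unique")
  }
  st <- S4Vectors::metadata(object)$scaleTag
  if (is.null(st) || !is.character(st) || length(st) != 1L ||
      !st %in% .SCALE_TAGS)
    msg <- c(msg, sprintf("metadata scaleTag must be one of %s",
                          paste(.SCALE_TAGS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PulldownExperiment
#'
#' @param abundance numeric matrix, proteins in rows, samples in columns.
#'   Rownames and colnames are required and must be unique.
#' @param bait character vector of bait strains per sample. If \code{NULL},
#'   parsed from sample names following the \code{"<BAIT>_r<replicate>"}
#'   convention (e.g. \code{"PSI_r1"}).
#' @param replicate integer vector of replicate indices per sample; parsed
#'   from sample names when \code{NULL}.
#' @param scaleTag normalization state of the values; new data are
#'   \code{"raw"}.
#' @return A \linkS4class{PulldownExperiment}.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("PsaA", "GFP"),
#'                                     c("PSI_r1", "PSI_r2")))
#' PulldownExperiment(m)
#' @export
PulldownExperiment <- function(abundance, bait = NULL, replicate = NULL,
                               scaleTag = "raw") {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(bait) || is.null(replicate)) {
    parsed <- .parseSampleNames(colnames(abundance))
    if (is.null(bait)) bait <- parsed$bait
    if (is.null(replicate)) replicate <- parsed$replicate
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = S4Vectors::DataFrame(bait = bait,
                                   replicate = as.integer(replicate),
                                   row.names = colnames(abundance)))
  S4Vectors::metadata(se)$scaleTag <- scaleTag
  new("PulldownExperiment", se)
}

# "<BAIT>_r<k>" -> bait/replicate; errors on names that do not follow the
# convention (callers with other names must pass explicit metadata)
.parseSampleNames <- function(ids) {
  if (is.null(ids)) stop("sample names are required to infer the design")
  m <- regmatches(ids, regexec("^([A-Za-z0-9]+)_r([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("cannot parse sample name(s) ", paste(ids[bad], collapse = ", "),
         "; expected '<BAIT>_r<replicate>' or explicit metadata")
  list(bait = toupper(vapply(m, `[`, "", 2L)),
       replicate = as.integer(vapply(m, `[`, "", 3L)))
}

#' ComplexMap: protein-to-complex membership
#'
#' Maps protein identifiers to the multi-subunit complex they belong to
#' (by default the thylakoid-membrane complexes PSI, PSII, Cyt b6f, ATP
#' synthase and NDH-1), and records the reserved identifier of the GFP bait
#' marker, which belongs to no complex.
#'
#' @slot membership named character vector: names are protein ids, values
#'   complex ids. A protein maps to at most one complex.
#' @slot gfpId reserved identifier of the GFP marker (default \code{"GFP"}).
#' @slot complexes the known complex ids.
#' @seealso \code{\link{defaultComplexMap}}, \code{\link{readComplexMap}}
#' @export
setClass("ComplexMap",
         representation(membership = "character", gfpId = "character",
                        complexes = "character"))

setValidity("ComplexMap", function(object) {
  msg <- character(0)
  if (length(object@gfpId) != 1L || is.na(object@gfpId) ||
      !nzchar(object@gfpId))
    msg <- c(msg, "gfpId must be a single non-empty string")
  nm <- names(object@membership)
  if (length(object@membership) && (is.null(nm) || any(!nzchar(nm))))
    msg <- c(msg, "membership must be a named character vector")
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("protein(s) mapped to more than one complex: %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(object@gfpId) == 1L && object@gfpId %in% nm)
    msg <- c(msg, "the GFP marker must not be mapped to a complex")
  if (anyDuplicated(object@complexes))
    msg <- c(msg, "complex ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @param membership named character vector (protein -> complex).
#' @param gfpId reserved GFP marker identifier.
#' @param complexes known complex ids; defaults to the complexes occurring
#'   in \code{membership}.
#' @rdname ComplexMap-class
#' @export
ComplexMap <- function(membership, gfpId = "GFP", complexes = NULL) {
  membership <- unlist(membership)
  if (is.null(complexes)) complexes <- unique(unname(membership))
  new("ComplexMap", membership = membership, gfpId = gfpId,
      complexes = as.character(complexes))
}

#' GroundTruth: generative parameters of the pull-down observation model
#'
#' Parameterizes the forward simulator. Complex copy numbers \code{N_C} are
#' monomer-equivalent complexes per cell (arbitrary units; only ratios
#' matter). For every unordered complex pair \{A, B\} the supercomplex count
#' \code{n_AB} gives how many copies of the pair are joined; the derived
#' association fraction of B engaged with A is \code{f[B][A] = n_AB / N_B},
#' constrained so that the fractions of any complex sum to at most 1.
#' Stoichiometry \code{s} is partner copies per bait copy inside a
#' supercomplex (1 under the 1:1 assumption). Per-protein detection
#' efficiencies, strain-independent nonspecific background rates, per-bait
#' capture scales and a log-normal measurement noise SD complete the model.
#'
#' @slot copyNumber named positive numeric, complex -> N_C.
#' @slot pairs data.frame with columns \code{a}, \code{b} (complex ids),
#'   \code{n} (supercomplex count, >= 0), \code{s} (stoichiometry, > 0).
#' @slot detectionEff named positive numeric, protein -> d_p; proteins not
#'   listed default to 1.
#' @slot backgroundRate named non-negative numeric, protein -> nu_p;
#'   unlisted proteins default to 0.
#' @slot noiseSd SD of Gaussian noise on the natural-log scale.
#' @slot captureScale named positive numeric, bait -> kappa; unlisted baits
#'   default to 1.
#' @slot interfaceBoost data.frame with columns \code{protein}, \code{bait},
#'   \code{multiplier}: occupancy multipliers applied to that protein's
#'   co-capture (non-home) occupancy in that bait's samples, the simulator's
#'   stand-in for interface-proximity enrichment.
#' @slot seed integer master seed.
#' @seealso \code{\link{makeGroundTruth}}, \code{\link{simulatePulldown}}
#' @export
setClass("GroundTruth",
         representation(copyNumber = "numeric", pairs = "data.frame",
                        detectionEff = "numeric", backgroundRate = "numeric",
                        noiseSd = "numeric", captureScale = "numeric",
                        interfaceBoost = "data.frame", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  cn <- object@copyNumber
  if (!length(cn) || is.null(names(cn)) || any(!nzchar(names(cn))))
    msg <- c(msg, "copyNumber must be a named numeric vector")
  if (any(!is.finite(cn)) || any(cn <= 0))
    msg <- c(msg, "copy numbers must be positive")
  p <- object@pairs
  if (!all(c("a", "b", "n", "s") %in% colnames(p))) {
    msg <- c(msg, "pairs needs columns a, b, n, s")
  } else if (nrow(p)) {
    if (any(p$a == p$b)) msg <- c(msg, "a pair must join two distinct complexes")
    if (any(p$n < 0)) msg <- c(msg, "supercomplex counts must be non-negative")
    if (any(p$s <= 0)) msg <- c(msg, "stoichiometries must be positive")
    key <- apply(cbind(pmin(p$a, p$b), pmax(p$a, p$b)), 1L, paste,
                 collapse = "|")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate complex pair")
    miss <- setdiff(unique(c(p$a, p$b)), names(cn))
    if (length(miss))
      msg <- c(msg, sprintf("pair complex(es) without copy number: %s",
                            paste(miss, collapse = ", ")))
    for (B in names(cn)) {
      tot <- sum(p$n[p$a == B | p$b == B])
      if (is.finite(cn[[B]]) && tot > cn[[B]] * (1 + 1e-12))
        msg <- c(msg, sprintf(
          "association fractions of %s exceed 1 (sum n = %g > N = %g)",
          B, tot, cn[[B]]))
    }
  }
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative number")
  if (any(object@detectionEff <= 0))
    msg <- c(msg, "detection efficiencies must be positive")
  if (any(object@backgroundRate < 0))
    msg <- c(msg, "background rates must be non-negative")
  if (any(object@captureScale <= 0))
    msg <- c(msg, "capture scales must be positive")
  if (length(msg)) msg else TRUE
})

#' AssociationEstimate: cross-pulldown association fraction for one pair
#'
#' Result of \code{\link{associationFraction}}: per-replicate ratios of the
#' partner complex's bait-normalized abundance in the bait pulldown to its
#' mean abundance in its own pulldown, interpreted (under 1:1 stoichiometry)
#' as the fraction of the bait complex engaged with the partner.
#'
#' @slot bait bait complex id (the complex whose engaged fraction is
#'   estimated).
#' @slot partner partner complex id.
#' @slot ratios per-replicate ratios (one per bait-strain replicate).
#' @seealso \code{\link{meanPercent}}, \code{\link{compareAssociations}}
#' @export
setClass("AssociationEstimate",
         representation(bait = "character", partner = "character",
                        ratios = "numeric"))

setValidity("AssociationEstimate", function(object) {
  msg <- character(0)
  if (length(object@ratios) < 1L)
    msg <- c(msg, "at least one replicate ratio is required")
  if (any(!is.finite(object@ratios)) || any(object@ratios < 0))
    msg <- c(msg, "ratios must be finite and non-negative")
  if (length(object@bait) != 1L || length(object@partner) != 1L)
    msg <- c(msg, "bait and partner must be single complex ids")
  else if (object@bait == object@partner)
    msg <- c(msg, "bait and partner must differ")
  if (length(msg)) msg else TRUE
})

#' Topograph: AFM height map
#'
#' A two-dimensional grid of surface heights (nm) with a physical pixel
#' size, as produced by atomic force microscopy or by
#' \code{\link{synthTopograph}}. Coordinates are in nm with x rightwards
#' (columns), y downwards (rows), origin at the grid corner; pixel centres
#' sit at half-integer multiples of the pixel size.
#'
#' @slot heights numeric matrix of heights in nm (rows = y, cols = x).
#' @slot pixelNm nm per pixel (> 0).
#' @seealso \code{\link{extractProfile}}, \code{\link{measureProfile}}
#' @export
setClass("Topograph",
         representation(heights = "matrix", pixelNm = "numeric"))

setValidity("Topograph", function(object) {
  msg <- character(0)
  if (nrow(object@heights) < 8L || ncol(object@heights) < 8L)
    msg <- c(msg, "height grid must be at least 8 x 8")
  if (anyNA(object@heights) || any(!is.finite(object@heights)))
    msg <- c(msg, "heights must be finite")
  if (length(object@pixelNm) != 1L || object@pixelNm <= 0)
    msg <- c(msg, "pixelNm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param heights numeric matrix of heights (nm).
#' @param pixelNm nm per pixel.
#' @rdname Topograph-class
#' @export
Topograph <- function(heights, pixelNm) {
  new("Topograph", heights = as.matrix(heights), pixelNm = pixelNm)
}

#' ValidationReport: dataset consistency check results
#'
#' Carries the errors and warnings found by \code{\link{validateDataset}}.
#' The dataset is usable iff there are no errors (\code{\link{isOK}}).
#'
#' @slot errors character vector of error messages.
#' @slot warnings character vector of warning messages.
#' @export
setClass("ValidationReport",
         representation(errors = "character", warnings = "character"))
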