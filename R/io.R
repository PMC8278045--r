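#' Read a protein-by-sample abundance table
#'
#' Reads a dense CSV/TSV abundance table (first column \code{protein},
#' remaining columns one per sample, UTF-8, '.' decimal separator). Blank
#' and \code{NA} cells become 0 with a warning, following the dense
#' aggregate-table convention of label-free quantification software, under
#' which an undetected protein is a zero, not a missing value. An optional
#' scale-tag header comment (\code{# scale_tag: ...}) written by
#' \code{\link{writeAbundanceTable}} is honoured; otherwise the values are
#' taken as \code{"raw"}.
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"tsv"}; default guessed from the
#'   file extension.
#' @param meta optional sample metadata: a data.frame (or path to a CSV)
#'   with columns \code{sample_id}, \code{bait}, \code{replicate}. When
#'   omitted, sample names must follow \code{"<BAIT>_r<replicate>"}.
#' @return A \linkS4class{PulldownExperiment}.
#' @seealso \code{\link{writeAbundanceTable}}, \code{\link{readSampleMeta}}
#' @export
readAbundanceTable <- function(path, format = NULL, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  sep <- if (format == "csv") "," else "\t"

  first <- readLines(path, n = 5L)
  tagLine <- grep("^#\\s*scale_tag\\s*:", first, value = TRUE)
  tag <- if (length(tagLine))
    trimws(sub("^#\\s*scale_tag\\s*:", "", tagLine[1L])) else "raw"
  if (!tag %in% .SCALE_TAGS)
    stop("unknown scale_tag in header comment: ", tag)

  raw <- read.csv(path, sep = sep, comment.char = "#",
                  colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 1L) stop("table must have a protein id column")
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sampleIds <- colnames(raw)[-1L]
  vals <- matrix(0, nrow(raw), length(sampleIds),
                 dimnames = list(ids, sampleIds))
  nBlank <- 0L
  for (j in seq_along(sampleIds)) {
    cell <- trimws(raw[[j + 1L]])
    blank <- is.na(cell) | !nzchar(cell) | toupper(cell) == "NA"
    cell[blank] <- ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) & !blank
    if (any(bad))
      stop(sprintf("malformed numeric cell '%s' at protein '%s', sample '%s'",
                   cell[which(bad)[1L]], ids[which(bad)[1L]],
                   sampleIds[j]))
    num[blank] <- 0
    nBlank <- nBlank + sum(blank)
    vals[, j] <- num
  }
  if (nBlank > 0L)
    warning(nBlank, " blank/NA cell(s) set to 0")

  if (!is.null(meta)) {
    if (is.character(meta)) meta <- readSampleMeta(meta)
    meta <- as.data.frame(meta)
    miss <- setdiff(sampleIds, meta$sample_id)
    if (length(miss))
      stop("sample(s) without metadata: ", paste(miss, collapse = ", "))
    idx <- match(sampleIds, meta$sample_id)
    return(PulldownExperiment(vals, bait = toupper(meta$bait[idx]),
                              replicate = meta$replicate[idx],
                              scaleTag = tag))
  }
  PulldownExperiment(vals, scaleTag = tag)
}

#' Write an abundance table to CSV/TSV
#'
#' Writes the table in the format read by \code{\link{readAbundanceTable}},
#' with the scale tag preserved in a \code{# scale_tag:} header comment so
#' that a round trip reproduces the object.
#'
#' @param x a \linkS4class{PulldownExperiment}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @export
writeAbundanceTable <- function(x, path, format = c("csv", "tsv")) {
  stopifnot(is(x, "PulldownExperiment"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  a <- SummarizedExperiment::assay(x, "abundance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale_tag: ", scaleTag(x)), con)
  df <- data.frame(protein = rownames(a), a, check.names = FALSE)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read sample metadata
#'
#' CSV with columns \code{sample_id}, \code{bait}, \code{replicate}.
#'
#' @param path file to read.
#' @return data.frame with those three columns.
#' @export
readSampleMeta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- read.csv(path, check.names = FALSE, comment.char = "#")
  need <- c("sample_id", "bait", "replicate")
  if (!all(need %in% colnames(m)))
    stop("sample metadata needs columns ", paste(need, collapse = ", "))
  m$bait <- toupper(m$bait)
  m$replicate <- as.integer(m$replicate)
  m[need]
}

#' Read a protein-to-complex map from JSON
#'
#' Expected layout: \code{{"gfp_id": "GFP", "membership": {"PsaA": "PSI",
#' ...}}}. A protein mapped to two complexes or a missing \code{gfp_id} is
#' an error; complexes outside the default thylakoid set are allowed with a
#' warning.
#'
#' @param path JSON file.
#' @return A \linkS4class{ComplexMap}.
#' @seealso \code{\link{defaultComplexMap}}
#' @export
readComplexMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$gfp_id)) stop("complex map is missing 'gfp_id'")
  if (is.null(j$membership)) stop("complex map is missing 'membership'")
  prot <- names(j$membership)
  if (anyDuplicated(prot))
    stop("protein(s) mapped more than once: ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "))
  mem <- vapply(j$membership, as.character, "")
  known <- c(.FOUR_COMPLEXES, "NDH1")
  unknown <- setdiff(unique(mem), known)
  if (length(unknown))
    warning("complex id(s) outside the default set: ",
            paste(unknown, collapse = ", "))
  ComplexMap(mem, gfpId = as.character(j$gfp_id),
             complexes = union(intersect(known, unique(mem)), unknown))
}

#' Write a complex map to JSON
#'
#' @param map a \linkS4class{ComplexMap}.
#' @param path output file.
#' @export
writeComplexMap <- function(map, path) {
  stopifnot(is(map, "ComplexMap"))
  jsonlite::write_json(
    list(gfp_id = map@gfpId, membership = as.list(membership(map))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Default Syn7942 thylakoid complex map
#'
#' The packaged membership map of the detected subunits of the four
#' photosynthetic complexes (PSI, PSII, cytochrome b6f, ATP synthase; 38
#' subunits in total, gene names as used for Synechococcus elongatus PCC
#' 7942) plus the NDH-1 subunits, with \code{"GFP"} reserved for the bait
#' marker. The ATP synthase peripheral-stalk subunit b' is spelled
#' \code{AtpF2_bprime}.
#'
#' @return A \linkS4class{ComplexMap}.
#' @export
defaultComplexMap <- function() {
  readComplexMap(system.file("extdata", "complex_map_syn7942.json",
                             package = "PulldownAssoc", mustWork = TRUE))
}

#' Validate a dataset against a complex map
#'
#' Checks the consistency conditions the downstream estimators rely on.
#' Errors (fatal for analysis): a non-WT sample whose GFP abundance is zero
#' or whose GFP row is missing; a bait complex among the samples with no
#' mapped subunit detected. Warnings: mapped subunits absent from the
#' table; detected proteins not covered by the map.
#'
#' @param x a \linkS4class{PulldownExperiment}.
#' @param map a \linkS4class{ComplexMap}.
#' @return A \linkS4class{ValidationReport}.
#' @export
validateDataset <- function(x, map) {
  stopifnot(is(x, "PulldownExperiment"), is(map, "ComplexMap"))
  errors <- character(0)
  warns <- character(0)
  a <- SummarizedExperiment::assay(x, "abundance")
  cd <- SummarizedExperiment::colData(x)
  gfp <- gfpId(map)

  nonWT <- colnames(a)[cd$bait != "WT"]
  if (length(nonWT)) {
    if (!gfp %in% rownames(a)) {
      errors <- c(errors, sprintf(
        "GFP row '%s' missing but non-WT samples present", gfp))
    } else {
      zero <- nonWT[a[gfp, nonWT] <= 0]
      if (length(zero))
        errors <- c(errors, sprintf(
          "non-WT sample(s) with zero GFP abundance: %s",
          paste(zero, collapse = ", ")))
    }
  }

  for (B in setdiff(unique(cd$bait), "WT")) {
    subs <- intersect(complexSubunits(map, B), rownames(a))
    bSamples <- colnames(a)[cd$bait == B]
    if (!length(subs) ||
        all(a[subs, bSamples, drop = FALSE] == 0))
      errors <- c(errors, sprintf(
        "bait complex %s has no mapped detected subunit", B))
  }

  absent <- setdiff(names(membership(map)), rownames(a))
  if (length(absent))
    warns <- c(warns, sprintf("mapped subunit(s) absent from table: %s",
                              paste(absent, collapse = ", ")))
  unmapped <- setdiff(rownames(a), c(names(membership(map)), gfp))
  if (length(unmapped))
    warns <- c(warns, sprintf("%d detected protein(s) not in the map",
                              length(unmapped)))

  new("ValidationReport", errors = errors, warnings = warns)
}
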