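#' Run the full pull-down analysis pipeline
#'
#' One-call orchestration: load (or simulate) an abundance dataset,
#' validate it, bait-normalize for the association and interface analyses,
#' total-normalize for the volcano against WT, and write all stage outputs
#' plus a manifest and a human-readable summary. Deterministic for a given
#' configuration and seed; on any stage failure the partial outputs are
#' removed and an error naming the stage is raised.
#'
#' The YAML (or JSON) configuration contains either a \code{simulate}
#' block (the \code{\link{makeGroundTruth}} parameters, plus optional
#' \code{replicates} and \code{baits}) or an \code{inputs} block with
#' paths \code{table}, \code{map} and optionally \code{meta}; optional
#' top-level keys \code{seed}, \code{alpha} (default 0.05),
#' \code{label_fold} (default 20), \code{pseudo} and \code{map} (path
#' overriding the packaged default complex map).
#'
#' @param config path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @param outDir output directory (created if needed).
#' @param seed overrides the configuration seed.
#' @return (invisibly) the result bundle: a list with the experiment, the
#'   complex map, \code{association}, \code{interfaces},
#'   \code{candidates}, \code{volcano}, \code{detected} and
#'   \code{manifest}.
#' @seealso \code{\link{renderReport}}
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  cfg <- if (is.character(config)) .readConfig(config) else config
  if (!is.list(cfg)) stop("config must be a file path or a list")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config must contain a 'simulate' or an 'inputs' block")
  if (is.null(seed)) seed <- cfg$seed %||% 1L
  alpha <- cfg$alpha %||% 0.05
  labelFold <- cfg$label_fold %||% 20
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    f <- file.path(outDir, name)
    write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
    f
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) fail(name, e))
  }

  map <- stage("map", {
    if (!is.null(cfg$inputs$map)) readComplexMap(cfg$inputs$map)
    else if (!is.null(cfg$map)) readComplexMap(cfg$map)
    else defaultComplexMap()
  })

  pe <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      design <- list(replicates = sim$replicates %||% 3L,
                     baits = sim$baits)
      sim$replicates <- NULL; sim$baits <- NULL
      truth <- makeGroundTruth(sim, seed = seed, map = map)
      simulatePulldown(truth, map, baits = design$baits,
                       replicates = design$replicates, seed = seed)
    } else {
      if (is.null(cfg$inputs$table)) stop("config key 'inputs$table' missing")
      readAbundanceTable(cfg$inputs$table, meta = cfg$inputs$meta)
    }
  })

  stage("validate", {
    rep <- validateDataset(pe, map)
    if (!isOK(rep))
      stop(paste(validationErrors(rep), collapse = "; "))
  })

  baitNorm <- stage("bait_normalization", normalizeToBait(pe, map))
  assoc <- stage("association", associationMatrix(baitNorm, map))
  ifs <- stage("interfaces",
               suppressWarnings(interfaceScores(baitNorm, map)))
  cand <- stage("interfaces", rankInterfaceCandidates(ifs, alpha = alpha))
  volcano <- stage("enrichment", {
    cd <- SummarizedExperiment::colData(pe)
    if (any(cd$bait == "WT"))
      enrichmentVsControl(normalizeTotal(pe), pseudo = cfg$pseudo,
                          alpha = alpha, labelFold = labelFold)
    else NULL
  })
  detected <- detectedSubunitCount(pe, map)

  manifest <- list(
    package = "PulldownAssoc",
    version = as.character(utils::packageVersion("PulldownAssoc")),
    seed = seed, alpha = alpha, label_fold = labelFold,
    config = cfg,
    n_proteins = nrow(pe), n_samples = ncol(pe),
    detected = detected)

  bundle <- list(experiment = pe, map = map, association = assoc,
                 interfaces = ifs, candidates = cand, volcano = volcano,
                 detected = detected, manifest = manifest)

  stage("write", {
    emit(assoc$table, "association.csv")
    emit(ifs, "interface_scores.csv")
    emit(cand, "interface_candidates.csv")
    if (!is.null(volcano)) emit(volcano, "volcano.csv")
    f <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <<- c(written, f)
    f <- file.path(outDir, "summary.txt")
    writeLines(renderReport(bundle), f)
    written <<- c(written, f)
  })
  invisible(bundle)
}

.readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

#' Render a human-readable report from a pipeline bundle
#'
#' Summarizes the bundle produced by \code{\link{runPipeline}}: detection
#' counts, the association percentage table with pairwise significance
#' stars per bait panel, the top interface candidates per complex, and
#' volcano category counts. Regeneration from the same bundle is
#' idempotent.
#'
#' @param bundle result list from \code{\link{runPipeline}}.
#' @param topN interface candidates shown per complex (default 3).
#' @return character vector of report lines.
#' @export
renderReport <- function(bundle, topN = 3L) {
  need <- c("association", "interfaces", "candidates", "detected")
  miss <- need[!need %in% names(bundle)]
  if (length(miss))
    stop("incomplete bundle; missing: ", paste(miss, collapse = ", "))
  out <- c("Pull-down supercomplex association report",
           "=========================================", "")
  det <- bundle$detected
  out <- c(out, sprintf(
    "Detected proteins: %d (of which %d mapped to the four photosynthetic complexes)",
    det$total, det$mappedToFour), "")

  tab <- bundle$association$table
  out <- c(out, sprintf("Association estimates (%d ordered pairs):",
                        nrow(tab)))
  for (i in seq_len(nrow(tab)))
    out <- c(out, sprintf("  %-7s with %-7s %6.2f%% +/- %s (n = %d)",
                          tab$bait[i], tab$partner[i], tab$meanPercent[i],
                          ifelse(is.na(tab$sdPercent[i]), "NA",
                                 sprintf("%.2f%%", tab$sdPercent[i])),
                          tab$n[i]))
  ests <- bundle$association$estimates
  cmp <- .pairwiseAssociationStars(ests)
  if (nrow(cmp)) {
    out <- c(out, "", "Within-bait partner comparisons (Student's t-test;",
             "  *0.01 < p < 0.05; **0.001 < p < 0.01; ***p < 0.001):")
    for (i in seq_len(nrow(cmp)))
      out <- c(out, sprintf("  %s: %s vs %s  p = %.3g %s", cmp$bait[i],
                            cmp$partner1[i], cmp$partner2[i], cmp$p[i],
                            cmp$star[i]))
  }

  out <- c(out, "", "Interface candidates (one-vs-rest):")
  cand <- bundle$candidates
  if (!nrow(cand)) {
    out <- c(out, "  none nominated")
  } else {
    for (cx in unique(cand$home)) {
      sub <- cand[cand$home == cx, , drop = FALSE]
      sub <- sub[seq_len(min(topN, nrow(sub))), , drop = FALSE]
      out <- c(out, sprintf("  %s: %s", cx,
                            paste(sprintf("%s in %s pulldown (ratio %.2f, p = %.3g %s)",
                                          sub$subunit, sub$bait,
                                          sub$meanRatio, sub$p, sub$star),
                                  collapse = "; ")))
    }
  }

  if (!is.null(bundle$volcano)) {
    out <- c(out, "", "Volcano vs WT control:")
    v <- bundle$volcano
    for (B in unique(v$bait)) {
      sub <- v[v$bait == B, ]
      out <- c(out, sprintf(
        "  %-7s %d enriched (%d labelled, > 20-fold), %d depleted, %d n.s.",
        B, sum(sub$category == "enriched"),
        sum(sub$labelled & sub$category == "enriched"),
        sum(sub$category == "depleted"),
        sum(sub$category == "not_significant")))
    }
  }
  out
}

# per bait panel, t-test each pair of partner estimates
.pairwiseAssociationStars <- function(ests) {
  rows <- list()
  baits <- unique(vapply(ests, function(e) e@bait, ""))
  for (B in baits) {
    es <- Filter(function(e) e@bait == B, ests)
    if (length(es) < 2L) next
    for (i in seq_len(length(es) - 1L)) for (j in seq(i + 1L, length(es))) {
      if (length(replicateRatios(es[[i]])) < 2L ||
          length(replicateRatios(es[[j]])) < 2L) next
      tt <- compareAssociations(es[[i]], es[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        bait = B, partner1 = es[[i]]@partner, partner2 = es[[j]]@partner,
        t = tt$t, p = tt$p, star = starAnnotation(tt$p))
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(bait = character(0), partner1 = character(0),
                  partner2 = character(0), t = numeric(0), p = numeric(0),
                  star = character(0))
}
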