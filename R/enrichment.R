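#' Equal-variance two-sample t-test
#'
#' Student's two-sided pooled-variance t-test, the statistic used
#' throughout the pipeline (association comparisons, interface one-vs-rest
#' tests, volcano analysis). Degenerate input in which both groups have
#' zero variance is resolved by convention: equal means give (t = 0,
#' p = 1); unequal means give infinite t and p = 0.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
twoSampleT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two values")
  df <- length(x) + length(y) - 2L
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Volcano classification of an enrichment result
#'
#' A protein is \code{enriched} when p < 0.05 with positive log2 fold
#' change, \code{depleted} when p < 0.05 with negative log2 fold change,
#' and \code{not_significant} otherwise (including the boundary log2FC = 0,
#' whose direction is undefined). Proteins beyond a 20-fold change in
#' either significant category carry the label flag used to annotate gene
#' names on the plot.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p numeric vector of p-values.
#' @param alpha significance line (default 0.05).
#' @param labelFold labelling threshold on the linear fold scale
#'   (default 20).
#' @return data.frame with columns \code{category} and \code{labelled}.
#' @export
classifyVolcano <- function(log2fc, p, alpha = 0.05, labelFold = 20) {
  stopifnot(length(log2fc) == length(p))
  category <- rep("not_significant", length(p))
  category[p < alpha & log2fc > 0] <- "enriched"
  category[p < alpha & log2fc < 0] <- "depleted"
  labelled <- category != "not_significant" & abs(log2fc) > log2(labelFold)
  data.frame(category = category, labelled = labelled)
}

#' Pulldown-versus-WT enrichment (volcano) analysis
#'
#' For every bait strain and protein, compares the replicate abundances in
#' the pulldown against the WT control on the equal-total scale (WT has no
#' GFP, so bait normalization cannot make it comparable): log2 fold change
#' of the replicate means (guarded by a pseudo-count) and a Student
#' t-test on the linear normalized values. Raw p-values drive the
#' classification, matching a volcano drawn at the p = 0.05 line; a
#' Benjamini-Hochberg column (per bait) is emitted alongside for
#' transparency.
#'
#' @param x a total-normalized \linkS4class{PulldownExperiment} containing
#'   WT samples.
#' @param pseudo pseudo-count added to both means before the ratio;
#'   default \code{1e-6} times the grand mean abundance.
#' @param alpha significance line (default 0.05).
#' @param labelFold labelling fold threshold (default 20).
#' @return data.frame with columns \code{protein}, \code{bait},
#'   \code{log2fc}, \code{t}, \code{p}, \code{bhP}, \code{category},
#'   \code{labelled}.
#' @export
enrichmentVsControl <- function(x, pseudo = NULL, alpha = 0.05,
                                labelFold = 20) {
  stopifnot(is(x, "PulldownExperiment"))
  if (scaleTag(x) != "total_normalized")
    stop("enrichmentVsControl expects total-normalized values; ",
         "run normalizeTotal() first")
  a <- SummarizedExperiment::assay(x, "abundance")
  cd <- SummarizedExperiment::colData(x)
  wt <- colnames(a)[cd$bait == "WT"]
  if (length(wt) < 2L) stop("at least two WT replicates are required")
  if (is.null(pseudo)) pseudo <- 1e-6 * mean(a)
  out <- list()
  for (B in setdiff(unique(cd$bait), "WT")) {
    bs <- colnames(a)[cd$bait == B]
    if (length(bs) < 2L)
      stop("at least two replicates are required for bait ", B)
    lfc <- numeric(nrow(a)); tv <- numeric(nrow(a)); pv <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      xi <- a[i, bs]; yi <- a[i, wt]
      lfc[i] <- log2((mean(xi) + pseudo) / (mean(yi) + pseudo))
      tt <- twoSampleT(xi, yi)
      tv[i] <- tt$t; pv[i] <- tt$p
    }
    cls <- classifyVolcano(lfc, pv, alpha = alpha, labelFold = labelFold)
    out[[B]] <- data.frame(protein = rownames(a), bait = B, log2fc = lfc,
                           t = tv, p = pv,
                           bhP = p.adjust(pv, method = "BH"),
                           category = cls$category,
                           labelled = cls$labelled)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
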