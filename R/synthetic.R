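#' Build the generative parameters of the pull-down simulator
#'
#' Constructs a \linkS4class{GroundTruth} from a configuration list. The
#' defaults emulate the Syn7942 study conditions: a PSI:PSII copy-number
#' ratio of 4.5, supercomplex counts chosen so that 9.9\% of PSII is
#' engaged with PSI, 4.1\% of Cyt b6f with PSI and 2.0\% of Cyt b6f with
#' PSII, 1:1 stoichiometry, uniform detection efficiency, capture scales
#' equal to the bait complex's copy number (reproducing the observed GFP
#' ordering PSI > PSII > Cyt b6f > ATPase), no nonspecific background and
#' log-scale noise SD 0.2. Copy numbers for Cyt b6f (0.7) and ATP synthase
#' (0.5) are placeholders, chosen only to preserve that ordering.
#'
#' @param config list (or parsed YAML/JSON) overriding the defaults; keys:
#'   \describe{
#'     \item{copy_number}{named list, complex -> copies per cell.}
#'     \item{supercomplex_count}{list of \code{{a, b, n}} (and optionally
#'       \code{s}) entries, one per unordered complex pair.}
#'     \item{stoichiometry}{single number applied to all pairs lacking an
#'       explicit \code{s} (default 1).}
#'     \item{detection_eff}{named list, protein -> d_p (default 1).}
#'     \item{background}{named list protein -> nu_p, or a single number
#'       applied to every mapped protein.}
#'     \item{extra_proteins}{list \code{{count, rate, prefix}} adding
#'       unmapped nonspecific proteins (ids \code{<prefix>001}, ...) with
#'       background rate \code{rate}; emulates the sticky proteome seen in
#'       WT controls.}
#'     \item{noise_sd}{log-scale Gaussian noise SD (default 0.2).}
#'     \item{capture_scale}{named list, bait -> kappa.}
#'     \item{interface_boost}{list of \code{{protein, bait, multiplier}}
#'       entries planting interface-proximity co-capture enrichment.}
#'   }
#' @param seed integer master seed (default 1).
#' @param map \linkS4class{ComplexMap} used to expand \code{background}
#'   given as a single number and to check complex ids; default
#'   \code{\link{defaultComplexMap}()}.
#' @return A validated \linkS4class{GroundTruth}; configurations in which
#'   some complex's association fractions would sum above 1 are rejected
#'   with an error naming the complex.
#' @examples
#' gt <- makeGroundTruth(list(copy_number = list(PSI = 450, PSII = 100),
#'                            supercomplex_count = list(
#'                              list(a = "PSI", b = "PSII", n = 10))))
#' associationTruth(gt)
#' @export
makeGroundTruth <- function(config = list(), seed = 1L,
                            map = defaultComplexMap()) {
  defaults <- list(
    copy_number = list(PSI = 4.5, PSII = 1.0, CYTB6F = 0.7, ATPASE = 0.5,
                       NDH1 = 0.4),
    supercomplex_count = list(
      list(a = "PSI", b = "PSII", n = 0.099),   # f[PSII][PSI] = 9.9%
      list(a = "PSI", b = "CYTB6F", n = 0.0287), # f[CYTB6F][PSI] = 4.1%
      list(a = "PSII", b = "CYTB6F", n = 0.014), # f[CYTB6F][PSII] = 2.0%
      list(a = "PSI", b = "ATPASE", n = 0.005),
      list(a = "PSII", b = "ATPASE", n = 0.005),
      list(a = "CYTB6F", b = "ATPASE", n = 0.005),
      list(a = "PSI", b = "NDH1", n = 0.02)),
    stoichiometry = 1,
    detection_eff = list(),
    background = list(),
    extra_proteins = NULL,
    noise_sd = 0.2,
    capture_scale = NULL)
  if (length(config)) {
    unknown <- setdiff(names(config),
                       c(names(defaults), "interface_boost", "seed"))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults[names(config)] <- config
  }
  cfg <- defaults
  if (!is.null(cfg$seed)) seed <- cfg$seed

  cn <- unlist(cfg$copy_number)
  # pairs involving complexes without a copy number are dropped (defaults
  # cover five complexes; a reduced copy_number restricts the system)
  pairs <- do.call(rbind, lapply(cfg$supercomplex_count, function(p) {
    # YAML 1.1 readers turn a bare "n" key into the boolean FALSE; accept
    # "count" and the mangled key as synonyms
    cnt <- p$n %||% p$count %||% p[["FALSE"]]
    if (is.null(cnt)) stop("supercomplex_count entry without an 'n' value")
    data.frame(a = as.character(p$a), b = as.character(p$b),
               n = as.numeric(cnt),
               s = if (!is.null(p$s)) as.numeric(p$s)
                   else as.numeric(cfg$stoichiometry))
  }))
  if (is.null(pairs))
    pairs <- data.frame(a = character(0), b = character(0),
                        n = numeric(0), s = numeric(0))
  keep <- pairs$a %in% names(cn) & pairs$b %in% names(cn)
  pairs <- pairs[keep, , drop = FALSE]

  for (B in names(cn)) {
    tot <- sum(pairs$n[pairs$a == B | pairs$b == B])
    if (tot > cn[[B]] * (1 + 1e-12))
      stop(sprintf(
        "supercomplex counts exceed the copy number of %s (sum n = %g > N = %g)",
        B, tot, cn[[B]]))
  }

  bg <- cfg$background
  if (is.numeric(bg) && length(bg) == 1L && is.null(names(bg))) {
    bg <- setNames(rep(as.numeric(bg), length(membership(map))),
                   names(membership(map)))
  } else bg <- unlist(bg)
  if (is.null(bg)) bg <- numeric(0)
  if (!is.null(cfg$extra_proteins)) {
    ex <- cfg$extra_proteins
    prefix <- if (is.null(ex$prefix)) "Nsb" else ex$prefix
    ids <- sprintf("%s%03d", prefix, seq_len(ex$count))
    bg <- c(bg, setNames(rep(as.numeric(ex$rate), length(ids)), ids))
  }

  kappa <- if (is.null(cfg$capture_scale)) {
    k <- cn[intersect(names(cn), .BAITS)]
    c(k, WT = 1)
  } else unlist(cfg$capture_scale)

  boost <- config$interface_boost
  boost <- if (is.null(boost))
    data.frame(protein = character(0), bait = character(0),
               multiplier = numeric(0))
  else do.call(rbind, lapply(boost, function(b)
    data.frame(protein = as.character(b$protein),
               bait = as.character(b$bait),
               multiplier = as.numeric(b$multiplier))))

  new("GroundTruth", copyNumber = cn, pairs = pairs,
      detectionEff = unlist(cfg$detection_eff) %||% numeric(0),
      backgroundRate = bg, noiseSd = as.numeric(cfg$noise_sd),
      captureScale = kappa, interfaceBoost = boost,
      seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.lookup <- function(v, key, default) {
  if (length(v) && key %in% names(v)) unname(v[[key]]) else default
}

# f[B][A] = n_AB / N_B and per-pair stoichiometry
.truthFraction <- function(truth, bait, partner) {
  p <- truth@pairs
  hit <- (p$a == bait & p$b == partner) | (p$b == bait & p$a == partner)
  if (!any(hit)) return(list(f = 0, s = 1))
  list(f = p$n[hit][1L] / truth@copyNumber[[bait]], s = p$s[hit][1L])
}

#' Noise-free expected abundance under the observation model
#'
#' The closed-form expectation the simulator draws around, used as the
#' oracle for the downstream estimators. For bait strain B (not WT) and a
#' protein p belonging to complex C the expected raw abundance is
#' \code{kappa_B * d_p * m + nu_p}, with occupancy \code{m = 1} when
#' \code{C == B} (the bait's own subunits ride along once per captured
#' complex) and \code{m = f[B][C] * s} otherwise (only the engaged fraction
#' of B brings C along, s partner copies per supercomplex); planted
#' interface boosts multiply the co-capture occupancy. The GFP marker has
#' expectation \code{kappa_B * d_GFP}. In the WT strain nothing is
#' captured: every protein shows only its nonspecific background
#' \code{nu_p}, and GFP is absent (0).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param bait bait strain: a complex id or \code{"WT"}.
#' @param protein protein id (mapped in \code{map}, or the GFP marker).
#' @param map a \linkS4class{ComplexMap}.
#' @return the expected abundance (non-negative scalar).
#' @export
expectedAbundance <- function(truth, bait, protein, map) {
  stopifnot(is(truth, "GroundTruth"), is(map, "ComplexMap"))
  kappa <- .lookup(truth@captureScale, bait, 1)
  if (protein == gfpId(map)) {
    if (bait == "WT") return(0)
    return(kappa * .lookup(truth@detectionEff, protein, 1))
  }
  nu <- .lookup(truth@backgroundRate, protein, 0)
  mapped <- protein %in% names(membership(map))
  if (!mapped && protein %in% names(truth@backgroundRate))
    return(nu)  # unmapped nonspecific protein: background only
  if (!mapped) stop("unknown protein: ", protein)
  if (bait == "WT") return(nu)
  cx <- membership(map)[[protein]]
  if (cx == bait) {
    m <- 1
  } else if (bait %in% names(truth@copyNumber) &&
             cx %in% names(truth@copyNumber)) {
    fs <- .truthFraction(truth, bait, cx)
    m <- fs$f * fs$s
  } else m <- 0
  b <- truth@interfaceBoost
  if (cx != bait && nrow(b)) {
    hit <- b$protein == protein & b$bait == bait
    if (any(hit)) m <- m * b$multiplier[hit][1L]
  }
  kappa * .lookup(truth@detectionEff, protein, 1) * m + nu
}

# deterministic per-cell RNG substream: a string hash of (sample, protein)
# combined with the master seed, so adding a protein or sample never
# perturbs other cells. All arithmetic stays below 2^53 (exact in doubles).
.strHash <- function(s) {
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  h
}

.cellSeed <- function(seed, sampleId, proteinId) {
  h <- (abs(seed) %% 2147483647) * 2654435 +
    .strHash(sampleId) * 40503 + .strHash(proteinId)
  as.integer(h %% 2147483647)
}

#' Simulate a pull-down experiment
#'
#' Forward-simulates triplicate (by default) GFP pull-downs for the four
#' bait strains plus the untagged WT control. Each cell of the resulting
#' table is the model expectation (\code{\link{expectedAbundance}})
#' perturbed by multiplicative log-normal noise,
#' \code{value = E * exp(eps)}, \code{eps ~ N(0, noiseSd^2)}, drawn from a
#' substream seeded deterministically by (seed, sample, protein). The same
#' (truth, design, seed) always reproduces the identical table.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param map a \linkS4class{ComplexMap}; simulated proteins are the
#'   mapped subunits, any proteins with a background rate, and the GFP
#'   marker.
#' @param baits bait strains to simulate (default the four complexes plus
#'   WT, restricted to complexes with a copy number).
#' @param replicates replicates per strain (default 3, the study design).
#' @param seed master seed; defaults to the seed stored in \code{truth}.
#' @return A \linkS4class{PulldownExperiment} with scale tag \code{"raw"}.
#' @examples
#' gt <- makeGroundTruth(list(noise_sd = 0))
#' pe <- simulatePulldown(gt)
#' dim(pe)
#' @export
simulatePulldown <- function(truth, map = defaultComplexMap(),
                             baits = NULL, replicates = 3L,
                             seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(map, "ComplexMap"),
            replicates >= 1L)
  if (is.null(seed)) seed <- truth@seed
  if (is.null(baits))
    baits <- c(intersect(.FOUR_COMPLEXES, names(truth@copyNumber)), "WT")
  proteins <- unique(c(gfpId(map), names(membership(map)),
                       names(truth@backgroundRate)))
  sampleIds <- as.vector(t(outer(baits, seq_len(replicates),
                                 function(b, r) sprintf("%s_r%d", b, r))))
  sampleBait <- rep(baits, each = replicates)
  sampleRep <- rep(seq_len(replicates), times = length(baits))

  vals <- matrix(0, length(proteins), length(sampleIds),
                 dimnames = list(proteins, sampleIds))
  sigma <- truth@noiseSd
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  for (j in seq_along(sampleIds)) {
    for (i in seq_along(proteins)) {
      mu <- expectedAbundance(truth, sampleBait[j], proteins[i], map)
      if (mu > 0 && sigma > 0) {
        set.seed(.cellSeed(seed, sampleIds[j], proteins[i]))
        mu <- mu * exp(rnorm(1L, 0, sigma))
      }
      vals[i, j] <- mu
    }
  }
  PulldownExperiment(vals, bait = sampleBait, replicate = sampleRep,
                     scaleTag = "raw")
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
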