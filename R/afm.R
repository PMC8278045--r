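#' Synthesize an AFM topograph
#'
#' Builds a height grid as a sum of isotropic Gaussian bumps — one per
#' listed peak of each particle (a trimer contributes its vertex
#' protrusions, a dimer two) — plus i.i.d. Gaussian height noise.
#' Tip-sample convolution is deliberately not modelled: synthetic widths
#' are not comparable to real images, while peak heights and peak-to-peak
#' (vertex) distances are, and those are the observables measured here.
#'
#' @param particles list of particles; each a list with \code{peaks}
#'   (n x 2 matrix of x, y positions in nm), \code{amplitude} (bump height
#'   in nm) and \code{width} (Gaussian SD in nm); an optional
#'   \code{center} (x, y offset in nm, default c(0, 0)) shifts all peaks.
#' @param pixelNm nm per pixel.
#' @param gridSize c(rows, cols) of the grid (default 64 x 64).
#' @param noiseSd SD of per-pixel height noise in nm (default 0).
#' @param seed integer seed for the noise (default 1).
#' @return A \linkS4class{Topograph}.
#' @examples
#' t <- synthTopograph(list(list(peaks = rbind(c(10, 16), c(22, 16)),
#'                               amplitude = 5.6, width = 2)),
#'                     pixelNm = 0.5)
#' @export
synthTopograph <- function(particles, pixelNm, gridSize = c(64L, 64L),
                           noiseSd = 0, seed = 1L) {
  stopifnot(pixelNm > 0, length(gridSize) == 2L, all(gridSize >= 8L))
  H <- gridSize[1L]; W <- gridSize[2L]
  # pixel centres
  xs <- (seq_len(W) - 0.5) * pixelNm
  ys <- (seq_len(H) - 0.5) * pixelNm
  z <- matrix(0, H, W)
  for (p in particles) {
    ctr <- if (is.null(p$center)) c(0, 0) else p$center
    pk <- rbind(p$peaks)
    pk <- sweep(matrix(as.numeric(pk), ncol = 2L), 2L, ctr, "+")
    if (any(pk[, 1L] < 0 | pk[, 1L] > W * pixelNm |
            pk[, 2L] < 0 | pk[, 2L] > H * pixelNm))
      stop("peak outside the grid")
    for (k in seq_len(nrow(pk))) {
      dx2 <- outer(rep(1, H), (xs - pk[k, 1L])^2)
      dy2 <- outer((ys - pk[k, 2L])^2, rep(1, W))
      z <- z + p$amplitude * exp(-(dx2 + dy2) / (2 * p$width^2))
    }
  }
  if (noiseSd > 0) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(as.integer(seed))
    z <- z + matrix(rnorm(H * W, 0, noiseSd), H, W)
  }
  Topograph(z, pixelNm)
}

# bilinear interpolation of heights at (x, y) nm; pixel centres at
# half-integers, values clamped to the border pixel beyond the centres
.bilinear <- function(z, pixelNm, x, y) {
  H <- nrow(z); W <- ncol(z)
  cx <- pmin(pmax(x / pixelNm - 0.5, 0), W - 1)
  cy <- pmin(pmax(y / pixelNm - 0.5, 0), H - 1)
  j0 <- pmin(floor(cx), W - 2); i0 <- pmin(floor(cy), H - 2)
  fx <- cx - j0; fy <- cy - i0
  idx <- function(i, j) z[cbind(i + 1, j + 1)]
  (1 - fx) * (1 - fy) * idx(i0, j0) + fx * (1 - fy) * idx(i0, j0 + 1) +
    (1 - fx) * fy * idx(i0 + 1, j0) + fx * fy * idx(i0 + 1, j0 + 1)
}

#' Extract a cross-section profile from a topograph
#'
#' Samples heights by bilinear interpolation at pixel-spaced positions
#' along the segment from \code{p1} to \code{p2} (both in nm), averaging
#' over \code{widthPx} parallel lines offset perpendicular to the segment
#' at pixel spacing — the standard cross-section tool of AFM analysis
#' software.
#'
#' @param topo a \linkS4class{Topograph}.
#' @param p1,p2 segment endpoints, c(x, y) in nm, inside the grid.
#' @param widthPx odd integer number of averaged parallel lines
#'   (default 1).
#' @return data.frame with columns \code{position} (nm along the segment)
#'   and \code{height} (nm).
#' @export
extractProfile <- function(topo, p1, p2, widthPx = 1L) {
  stopifnot(is(topo, "Topograph"), length(p1) == 2L, length(p2) == 2L,
            widthPx >= 1L, widthPx %% 2L == 1L)
  z <- heights(topo); px <- pixelNm(topo)
  lim <- c(ncol(z), nrow(z)) * px
  for (p in list(p1, p2))
    if (any(p < 0) || p[1L] > lim[1L] || p[2L] > lim[2L])
      stop("profile endpoint outside the grid")
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length profile segment")
  u <- d / len
  normal <- c(-u[2L], u[1L])
  pos <- seq(0, len, by = px)
  offs <- (seq_len(widthPx) - (widthPx + 1L) / 2L) * px
  h <- vapply(pos, function(s) {
    pt <- p1 + s * u
    mean(vapply(offs, function(o) {
      q <- pt + o * normal
      .bilinear(z, px, q[1L], q[2L])
    }, 0))
  }, 0)
  data.frame(position = pos, height = h)
}

# local maxima (plateau-aware) of a numeric vector; returns indices
.localMaxima <- function(h) {
  n <- length(h)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (h[i] > h[i - 1L]) {
      j <- i
      while (j < n && h[j + 1L] == h[i]) j <- j + 1L
      if (j < n && h[j + 1L] < h[i])
        out <- c(out, as.integer((i + j) %/% 2L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of the peak at index i: height above the higher
# of the two key saddles (minimum towards the nearest higher terrain on
# each side, or towards the data edge when none exists)
.prominence <- function(h, i) {
  left <- h[seq_len(i - 1L)]
  right <- h[seq(i + 1L, length(h))]
  side <- function(v) {
    higher <- which(v > h[i])
    if (length(v) == 0L) return(h[i])
    if (length(higher)) min(v[seq(max(higher), length(v))]) else min(v)
  }
  lbase <- side(rev(left))   # walk leftwards
  rbase <- side(right)
  h[i] - max(lbase, rbase)
}

#' Measure particle height and vertex distance from a profile
#'
#' Mirrors manual cross-section morphometry: the background is the median
#' of the first and last 10\% of profile samples (the profile ends rest on
#' the support), the particle height is the profile maximum above that
#' background, and the vertex distance is the separation between the first
#' and last local maximum whose topographic prominence reaches
#' \code{minProminenceNm}. Profiles with fewer than two prominent peaks
#' yield a height but no vertex distance; profiles with no signal above
#' background + prominence yield no measurement.
#'
#' @param profile data.frame from \code{\link{extractProfile}} (columns
#'   \code{position}, \code{height}), at least 5 samples.
#' @param minProminenceNm minimum peak prominence in nm (default 0.5,
#'   the scale of the height SDs reported for these particles).
#' @return list with \code{height_nm}, \code{vertex_distance_nm}
#'   (\code{NA} when fewer than two prominent peaks), \code{n_peaks},
#'   \code{background_nm} and, when no measurement is possible,
#'   \code{reason}.
#' @export
measureProfile <- function(profile, minProminenceNm = 0.5) {
  stopifnot(is.data.frame(profile),
            all(c("position", "height") %in% colnames(profile)))
  h <- profile$height
  n <- length(h)
  if (n < 5L) stop("profile too short (need >= 5 samples)")
  k <- max(1L, floor(0.1 * n))
  bg <- median(c(h[seq_len(k)], h[seq(n - k + 1L, n)]))
  if (max(h) < bg + minProminenceNm)
    return(list(height_nm = NA_real_, vertex_distance_nm = NA_real_,
                n_peaks = 0L, background_nm = bg,
                reason = "no sample above background + prominence"))
  peaks <- .localMaxima(h)
  peaks <- peaks[vapply(peaks, function(i)
    .prominence(h, i) >= minProminenceNm, NA)]
  vd <- if (length(peaks) >= 2L)
    abs(profile$position[peaks[length(peaks)]] -
          profile$position[peaks[1L]])
  else NA_real_
  list(height_nm = max(h) - bg, vertex_distance_nm = vd,
       n_peaks = length(peaks), background_nm = bg)
}

#' Summarize particle measurements
#'
#' Mean and sample SD (n - 1 denominator) of the measured heights and
#' vertex distances over a set of particles; the SD is absent for a single
#' observation and \code{NA} measurements are dropped per observable.
#'
#' @param ms list of measurements from \code{\link{measureProfile}}.
#' @return data.frame with one row per observable: \code{observable},
#'   \code{n}, \code{mean}, \code{sd}.
#' @export
summarizeMeasurements <- function(ms) {
  if (!length(ms)) stop("no measurements to summarize")
  one <- function(field) {
    v <- vapply(ms, function(m) as.numeric(m[[field]]), 0)
    v <- v[!is.na(v)]
    data.frame(observable = field, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_)
  }
  out <- rbind(one("height_nm"), one("vertex_distance_nm"))
  rownames(out) <- NULL
  out
}

#' Reference AFM morphometry of Syn7942 photosystem particles
#'
#' Published reference values for comparison with measured summaries: the
#' PSI trimer (height 5.7 +/- 0.5 nm, vertex distance 9.6 +/- 0.8 nm,
#' n = 21) and the PSII dimer (5.6 +/- 0.5 nm, 10.4 +/- 1.16 nm, n = 11).
#'
#' @return data.frame with one row per particle type.
#' @export
afmReference <- function() {
  data.frame(
    particle = c("PSI_trimer", "PSII_dimer"),
    height_mean_nm = c(5.7, 5.6), height_sd_nm = c(0.5, 0.5),
    vertex_mean_nm = c(9.6, 10.4), vertex_sd_nm = c(0.8, 1.16),
    n = c(21L, 11L))
}

#' Read a topograph from a CSV height grid
#'
#' A plain numeric grid (rows y, columns x, heights in nm) with no header.
#'
#' @param path CSV file.
#' @param pixelNm nm per pixel.
#' @return A \linkS4class{Topograph}.
#' @export
readTopographCSV <- function(path, pixelNm) {
  if (!file.exists(path)) stop("file not found: ", path)
  z <- as.matrix(read.csv(path, header = FALSE))
  dimnames(z) <- NULL
  Topograph(z, pixelNm)
}
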