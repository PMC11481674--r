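# A profile channel counts as constant when its range is negligible relative
# to its magnitude (bilinear interpolation leaves ~1e-14 wobble on a flat
# image).
near_constant <- function(v) {
  diff(range(v)) <= 1e-9 * max(1, max(abs(v)))
}

# Intensity profiles along a cell's plasma-membrane contour: unwrapping the
# fitted ellipse into an arc-length axis, per-channel radial-max sampling
# within the membrane band, min-max normalization, two-channel Pearson
# correlation with a circular-permutation null, and cortical-puncta peak
# detection / overlap. Profiles are circular (they wrap); the start point is
# anchored at the major-axis vertex so repeated runs line up.

#' Extract a membrane intensity profile for one cell
#'
#' At `n_samples` points equally spaced in arc length along the ROI's fitted
#' ellipse (starting at the major-axis vertex, counter-clockwise), records a
#' radial statistic of the image within `band_halfwidth` of the contour
#' along the local normal. The default statistic is the maximum, which
#' preserves the contrast of sub-band-width cortical punctae; `"mean"` is
#' available as an option.
#'
#' @param m a [micrograph()]
#' @param roi a `cell_roi`
#' @param band_halfwidth radial search half-width, micrometres
#' @param n_samples number of contour samples (>= 36); the default gives
#'   roughly one sample per boundary pixel for a 4--6 um yeast cell at
#'   0.08 um/px
#' @param stat `"max"` (default) or `"mean"`
#' @return object of class `membrane_profile`: arc positions (micrometres),
#'   per-channel raw `intensity` matrix (`n_samples` x channels), the
#'   contour `perimeter_um`, and per-channel `constant` flags
#' @export
extract_membrane_profile <- function(m, roi, band_halfwidth = 0.25,
                                     n_samples = 144L,
                                     stat = c("max", "mean")) {
  stat <- match.arg(stat)
  if (n_samples < 36L) stop("n_samples must be at least 36")
  ell <- roi$ellipse
  tab <- ellipse_arc_table(ell)
  per_px <- ellipse_perimeter(ell, tab)
  if (per_px < n_samples) {
    warning(sprintf("contour (%.0f px) shorter than n_samples=%d; reduced",
                    per_px, n_samples))
    n_samples <- max(36L, floor(per_px))
  }
  s <- seq(0, per_px, length.out = n_samples + 1L)[seq_len(n_samples)]
  tt <- ellipse_arc_to_t(ell, s, tab)
  pts <- ellipse_point(ell, tt)
  nrm <- ellipse_normal(ell, tt)
  band_px <- band_halfwidth / m$pixel_size
  offs <- seq(-band_px, band_px, by = 0.25)
  inten <- sapply(names(m$channels), function(chn) {
    img <- m$channels[[chn]]
    vals <- vapply(seq_len(n_samples), function(i) {
      v <- bilinear(img, pts[i, 1] + offs * nrm[i, 1],
                    pts[i, 2] + offs * nrm[i, 2])
      if (stat == "max") max(v) else mean(v)
    }, numeric(1))
    vals
  })
  inten <- matrix(inten, nrow = n_samples,
                  dimnames = list(NULL, names(m$channels)))
  structure(list(cell_label = roi$label, n_samples = n_samples,
                 arc_um = s * m$pixel_size,
                 perimeter_um = per_px * m$pixel_size,
                 intensity = inten,
                 normalized = NULL,
                 constant = apply(inten, 2, near_constant)),
            class = "membrane_profile")
}

#' Min-max normalize a membrane profile to [0, 1]
#'
#' Per channel; a constant channel maps to 0.5 everywhere and keeps its
#' `constant` flag. Idempotent on already-normalized profiles.
#'
#' @param profile a `membrane_profile`
#' @return the profile with its `normalized` matrix filled in
#' @export
normalize_profile <- function(profile) {
  norm <- apply(profile$intensity, 2, function(v) {
    r <- range(v)
    if (near_constant(v)) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
  profile$normalized <- matrix(norm, nrow = profile$n_samples,
                               dimnames = dimnames(profile$intensity))
  profile
}

#' Pearson correlation of two membrane-profile channels
#'
#' Computed on the raw (un-normalized) profiles; invariant to per-channel
#' affine rescaling, so it equals the correlation of the normalized traces.
#'
#' @param v1,v2 numeric vectors of equal length (profile channels), or a
#'   `membrane_profile` each with the channel chosen via `channel1`,
#'   `channel2`
#' @param channel1,channel2 channel names used when profiles are passed
#' @return list with `r` (in `[-1, 1]`, `NA` with `undefined = TRUE` for a
#'   constant channel) and `n`
#' @export
profile_correlation <- function(v1, v2, channel1 = 1L, channel2 = 2L) {
  if (inherits(v1, "membrane_profile")) v1 <- v1$intensity[, channel1]
  if (inherits(v2, "membrane_profile")) v2 <- v2$intensity[, channel2]
  if (length(v1) != length(v2)) stop("profiles must have equal n_samples")
  if (near_constant(v1) || near_constant(v2))
    return(list(r = NA_real_, n = length(v1), undefined = TRUE))
  list(r = cor(v1, v2), n = length(v1), undefined = FALSE)
}

#' Circular-permutation null for a profile correlation
#'
#' Breaks the spatial registration of two circular profiles by correlating
#' channel 1 against random circular shifts of channel 2, preserving each
#' channel's autocorrelation. Returns the observed r, the null quantile of
#' |r| at `level`, and a permutation p-value for |r|.
#'
#' @param v1,v2 profile channels (vectors of equal length)
#' @param n_perm number of random shifts
#' @param level quantile of the null |r| distribution to report
#' @return list with `r`, `null_q`, `p_value`, `n_perm`
#' @export
profile_correlation_null <- function(v1, v2, n_perm = 1000L, level = 0.95) {
  n <- length(v1)
  if (length(v2) != n) stop("profiles must have equal n_samples")
  obs <- profile_correlation(v1, v2)
  if (obs$undefined) return(list(r = NA_real_, null_q = NA_real_,
                                 p_value = NA_real_, n_perm = n_perm))
  shifts <- sample.int(n - 1L, n_perm, replace = TRUE)
  rnull <- vapply(shifts, function(k)
    cor(v1, v2[c((k + 1L):n, 1L:k)]), numeric(1))
  list(r = obs$r,
       null_q = as.numeric(quantile(abs(rnull), level)),
       p_value = (1 + sum(abs(rnull) >= abs(obs$r))) / (1 + n_perm),
       n_perm = n_perm)
}

# Circular prominence of each local maximum of v: walk both ways from the
# peak until a higher sample appears; prominence = peak - the higher of the
# two valley minima found on the walks.
circular_prominences <- function(v) {
  n <- length(v)
  vv <- c(v, v, v)  # unrolled for circular walks
  peaks <- which(v > vv[n + seq_len(n) - 1] & v >= vv[n + seq_len(n) + 1])
  if (length(peaks) == 0) return(list(peaks = integer(0), prom = numeric(0)))
  prom <- vapply(peaks, function(p) {
    pc <- n + p
    lo_l <- vv[pc]
    i <- pc - 1L
    while (i > pc - n && vv[i] <= vv[pc]) { lo_l <- min(lo_l, vv[i]); i <- i - 1L }
    lo_r <- vv[pc]
    i <- pc + 1L
    while (i < pc + n && vv[i] <= vv[pc]) { lo_r <- min(lo_r, vv[i]); i <- i + 1L }
    vv[pc] - max(lo_l, lo_r)
  }, numeric(1))
  list(peaks = peaks, prom = prom)
}

#' Detect cortical punctae as circular profile peaks
#'
#' Local maxima of the normalized profile with circular prominence at least
#' `min_prominence`, thinned to a minimum circular arc separation by keeping
#' higher-prominence peaks first (ties broken toward lower arc position).
#' Deterministic; may return an empty set.
#'
#' @param profile a `membrane_profile` (normalized if needed)
#' @param channel channel name or index
#' @param min_prominence minimum peak prominence on the normalized `[0,1]`
#'   scale
#' @param min_separation minimum circular separation between reported peaks,
#'   micrometres
#' @return numeric vector of peak arc positions (micrometres along the
#'   contour)
#' @export
detect_cortical_puncta <- function(profile, channel = 1L,
                                   min_prominence = 0.2,
                                   min_separation = 0.2) {
  if (is.null(profile$normalized)) profile <- normalize_profile(profile)
  if (isTRUE(profile$constant[[channel]])) return(numeric(0))
  v <- profile$normalized[, channel]
  if (diff(range(v)) == 0) return(numeric(0))
  cp <- circular_prominences(v)
  keep <- cp$prom >= min_prominence
  peaks <- cp$peaks[keep]; prom <- cp$prom[keep]
  if (length(peaks) == 0) return(numeric(0))
  ord <- order(-prom, peaks)  # higher prominence first, then lower arc
  per <- profile$perimeter_um
  pos <- profile$arc_um[peaks[ord]]
  chosen <- numeric(0)
  for (p in pos) {
    d <- abs(p - chosen)
    d <- pmin(d, per - d)
    if (all(d >= min_separation)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Fraction of channel-1 punctae matched in channel 2
#'
#' Greedy nearest-first matching on the circular contour: peak pairs are
#' considered in order of circular distance and matched within
#' `tolerance_arc`, each peak used at most once.
#'
#' @param peaks1,peaks2 arc positions (micrometres) from
#'   [detect_cortical_puncta()] on the same contour
#' @param perimeter_um contour perimeter, micrometres
#' @param tolerance_arc match tolerance along the contour, micrometres
#' @return list with `fraction` (of channel-1 peaks matched; `NA` with
#'   `undefined = TRUE` when channel 1 has no peaks), `n_matched`, and the
#'   matched index `pairs`
#' @export
puncta_overlap <- function(peaks1, peaks2, perimeter_um,
                           tolerance_arc = 0.3) {
  if (length(peaks1) == 0)
    return(list(fraction = NA_real_, n_matched = 0L,
                pairs = matrix(integer(0), 0, 2), undefined = TRUE))
  if (length(peaks2) == 0)
    return(list(fraction = 0, n_matched = 0L,
                pairs = matrix(integer(0), 0, 2), undefined = FALSE))
  d <- abs(outer(peaks1, peaks2, "-"))
  d <- pmin(d, perimeter_um - d)
  ord <- order(d)
  used1 <- logical(length(peaks1)); used2 <- logical(length(peaks2))
  pairs <- matrix(integer(0), 0, 2)
  for (k in ord) {
    if (d[k] > tolerance_arc) break
    i <- (k - 1) %% length(peaks1) + 1
    j <- (k - 1) %/% length(peaks1) + 1
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  list(fraction = sum(used1) / length(peaks1), n_matched = sum(used1),
       pairs = pairs, undefined = FALSE)
}

#' Serialize a membrane profile as a CSV table
#'
#' Columns: sample index, arc position (micrometres), then raw and
#' normalized intensity per channel.
#'
#' @param profile a `membrane_profile`
#' @param path output CSV path
#' @export
write_profile <- function(profile, path) {
  if (is.null(profile$normalized)) profile <- normalize_profile(profile)
  df <- data.frame(sample = seq_len(profile$n_samples),
                   arc_um = fmt_num(profile$arc_um))
  for (chn in colnames(profile$intensity)) {
    df[[paste0("raw_", chn)]] <- fmt_num(profile$intensity[, chn])
    df[[paste0("norm_", chn)]] <- fmt_num(profile$normalized[, chn])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
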