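#' Fourier self-deconvolution configuration
#'
#' FSD narrows absorption bands by dividing the Fourier transform of the
#' spectrum by the transform of an assumed intrinsic Lorentzian lineshape.
#' This implementation uses the re-convolution form: the interferogram is
#' multiplied by `exp(pi * band_fwhm * (1 - 1/K) * |t|)`, i.e. the assumed
#' Lorentzian of width `band_fwhm` is removed and a Lorentzian of width
#' `band_fwhm / K` is put back, so a matched band comes out narrowed by the
#' enhancement factor `K` with its integrated area preserved. An apodization
#' taper over the outer half of the interferogram controls noise
#' amplification.
#'
#' @param band_fwhm assumed intrinsic Lorentzian full width at half maximum
#'   (cm-1), default 12.
#' @param enhancement narrowing factor K, `1 < K <= 4`, default 2.
#' @param apodization `"triangle_squared"` (default), `"bessel"` or
#'   `"boxcar"` (no taper; with K -> 1 this makes FSD the identity).
#' @return Object of class `fsd_config`.
#' @export
fsd_config <- function(band_fwhm = 12, enhancement = 2.0,
                       apodization = c("triangle_squared", "bessel",
                                       "boxcar")) {
  apodization <- match.arg(apodization)
  if (band_fwhm <= 0) stop("band_fwhm must be positive")
  if (enhancement <= 1 || enhancement > 4)
    stop("enhancement must satisfy 1 < K <= 4")
  structure(list(band_fwhm = band_fwhm, enhancement = enhancement,
                 apodization = apodization),
            class = "fsd_config")
}

#' Fourier self-deconvolution of a spectrum
#'
#' See [fsd_config()] for the algorithm. A linear ramp through the first and
#' last point is subtracted before the FFT (and restored afterwards) and the
#' trace is zero-padded to reduce wrap-around. The maximum interferogram
#' weight (the worst-case noise amplification) is attached as attribute
#' `amplification`.
#'
#' @param s an `ir_spectrum` on a uniform grid.
#' @param cfg an [fsd_config()].
#' @return The deconvolved `ir_spectrum`.
#' @export
fsd <- function(s, cfg = fsd_config()) {
  stopifnot(inherits(s, "ir_spectrum"))
  y <- s$absorbance
  n <- length(y)
  step <- wn_step(s$wavenumber)
  # remove the endpoint-to-endpoint ramp so the padded signal has no jump
  ramp <- y[1] + (y[n] - y[1]) * (seq_len(n) - 1) / (n - 1)
  yd <- y - ramp
  m <- 2^ceiling(log2(2 * n))
  yp <- c(yd, rep(0, m - n))
  j <- 0:(m - 1)
  t <- pmin(j, m - j) / (m * step)  # conjugate variable, cm
  w <- exp(pi * cfg$band_fwhm * (1 - 1 / cfg$enhancement) * t) *
    fsd_apodization(t, 1 / (2 * step), cfg$apodization)
  amp <- max(w)
  if (amp > 1e6)
    stop(sprintf(
      "FSD weight reaches %.3g (> 1e6); reduce enhancement or band_fwhm",
      amp))
  out <- Re(stats::fft(stats::fft(yp) * w, inverse = TRUE)) / m
  res <- ir_spectrum(s$wavenumber, out[seq_len(n)] + ramp, s$meta)
  attr(res, "amplification") <- amp
  res
}

# Apodization over the interferogram: unity up to half the usable range,
# tapered to zero at the end (t_max = 1/(2*step), the sampling limit).
fsd_apodization <- function(t, t_max, kind) {
  if (kind == "boxcar") return(rep(1, length(t)))
  t0 <- 0.5 * t_max
  u <- pmin(pmax((t - t0) / (t_max - t0), 0), 1)
  switch(kind,
         triangle_squared = (1 - u)^2,
         bessel = (1 - u^2)^2)
}

#' Pick absorption bands via second-derivative minima
#'
#' Band maxima of the raw spectrum appear as minima of the Savitzky-Golay
#' second derivative, independently of baseline. Minima within `window`
#' whose depth is at least `rel_threshold` times the deepest minimum are
#' reported as peaks; minima between `shoulder_floor` and `rel_threshold`
#' times the deepest are flagged `"shoulder"`. Minima closer than
#' `min_separation` are merged, keeping the deeper one (ties: higher
#' wavenumber).
#'
#' @param s an `ir_spectrum`.
#' @param window numeric `c(lo, hi)` in cm-1 (inclusive, snapped to grid).
#' @param rel_threshold fraction of the deepest minimum (default 0.1).
#' @param min_separation minimum distance between reported bands (cm-1).
#' @param shoulder_floor fraction below which minima are discarded.
#' @param cfg [preprocess_config()] controlling the derivative filter.
#' @return Data frame of class `peak_list` with columns `center`,
#'   `prominence` (second-derivative depth) and `kind`, sorted by
#'   descending wavenumber; attribute `id` carries the sample id.
#' @export
pick_peaks <- function(s, window, rel_threshold = 0.1, min_separation = 6,
                       shoulder_floor = 0.05, cfg = preprocess_config()) {
  stopifnot(inherits(s, "ir_spectrum"), length(window) == 2)
  empty <- structure(data.frame(center = numeric(0), prominence = numeric(0),
                                kind = character(0),
                                stringsAsFactors = FALSE),
                     class = c("peak_list", "data.frame"),
                     id = s$meta$sample_id[1])
  if (diff(range(s$absorbance)) == 0) return(empty)
  d <- second_derivative(s, cfg)
  grid <- canonical_grid(d$wavenumber[1],
                         d$wavenumber[length(d$wavenumber)],
                         wn_step(d$wavenumber))
  idx <- snap_window(min(window), max(window), grid)
  sel <- idx[1]:idx[2]
  v <- d$absorbance[sel]
  wn <- d$wavenumber[sel]
  k <- length(v)
  if (k < 2) stop("window too narrow for peak picking")
  left <- c(Inf, v[-k])   # window-edge points use their single neighbor
  right <- c(v[-1], Inf)
  is_min <- v < 0 & v <= left & v <= right
  cand <- which(is_min)
  if (!length(cand)) return(empty)
  depth <- -v[cand]
  deepest <- max(depth)
  keep <- depth >= shoulder_floor * deepest
  cand <- cand[keep]; depth <- depth[keep]
  # merge near-coincident minima: deepest first, ties to higher wavenumber
  o <- order(-depth, -wn[cand])
  acc <- integer(0)
  for (i in o) {
    if (!length(acc) || all(abs(wn[cand[acc]] - wn[cand[i]]) >= min_separation))
      acc <- c(acc, i)
  }
  cand <- cand[acc]; depth <- depth[acc]
  kind <- ifelse(depth >= rel_threshold * deepest, "peak", "shoulder")
  o <- order(wn[cand], decreasing = TRUE)
  structure(data.frame(center = wn[cand][o], prominence = depth[o],
                       kind = kind[o], stringsAsFactors = FALSE),
            class = c("peak_list", "data.frame"),
            id = s$meta$sample_id[1])
}

#' Screen a spectrum for plant (cellulose) contamination
#'
#' ATR only probes the outer fungal mantle, so root-tip spectra should lack
#' the cellulose marker bands at 1641, 1427, 1335 and 1160 cm-1. The screen
#' picks bands over 1700--1100 cm-1 and flags the spectrum as contaminated
#' when at least three of the four markers are matched within `tolerance`.
#'
#' @param s an `ir_spectrum` covering 1100--1700 cm-1.
#' @param tolerance matching tolerance (cm-1), default 4.
#' @param ... passed to [pick_peaks()].
#' @return List with `contaminated` (logical), `n_matched`, and `evidence`
#'   (data frame of markers and the matched band centers, `NA` if unmatched).
#' @export
cellulose_screen <- function(s, tolerance = 4, ...) {
  markers <- c(1641, 1427, 1335, 1160)
  pk <- pick_peaks(s, window = c(1100, 1700), ...)
  matched <- vapply(markers, function(m) {
    if (!nrow(pk)) return(NA_real_)
    d <- abs(pk$center - m)
    if (min(d) <= tolerance) pk$center[which.min(d)] else NA_real_
  }, numeric(1))
  n <- sum(!is.na(matched))
  list(contaminated = n >= 3, n_matched = n,
       evidence = data.frame(marker = markers, matched_center = matched))
}

#' Compare two picked band sets
#'
#' Greedy nearest-neighbor matching: candidate pairs within `tolerance` are
#' accepted closest-first (ties to the pair at higher wavenumber), each band
#' matched at most once. Unmatched bands are "supplementary" to their own
#' group. Swapping the inputs swaps the two supplementary lists exactly.
#'
#' @param a,b `peak_list` objects (see [pick_peaks()]).
#' @param tolerance maximum distance for two bands to count as shared
#'   (cm-1), default 4 (the instrument resolution).
#' @param group_a,group_b labels for the two groups.
#' @return List of class `band_comparison`: `supplementary_in_a`,
#'   `supplementary_in_b` (wavenumbers, descending), `shared` (data frame
#'   with columns `a`, `b`), `tolerance`, group labels.
#' @export
compare_band_sets <- function(a, b, tolerance = 4,
                              group_a = attr(a, "id") %||% "a",
                              group_b = attr(b, "id") %||% "b") {
  ca <- a$center
  cb <- b$center
  pairs <- expand.grid(i = seq_along(ca), j = seq_along(cb))
  if (nrow(pairs)) {
    pairs$d <- abs(ca[pairs$i] - cb[pairs$j])
    pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d, -pmax(ca[pairs$i], cb[pairs$j])), ,
                   drop = FALSE]
  }
  used_a <- logical(length(ca))
  used_b <- logical(length(cb))
  sa <- sb <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      sa <- c(sa, i); sb <- c(sb, j)
    }
  }
  shared <- data.frame(a = ca[sa], b = cb[sb])
  shared <- shared[order(-shared$a), , drop = FALSE]
  rownames(shared) <- NULL
  structure(list(group_a = group_a, group_b = group_b,
                 supplementary_in_a = sort(ca[!used_a], decreasing = TRUE),
                 supplementary_in_b = sort(cb[!used_b], decreasing = TRUE),
                 shared = shared, tolerance = tolerance),
            class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf("<band_comparison> %s vs %s (tolerance %g cm-1)\n",
              x$group_a, x$group_b, x$tolerance))
  cat(sprintf("  shared: %d bands\n", nrow(x$shared)))
  cat(sprintf("  only in %s: %s\n", x$group_a,
              if (length(x$supplementary_in_a))
                paste(round(x$supplementary_in_a), collapse = ", ")
              else "none"))
  cat(sprintf("  only in %s: %s\n", x$group_b,
              if (length(x$supplementary_in_b))
                paste(round(x$supplementary_in_b), collapse = ", ")
              else "none"))
  invisible(x)
}
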