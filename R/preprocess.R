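#' Diagnostic spectral windows
#'
#' Two named window sets are shipped. `"two_region"` is the clustering
#' region: the fatty-acid C-H stretch interval (3000--2800 cm-1) together
#' with the whole 1700--600 cm-1 block. `"five_region"` is the classic
#' five-window layout for fungal fingerprints: (I) fatty acids 3000--2800,
#' (II) amide I 1700--1600, (III) amide II and III 1575--1300, (IV)
#' polysaccharides 1200--900, (V) the fingerprint region 900--600 cm-1.
#'
#' @param which `"two_region"` or `"five_region"`.
#' @return Data frame with columns `name`, `lo`, `hi`, ordered by
#'   descending wavenumber.
#' @export
spectral_windows <- function(which = c("two_region", "five_region")) {
  which <- match.arg(which)
  if (which == "two_region") {
    data.frame(name = c("fatty_acids", "mid_ir"),
               lo = c(2800, 600), hi = c(3000, 1700),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = c("fatty_acids", "amide_I", "amide_II_III",
                        "polysaccharides", "fingerprint"),
               lo = c(2800, 1600, 1300, 900, 600),
               hi = c(3000, 1700, 1575, 1200, 900),
               stringsAsFactors = FALSE)
  }
}

#' Preprocessing configuration
#'
#' Parameters of the feature-extraction chain: Savitzky-Golay second
#' derivative, window slicing, vector normalization.
#'
#' @param sg_points odd number of Savitzky-Golay smoothing points
#'   (default 17).
#' @param sg_polyorder fitted polynomial order (default 3).
#' @param derivative_order derivative order (fixed at 2 for this workflow).
#' @param normalize `"vector"` (mean-center, unit Euclidean norm) or
#'   `"none"`.
#' @param windows window set name (see [spectral_windows()]) or a data
#'   frame with columns `name`, `lo`, `hi`.
#' @param derivative_wrt `"wavenumber"` (values divided by step^2, grid
#'   independent) or `"index"`.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_points = 17, sg_polyorder = 3,
                              derivative_order = 2,
                              normalize = c("vector", "none"),
                              windows = "two_region",
                              derivative_wrt = c("wavenumber", "index")) {
  normalize <- match.arg(normalize)
  derivative_wrt <- match.arg(derivative_wrt)
  if (sg_points %% 2 != 1) stop("sg_points must be odd")
  if (sg_points <= sg_polyorder) stop("sg_points must exceed sg_polyorder")
  if (derivative_order > sg_polyorder)
    stop("derivative_order must be <= sg_polyorder")
  if (is.character(windows)) windows <- spectral_windows(windows)
  stopifnot(all(c("name", "lo", "hi") %in% names(windows)),
            all(windows$lo < windows$hi))
  windows <- windows[order(windows$hi, decreasing = TRUE), , drop = FALSE]
  structure(list(sg_points = as.integer(sg_points),
                 sg_polyorder = as.integer(sg_polyorder),
                 derivative_order = as.integer(derivative_order),
                 normalize = normalize, windows = windows,
                 derivative_wrt = derivative_wrt),
            class = "preprocess_config")
}

# Savitzky-Golay derivative of a plain numeric vector on a uniform grid.
# Edge points come from signal::sgolay's one-sided polynomial fits (no
# padding), so the filter is exact on polynomials up to sg_polyorder
# everywhere, including the first/last (sg_points-1)/2 points.
sg_derivative <- function(y, step, cfg) {
  if (length(y) < cfg$sg_points)
    stop(sprintf("spectrum has %d points but sg_points = %d",
                 length(y), cfg$sg_points))
  ts <- if (cfg$derivative_wrt == "wavenumber") step else 1
  signal::sgolayfilt(y, p = cfg$sg_polyorder, n = cfg$sg_points,
                     m = cfg$derivative_order, ts = ts)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' With `derivative_wrt = "wavenumber"` the output is d2A/dnu2 in
#' absorbance per cm-2 (values divided by step^2). Edge points are computed
#' by one-sided polynomial fits; no reflection padding is used.
#'
#' @param s an `ir_spectrum`.
#' @param cfg a [preprocess_config()].
#' @return An `ir_spectrum` holding the derivative trace.
#' @export
second_derivative <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "ir_spectrum"))
  step <- wn_step(s$wavenumber)
  d <- sg_derivative(s$absorbance, step, cfg)
  structure(list(wavenumber = s$wavenumber, absorbance = d, meta = s$meta),
            class = "ir_spectrum")
}

#' Vector normalization
#'
#' Mean-center, then scale to unit Euclidean norm:
#' `(v - mean(v)) / ||v - mean(v)||`. Idempotent, and invariant to affine
#' transformations `a*v + b` with `a > 0`.
#'
#' @param v numeric vector, non-constant.
#' @return Normalized vector with unit Euclidean norm.
#' @export
vector_normalize <- function(v) {
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot vector-normalize a constant vector (zero norm)")
  v / nrm
}

#' Extract the clustering feature vector of a spectrum
#'
#' Chain: Savitzky-Golay second derivative, slicing of the configured
#' windows (inclusive endpoints; windows ordered by descending wavenumber,
#' values within a window in descending wavenumber), concatenation, then
#' vector normalization over the concatenated vector.
#'
#' @param s an `ir_spectrum`.
#' @param cfg a [preprocess_config()].
#' @return List of class `feature_vector`: `sample_id`, `values`, `support`
#'   (wavenumbers of the values).
#' @export
extract_features <- function(s, cfg = preprocess_config()) {
  d <- second_derivative(s, cfg)
  grid <- canonical_grid(d$wavenumber[1],
                         d$wavenumber[length(d$wavenumber)],
                         wn_step(d$wavenumber))
  support <- numeric(0)
  values <- numeric(0)
  for (w in seq_len(nrow(cfg$windows))) {
    idx <- tryCatch(
      snap_window(cfg$windows$lo[w], cfg$windows$hi[w], grid),
      error = function(e) stop(sprintf("window '%s': %s",
                                       cfg$windows$name[w], conditionMessage(e))))
    sel <- idx[2]:idx[1]  # descending wavenumber within the window
    support <- c(support, d$wavenumber[sel])
    values <- c(values, d$absorbance[sel])
  }
  if (cfg$normalize == "vector") values <- vector_normalize(values)
  structure(list(sample_id = s$meta$sample_id[1], values = values,
                 support = support),
            class = "feature_vector")
}

#' Extract features for every sample of a dataset
#'
#' A pure per-sample map of [extract_features()].
#'
#' @param ds an `ir_dataset`.
#' @param cfg a [preprocess_config()].
#' @return Object of class `feature_set`: list with `support` (shared
#'   wavenumbers), `values` (features x samples matrix), `meta`.
#' @export
extract_feature_set <- function(ds, cfg = preprocess_config()) {
  fv <- lapply(seq_len(n_samples(ds)),
               function(i) extract_features(get_spectrum(ds, i), cfg))
  vals <- vapply(fv, `[[`, numeric(length(fv[[1]]$values)), "values")
  structure(list(support = fv[[1]]$support,
                 values = matrix(vals, ncol = n_samples(ds),
                                 dimnames = list(NULL, ds$meta$sample_id)),
                 meta = ds$meta),
            class = "feature_set")
}
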