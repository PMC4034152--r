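#' @title Spectrum and dataset containers
#' @description S3 containers for single absorbance spectra (`ir_spectrum`)
#'   and collections on a shared grid (`ir_dataset`).
#' @name spectrum-containers
NULL

.species_levels <- c("Amanita_rubescens", "Cenococcum_geophilum",
                     "Lactarius_subdulcis", "Russula_ochroleuca",
                     "Xerocomus_pruinatus", "unknown")
.forest_levels <- c("mono", "mixed")
.site_levels <- c("Hainich", "Swabian")
.host_levels <- c("beech", "lime", "hornbeam", "unknown")

#' Sample metadata record
#'
#' @param sample_id unique sample identifier.
#' @param species fungal species forming the ectomycorrhiza; one of the five
#'   study taxa or `"unknown"`.
#' @param forest_type `"mono"` (mono-specific beech stand) or `"mixed"`
#'   (mixed deciduous stand).
#' @param site `"Hainich"` or `"Swabian"`.
#' @param host_tree `"beech"`, `"lime"`, `"hornbeam"` or `"unknown"`.
#' @return One-row data frame with the five metadata columns.
#' @export
sample_meta <- function(sample_id, species = "unknown", forest_type = "mono",
                        site = "Hainich", host_tree = "unknown") {
  species <- match.arg(species, .species_levels)
  forest_type <- match.arg(forest_type, .forest_levels)
  site <- match.arg(site, .site_levels)
  host_tree <- match.arg(host_tree, .host_levels)
  data.frame(sample_id = as.character(sample_id), species = species,
             forest_type = forest_type, site = site, host_tree = host_tree,
             stringsAsFactors = FALSE)
}

#' Construct a single spectrum
#'
#' @param wavenumber ascending wavenumber vector (cm-1) or a `wn_grid`.
#' @param absorbance absorbance values, same length as the grid, all finite.
#' @param meta one-row metadata data frame (see [sample_meta()]).
#' @return Object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, meta = sample_meta("s1")) {
  if (inherits(wavenumber, "wn_grid")) wavenumber <- grid_points(wavenumber)
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("absorbance length does not match grid length")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance values must be finite")
  d <- diff(wavenumber)
  if (any(d <= 0)) stop("wavenumber must be strictly ascending")
  if (diff(range(d)) > 1e-6 * mean(d))
    stop("wavenumber grid must be uniform")
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s: %d points, %g..%g cm-1\n",
              x$meta$sample_id[1], length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# step of a uniform wavenumber vector
wn_step <- function(wavenumber) {
  (wavenumber[length(wavenumber)] - wavenumber[1]) / (length(wavenumber) - 1)
}

#' Construct a spectral dataset
#'
#' A dataset holds one absorbance matrix (points x samples) on a shared
#' ascending wavenumber grid, plus per-sample metadata. Sample ids must be
#' unique.
#'
#' @param wavenumber shared ascending wavenumber vector or `wn_grid`.
#' @param absorbance numeric matrix, `length(wavenumber)` rows, one column
#'   per sample.
#' @param meta data frame with one row per sample; columns `sample_id`,
#'   `species`, `forest_type`, `site`, `host_tree`.
#' @return Object of class `ir_dataset`.
#' @export
ir_dataset <- function(wavenumber, absorbance, meta) {
  if (inherits(wavenumber, "wn_grid")) wavenumber <- grid_points(wavenumber)
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumber))
    stop("absorbance must have one row per grid point")
  if (ncol(absorbance) != nrow(meta))
    stop("metadata must have one row per sample")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance values must be finite")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  needed <- c("sample_id", "species", "forest_type", "site", "host_tree")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  meta <- meta[, needed]
  meta$sample_id <- as.character(meta$sample_id)
  rownames(meta) <- NULL
  colnames(absorbance) <- meta$sample_id
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 meta = meta),
            class = "ir_dataset")
}

#' @export
print.ir_dataset <- function(x, ...) {
  cat(sprintf("<ir_dataset> %d spectra, %d points, %g..%g cm-1\n",
              ncol(x$absorbance), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (ncol(x$absorbance))
    print(table(x$meta$species))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds an `ir_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) ncol(ds$absorbance)

#' Extract one spectrum from a dataset
#' @param ds an `ir_dataset`.
#' @param i sample index or sample id.
#' @return An `ir_spectrum`.
#' @export
get_spectrum <- function(ds, i) {
  if (is.character(i)) i <- match(i, ds$meta$sample_id)
  if (is.na(i) || i < 1 || i > n_samples(ds)) stop("no such sample")
  ir_spectrum(ds$wavenumber, ds$absorbance[, i], ds$meta[i, , drop = FALSE])
}

#' Resample a trace onto a grid by linear interpolation
#'
#' Extrapolation is refused: the input must cover the full target grid.
#' Resampling a trace already on the target grid is the identity.
#'
#' @param wavenumber input wavenumber vector (any monotone orientation).
#' @param values input values.
#' @param grid target `wn_grid`.
#' @return Values on `grid_points(grid)`.
#' @export
resample_to_grid <- function(wavenumber, values, grid) {
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]
  values <- values[o]
  target <- grid_points(grid)
  if (wavenumber[1] > target[1] + 1e-9 ||
      wavenumber[length(wavenumber)] < target[length(target)] - 1e-9)
    stop(sprintf(
      "spectrum covers %g..%g cm-1 but must cover the full grid %g..%g (extrapolation refused)",
      wavenumber[1], wavenumber[length(wavenumber)], grid$start, grid$stop))
  if (length(wavenumber) == length(target) &&
      max(abs(wavenumber - target)) < 1e-9 * grid$step)
    return(values)
  stats::approx(wavenumber, values, xout = target, method = "linear",
                rule = 1)$y
}

#' Group mean spectrum
#'
#' Pointwise arithmetic mean over the samples matched by `selector`. The
#' result's metadata records the group id and the number of averaged
#' samples is attached as attribute `n`.
#'
#' @param ds an `ir_dataset`.
#' @param selector logical vector over samples, or a function taking the
#'   metadata data frame and returning one.
#' @param group_id id recorded in the output metadata.
#' @return An `ir_spectrum` with attribute `n`.
#' @export
mean_spectrum <- function(ds, selector = TRUE, group_id = "mean") {
  if (is.function(selector)) selector <- selector(ds$meta)
  sel <- which(rep_len(selector, n_samples(ds)))
  if (!length(sel)) stop("selector matches no sample")
  m <- rowMeans(ds$absorbance[, sel, drop = FALSE])
  sp <- unique(ds$meta$species[sel])
  out <- ir_spectrum(ds$wavenumber, m,
                     sample_meta(group_id,
                                 species = if (length(sp) == 1) sp else "unknown"))
  attr(out, "n") <- length(sel)
  out
}

#' Subset a dataset by metadata predicate
#' @param ds an `ir_dataset`.
#' @param selector logical vector or function of the metadata data frame.
#' @return An `ir_dataset` with the matching samples.
#' @export
subset_dataset <- function(ds, selector) {
  if (is.function(selector)) selector <- selector(ds$meta)
  sel <- which(rep_len(selector, n_samples(ds)))
  ir_dataset(ds$wavenumber, ds$absorbance[, sel, drop = FALSE],
             ds$meta[sel, , drop = FALSE])
}
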