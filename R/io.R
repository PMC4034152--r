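#' Read a wide-format spectra CSV with metadata sidecar
#'
#' The spectra file is wide: first column is the wavenumber axis (ascending
#' or descending), every further column is one sample's absorbance trace.
#' The sidecar is a CSV with header
#' `sample_id,species,forest_type,site,host_tree`; samples without a sidecar
#' row are kept with `species = "unknown"`. All spectra are resampled onto
#' the canonical grid (linear interpolation, no extrapolation).
#'
#' @param path spectra CSV path.
#' @param meta_path optional metadata sidecar path.
#' @param grid target `wn_grid` (default [canonical_grid()]).
#' @return An `ir_dataset`.
#' @export
read_spectra_csv <- function(path, meta_path = NULL, grid = canonical_grid()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 1) stop("empty spectra file: ", path)
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(col))
      if (length(bad))
        stop(sprintf("non-numeric cell in '%s', row %d, column '%s': \"%s\"",
                     path, bad[1], names(raw)[j], col[bad[1]]))
      raw[[j]] <- num
    }
    if (anyNA(raw[[j]]))
      stop(sprintf("missing value in '%s', column '%s'", path, names(raw)[j]))
  }
  wn <- raw[[1]]
  if (length(wn) > 1) {
    d <- diff(wn)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumber column is not strictly monotone in ", path)
  }
  ids <- names(raw)[-1]
  if (anyDuplicated(ids))
    stop("duplicate sample columns in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- make_meta(ids, meta_path)
  a <- matrix(0, nrow = grid$n_points, ncol = length(ids))
  for (j in seq_along(ids))
    a[, j] <- resample_to_grid(wn, raw[[j + 1]], grid)
  ir_dataset(grid, a, meta)
}

make_meta <- function(ids, meta_path) {
  meta <- if (length(ids)) do.call(rbind, lapply(ids, sample_meta))
          else sample_meta("placeholder")[0, , drop = FALSE]
  if (is.null(meta_path) || !length(ids)) return(meta)
  side <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "species", "forest_type", "site", "host_tree")
  missing_cols <- setdiff(needed, names(side))
  if (length(missing_cols))
    stop("metadata sidecar lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(side$sample_id))
    stop("duplicate sample_id in metadata sidecar")
  hit <- match(ids, side$sample_id)
  for (k in which(!is.na(hit)))
    meta[k, ] <- sample_meta(ids[k],
                             species = side$species[hit[k]],
                             forest_type = side$forest_type[hit[k]],
                             site = side$site[hit[k]],
                             host_tree = side$host_tree[hit[k]])
  meta
}

#' Write a dataset as wide CSV plus metadata sidecar
#'
#' Absorbance values are written with `%.10g` formatting, so
#' `read_spectra_csv()` of the output reproduces the dataset to within
#' 1e-9 absorbance for values of order 1, and the output is byte-stable for
#' a given dataset.
#'
#' @param ds an `ir_dataset`.
#' @param path spectra CSV path to write.
#' @param meta_path metadata sidecar path to write.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(ds, path, meta_path) {
  stopifnot(inherits(ds, "ir_dataset"))
  ids <- ds$meta$sample_id
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("wavenumber", ids), collapse = ","), con)
  if (n_samples(ds) > 0) {
    body <- cbind(fmt_num(ds$wavenumber),
                  apply(ds$absorbance, 2, fmt_num))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  utils::write.csv(ds$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports uncompressed (AFFN) `##XYDATA=(X++(Y..Y))` and
#' `##XYPOINTS=(XY..XY)` records with `##XUNITS=1/CM`. Transmittance data
#' are converted to absorbance via -log10(T) (T clipped to >= 1e-6) only
#' when `convert = TRUE`; otherwise transmittance input is an error. ASDF
#' compression (SQZ/DIF/DUP) is refused with an explicit error.
#'
#' @param path JCAMP-DX file path.
#' @param convert convert transmittance to absorbance.
#' @param grid target `wn_grid`.
#' @return An `ir_spectrum` on `grid`; `##TITLE` becomes the sample id.
#' @export
read_jcamp <- function(path, convert = FALSE, grid = canonical_grid()) {
  lines <- readLines(path, warn = FALSE)
  get_label <- function(lab) {
    hit <- grep(paste0("^##", lab, "="), lines, ignore.case = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", lab, "=\\s*"), "", lines[hit[1]], ignore.case = TRUE)
  }
  if (!length(grep("^##END=", lines, ignore.case = TRUE)))
    stop("truncated JCAMP-DX file (no ##END=): ", path)
  title <- get_label("TITLE")
  if (is.null(title)) title <- basename(path)
  xunits <- toupper(trimws(get_label("XUNITS") %||% ""))
  if (!xunits %in% c("1/CM", "1/ CM", "CM-1"))
    stop("unsupported ##XUNITS (need 1/CM): '", xunits, "'")
  yunits <- toupper(trimws(get_label("YUNITS") %||% ""))
  xf <- as.numeric(get_label("XFACTOR") %||% "1")
  yf <- as.numeric(get_label("YFACTOR") %||% "1")

  xy_start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(xy_start)) stop("no ##XYDATA or ##XYPOINTS block in ", path)
  i0 <- xy_start[1]
  mode <- if (grepl("^##XYDATA", lines[i0], ignore.case = TRUE)) "xydata"
          else "xypoints"
  end_at <- grep("^##", lines)
  end_at <- end_at[end_at > i0]
  i1 <- if (length(end_at)) min(end_at) - 1 else length(lines)
  body <- lines[(i0 + 1):i1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty data block in ", path)
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body))))
    stop("unsupported JCAMP-DX dialect (ASDF-compressed Y values) in ", path)

  if (mode == "xydata") {
    rows <- lapply(body, function(ln) {
      v <- as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1]])
      if (anyNA(v) || length(v) < 2) stop("unparseable XYDATA line: ", ln)
      v
    })
    # X++(Y..Y): each line starts with the X of its first y
    npt <- as.numeric(get_label("NPOINTS") %||% NA)
    firstx <- as.numeric(get_label("FIRSTX") %||% rows[[1]][1])
    lastx <- as.numeric(get_label("LASTX") %||% NA)
    ys <- unlist(lapply(rows, function(v) v[-1]))
    if (is.na(lastx) || is.na(npt)) stop("XYDATA needs ##NPOINTS and ##LASTX")
    if (length(ys) != npt)
      stop(sprintf("##NPOINTS=%d but %d y values found", npt, length(ys)))
    wn <- seq(firstx, lastx, length.out = npt) * xf
    y <- ys * yf
  } else {
    v <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (anyNA(v) || length(v) %% 2 != 0) stop("unparseable XYPOINTS block")
    wn <- v[seq(1, length(v), by = 2)] * xf
    y <- v[seq(2, length(v), by = 2)] * yf
  }

  if (grepl("TRANSMIT", yunits)) {
    if (!convert)
      stop("YUNITS=TRANSMITTANCE: pass convert=TRUE for -log10 conversion")
    y <- -log10(pmax(y, 1e-6))
  } else if (!grepl("ABSORB", yunits)) {
    stop("missing or unsupported ##YUNITS (need ABSORBANCE or TRANSMITTANCE)")
  }
  ir_spectrum(grid, resample_to_grid(wn, y, grid), sample_meta(title))
}

#' Write a spectrum as minimal JCAMP-DX
#'
#' Uncompressed `(X++(Y..Y))` AFFN output, absorbance units.
#'
#' @param s an `ir_spectrum`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_jcamp <- function(s, path) {
  stopifnot(inherits(s, "ir_spectrum"))
  n <- length(s$wavenumber)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    paste0("##TITLE=", s$meta$sample_id[1]),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", fmt_num(s$wavenumber[1])),
    paste0("##LASTX=", fmt_num(s$wavenumber[n])),
    paste0("##NPOINTS=", n),
    "##XYDATA=(X++(Y..Y))"), con)
  per <- 6L
  for (i in seq(1, n, by = per)) {
    j <- min(i + per - 1, n)
    writeLines(paste(c(fmt_num(s$wavenumber[i]),
                       sprintf("%.8g", s$absorbance[i:j])), collapse = " "),
               con)
  }
  writeLines("##END=", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
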