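#' Canonical wavenumber grid
#'
#' All spectra handled by the package live on a shared uniform wavenumber
#' grid, ascending in wavenumber. The default covers the mid-infrared range
#' 600--4000 cm-1 at 2 cm-1 per point (1701 points), i.e. a 2x oversampling
#' of a 4 cm-1 instrument resolution.
#'
#' @param start lowest wavenumber (cm-1).
#' @param stop highest wavenumber (cm-1); must equal
#'   `start + (n-1) * step` for integer `n`.
#' @param step grid spacing (cm-1), positive.
#' @return An object of class `wn_grid`: list with `start`, `stop`, `step`,
#'   `n_points`.
#' @examples
#' g <- canonical_grid()
#' g$n_points  # 1701
#' @export
canonical_grid <- function(start = 600, stop = 4000, step = 2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1)
  if (step <= 0) stop("grid step must be positive")
  if (stop <= start) stop("grid stop must exceed start")
  n <- (stop - start) / step + 1
  if (abs(n - round(n)) > 1e-8)
    stop("grid is not uniform: (stop - start) must be a multiple of step")
  structure(list(start = start, stop = stop, step = step,
                 n_points = as.integer(round(n))),
            class = "wn_grid")
}

#' Grid points of a wavenumber grid
#' @param grid a `wn_grid`.
#' @return Numeric vector of ascending wavenumbers.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "wn_grid"))
  grid$start + grid$step * (seq_len(grid$n_points) - 1)
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g..%g cm-1, step %g (%d points)\n",
              x$start, x$stop, x$step, x$n_points))
  invisible(x)
}

# Snap a [lo, hi] window onto the grid: lo floored, hi ceiled, so the stated
# interval is always contained. Returns integer point indices (lo_idx:hi_idx).
snap_window <- function(lo, hi, grid) {
  if (lo >= hi) stop("window lo must be < hi")
  if (lo < grid$start || hi > grid$stop)
    stop(sprintf("window [%g, %g] outside grid [%g, %g]",
                 lo, hi, grid$start, grid$stop))
  lo_idx <- floor((lo - grid$start) / grid$step) + 1
  hi_idx <- ceiling((hi - grid$start) / grid$step) + 1
  c(as.integer(lo_idx), as.integer(hi_idx))
}
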