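# shared fixtures: analytic band shapes, FWHM measurement, a from-scratch
# Ward oracle, and generator configs used across test files

grid_wn <- grid_points(canonical_grid())

lorentz <- function(wn, center, fwhm, area = NULL, height = NULL) {
  gam <- fwhm / 2
  if (!is.null(area)) (area / pi) * gam / ((wn - center)^2 + gam^2)
  else height * gam^2 / ((wn - center)^2 + gam^2)
}

gauss <- function(wn, center, fwhm, height) {
  height * exp(-log(2) * ((wn - center) / (fwhm / 2))^2)
}

spec_of <- function(y, id = "s") ir_spectrum(grid_wn, y, sample_meta(id))

# FWHM by linear interpolation of the half-maximum crossings
fwhm_of <- function(wn, y) {
  i <- which.max(y)
  half <- y[i] / 2
  li <- max(which(y[1:i] <= half))
  ri <- i - 1 + min(which(y[i:length(y)] <= half))
  xl <- stats::approx(y[c(li, li + 1)], wn[c(li, li + 1)], xout = half)$y
  xr <- stats::approx(y[c(ri - 1, ri)], wn[c(ri - 1, ri)], xout = half)$y
  xr - xl
}

# local maxima of y restricted to wavenumber range, above frac of the max
local_maxima <- function(wn, y, range, frac = 0.2) {
  i <- which(wn >= range[1] & wn <= range[2])
  v <- y[i]
  j <- which(v > c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf))
  wn[i][j[v[j] > frac * max(v)]]
}

# exhaustive greedy Ward: recomputes the within-cluster sum-of-squares
# objective from scratch at every step; heights in ward.D2 distance units
oracle_ward <- function(X) {
  n <- nrow(X)
  sse <- function(idx) {
    if (length(idx) < 2) return(0)
    m <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  active <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  while (length(active) > 1) {
    best_h2 <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(active) - 1)) {
      for (j in (i + 1):length(active)) {
        h2 <- 2 * (sse(c(active[[i]], active[[j]])) -
                     sse(active[[i]]) - sse(active[[j]]))
        if (h2 < best_h2 - 1e-12) { best_h2 <- h2; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, sqrt(max(best_h2, 0)))
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active <- active[-bj]
    memb <- integer(n)
    for (g in seq_along(active)) memb[active[[g]]] <- g
    partitions[[length(active)]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# canonical cluster labels (relabel by first appearance) for comparing
# partitions up to renaming
canon_part <- function(memb) match(memb, unique(memb))

noiseless_config <- function(...) {
  generator_config(center_jitter_sd = 0, amplitude_cv = 0, noise_sd = 0,
                   baseline_scale = 0, ...)
}

.species_levels_test <- function() {
  c("Amanita_rubescens", "Cenococcum_geophilum", "Lactarius_subdulcis",
    "Russula_ochroleuca", "Xerocomus_pruinatus")
}

phylum_split_ok <- function(ds, tree) {
  cl2 <- cut_tree(tree, 2)
  cg <- ds$meta$species == "Cenococcum_geophilum"
  length(unique(cl2[cg])) == 1 && length(unique(cl2[!cg])) == 1 &&
    unique(cl2[cg]) != unique(cl2[!cg])
}

# small composition for fast dataset-level tests
small_composition <- function() {
  comp <- default_composition()
  comp$n <- pmax(2L, comp$n %/% 8L)
  comp
}
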