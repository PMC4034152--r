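#' Default field-study sample composition
#'
#' The sample inventory the generator reproduces: per species, counts by
#' site (Hainich / Swabian), forest type (mono-specific beech / mixed
#' deciduous) and host tree, totalling 181 ectomycorrhizal root-tip spectra
#' (61 Cenococcum geophilum, 67 Lactarius subdulcis, 23 Xerocomus
#' pruinatus, 17 Amanita rubescens, 13 Russula ochroleuca).
#'
#' @return Data frame with columns `species`, `site`, `forest_type`,
#'   `host_tree`, `n`.
#' @export
default_composition <- function() {
  comp <- rbind(
    c("Amanita_rubescens",    "Hainich", "mono",  "beech",    7),
    c("Amanita_rubescens",    "Hainich", "mixed", "beech",    5),
    c("Amanita_rubescens",    "Hainich", "mixed", "hornbeam", 5),
    c("Cenococcum_geophilum", "Hainich", "mono",  "beech",    4),
    c("Cenococcum_geophilum", "Hainich", "mixed", "beech",   29),
    c("Cenococcum_geophilum", "Hainich", "mixed", "lime",     8),
    c("Cenococcum_geophilum", "Hainich", "mixed", "hornbeam", 3),
    c("Cenococcum_geophilum", "Swabian", "mono",  "beech",   17),
    c("Lactarius_subdulcis",  "Hainich", "mono",  "beech",   32),
    c("Lactarius_subdulcis",  "Hainich", "mixed", "beech",   33),
    c("Lactarius_subdulcis",  "Hainich", "mixed", "lime",     2),
    c("Russula_ochroleuca",   "Hainich", "mono",  "beech",   13),
    c("Xerocomus_pruinatus",  "Hainich", "mono",  "beech",   21),
    c("Xerocomus_pruinatus",  "Hainich", "mixed", "beech",    2))
  data.frame(species = comp[, 1], site = comp[, 2], forest_type = comp[, 3],
             host_tree = comp[, 4], n = as.integer(comp[, 5]),
             stringsAsFactors = FALSE)
}

#' Synthetic-spectrum generator configuration
#'
#' @param composition sample composition data frame (see
#'   [default_composition()]).
#' @param center_jitter_sd per-band, per-sample Gaussian jitter of band
#'   centers (cm-1).
#' @param amplitude_cv per-band log-normal coefficient of variation of band
#'   amplitudes.
#' @param noise_sd standard deviation of i.i.d. detector noise (absorbance).
#' @param baseline_scale scale of the random degree-2 baseline coefficients.
#' @param modifier_amplitude_scale amplitude scale applied to
#'   environment-modifier bands (environment effects weaker than species
#'   effects).
#' @param seed integer master seed; every sample draws from its own
#'   substream keyed on (seed, sample id), so spectra do not depend on the
#'   composition row order.
#' @param grid target `wn_grid`.
#' @param templates per-species band templates (default packaged set).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(composition = default_composition(),
                             center_jitter_sd = 1.5, amplitude_cv = 0.20,
                             noise_sd = 0.002, baseline_scale = 0.01,
                             modifier_amplitude_scale = 0.5, seed = 42,
                             grid = canonical_grid(),
                             templates = builtin_templates()) {
  stopifnot(all(c("species", "site", "forest_type", "host_tree", "n") %in%
                  names(composition)),
            all(composition$n >= 0),
            center_jitter_sd >= 0, amplitude_cv >= 0, noise_sd >= 0,
            baseline_scale >= 0)
  structure(list(composition = composition,
                 center_jitter_sd = center_jitter_sd,
                 amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                 baseline_scale = baseline_scale,
                 modifier_amplitude_scale = modifier_amplitude_scale,
                 seed = as.integer(seed), grid = grid,
                 templates = templates),
            class = "generator_config")
}

# deterministic 31-bit stream seed from the master seed and a string key
stream_seed <- function(seed, key) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% m
  as.integer(h)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# context key used to resolve template modifiers
context_of <- function(site, forest_type) {
  if (site == "Swabian") "swabian" else forest_type
}

#' Generate one synthetic spectrum
#'
#' Sum of the context-resolved template bands with per-band center jitter
#' (Gaussian, sd `center_jitter_sd`) and amplitude variation (log-normal
#' with unit mean and CV `amplitude_cv`), plus a random degree-2 baseline
#' and i.i.d. Gaussian detector noise. With all noise parameters zero the
#' output equals the pure template sum for the context.
#'
#' @param tmpl a `species_template`.
#' @param meta one-row metadata (see [sample_meta()]); site and forest type
#'   select the modifier context.
#' @param cfg a [generator_config()].
#' @return An `ir_spectrum`.
#' @export
generate_spectrum <- function(tmpl, meta, cfg = generator_config()) {
  ctx <- context_of(meta$site[1], meta$forest_type[1])
  bands <- active_bands(tmpl, ctx, cfg$modifier_amplitude_scale)
  wn <- grid_points(cfg$grid)
  sdlog <- sqrt(log(1 + cfg$amplitude_cv^2))
  with_stream(stream_seed(cfg$seed, meta$sample_id[1]), {
    y <- rep(0, length(wn))
    for (i in seq_len(nrow(bands))) {
      jit <- if (cfg$center_jitter_sd > 0)
        stats::rnorm(1, 0, cfg$center_jitter_sd) else 0
      fac <- if (cfg$amplitude_cv > 0)
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
      y <- y + band_profile(wn, bands$center[i] + jit, bands$fwhm[i],
                            bands$amplitude[i] * fac, bands$shape[i])
    }
    if (cfg$baseline_scale > 0) {
      u <- (wn - cfg$grid$start) / (cfg$grid$stop - cfg$grid$start)
      b <- stats::rnorm(3, 0, cfg$baseline_scale)
      y <- y + b[1] + b[2] * u + b[3] * u^2
    }
    if (cfg$noise_sd > 0)
      y <- y + stats::rnorm(length(wn), 0, cfg$noise_sd)
    ir_spectrum(wn, y, meta)
  })
}

#' Generate a labelled synthetic dataset
#'
#' One spectrum per sample of `cfg$composition`, each drawn from its own
#' RNG substream keyed on `(seed, sample_id)`; identical configurations give
#' bit-identical datasets and per-sample spectra are independent of the
#' composition row order.
#'
#' @param cfg a [generator_config()].
#' @return An `ir_dataset`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  comp <- cfg$composition
  rows <- list()
  for (r in seq_len(nrow(comp))) {
    if (comp$n[r] == 0) next
    for (i in seq_len(comp$n[r])) {
      id <- sprintf("%s_%s_%s_%s_%02d", comp$species[r], comp$site[r],
                    comp$forest_type[r], comp$host_tree[r], i)
      rows[[length(rows) + 1]] <-
        sample_meta(id, species = comp$species[r],
                    forest_type = comp$forest_type[r], site = comp$site[r],
                    host_tree = comp$host_tree[r])
    }
  }
  meta <- if (length(rows)) do.call(rbind, rows)
          else sample_meta("placeholder")[0, , drop = FALSE]
  a <- matrix(0, nrow = cfg$grid$n_points, ncol = nrow(meta))
  for (j in seq_len(nrow(meta))) {
    tmpl <- cfg$templates[[meta$species[j]]]
    if (is.null(tmpl)) stop("no template for species ", meta$species[j])
    a[, j] <- generate_spectrum(tmpl, meta[j, , drop = FALSE], cfg)$absorbance
  }
  ir_dataset(cfg$grid, a, meta)
}

#' Generate a synthetic cellulose spectrum
#'
#' Positive control for [cellulose_screen()]: exactly the four cellulose
#' marker bands (1641, 1427, 1335, 1160 cm-1) plus the configured baseline
#' and noise.
#'
#' @param cfg a [generator_config()] (noise parameters reused).
#' @return An `ir_spectrum` with `sample_id = "cellulose"`.
#' @export
generate_cellulose_spectrum <- function(cfg = generator_config()) {
  wn <- grid_points(cfg$grid)
  bands <- data.frame(center = c(1641, 1427, 1335, 1160),
                      fwhm = c(16, 14, 12, 14),
                      amplitude = c(0.9, 0.7, 0.5, 0.8))
  y <- rep(0, length(wn))
  for (i in seq_len(nrow(bands)))
    y <- y + band_profile(wn, bands$center[i], bands$fwhm[i],
                          bands$amplitude[i], "lorentzian")
  with_stream(stream_seed(cfg$seed, "cellulose_control"), {
    if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(wn), 0, cfg$noise_sd)
    ir_spectrum(wn, y, sample_meta("cellulose"))
  })
}
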