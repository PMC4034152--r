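#' Built-in per-species band templates
#'
#' The packaged band table (`inst/extdata/band_templates.csv`) encodes, for
#' each of the five ectomycorrhizal species, the infrared bands that make up
#' its mid-infrared fingerprint: shared cell-wall bands (chitin, glucan,
#' lipids, tyrosine), the species-specific amide I positions and
#' carbohydrate markers, and context modifiers (bands added in mixed-forest
#' or Swabian-site samples, or removed in mono-specific beech stands). Band
#' positions are literature values; widths and relative amplitudes are the
#' package's own calibration (positions, not intensities, are published).
#'
#' @param path optional alternative template CSV with the same columns.
#' @return Named list of `species_template` objects, each a list with
#'   `species`, `core_bands` (data frame `center`, `fwhm`, `amplitude`,
#'   `shape`, `assignment`) and `modifiers` (per context: `add` data frame
#'   and `remove` centers).
#' @export
builtin_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "band_templates.csv", package = "ectospec",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "context", "action", "center_cm1", "fwhm_cm1",
              "rel_amplitude", "shape", "assignment")
  stopifnot(all(needed %in% names(tab)))
  species <- setdiff(unique(tab$species), "all")
  shared <- tab[tab$species == "all", ]
  out <- lapply(species, function(sp) {
    own <- tab[tab$species == sp, ]
    core <- rbind(shared[shared$context == "core", ],
                  own[own$context == "core", ])
    core_df <- data.frame(center = core$center_cm1, fwhm = core$fwhm_cm1,
                          amplitude = core$rel_amplitude, shape = core$shape,
                          assignment = core$assignment,
                          stringsAsFactors = FALSE)
    mods <- list()
    for (ctx in setdiff(unique(own$context), "core")) {
      blk <- own[own$context == ctx, ]
      add <- blk[blk$action == "add", ]
      rem <- blk$center_cm1[blk$action == "remove"]
      if (length(rem) && !all(rem %in% core_df$center))
        stop(sprintf("template %s/%s removes bands not in core: %s", sp, ctx,
                     paste(setdiff(rem, core_df$center), collapse = ", ")))
      mods[[ctx]] <- list(
        add = data.frame(center = add$center_cm1, fwhm = add$fwhm_cm1,
                         amplitude = add$rel_amplitude, shape = add$shape,
                         assignment = add$assignment,
                         stringsAsFactors = FALSE),
        remove = rem)
    }
    structure(list(species = sp, core_bands = core_df, modifiers = mods),
              class = "species_template")
  })
  names(out) <- species
  out
}

#' @export
print.species_template <- function(x, ...) {
  cat(sprintf("<species_template> %s: %d core bands, modifiers: %s\n",
              x$species, nrow(x$core_bands),
              if (length(x$modifiers)) paste(names(x$modifiers), collapse = ", ")
              else "none"))
  invisible(x)
}

# evaluate one band profile on a wavenumber vector (peak height = amplitude)
band_profile <- function(wn, center, fwhm, amplitude, shape) {
  hw <- fwhm / 2
  if (shape == "gaussian") {
    amplitude * exp(-log(2) * ((wn - center) / hw)^2)
  } else {
    amplitude * hw^2 / ((wn - center)^2 + hw^2)
  }
}

# bands active for a template in a given context (modifier additions scaled)
active_bands <- function(tmpl, context = NULL, modifier_scale = 0.5) {
  bands <- tmpl$core_bands
  if (!is.null(context) && context %in% names(tmpl$modifiers)) {
    mod <- tmpl$modifiers[[context]]
    if (length(mod$remove))
      bands <- bands[!bands$center %in% mod$remove, , drop = FALSE]
    if (nrow(mod$add)) {
      add <- mod$add
      add$amplitude <- add$amplitude * modifier_scale
      bands <- rbind(bands, add)
    }
  }
  bands
}

#' Noiseless template spectrum of a species
#'
#' Sum of the template's band profiles with no jitter, amplitude variation,
#' baseline or noise. With `context = NULL` only the core bands are used.
#'
#' @param species species id (name in [builtin_templates()]) or a
#'   `species_template`.
#' @param context `NULL`, `"mono"`, `"mixed"` or `"swabian"`.
#' @param grid target `wn_grid`.
#' @param modifier_scale amplitude scale for context modifier bands.
#' @param templates template list (default the packaged one).
#' @return An `ir_spectrum`.
#' @export
template_spectrum <- function(species, context = NULL,
                              grid = canonical_grid(), modifier_scale = 0.5,
                              templates = builtin_templates()) {
  tmpl <- if (inherits(species, "species_template")) species
          else templates[[species]]
  if (is.null(tmpl)) stop("unknown species: ", species)
  bands <- active_bands(tmpl, context, modifier_scale)
  wn <- grid_points(grid)
  y <- rep(0, length(wn))
  for (i in seq_len(nrow(bands)))
    y <- y + band_profile(wn, bands$center[i], bands$fwhm[i],
                          bands$amplitude[i], bands$shape[i])
  ir_spectrum(wn, y, sample_meta(paste0(tmpl$species, "_template"),
                                 species = tmpl$species))
}
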