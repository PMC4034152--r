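#' Run the full identification pipeline
#'
#' End-to-end driver: simulate (or accept) a dataset, extract
#' second-derivative vector-normalized features over the clustering
#' windows, run Ward hierarchical clustering, score the k-cut against the
#' true species labels, check the phylum-level k = 2 split (the
#' ascomycete Cenococcum geophilum versus the four basidiomycetes), pick
#' bands on per-species mean spectra, and compare deconvolved mean spectra
#' between forest environments (mono vs mixed per species; Hainich vs
#' Swabian for C. geophilum).
#'
#' @param generator a [generator_config()], or an `ir_dataset` to analyse
#'   directly.
#' @param preprocess a [preprocess_config()].
#' @param k number of clusters for the species cut (default 5).
#' @param fsd_cfg an [fsd_config()] used before environment band
#'   comparisons.
#' @param tolerance band-matching tolerance (cm-1).
#' @param peak_window window for per-species and comparison peak picking.
#' @param average_before_fsd average group spectra first, then deconvolve
#'   (default), or deconvolve each sample then average.
#' @param output_dir if non-NULL, write `report.json`, `dendrogram.nwk`,
#'   `assignments.csv`, `peaks/<species>.csv` and
#'   `comparisons/<contrast>.csv` there.
#' @param verbose log stage progress to stderr.
#' @return List of class `run_report`: `n_samples`, `k`, `accuracy`,
#'   `n_misassigned`, `phylum_split_ok`, `report` (the full
#'   [species_report()]), `tree`, `per_species_peaks`,
#'   `environment_comparisons`, `heterogeneity`, `config_echo`.
#' @export
run_pipeline <- function(generator = generator_config(),
                         preprocess = preprocess_config(), k = 5,
                         fsd_cfg = fsd_config(), tolerance = 4,
                         peak_window = c(650, 3000),
                         average_before_fsd = TRUE,
                         output_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) say("[%7.2fs] %s", proc.time()[["elapsed"]] - t0, what)

  if (inherits(generator, "ir_dataset")) {
    ds <- generator
    gen_echo <- list(source = "user dataset")
  } else {
    stopifnot(inherits(generator, "generator_config"))
    stage("simulating dataset")
    ds <- generate_dataset(generator)
    gen_echo <- list(source = "synthetic",
                     seed = generator$seed,
                     noise_sd = generator$noise_sd,
                     center_jitter_sd = generator$center_jitter_sd,
                     amplitude_cv = generator$amplitude_cv,
                     modifier_amplitude_scale =
                       generator$modifier_amplitude_scale)
  }
  if (n_samples(ds) < 2) stop("pipeline needs at least two samples")

  stage("extracting features")
  fs <- extract_feature_set(ds, preprocess)
  stage("clustering")
  tree <- ward_linkage(distance_matrix(fs))
  truth <- stats::setNames(ds$meta$species, ds$meta$sample_id)
  rep_k <- species_report(tree, truth, k)

  # phylum check: does the 2-cut isolate the ascomycete exactly?
  cl2 <- cut_tree(tree, 2)
  is_cg <- ds$meta$species == "Cenococcum_geophilum"
  phylum_ok <- length(unique(cl2[is_cg])) == 1 &&
    length(unique(cl2[!is_cg])) == 1 &&
    unique(cl2[is_cg]) != unique(cl2[!is_cg])

  stage("species mean spectra and peak lists")
  species <- sort(unique(ds$meta$species))
  per_species_peaks <- lapply(species, function(sp) {
    m <- mean_spectrum(ds, ds$meta$species == sp, group_id = sp)
    pick_peaks(m, peak_window, cfg = preprocess)
  })
  names(per_species_peaks) <- species

  stage("environment band comparisons")
  comparisons <- list()
  group_peaks <- function(sel, id) {
    m <- if (average_before_fsd) fsd(mean_spectrum(ds, sel, group_id = id),
                                     fsd_cfg)
    else {
      sub <- subset_dataset(ds, sel)
      dec <- vapply(seq_len(n_samples(sub)), function(i)
        fsd(get_spectrum(sub, i), fsd_cfg)$absorbance,
        numeric(length(sub$wavenumber)))
      ir_spectrum(sub$wavenumber, rowMeans(dec), sample_meta(id))
    }
    pick_peaks(m, peak_window, cfg = preprocess)
  }
  for (sp in species) {
    mono <- ds$meta$species == sp & ds$meta$forest_type == "mono" &
      ds$meta$site == "Hainich"
    mixed <- ds$meta$species == sp & ds$meta$forest_type == "mixed"
    if (any(mono) && any(mixed)) {
      nm <- paste0(sp, "_mono_vs_mixed")
      comparisons[[nm]] <- compare_band_sets(
        group_peaks(mono, paste0(sp, "_mono")),
        group_peaks(mixed, paste0(sp, "_mixed")), tolerance)
    }
  }
  cg_h <- is_cg & ds$meta$site == "Hainich"
  cg_s <- is_cg & ds$meta$site == "Swabian"
  if (any(cg_h) && any(cg_s))
    comparisons[["Cenococcum_geophilum_Hainich_vs_Swabian"]] <-
      compare_band_sets(group_peaks(cg_h, "Cg_Hainich"),
                        group_peaks(cg_s, "Cg_Swabian"), tolerance)

  # direction-only site effect: Swabian C. geophilum subgroup tightness
  het <- list()
  if (any(cg_s) && sum(is_cg) > sum(cg_s)) {
    swab_ids <- ds$meta$sample_id[cg_s]
    cg_ids <- ds$meta$sample_id[is_cg]
    het$swabian_subcluster_vs_species <- tryCatch(
      subtree_heterogeneity(tree, swab_ids) /
        subtree_heterogeneity(tree, cg_ids),
      error = function(e) NA_real_)
  }

  out <- structure(list(
    n_samples = n_samples(ds), k = k,
    accuracy = rep_k$accuracy, n_misassigned = rep_k$n_misassigned,
    phylum_split_ok = phylum_ok, report = rep_k, tree = tree,
    per_species_peaks = per_species_peaks,
    environment_comparisons = comparisons, heterogeneity = het,
    config_echo = list(generator = gen_echo,
                       sg_points = preprocess$sg_points,
                       sg_polyorder = preprocess$sg_polyorder,
                       normalize = preprocess$normalize,
                       windows = preprocess$windows,
                       k = k, fsd = unclass(fsd_cfg),
                       tolerance = tolerance,
                       peak_window = peak_window,
                       average_before_fsd = average_before_fsd)),
    class = "run_report")

  if (!is.null(output_dir)) {
    stage(paste("writing outputs to", output_dir))
    write_run_report(out, output_dir)
  }
  stage("done")
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> n = %d, k = %d: accuracy %.4f (%d misassigned), phylum split %s\n",
    x$n_samples, x$k, x$accuracy, x$n_misassigned,
    if (x$phylum_split_ok) "ok" else "NOT ok"))
  for (nm in names(x$environment_comparisons)) {
    cmp <- x$environment_comparisons[[nm]]
    cat(sprintf("  %s: %d / %d supplementary bands\n", nm,
                length(cmp$supplementary_in_a), length(cmp$supplementary_in_b)))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `report.json` (numbers at 12 significant digits, no timestamps so
#' re-runs are byte-identical), `dendrogram.nwk`, `assignments.csv`, one
#' `peaks/<group>.csv` per species and one `comparisons/<contrast>.csv` per
#' environment contrast.
#'
#' @param report a `run_report`.
#' @param output_dir directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_run_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "comparisons"), showWarnings = FALSE)
  export_newick(report$tree, file.path(output_dir, "dendrogram.nwk"))
  utils::write.csv(report$report$assignments,
                   file.path(output_dir, "assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(report$per_species_peaks))
    utils::write.csv(report$per_species_peaks[[nm]],
                     file.path(output_dir, "peaks", paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  row_block <- function(centers, status, group)
    data.frame(center_cm1 = centers,
               status = rep(status, length(centers)),
               group = rep(group, length(centers)))
  for (nm in names(report$environment_comparisons)) {
    cmp <- report$environment_comparisons[[nm]]
    rows <- rbind(
      row_block(cmp$supplementary_in_a, "supplementary", cmp$group_a),
      row_block(cmp$supplementary_in_b, "supplementary", cmp$group_b),
      row_block(cmp$shared$a, "shared",
                paste(cmp$group_a, cmp$group_b, sep = "|")))
    utils::write.csv(rows,
                     file.path(output_dir, "comparisons", paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  js <- list(
    schema = "ectospec-run-report/1",
    n_samples = report$n_samples, k = report$k,
    accuracy = signif(report$accuracy, 12),
    n_misassigned = report$n_misassigned,
    phylum_split_ok = report$phylum_split_ok,
    cluster_label = report$report$cluster_label,
    per_cluster_heterogeneity =
      signif(report$report$per_cluster_heterogeneity, 12),
    heterogeneity = lapply(report$heterogeneity, signif, 12),
    environment_comparisons = lapply(report$environment_comparisons,
                                     function(cmp) list(
                                       group_a = cmp$group_a,
                                       group_b = cmp$group_b,
                                       supplementary_in_a = cmp$supplementary_in_a,
                                       supplementary_in_b = cmp$supplementary_in_b,
                                       n_shared = nrow(cmp$shared),
                                       tolerance = cmp$tolerance)),
    config = report$config_echo)
  path <- file.path(output_dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
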