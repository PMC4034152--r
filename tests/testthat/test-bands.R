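test_that("FSD narrows a matched Lorentzian by the enhancement factor", {
  s <- spec_of(lorentz(grid_wn, 1650, 12, area = 1))
  out <- fsd(s, fsd_config(band_fwhm = 12, enhancement = 2))
  expect_equal(grid_wn[which.max(out$absorbance)], 1650)
  w <- fwhm_of(grid_wn, out$absorbance)
  expect_lte(w, 7)
  expect_lt(abs(w - 6) / 6, 0.15)  # halving within 15%
  # isolated-band area conserved within 2% up to K = 3
  a_in <- sum(s$absorbance) * 2
  for (k in c(2, 3)) {
    a_out <- sum(fsd(s, fsd_config(12, k))$absorbance) * 2
    expect_lt(abs(a_out - a_in) / a_in, 0.02)
  }
})

test_that("FSD with K -> 1 and boxcar apodization is the identity", {
  s <- spec_of(lorentz(grid_wn, 1650, 12, area = 1) +
                 lorentz(grid_wn, 1100, 30, height = 0.4))
  out <- fsd(s, fsd_config(12, 1 + 1e-9, "boxcar"))
  expect_lt(max(abs(out$absorbance - s$absorbance)) / max(s$absorbance), 1e-6)
})

test_that("FSD resolves an unresolved amide I doublet", {
  # FWHM 28: an equal pair split by 15 cm-1 is genuinely unimodal
  # (two equal Lorentzians stay unimodal up to FWHM/sqrt(3) separation)
  y <- lorentz(grid_wn, 1632, 28, area = 1) + lorentz(grid_wn, 1617, 28, area = 1)
  expect_length(local_maxima(grid_wn, y, c(1560, 1690)), 1L)
  out <- fsd(spec_of(y), fsd_config(band_fwhm = 28, enhancement = 2.5))
  mx <- local_maxima(grid_wn, out$absorbance, c(1560, 1690))
  expect_length(mx, 2L)
  expect_lte(abs(max(mx) - 1632), 2)
  expect_lte(abs(min(mx) - 1617), 2)
})

test_that("FSD on pure noise stays finite and reports its amplification", {
  set.seed(9)
  s <- spec_of(rnorm(1701, 0, 0.01))
  out <- fsd(s, fsd_config())
  expect_true(all(is.finite(out$absorbance)))
  amp <- attr(out, "amplification")
  expect_true(is.finite(amp) && amp > 1)
  expect_lt(sd(out$absorbance) / sd(s$absorbance), amp)
})

test_that("excessive enhancement is refused with advice", {
  s <- spec_of(lorentz(grid_wn, 1650, 40, height = 1))
  expect_error(fsd(s, fsd_config(band_fwhm = 40, enhancement = 4)),
               "reduce enhancement")
  expect_error(fsd_config(enhancement = 1), "enhancement")
  expect_error(fsd_config(band_fwhm = -3), "band_fwhm")
})

test_that("peak picking finds band maxima as second-derivative minima", {
  y <- gauss(grid_wn, 1632, 20, 1.0) + gauss(grid_wn, 1515, 20, 0.6)
  pk <- pick_peaks(spec_of(y), c(1480, 1700), rel_threshold = 0.1)
  expect_equal(nrow(pk), 2L)
  expect_lte(abs(pk$center[1] - 1632), 2)
  expect_lte(abs(pk$center[2] - 1515), 2)
  expect_true(all(pk$kind == "peak"))
  # sorted by descending wavenumber
  expect_false(is.unsorted(rev(pk$center)))
})

test_that("peak picking is scale-invariant and empty on flat input", {
  y <- gauss(grid_wn, 1632, 20, 1.0) + gauss(grid_wn, 1515, 20, 0.6)
  pk1 <- pick_peaks(spec_of(y), c(1480, 1700))
  pk2 <- pick_peaks(spec_of(y * 37.5), c(1480, 1700))
  expect_equal(pk1$center, pk2$center)
  expect_equal(pk1$kind, pk2$kind)
  flat <- pick_peaks(spec_of(rep(0.3, 1701)), c(1480, 1700))
  expect_equal(nrow(flat), 0L)
})

test_that("a band at the window edge is never reported outside the window", {
  y <- gauss(grid_wn, 1480, 20, 1.0)
  pk <- pick_peaks(spec_of(y), c(1480, 1700))
  expect_true(all(pk$center >= 1480 & pk$center <= 1700))
})

test_that("minima closer than the separation are merged keeping the deeper", {
  y <- gauss(grid_wn, 1600, 18, 1.0) + gauss(grid_wn, 1604, 18, 0.8)
  pk <- pick_peaks(spec_of(y), c(1550, 1650), min_separation = 6)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$center - 1601), 3)
})

test_that("weak minima are classified as shoulders", {
  y <- gauss(grid_wn, 1600, 16, 1.0) + gauss(grid_wn, 1500, 16, 0.07)
  pk <- pick_peaks(spec_of(y), c(1450, 1650), rel_threshold = 0.1,
                   shoulder_floor = 0.05)
  expect_setequal(pk$kind[abs(pk$center - 1500) <= 4], "shoulder")
  expect_setequal(pk$kind[abs(pk$center - 1600) <= 4], "peak")
})

test_that("cellulose screen flags the marker pattern and not fungal templates", {
  cel <- generate_cellulose_spectrum(noiseless_config())
  mx <- local_maxima(grid_wn, cel$absorbance, c(1100, 1700), 0.2)
  expect_length(mx, 4L)
  for (m in c(1641, 1427, 1335, 1160))
    expect_lte(min(abs(mx - m)), 2)  # noiseless maxima at the markers
  scr <- cellulose_screen(cel)
  expect_true(scr$contaminated)
  expect_equal(scr$n_matched, 4L)
  for (sp in names(builtin_templates()))
    expect_false(cellulose_screen(template_spectrum(sp))$contaminated)
  # markers survive superposition with a fungal spectrum
  mix <- spec_of(cel$absorbance +
                   template_spectrum("Cenococcum_geophilum")$absorbance)
  expect_true(cellulose_screen(mix)$contaminated)
  # two markers only is below the contamination threshold
  two <- spec_of(lorentz(grid_wn, 1641, 16, height = 0.9) +
                   lorentz(grid_wn, 1427, 14, height = 0.7))
  expect_false(cellulose_screen(two)$contaminated)
})

test_that("band-set comparison separates supplementary from shared bands", {
  mk <- function(centers, id) structure(
    data.frame(center = sort(centers, decreasing = TRUE),
               prominence = seq_along(centers), kind = "peak"),
    class = c("peak_list", "data.frame"), id = id)
  shared <- c(2925, 1632, 1515, 1031)
  a <- mk(c(2363, 1663, 1453, 1372, 830, shared), "mixed")
  b <- mk(shared, "mono")
  cmp <- compare_band_sets(a, b, tolerance = 4)
  expect_equal(cmp$supplementary_in_a, c(2363, 1663, 1453, 1372, 830))
  expect_length(cmp$supplementary_in_b, 0L)
  expect_equal(nrow(cmp$shared), length(shared))
  # identical lists -> everything shared
  cmp_id <- compare_band_sets(b, b)
  expect_length(cmp_id$supplementary_in_a, 0L)
  expect_length(cmp_id$supplementary_in_b, 0L)
  # tolerance boundary
  p1 <- mk(1000, "x"); p2 <- mk(1003, "y")
  expect_equal(nrow(compare_band_sets(p1, p2, 4)$shared), 1L)
  expect_equal(nrow(compare_band_sets(p1, p2, 2)$shared), 0L)
  expect_length(compare_band_sets(p1, p2, 2)$supplementary_in_a, 1L)
})

test_that("band-set comparison is symmetric under swapping inputs", {
  set.seed(21)
  mk <- function(centers, id) structure(
    data.frame(center = sort(centers, decreasing = TRUE),
               prominence = seq_along(centers), kind = "peak"),
    class = c("peak_list", "data.frame"), id = id)
  for (i in 1:10) {
    a <- mk(sample(600:3000, 12), "a")
    b <- mk(sample(600:3000, 9), "b")
    ab <- compare_band_sets(a, b, 6)
    ba <- compare_band_sets(b, a, 6)
    expect_equal(ab$supplementary_in_a, ba$supplementary_in_b)
    expect_equal(ab$supplementary_in_b, ba$supplementary_in_a)
    expect_equal(ab$shared$a, ba$shared$b)
  }
})

test_that("group mean spectra average pointwise and record group size", {
  ds <- generate_dataset(generator_config(composition = small_composition(),
                                          seed = 3))
  m <- mean_spectrum(ds, ds$meta$species == "Lactarius_subdulcis", "Ls")
  expect_equal(attr(m, "n"), sum(ds$meta$species == "Lactarius_subdulcis"))
  expect_equal(m$absorbance,
               rowMeans(ds$absorbance[, ds$meta$species ==
                                        "Lactarius_subdulcis"]))
  # mean of a spectrum with itself is itself; a and -a cancel
  two <- ir_dataset(ds$wavenumber, cbind(ds$absorbance[, 1],
                                         ds$absorbance[, 1]),
                    rbind(sample_meta("p"), sample_meta("q")))
  expect_equal(mean_spectrum(two)$absorbance, ds$absorbance[, 1])
  pm <- ir_dataset(ds$wavenumber, cbind(ds$absorbance[, 1],
                                        -ds$absorbance[, 1]),
                   rbind(sample_meta("p"), sample_meta("q")))
  expect_equal(mean_spectrum(pm)$absorbance, rep(0, 1701))
  expect_error(mean_spectrum(ds, ds$meta$species == "nope"), "no sample")
})
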