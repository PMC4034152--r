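test_that("canonical grid has 1701 points and window snapping matches inclusive counts", {
  g <- canonical_grid()
  expect_equal(g$n_points, 1701L)
  expect_equal(grid_points(g)[1], 600)
  expect_equal(grid_points(g)[1701], 4000)
  # 3-sample CSV covering 600-4000 at 2 cm-1 -> 1701 points per spectrum
  tmp <- withr::local_tempfile(fileext = ".csv")
  wn <- grid_points(g)
  df <- data.frame(wavenumber = wn, a = sin(wn / 100), b = cos(wn / 150),
                   c = wn / 4000)
  utils::write.csv(df, tmp, row.names = FALSE)
  ds <- read_spectra_csv(tmp)
  expect_equal(n_samples(ds), 3L)
  expect_equal(length(ds$wavenumber), 1701L)
})

test_that("descending wavenumber order reads to the identical dataset", {
  tmp_a <- withr::local_tempfile(fileext = ".csv")
  tmp_d <- withr::local_tempfile(fileext = ".csv")
  wn <- grid_wn
  y <- lorentz(wn, 1650, 20, height = 1)
  utils::write.csv(data.frame(wavenumber = wn, s1 = y), tmp_a,
                   row.names = FALSE)
  utils::write.csv(data.frame(wavenumber = rev(wn), s1 = rev(y)), tmp_d,
                   row.names = FALSE)
  da <- read_spectra_csv(tmp_a)
  dd <- read_spectra_csv(tmp_d)
  expect_equal(da$absorbance, dd$absorbance)
  expect_equal(da$wavenumber, dd$wavenumber)
})

test_that("off-grid sampling is interpolated onto the canonical grid accurately", {
  # spectrum sampled at 1.929 cm-1; smooth Lorentzian band; compare the
  # resampled trace with the dense analytic evaluation on the canonical grid
  # linear interpolation error <= h^2/8 * max|f''|; a band of FWHM 80 keeps
  # that below 1e-3 at h = 1.929
  wn_in <- seq(598, 4002, by = 1.929)
  y_in <- lorentz(wn_in, 1650, 80, height = 0.8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wavenumber = wn_in, s1 = y_in), tmp,
                   row.names = FALSE)
  ds <- read_spectra_csv(tmp)
  truth <- lorentz(ds$wavenumber, 1650, 80, height = 0.8)
  expect_lt(max(abs(ds$absorbance[, 1] - truth)), 1e-3)
  # resampling a spectrum already on the grid changes nothing
  expect_identical(resample_to_grid(grid_wn, truth, canonical_grid()), truth)
})

test_that("spectra that do not cover the canonical range are rejected", {
  wn_in <- seq(700, 4000, by = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wavenumber = wn_in, s1 = wn_in * 0), tmp,
                   row.names = FALSE)
  expect_error(read_spectra_csv(tmp), "extrapolation")
})

test_that("malformed CSV input fails with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,s1", "600,0.1", "602,oops", "604,0.2"), tmp)
  expect_error(read_spectra_csv(tmp), "non-numeric.*s1")
  writeLines(c("wavenumber,s1", "600,0.1", "604,0.2", "602,0.3"), tmp)
  expect_error(read_spectra_csv(tmp), "monotone")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  meta <- data.frame(sample_id = c("a", "a"), species = "unknown",
                     forest_type = "mono", site = "Hainich",
                     host_tree = "beech")
  utils::write.csv(data.frame(wavenumber = grid_wn, a = 0 * grid_wn + 1,
                              b = 0 * grid_wn + 2),
                   tmp2, row.names = FALSE)
  m2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(meta, m2, row.names = FALSE)
  expect_error(read_spectra_csv(tmp2, m2), "duplicate sample_id")
})

test_that("write/read round trip is the identity up to float formatting", {
  ds <- generate_dataset(generator_config(composition = small_composition(),
                                          seed = 7))
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, sp, mp)
  back <- read_spectra_csv(sp, mp)
  expect_equal(back$meta, ds$meta)
  expect_lt(max(abs(back$absorbance - ds$absorbance)), 1e-9)
  # column count = samples + wavenumber column
  expect_equal(length(strsplit(readLines(sp, n = 1), ",")[[1]]),
               n_samples(ds) + 1L)
  # byte-stable output
  sp2 <- withr::local_tempfile(fileext = ".csv")
  mp2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, sp2, mp2)
  expect_identical(readLines(sp), readLines(sp2))
})

test_that("empty dataset round trips as header-only files", {
  comp <- default_composition()
  comp$n <- 0L
  empty <- generate_dataset(generator_config(composition = comp))
  expect_equal(n_samples(empty), 0L)
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(empty, sp, mp)
  expect_equal(length(readLines(sp)), 1L)
  back <- read_spectra_csv(sp, mp)
  expect_equal(n_samples(back), 0L)
})

test_that("JCAMP round trip preserves the band position", {
  y <- gauss(grid_wn, 1632, 24, 0.9)
  s <- ir_spectrum(grid_wn, y, sample_meta("jfix"))
  tmp <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(s, tmp)
  back <- read_jcamp(tmp)
  expect_equal(back$meta$sample_id, "jfix")
  expect_lte(abs(back$wavenumber[which.max(back$absorbance)] - 1632), 2)
  expect_lt(max(abs(back$absorbance - y)), 1e-6)
})

test_that("JCAMP transmittance needs an explicit conversion flag", {
  tmp <- withr::local_tempfile(fileext = ".jdx")
  tr <- 10^(-gauss(grid_wn, 1500, 30, 0.5))
  n <- length(grid_wn)
  writeLines(c("##TITLE=trans", "##XUNITS=1/CM", "##YUNITS=TRANSMITTANCE",
               sprintf("##FIRSTX=%g", grid_wn[1]),
               sprintf("##LASTX=%g", grid_wn[n]),
               sprintf("##NPOINTS=%d", n), "##XYDATA=(X++(Y..Y))",
               vapply(seq(1, n, by = 8), function(i) {
                 j <- min(i + 7, n)
                 paste(c(sprintf("%g", grid_wn[i]),
                         sprintf("%.8g", tr[i:j])), collapse = " ")
               }, character(1)),
               "##END="), tmp)
  expect_error(read_jcamp(tmp), "convert=TRUE")
  s <- read_jcamp(tmp, convert = TRUE)
  expect_lt(max(abs(s$absorbance - gauss(grid_wn, 1500, 30, 0.5))), 1e-6)
})

test_that("truncated or compressed JCAMP files are refused outright", {
  y <- gauss(grid_wn, 1632, 24, 0.9)
  s <- ir_spectrum(grid_wn, y, sample_meta("trunc"))
  tmp <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(s, tmp)
  lines <- readLines(tmp)
  writeLines(utils::head(lines, length(lines) - 10), tmp)
  expect_error(read_jcamp(tmp), "truncated")
  # SQZ-style compressed y values -> unsupported dialect
  writeLines(c("##TITLE=sqz", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##FIRSTX=600", "##LASTX=4000", "##NPOINTS=1701",
               "##XYDATA=(X++(Y..Y))", "600 A123 B45 J12", "##END="), tmp)
  expect_error(read_jcamp(tmp), "dialect")
})
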