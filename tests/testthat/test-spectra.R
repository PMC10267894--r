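test_that("IRMPD yield follows the first-order survival form", {
  expect_identical(irmpd_yield(100, numeric(0)), 0)
  expect_equal(irmpd_yield(50, c(25, 25)), 0.693147, tolerance = 1e-6)
  expect_equal(irmpd_yield(90, 10), 0.105361, tolerance = 1e-5)
  expect_equal(irmpd_yield(90, 10, form = "fraction"), 0.1)
  expect_error(irmpd_yield(0, 5), "parent")
  expect_error(irmpd_yield(-1, 5), "parent")
})

test_that("power correction divides by interpolated pulse energy", {
  g <- grid_spectrum(seq(1000, 1100, 10), rep(2, 11))
  pc1 <- power_curve(c(900, 1200), c(1, 1))
  expect_equal(power_correct(g, pc1)$intensity, g$intensity)
  pc2 <- power_curve(c(900, 1200), c(2, 2))
  expect_equal(power_correct(g, pc2)$intensity, g$intensity / 2)
  # linear interpolation between samples
  g2 <- grid_spectrum(c(1000, 1100), c(1, 1))
  pc3 <- power_curve(c(1000, 1100), c(1, 2))
  expect_equal(power_correct(g2, pc3)$intensity, c(1, 0.5))
  # scaling the power curve by c scales the output by exactly 1/c
  pc4 <- power_curve(c(1000, 1100), 3 * c(1, 2))
  expect_equal(power_correct(g2, pc4)$intensity,
               power_correct(g2, pc3)$intensity / 3, tolerance = 1e-15)
  expect_error(power_correct(g, power_curve(c(1050, 1200), c(1, 1))), "span")
})

test_that("scale-and-broaden places, normalizes and widths bands correctly", {
  g <- scale_and_broaden(stick_spectrum(1000, 1), scale = 0.975, fwhm = 45,
                         grid = c(600, 1850, 0.5))
  peak <- which.max(g$intensity)
  expect_equal(g$wavenumber[peak], 975, tolerance = 0.5)
  expect_equal(max(g$intensity), 0.020876, tolerance = 1e-5 / 0.02)
  # unit area
  expect_equal(sum(g$intensity) * 0.5, 1, tolerance = 1e-3)
  # measured FWHM within one grid step of requested
  half <- max(g$intensity) / 2
  above <- range(which(g$intensity >= half))
  measured <- g$wavenumber[above[2]] - g$wavenumber[above[1]]
  expect_lt(abs(measured - 45), 2 * 0.5 + 1e-9)
})

test_that("convolution is linear and conserves stick intensity sums", {
  s1 <- stick_spectrum(c(900, 1200), c(2, 1))
  s2 <- stick_spectrum(c(1000, 1500), c(3, 0.5))
  both <- stick_spectrum(c(s1$frequency, s2$frequency),
                         c(s1$intensity, s2$intensity))
  g1 <- scale_and_broaden(s1)
  g2 <- scale_and_broaden(s2)
  gb <- scale_and_broaden(both)
  expect_lt(max(abs(gb$intensity - (g1$intensity + g2$intensity))), 1e-10)
  # area equals the sum of stick intensities (all bands >= 3 fwhm inside)
  expect_equal(sum(gb$intensity) * 1, sum(both$intensity), tolerance = 1e-3)
})

test_that("empty stick spectra broaden to an all-zero grid with a warning", {
  expect_warning(g <- scale_and_broaden(stick_spectrum()), "empty")
  expect_true(all(g$intensity == 0))
})

test_that("resampling interpolates inside coverage and zeroes outside", {
  g <- grid_spectrum(seq(1000, 1010, 2), c(0, 1, 2, 3, 4, 5))
  same <- resample_spectrum(g, c(1000, 1010, 2))
  expect_equal(same$intensity, g$intensity)
  mid <- resample_spectrum(grid_spectrum(c(1000, 1002), c(0, 2)),
                           c(999, 1003, 1))
  expect_equal(mid$intensity[mid$wavenumber == 1001], 1)
  expect_equal(mid$intensity[mid$wavenumber == 999], 0)
  const <- resample_spectrum(grid_spectrum(c(1000, 1010), c(4, 4)),
                             c(1000, 1010, 0.5))
  expect_true(all(const$intensity == 4))
  expect_error(resample_spectrum(g, c(2000, 2100, 1)), "overlap")
})

test_that("experimental preprocessing sorts, clips and resamples", {
  grid <- c(1000, 1004, 1)
  pts <- data.frame(wn = c(1002, 1000, 1004, 1001, 1003),
                    i = c(2, 1, -0.1, 1.5, 0.5))
  out <- preprocess_experimental(pts, grid = grid)
  expect_true(all(out$intensity >= 0))
  expect_equal(out$intensity[out$wavenumber == 1004], 0)  # clipped
  sorted <- pts[order(pts$wn), ]
  expect_identical(preprocess_experimental(sorted, grid = grid)$intensity,
                   out$intensity)
  expect_error(preprocess_experimental(pts[1, , drop = FALSE], grid = grid),
               "2")
})

test_that("two-column and JCAMP-DX spectrum files are read correctly", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path), add = TRUE)
  writeLines(c("# comment", "1000.0 0.5", "1001.0, 0.7", "1002.0\t0.9"), path)
  sp <- read_spectrum(path)
  expect_equal(sp$wavenumber, c(1000, 1001, 1002))
  expect_equal(sp$intensity, c(0.5, 0.7, 0.9))

  jpath <- tempfile(fileext = ".jdx")
  on.exit(unlink(jpath), add = TRUE)
  writeLines(c(
    "##TITLE=synthetic test spectrum",
    "##JCAMP-DX=4.24", "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.001",
    "##FIRSTX=1000", "##LASTX=1004", "##NPOINTS=5",
    "##XYDATA=(X++(Y..Y))",
    "1000 100 200 300", "1003 400 500",
    "##END="
  ), jpath)
  j <- read_jcamp(jpath)
  expect_equal(j$wavenumber, 1000:1004)
  expect_equal(j$intensity, c(0.1, 0.2, 0.3, 0.4, 0.5))
})

test_that("stick-spectrum tables round-trip with their metadata headers", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeLines(c(
    "# molecule_id: gly", "# adduct: deprotonated", "# site: 5",
    "# variant: g1", "# relative_energy_kj_mol: 12.5",
    "mode_index frequency_cm-1 intensity_km_mol",
    "1 612.3 45.0", "2 1301.7 210.2", "3 1648.9 305.0"
  ), path)
  st <- read_stick_table(path)
  expect_s3_class(st, "ir_stick")
  expect_equal(st$frequency, c(612.3, 1301.7, 1648.9))
  expect_equal(st$intensity, c(45, 210.2, 305))
  meta <- attr(st, "meta")
  expect_equal(meta$molecule_id, "gly")
  expect_equal(as.numeric(meta$relative_energy_kj_mol), 12.5)
})
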