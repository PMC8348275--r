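test_that("spectrum files round-trip at full precision", {
  s <- raman_spectrum(c(100.05, 100.15, 100.25), c(1.234567890123, 0, -3e-7),
                      meta = list(T_rot = 30))
  path <- withr::local_tempfile(fileext = ".dat")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_identical(r$wavenumber, s$wavenumber)
  expect_identical(r$intensity, s$intensity)
  expect_true(any(grepl("T_rot", r$meta$header)))
})

test_that("read_spectrum handles comments, sorting and bad rows", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# a header", "1 2", "3 4", "2 3"), path)
  expect_warning(s <- read_spectrum(path), "unsorted")
  expect_equal(s$wavenumber, c(1, 2, 3))
  expect_equal(s$intensity, c(2, 3, 4))
  writeLines(c("1 2", "oops nope"), path)
  expect_error(read_spectrum(path), "line 2")
  # constant readout offset subtraction
  writeLines(c("1 10", "2 11"), path)
  expect_equal(read_spectrum(path, offset = 10)$intensity, c(0, 1))
})

test_that("despike removes spikes the way the scan count allows", {
  base <- c(1, 2, 3, 4, 5)
  expect_equal(despike(list(base, base, base)), base)
  spiked <- base; spiked[3] <- 1e6
  expect_equal(despike(list(base, spiked, base)), base)
  expect_equal(despike(list(base, spiked)), base)  # two scans: minimum
  expect_warning(out <- despike(list(spiked)), "single scan")
  expect_equal(out, spiked)
  # random spikes at low rate: output matches truth almost everywhere
  set.seed(3)
  truth <- sin(seq(0, 10, length.out = 5000)) + 2
  scans <- lapply(1:3, function(i) {
    x <- truth
    hit <- runif(5000) < 1e-3
    x[hit] <- x[hit] + 1e6
    x
  })
  out <- despike(scans)
  expect_gte(mean(out == truth), 0.999)
})

test_that("jacobian correction preserves the total signal", {
  counts <- rep(7, 100)
  lin <- seq(1000, 1099, by = 1)
  s <- jacobian_correct(counts, lin)
  expect_equal(s$intensity, rep(7, 100))  # uniform rescale only
  # quadratic mapping: the density times the local width returns the counts
  # exactly, and the trapezoidal integral agrees with the pixel sum within
  # discretisation error
  px <- 0:199
  quad <- 1000 + 0.8 * px + 0.001 * px^2
  counts <- 5 + sin(px / 20)
  s2 <- jacobian_correct(counts, quad)
  w <- c(quad[2] - quad[1], (quad[3:200] - quad[1:198]) / 2,
         quad[200] - quad[199])
  expect_equal(sum(s2$intensity * w), sum(counts), tolerance = 1e-12)
  expect_equal(spectrum_integral(s2), sum(counts), tolerance = 1e-2)
  # intensity inversely proportional to the local spectral width
  s3 <- jacobian_correct(rep(1, 200), quad)
  mid <- 50:150
  expect_equal(s3$intensity[mid] * (quad[mid + 1] - quad[mid - 1]) / 2,
               rep(1, length(mid)), tolerance = 1e-12)
  expect_error(jacobian_correct(c(1, 2, 3), c(1, 3, 2)), "monotone")
})

test_that("stitching equalises anchor heights across segments", {
  grid1 <- seq(100, 200, by = 0.5)
  seg1 <- raman_spectrum(grid1, dnorm(grid1, 150, 2) + dnorm(grid1, 195, 2))
  grid2 <- seq(190, 300, by = 0.5)
  seg2 <- raman_spectrum(grid2, 2 * (dnorm(grid2, 195, 2) + dnorm(grid2, 260, 2)))
  out <- stitch_segments(list(seg1, seg2), anchors = c(195))
  h1 <- peak_height(seg1, 195, 5)$height
  expect_equal(peak_height(out, 195, 5)$height, h1, tolerance = 1e-9)
  expect_equal(peak_height(out, 260, 5)$height,
               peak_height(seg2, 260, 5)$height / 2, tolerance = 1e-9)
  # identical segments stitch to themselves; stitching is idempotent
  same <- stitch_segments(list(seg1, seg1), anchors = c(150))
  expect_equal(same$intensity, seg1$intensity, tolerance = 1e-12)
  again <- stitch_segments(list(out), anchors = c(195))
  expect_equal(again$intensity, out$intensity)
  expect_error(stitch_segments(list(seg1, seg2), anchors = c(500)),
               "anchor")
})

test_that("five randomly rescaled segments recover a common level", {
  set.seed(11)
  full_grid <- seq(0, 500, by = 0.5)
  centers <- seq(45, 455, by = 45)
  truth <- rowSums(sapply(centers, function(c0) dnorm(full_grid, c0, 3)))
  cuts <- seq(0, 500, length.out = 6)
  segs <- lapply(1:5, function(i) {
    keep <- full_grid >= max(0, cuts[i] - 20) & full_grid <= min(500, cuts[i + 1] + 20)
    raman_spectrum(full_grid[keep], truth[keep] * runif(1, 0.3, 3))
  })
  out <- stitch_segments(segs, anchors = centers)
  # every anchor ends up at the same multiple of the true (common) profile
  scales <- vapply(centers, function(c0)
    peak_height(out, c0, 5)$height / dnorm(0, 0, 3), numeric(1))
  expect_equal(max(scales) / min(scales), 1, tolerance = 1e-6)
})

test_that("peak_height recovers amplitudes and flags boundary maxima", {
  grid <- seq(0, 100, by = 0.1)
  g <- raman_spectrum(grid, 3 * dnorm(grid, 50, 2) / dnorm(0, 0, 2))
  pk <- peak_height(g, 50, 10)
  expect_equal(pk$height, 3, tolerance = 1e-6)
  expect_equal(pk$position, 50)
  expect_false(pk$boundary)
  # tilted baseline removed by linear endpoints
  tilt <- raman_spectrum(grid, g$intensity + 0.5 + 0.02 * grid)
  pk2 <- peak_height(tilt, 50, 10, baseline = "linear_endpoints")
  expect_equal(pk2$height, 3, tolerance = 0.01 * 3)
  # window that misses the peak: boundary flag
  pk3 <- peak_height(g, 80, 5)
  expect_true(pk3$boundary)
  expect_error(peak_height(g, 300, 5), "window")
})

test_that("concentration scaling recovers monomer and dimer exponents", {
  conc <- c(1, 2, 4, 8, 16, 32)
  suppressWarnings({  # summary.lm warns on the exact fits
    expect_equal(concentration_scaling(3 * conc, conc)$exponent, 1)
    expect_equal(concentration_scaling(0.1 * conc^2, conc)$exponent, 2)
  })
  set.seed(5)
  noisy <- conc^1.5 * exp(rnorm(6, sd = 0.05))
  fit <- concentration_scaling(noisy, conc)
  expect_equal(fit$exponent, 1.5, tolerance = 0.2)
  expect_error(concentration_scaling(c(1, 2), c(1, 2)), "3 points")
})
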