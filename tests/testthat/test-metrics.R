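test_that("averaged spectra localize tones and flatten white noise", {
  dwell <- 2e-5
  n <- 128L
  f0 <- 12 / (n * dwell)   # bin-aligned: 4687.5 Hz, no spectral leakage
  t <- (0:(n - 1)) * dwell
  tone <- exp(2i * pi * f0 * t)
  sp <- averagedSpectrum(tone, dwell)
  expect_equal(sp$freq[which.max(sp$magnitude)], f0, tolerance = 1e-9)
  expect_gt(max(sp$magnitude), 10 * sort(sp$magnitude, decreasing = TRUE)[2L])
  # white complex noise: flat up to Monte-Carlo tolerance; the mean bin
  # magnitude follows the chi distribution, sigma*sqrt(pi)/2 for unit-std
  # complex bins
  set.seed(1)
  lines <- matrix(complex(real = rnorm(400 * n, sd = 1 / sqrt(2)),
                          imaginary = rnorm(400 * n, sd = 1 / sqrt(2))),
                  400L, n)
  spw <- averagedSpectrum(lines, dwell)
  expect_lt(stats::sd(spw$magnitude) / mean(spw$magnitude), 0.15)
  expect_equal(mean(spw$magnitude), sqrt(pi) / 2, tolerance = 0.02)
  expect_error(averagedSpectrum(matrix(0+0i, 0L, 4L)), "at least one")
})

test_that("background noise estimation matches the Rayleigh closed form", {
  expect_equal(backgroundNoise(array(0, c(20L, 20L, 10L)),
                               array(TRUE, c(20L, 20L, 10L))), 0)
  # complex Gaussian with per-complex-sample std sigma: the magnitude std
  # in the background is sigma * sqrt(1 - pi/4) (Rayleigh)
  sigma <- 0.07
  set.seed(4)
  mag <- Mod(complex(real = rnorm(2e5, sd = sigma / sqrt(2)),
                     imaginary = rnorm(2e5, sd = sigma / sqrt(2))))
  img <- array(mag, c(100L, 100L, 20L))
  est <- backgroundNoise(img, array(TRUE, dim(img)))
  expect_equal(est, sigma * sqrt(1 - pi / 4), tolerance = 0.01)
  expect_error(backgroundNoise(img, array(c(TRUE, rep(FALSE, 1999L)),
                                          dim(img))), "2000")
})

test_that("the 2000-voxel mask keeps the estimator SE under 2%", {
  sigma <- 0.05
  set.seed(5)
  ests <- replicate(200, {
    mag <- Mod(complex(real = rnorm(2000, sd = sigma / sqrt(2)),
                       imaginary = rnorm(2000, sd = sigma / sqrt(2))))
    stats::sd(mag)
  })
  expect_lt(stats::sd(ests) / mean(ests), 0.02)
})

test_that("suppression reports pass trivially and fail the negative control", {
  ph <- smallPhantom()
  prot <- deskFseProtocol(nex = 1L, charCount = 4L)
  rec <- simulateScan(ph, prot, standardEmiWorld(), seed = 2L)
  twin <- shieldedTwin(rec)
  # cancelled == shielded: zero deviation, pass
  repPass <- suppressionReport(twin, rec, twin, ph, c(2L, 2L, 1L))
  expect_equal(shieldedDeviation(repPass), 0)
  expect_true(repPass@pass5pct)
  # the contaminated record passed off as cancelled: large deviation, fail
  repFail <- suppressionReport(rec, rec, twin, ph, c(2L, 2L, 1L))
  expect_false(repFail@pass5pct)
  expect_gt(shieldedDeviation(repFail), 0.25)
  expect_equal(repFail@suppressionDb, 0, tolerance = 1e-9)
  # deviation is invariant to global scaling of the records
  scl <- function(r) { r@rxAcq <- 3 * r@rxAcq; r }
  repScaled <- suppressionReport(scl(rec), scl(rec), scl(twin), ph,
                                 c(2L, 2L, 1L))
  expect_equal(shieldedDeviation(repScaled), shieldedDeviation(repFail),
               tolerance = 1e-10)
  # geometry mismatch is rejected
  prot32 <- deskFseProtocol(n = 32L, nex = 1L, charCount = 4L)
  rec32 <- simulateScan(smallPhantom(32L), prot32, NULL, seed = 1L)
  expect_error(suppressionReport(rec32, rec, twin, ph), "share")
})

test_that("reports serialize to JSON with spectra alongside", {
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 4L)
  rec <- simulateScan(ph, prot, standardEmiWorld(), seed = 2L)
  lc <- fitLinearCanceller(rec, taps = 3L, reg = 1e-10)
  rep <- suppressionReport(applyLinearCanceller(lc, rec), rec,
                           shieldedTwin(rec), ph, c(4L, 4L, 1L))
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$shieldedDeviation, shieldedDeviation(rep),
               tolerance = 1e-9)
  expect_true(file.exists(sub("\\.json$", "_spectra.csv", f)))
  unlink(c(f, sub("\\.json$", "_spectra.csv", f)))
})
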