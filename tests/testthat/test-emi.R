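dwell <- 2e-5

test_that("tone segments are phase-continuous across window boundaries", {
  src <- emiSource("tone", amplitude = 1, freq = 1234)
  a <- genSourceSegment(src, 0, 64L, dwell)
  b <- genSourceSegment(src, 64 * dwell, 64L, dwell)
  # analytic phase law: step between adjacent samples is 2*pi*f0*dwell
  step <- Arg(b[1L] / a[64L])
  expect_equal(step, ((2 * pi * 1234 * dwell + pi) %% (2 * pi)) - pi,
               tolerance = 1e-10)
  expect_equal(Mod(a), rep(1, 64L))
})

test_that("swept sources traverse their band monotonically", {
  src <- emiSource("swept", amplitude = 1, sweep = c(-2e4, 2e4))
  scanDur <- 2
  # short-time Fourier oracle: dominant bin of consecutive segments
  peaks <- vapply(seq(0, scanDur - 0.01, length.out = 12), function(t0) {
    seg <- genSourceSegment(src, t0, 256L, dwell, scanDuration = scanDur)
    sp <- averagedSpectrum(seg, dwell)
    sp$freq[which.max(sp$magnitude)]
  }, 0)
  expect_true(all(diff(peaks) > 0))
  expect_lt(peaks[1L], -1.5e4)
  expect_gt(peaks[12L], 1.5e4)
})

test_that("powerline harmonics land only on multiples of the fundamental", {
  src <- emiSource("powerline_harmonics", amplitude = 1, band = c(-2e3, 2e3),
                   fundamental = 50)
  # 1000 samples at 20 us -> exact 50 Hz bin spacing: no leakage
  seg <- genSourceSegment(src, 0, 1000L, dwell)
  sp <- averagedSpectrum(seg, dwell)
  onGrid <- abs(sp$freq %% 50) < 1e-9 & abs(sp$freq) > 1 & abs(sp$freq) <= 2e3
  expect_gt(sum(sp$magnitude[onGrid]^2) / sum(sp$magnitude^2), 1 - 1e-12)
  expect_equal(sqrt(mean(Mod(seg)^2)), 1, tolerance = 1e-2)
})

test_that("broadband segments are band-limited, seeded and unit-rms", {
  src <- emiSource("broadband", amplitude = 0.5, band = c(-1.5e4, -5e3))
  a <- genSourceSegment(src, 0, 256L, dwell, seed = 3L)
  b <- genSourceSegment(src, 0, 256L, dwell, seed = 3L)
  expect_identical(a, b)
  sp <- averagedSpectrum(a, dwell)
  out <- sp$freq < -1.55e4 | sp$freq > -4.5e3
  expect_lt(max(sp$magnitude[out]) / max(sp$magnitude), 1e-10)
  expect_equal(sqrt(mean(Mod(a)^2)), 0.5, tolerance = 1e-12)
  expect_error(genSourceSegment(emiSource("broadband", band = c(0, 5e4)),
                                0, 64L, dwell), "Nyquist")
})

test_that("coupling matches a naive convolution oracle and is linear", {
  world <- standardEmiWorld()
  cw <- coupleWindow(world, 0.123, 96L, seed = 9L, scanDuration = 1)
  # direct-convolution oracle over the same source segments
  rxOracle <- complex(96L)
  sensOracle <- matrix(0+0i, 96L, 10L)
  for (si in seq_along(world@sources)) {
    seg <- genSourceSegment(world@sources[[si]], 0.123, 96L, dwell,
                            scanDuration = 1, seed = 9L)
    rxOracle <- rxOracle + naiveFir(world@coupling@rxTaps[[si]], seg)
    for (c in 1:10)
      sensOracle[, c] <- sensOracle[, c] +
        naiveFir(world@coupling@sensTaps[[si]][c, ], seg)
  }
  expect_equal(cw$rx, rxOracle, tolerance = 1e-12)
  expect_equal(cw$sensEmi, sensOracle, tolerance = 1e-12)
  # superposition: doubling every source amplitude doubles the coupled EMI
  world2 <- standardEmiWorld(emiScale = 2)
  cw2 <- coupleWindow(world2, 0.123, 96L, seed = 9L, scanDuration = 1)
  expect_equal(cw2$rx, 2 * cw$rx, tolerance = 1e-10)
  expect_equal(cw2$sensEmi, 2 * cw$sensEmi, tolerance = 1e-10)
})

test_that("identity coupling and empty worlds behave trivially", {
  src <- emiSource("tone", amplitude = 1, freq = 2000)
  cp <- couplingModel(rxTaps = list(1 + 0i),
                      sensTaps = list(matrix(rep(1 + 0i, 10L), ncol = 1L)),
                      sensorNoiseSigma = 0)
  w <- emiWorld(list(src), cp)
  cw <- coupleWindow(w, 0, 64L, seed = 1L)
  seg <- genSourceSegment(src, 0, 64L, dwell)
  expect_equal(cw$sensEmi[, 3L], seg, tolerance = 1e-12)
  expect_equal(cw$rx, seg, tolerance = 1e-12)
  # zero sources: sensing carries only sensor noise, receive EMI is zero
  w0 <- emiWorld(list(), couplingModel(list(), list(), sensorNoiseSigma = 1e-3))
  cw0 <- coupleWindow(w0, 0, 64L, seed = 1L)
  expect_true(all(cw0$rx == 0))
  expect_true(all(cw0$sensEmi == 0))
  expect_gt(stats::sd(Re(cw0$sensNoise)), 0)
})

test_that("receive-coil drift modulates the coupling gain", {
  w <- standardEmiWorld()
  w@coupling@drift <- list(rate_hz = 0.5, depth = 0.2)
  cw0 <- coupleWindow(standardEmiWorld(), 0.5, 64L, seed = 2L, scanDuration = 2)
  cwD <- coupleWindow(w, 0.5, 64L, seed = 2L, scanDuration = 2)
  g <- 1 + 0.2 * sin(2 * pi * 0.5 * (0.5 + (0:63) * dwell))
  expect_equal(cwD$rx, cw0$rx * g, tolerance = 1e-10)
  expect_equal(cwD$sensEmi, cw0$sensEmi, tolerance = 1e-12)
})
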