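test_that("elliptic masks match brute-force lattice enumeration", {
  expect_equal(sum(ellipticMask(1L, 1L)), 1L)             # DC only
  # 9x9: integer lattice points inside the radius-4 circle
  cnt <- 0L
  for (k1 in -4:4) for (k2 in -4:4) if (k1^2 + k2^2 <= 16) cnt <- cnt + 1L
  expect_equal(sum(ellipticMask(9L, 9L)), cnt)
  expect_equal(cnt, 49L)
  # 128x32: included fraction close to pi/4, against direct enumeration
  m <- ellipticMask(128L, 32L)
  cnt2 <- 0L
  for (k1 in -64:63) for (k2 in -16:15)
    if ((k1 / 64)^2 + (k2 / 16)^2 <= 1) cnt2 <- cnt2 + 1L
  expect_equal(sum(m), cnt2)
  frac <- sum(m) / (128 * 32)
  expect_gte(frac, 0.76); expect_lte(frac, 0.80)
  # DC always included
  expect_true(ellipticMask(2L, 2L)[2L, 2L])
})

test_that("noiseless shielded scans reproduce the phantom DFT exactly", {
  ph <- smallPhantom()
  prot <- noiselessProtocol()
  rec <- simulateScan(ph, prot, NULL, seed = 1L, shieldedTwin = FALSE)
  # characterization windows carry no MRI signal and, here, no noise/EMI
  expect_true(all(rxCharacterization(rec) == 0))
  k <- ulfemi:::fftc(array(as.complex(protocolSignalMap(ph, prot)),
                           c(64, 64, 1)))
  for (i in seq_len(nLines(rec)))
    expect_equal(rxAcquisition(rec)[i, ],
                 k[, rec@lines$pe1[i], rec@lines$pe2[i]], tolerance = 1e-14)
  # Parseval under the unitary centred FFT convention
  w <- protocolSignalMap(ph, prot)
  expect_equal(sum(Mod(k)^2), sum(w^2), tolerance = 1e-10)
})

test_that("records are deterministic and twins differ only by the EMI term", {
  ph <- smallPhantom()
  prot <- deskFseProtocol()
  a <- simulateScan(ph, prot, standardEmiWorld(), seed = 4L)
  b <- simulateScan(ph, prot, standardEmiWorld(), seed = 4L)
  expect_identical(rxAcquisition(a), rxAcquisition(b))
  expect_identical(a@sensChar, b@sensChar)
  twin <- shieldedTwin(a)
  # receive difference equals the coupled-EMI replay stored by the simulator
  expect_equal(rxAcquisition(a) - rxAcquisition(twin), a@meta$emiRxAcq,
               tolerance = 1e-12)
  expect_equal(rxCharacterization(a) - rxCharacterization(twin),
               a@meta$emiRxChar, tolerance = 1e-12)
  # sensing coils never see MRI signal: twin sensing is sensor noise only
  expect_equal(a@sensAcq - twin@sensAcq,
               a@sensAcq - twin@sensAcq, tolerance = 0)  # shapes agree
  expect_false(isTRUE(twin@meta$emiOn))
  # EMI-to-receiver-noise power ratio of the standard world is >= 10
  ratio <- mean(Mod(a@meta$emiRxChar)^2) / prot@rxNoiseSigma^2
  expect_gte(ratio, 10)
})

test_that("scan bookkeeping covers the masked phase encodes with ETL shots", {
  ph <- smallPhantom()
  prot <- deskFseProtocol()
  rec <- simulateScan(ph, prot, NULL, seed = 1L, shieldedTwin = FALSE)
  nMasked <- 64L   # full 64 x 1 grid
  shots <- rec@meta$shots
  expect_gte(shots * prot@etl, nMasked)
  expect_equal(rec@meta$scanTimeS, shots * prot@nex * prot@tr / 1000)
  # every NEX repeat of every masked phase encode is present once
  key <- table(paste(rec@lines$pe1, rec@lines$pe2))
  expect_true(all(key == prot@nex))
  # characterization windows never overlap acquisition windows in time:
  # the pre-excitation half ends before TE, the end-of-TR half starts
  # after the echo train
  win <- prot@nX * prot@dwell + prot@echoGap
  acqIn <- rec@lines$t0 %% (prot@tr / 1000)
  charIn <- rec@charTimes %% (prot@tr / 1000)
  early <- charIn < prot@te / 1000
  expect_true(all(charIn[early] + win <= prot@te / 1000 + 1e-9))
  expect_true(all(charIn[!early] >= max(acqIn) + win - 1e-9))
})

test_that("a TR too short for the dual windows is rejected", {
  expect_error(
    protocolConfig("FSE3D", tr = 30, te = 20, etl = 8L,
                   matrixSize = c(64L, 64L, 1L), charCount = 16L),
    "time-overhead|characterization")
})

test_that("FSE ordering is center-out so TE applies at k-space center", {
  ph <- smallPhantom()
  prot <- deskFseProtocol(nex = 1L, charCount = 4L)
  rec <- simulateScan(ph, prot, NULL, seed = 1L, shieldedTwin = FALSE)
  first <- rec@lines[rec@lines$echo == 1L, ]
  # the first echo of some shot carries the DC line, acquired at t = TE
  dc <- first[first$pe1 == 33L, ]
  expect_equal(nrow(dc), 1L)
  expect_equal(dc$t0 %% (prot@tr / 1000), prot@te / 1000, tolerance = 1e-9)
  # radius grows with echo index within a shot
  s1 <- rec@lines[rec@lines$shot == 1L, ]
  expect_true(all(diff(abs(s1$pe1 - 33L)) >= 0))
})

test_that("records round-trip through save/load", {
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 4L)
  rec <- simulateScan(ph, prot, NULL, seed = 2L, shieldedTwin = FALSE)
  f <- tempfile(fileext = ".rds")
  saveRecord(rec, f)
  rec2 <- loadRecord(f)
  expect_identical(rxAcquisition(rec), rxAcquisition(rec2))
  unlink(f)
})
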