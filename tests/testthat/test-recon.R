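test_that("NEX averaging places complex means and flags missing repeats", {
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 4L, rxNoiseSigma = 0)
  rec <- simulateScan(ph, prot, NULL, seed = 1L, shieldedTwin = FALSE)
  kv <- averageNex(rec)                      # NEX = 1: identity placement
  for (i in seq_len(nLines(rec)))
    expect_equal(kv@data[, rec@lines$pe1[i], rec@lines$pe2[i]],
                 rec@rxAcq[i, ], tolerance = 1e-14)
  prot2 <- deskFseProtocol(n = 32L, nex = 2L, charCount = 4L, rxNoiseSigma = 0)
  rec2 <- simulateScan(ph, prot2, NULL, seed = 1L, shieldedTwin = FALSE)
  kv2 <- averageNex(rec2)                    # identical repeats: mean = repeat
  expect_equal(kv2@data, kv@data, tolerance = 1e-14)
  broken <- rec2
  broken@lines <- broken@lines[-1L, ]
  broken@rxAcq <- broken@rxAcq[-1L, , drop = FALSE]
  broken@sensAcq <- broken@sensAcq[-1L, , , drop = FALSE]
  expect_error(averageNex(broken), "missing NEX repeat")
})

test_that("averaging i.i.d. noise shrinks line noise std by 1/sqrt(n)", {
  ph <- makePhantom(c(32L, 32L, 1L), layout = "uniform", uniformTissue = "GM")
  sds <- vapply(c(1L, 4L), function(nn) {
    prot <- deskFseProtocol(n = 32L, nex = nn, charCount = 4L,
                            rxNoiseSigma = 0.05)
    mean(vapply(1:4, function(s) {
      rec <- simulateScan(ph, prot, NULL, seed = s, shieldedTwin = FALSE)
      k <- ulfemi:::fftc(array(as.complex(protocolSignalMap(ph, prot)),
                               c(32, 32, 1)))
      kv <- averageNex(rec)
      stats::sd(Re(kv@data - k))
    }, 0))
  }, 0)
  expect_equal(sds[2L] / sds[1L], 0.5, tolerance = 0.05)
})

test_that("Cartesian recon round-trips and zero-padding only resamples", {
  # delta at DC -> constant magnitude image
  k <- array(0+0i, c(16L, 16L, 1L))
  k[9L, 9L, 1L] <- 1+0i
  kv <- new("KSpaceVolume", data = k, mask = matrix(TRUE, 16L, 1L),
            voxelSize = c(2, 2, 10), nex = 1)
  img <- reconCartesian(kv)
  expect_equal(max(imageData(img)) - min(imageData(img)), 0, tolerance = 1e-14)
  # forward-DFT round trip at pad 1
  set.seed(2)
  x <- array(runif(16 * 16), c(16L, 16L, 1L))
  kv2 <- new("KSpaceVolume", data = ulfemi:::fftc(array(as.complex(x), dim(x))),
             mask = matrix(TRUE, 16L, 1L), voxelSize = c(2, 2, 10), nex = 1)
  expect_equal(imageData(reconCartesian(kv2)), x, tolerance = 1e-12)
  # display voxel size: 2 x 2 x 10 mm with pad (2,2,2) -> 1 x 1 x 5 mm
  kv3 <- new("KSpaceVolume", data = array(0+0i, c(8L, 8L, 4L)),
             mask = matrix(TRUE, 8L, 4L), voxelSize = c(2, 2, 10), nex = 1)
  img3 <- reconCartesian(kv3, c(2L, 2L, 2L))
  expect_equal(img3@voxelSize, c(1, 1, 5))
  expect_equal(dim(imageData(img3)), c(16L, 16L, 8L))
  # image values at original voxel centres are preserved under padding
  img1 <- reconCartesian(kv2, c(1L, 1L, 1L))
  img2 <- reconCartesian(kv2, c(2L, 2L, 1L))
  orig <- imageData(img1)
  up <- imageData(img2)[seq(1L, 32L, by = 2L), seq(1L, 32L, by = 2L), ,
                        drop = FALSE]
  expect_equal(up, orig, tolerance = 1e-12)
})

test_that("elliptic masking equals a direct masked-DFT oracle", {
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 4L,
                          rxNoiseSigma = 0)
  prot@elliptic <- TRUE
  rec <- simulateScan(ph, prot, NULL, seed = 1L, shieldedTwin = FALSE)
  img <- reconCartesian(averageNex(rec))
  # oracle: full DFT, zero outside the elliptic mask, inverse
  k <- ulfemi:::fftc(array(as.complex(protocolSignalMap(ph, prot)),
                           c(32, 32, 1)))
  m <- ellipticMask(32L, 1L)
  for (j in which(!m[, 1L])) k[, j, 1L] <- 0
  oracle <- Mod(ulfemi:::ifftc(k))
  expect_equal(imageData(img), oracle, tolerance = 1e-12)
})

test_that("ghost correction recovers an injected odd/even phase and is idempotent", {
  ph <- smallPhantom()
  prot <- protocolDwiEpi(nex = 1L, rxNoiseSigma = 0)
  recs <- simulateEpiDwi(ph, prot, NULL, seed = 1L, ghostPhase = c(0.3, 0.02))
  gc1 <- epiGhostCorrect(recs$b0)
  expect_equal(gc1@meta$epi$ghostFit, c(0.3, 0.02), tolerance = 0.01)
  # ghost-to-main intensity ratio: >20% before, <5% after
  obj <- phantomLabels(ph)[, , 1L] > 0
  ghostROI <- obj[, c(33:64, 1:32)] & !obj
  ratio <- function(rec) {
    im <- imageData(reconCartesian(averageNex(rec)))[, , 1L]
    mean(im[ghostROI]) / mean(im[obj])
  }
  expect_gt(ratio(recs$b0), 0.20)
  expect_lt(ratio(gc1), 0.05)
  gc2 <- epiGhostCorrect(gc1)
  expect_lt(abs(gc2@meta$epi$ghostFit[2L]), 1e-6)
  expect_equal(gc2@rxAcq, gc1@rxAcq, tolerance = 1e-10)
  # zero injected offset: correction is a no-op
  recs0 <- simulateEpiDwi(ph, prot, NULL, seed = 1L)
  gc0 <- epiGhostCorrect(recs0$b0)
  expect_equal(gc0@rxAcq, recs0$b0@rxAcq, tolerance = 1e-9)
})

test_that("distortion correction undoes field-map displacement", {
  ph <- smallPhantom()
  prot <- protocolDwiEpi(nex = 1L, rxNoiseSigma = 0)
  recs0 <- simulateEpiDwi(ph, prot, NULL, seed = 1L)
  img0 <- reconCartesian(averageNex(recs0$b0))
  bw <- recs0$b0@meta$epi$bwPerPixel
  # zero field map: identity
  same <- distortionCorrect(img0, array(0, c(64, 64, 1)), bw)
  expect_equal(imageData(same), imageData(img0), tolerance = 1e-14)
  # uniform offset of exactly 2 pixel-bandwidths: rigid shift, exactly undone
  phS <- ph; phS@fieldMap <- array(2 * bw, c(64, 64, 1))
  recsD <- simulateEpiDwi(phS, prot, NULL, seed = 1L, distortion = TRUE)
  imgD <- reconCartesian(averageNex(recsD$b0))
  fixed <- distortionCorrect(imgD, phS@fieldMap, bw)
  expect_equal(imageData(fixed), imageData(img0), tolerance = 1e-10)
  # smooth field map: object edges move back to within half a pixel
  phG <- makePhantom(c(64L, 64L, 1L), fieldMapHz = 2.5 * bw, seed = 5L)
  recsG <- simulateEpiDwi(phG, prot, NULL, seed = 1L, distortion = TRUE)
  imgG <- reconCartesian(averageNex(recsG$b0))
  fixedG <- distortionCorrect(imgG, fieldMap(phG), bw)
  edge <- function(img, i) {
    prof <- imageData(img)[i, , 1L]
    min(which(prof > 0.5 * max(prof)))   # leading-edge locator
  }
  for (i in c(24L, 32L, 40L))
    expect_lte(abs(edge(fixedG, i) - edge(img0, i)), 0.5)
})

test_that("the ADC pipeline recovers tissue ADCs and respects isotropy", {
  ph <- smallPhantom()
  prot <- protocolDwiEpi(nex = 1L, rxNoiseSigma = 0)
  recs <- simulateEpiDwi(ph, prot, NULL, seed = 1L)
  imgs <- lapply(recs, function(r) reconCartesian(averageNex(r)))
  out <- adcPipeline(imgs$b0, imgs$b1x, imgs$b1y, imgs$b1z, b = 500)
  lab <- phantomLabels(ph)[, , 1L]
  tt <- tissueTable(ph)
  for (nm in c("CSF", "GM", "WM")) {
    i <- match(nm, tt$name) - 1L
    got <- mean(out$adc[, , 1L][lab == i], na.rm = TRUE)
    expect_equal(got, tt$adc[i + 1L], tolerance = 0.02)
  }
  # isotropic phantom: combined b1 equals each directional b1
  expect_equal(imageData(out$iso), imageData(imgs$b1x), tolerance = 1e-9)
  # CSF shows the strongest attenuation, ~exp(-1.5)
  csf <- lab == 1L
  att <- mean(imageData(imgs$b1x)[, , 1L][csf]) /
         mean(imageData(imgs$b0)[, , 1L][csf])
  expect_equal(att, exp(-1.5), tolerance = 1e-6)
  # background stays masked
  expect_true(all(is.na(out$adc[, , 1L][lab == 0L])))
})
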