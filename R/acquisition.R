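## Dual-window multichannel acquisition simulator. Each TR holds the MRI
## signal acquisition windows (one per echo) plus EMI characterization
## windows at end-of-TR where transverse signal has fully decayed; receive
## and sensing coils are sampled in both. k-space convention: DC at 0-based
## index floor(N/2), unitary centred FFT, FE along the first axis.

#' Protocol constructor and the four 0.055 T presets
#'
#' `protocolConfig()` builds a validated [ProtocolConfig-class]. The presets
#' carry the published protocol parameters: T1W 3D GRE (TR/TE = 52/13 ms,
#' FA = 40), T2W 3D FSE (TR/TE = 1500/202 ms, ETL = 21), FLAIR-like 3D FSE
#' (TR/TE = 500/129 ms, ETL = 13, short-TR CSF saturation) and 2D EPI DWI
#' (TR/TE = 2800/102 ms, b = 500 s/mm^2, Delta/delta = 49/30 ms, NEX = 52).
#' `matrixSize` and `nex` can be overridden to desk-scale a protocol while
#' keeping its contrast parameters.
#'
#' @param kind sequence kind.
#' @param tr,te,fa,etl,nex,matrixSize,fov,sliceThickness,dwell,charCount,echoGap,elliptic,rxNoiseSigma,diffusion
#'   see [ProtocolConfig-class].
#' @return a [ProtocolConfig-class].
#' @export
protocolConfig <- function(kind, tr, te, fa = 90, etl = 1L, nex = 1L,
                           matrixSize = c(64L, 64L, 1L),
                           fov = c(250, 250, 320), sliceThickness = 10,
                           dwell = 2e-5, charCount = 1L, echoGap = 5e-4,
                           elliptic = FALSE, rxNoiseSigma = 0.01,
                           diffusion = NULL) {
  new("ProtocolConfig", kind = kind, tr = tr, te = te, fa = fa,
      etl = as.numeric(etl), nex = as.numeric(nex),
      matrixSize = as.integer(matrixSize), fov = as.numeric(fov),
      sliceThickness = sliceThickness, nX = as.integer(matrixSize[1L]),
      dwell = dwell, charCount = as.integer(charCount), echoGap = echoGap,
      elliptic = elliptic, rxNoiseSigma = rxNoiseSigma, diffusion = diffusion)
}

#' @rdname protocolConfig
#' @param ... overrides passed to [protocolConfig()].
#' @export
protocolT1wGre <- function(matrixSize = c(128L, 128L, 32L), nex = 2L,
                           elliptic = TRUE, ...) {
  protocolConfig("GRE3D", tr = 52, te = 13, fa = 40, etl = 1L, nex = nex,
                 matrixSize = matrixSize, elliptic = elliptic, ...)
}

#' @rdname protocolConfig
#' @export
protocolT2wFse <- function(matrixSize = c(128L, 126L, 32L), etl = 21L,
                           nex = 2L, elliptic = TRUE, ...) {
  protocolConfig("FSE3D", tr = 1500, te = 202, fa = 90, etl = etl, nex = nex,
                 matrixSize = matrixSize, elliptic = elliptic, ...)
}

#' @rdname protocolConfig
#' @export
protocolFlairFse <- function(matrixSize = c(128L, 117L, 32L), etl = 13L,
                             nex = 4L, elliptic = TRUE, ...) {
  protocolConfig("FLAIR_LIKE_FSE3D", tr = 500, te = 129, fa = 90, etl = etl,
                 nex = nex, matrixSize = matrixSize, elliptic = elliptic, ...)
}

#' @rdname protocolConfig
#' @param b,bigDelta,smallDelta diffusion weighting (s/mm^2) and gradient
#'   separation/duration (ms).
#' @export
protocolDwiEpi <- function(matrixSize = c(64L, 64L, 1L), nex = 52L,
                           b = 500, bigDelta = 49, smallDelta = 30, ...) {
  dirs <- diag(3)
  protocolConfig("EPI_DWI_2D", tr = 2800, te = 102, fa = 90,
                 etl = as.integer(matrixSize[2L]), nex = nex,
                 matrixSize = matrixSize, fov = c(250, 250, 10),
                 diffusion = list(b = b, bigDelta = bigDelta,
                                  smallDelta = smallDelta, directions = dirs),
                 ...)
}

#' Elliptic 2D phase-encode mask
#'
#' Includes the centred integer offsets `(k1, k2)` with
#' `(k1/a)^2 + (k2/b)^2 <= 1`, `a = floor(n1/2)`, `b = floor(n2/2)` (a
#' singleton axis contributes nothing); DC is always included. Keeps about
#' pi/4 of a full grid.
#'
#' @param nPe1,nPe2 phase-encode matrix sizes.
#' @return logical `nPe1 x nPe2` matrix.
#' @examples
#' sum(ellipticMask(9, 9))    # 49 lattice points inside the radius-4 circle
#' @export
ellipticMask <- function(nPe1, nPe2) {
  stopifnot(nPe1 >= 1L, nPe2 >= 1L)
  a <- max(floor(nPe1 / 2), 0.5)
  b <- max(floor(nPe2 / 2), 0.5)
  k1 <- kOffsets(nPe1)
  k2 <- kOffsets(nPe2)
  m <- outer((k1 / a)^2, (k2 / b)^2, `+`) <= 1
  m[floor(nPe1 / 2) + 1L, floor(nPe2 / 2) + 1L] <- TRUE
  m
}

## center-out ordering of the masked phase-encode set: sort by elliptic
## radius (ties broken by index) so the first echo of each shot carries
## k-space center and the stated TE applies there
.orderedPeList <- function(protocol) {
  n1 <- protocol@matrixSize[2L]; n2 <- protocol@matrixSize[3L]
  mask <- if (protocol@elliptic) ellipticMask(n1, n2) else
    matrix(TRUE, n1, n2)
  idx <- which(mask, arr.ind = TRUE)
  a <- max(floor(n1 / 2), 0.5); b <- max(floor(n2 / 2), 0.5)
  r2 <- ((idx[, 1L] - 1L - floor(n1 / 2)) / a)^2 +
        ((idx[, 2L] - 1L - floor(n2 / 2)) / b)^2
  ord <- order(r2, idx[, 1L], idx[, 2L])
  list(pe = idx[ord, , drop = FALSE], mask = mask)
}

## window layout within one TR. Acquisition (echo) windows start at TE;
## characterization windows bracket them: the first half sits at the very
## start of the TR (pre-excitation, so transverse signal is zero) and the
## second half at end-of-TR (transverse signal fully decayed). Sampling EMI
## on both sides of the acquisition keeps the training windows close in
## time — hence, for nonstationary sources, close in spectral content — to
## the windows being cancelled. All durations in seconds.
.windowLayout <- function(protocol) {
  win <- protocol@nX * protocol@dwell + protocol@echoGap
  nEarly <- ceiling(protocol@charCount / 2)
  list(win = win,
       acqStart = function(t0, e) t0 + protocol@te / 1000 + (e - 1) * win,
       charStart = function(t0, m)
         if (m <= nEarly) t0 + (m - 1) * win
         else t0 + protocol@tr / 1000 - (protocol@charCount - m + 1) * win)
}

#' Simulate a dual-window scan
#'
#' Produces the raw [AcquisitionRecord-class] for GRE/FSE protocols: every
#' FE line is the matching row of the unitary centred DFT of the contrast-
#' weighted phantom, plus receiver thermal noise and coupled EMI; the ten
#' sensing coils see coupled EMI plus sensor noise and never any MRI signal;
#' characterization windows at end-of-TR contain EMI and noise only. When
#' `shieldedTwin = TRUE` the returned record carries a twin with the same
#' MRI signal and receiver-noise realizations and EMI forced to zero.
#'
#' @param phantom a [Phantom-class].
#' @param protocol a [ProtocolConfig-class] (GRE3D / FSE3D /
#'   FLAIR_LIKE_FSE3D).
#' @param emiWorld an [EMIWorld-class], or `NULL` for a shielded scan.
#' @param seed run seed; fans out to per-stage streams.
#' @param shieldedTwin attach the EMI-free twin.
#' @return an [AcquisitionRecord-class]. `meta` holds seeds, scan-time
#'   accounting and the ground-truth coupled-EMI replay (`emiRxAcq`,
#'   `emiRxChar`) for suppression metrics.
#' @export
simulateScan <- function(phantom, protocol, emiWorld = NULL, seed = 1L,
                         shieldedTwin = TRUE) {
  stopifnot(is(phantom, "Phantom"), is(protocol, "ProtocolConfig"))
  if (protocol@kind == "EPI_DWI_2D")
    stop("use simulateEpiDwi() for EPI protocols")
  if (!identical(dim(phantom@labels), as.integer(protocol@matrixSize)))
    stop("protocol matrix must match the phantom grid")

  w <- protocolSignalMap(phantom, protocol)
  ksp <- fftc(array(as.complex(w), dim = dim(w)))

  peo <- .orderedPeList(protocol)
  nMasked <- nrow(peo$pe)
  shots <- ceiling(nMasked / protocol@etl)
  trS <- protocol@tr / 1000
  nex <- as.integer(protocol@nex)
  lay <- .windowLayout(protocol)
  scanDur <- shots * nex * trS

  ## bookkeeping: one row per acquired FE line, NEX repeats separate
  rows <- list(); ri <- 0L
  for (r in seq_len(nex)) for (s in seq_len(shots)) {
    g <- (r - 1L) * shots + (s - 1L)
    for (e in seq_len(protocol@etl)) {
      li <- (e - 1L) * shots + s
      if (li > nMasked) next
      ri <- ri + 1L
      rows[[ri]] <- c(peo$pe[li, 1L], peo$pe[li, 2L], s, e, r,
                      lay$acqStart(g * trS, e))
    }
  }
  lines <- as.data.frame(do.call(rbind, rows))
  names(lines) <- c("pe1", "pe2", "shot", "echo", "nex", "t0")

  nL <- nrow(lines); nX <- protocol@nX
  nCW <- shots * nex * protocol@charCount
  charTimes <- as.vector(vapply(seq_len(shots * nex) - 1L, function(g)
    vapply(seq_len(protocol@charCount), function(m)
      lay$charStart(g * trS, m), 0), numeric(protocol@charCount)))

  world <- emiWorld %||% emiWorld0()
  emiOn <- length(world@sources) > 0L

  mri <- matrix(0+0i, nL, nX)
  for (i in seq_len(nL))
    mri[i, ] <- ksp[, lines$pe1[i], lines$pe2[i]]

  set.seed(stageSeed(seed, "acquisition"))
  noiseAcq <- matrix(crnorm(nL * nX, protocol@rxNoiseSigma), nL, nX)
  noiseChar <- matrix(crnorm(nCW * nX, protocol@rxNoiseSigma), nCW, nX)

  emiSeed <- stageSeed(seed, "emi")
  sampleWin <- function(t0) coupleWindow(world, t0, nX, emiSeed, scanDur)

  emiRxAcq <- matrix(0+0i, nL, nX)
  sensAcqE <- array(0+0i, c(nL, nX, 10L)); sensAcqN <- sensAcqE
  for (i in seq_len(nL)) {
    cw <- sampleWin(lines$t0[i])
    emiRxAcq[i, ] <- cw$rx
    sensAcqE[i, , ] <- cw$sensEmi
    sensAcqN[i, , ] <- cw$sensNoise
  }
  emiRxChar <- matrix(0+0i, nCW, nX)
  sensCharE <- array(0+0i, c(nCW, nX, 10L)); sensCharN <- sensCharE
  for (i in seq_len(nCW)) {
    cw <- sampleWin(charTimes[i])
    emiRxChar[i, ] <- cw$rx
    sensCharE[i, , ] <- cw$sensEmi
    sensCharN[i, , ] <- cw$sensNoise
  }
  if (!emiOn) { emiRxAcq[] <- 0+0i; emiRxChar[] <- 0+0i }

  meta <- list(seed = seed, emiWorldHash = contentHash(world),
               emiOn = emiOn, scanTimeS = scanDur,
               charOverheadS = protocol@charCount * lay$win * shots * nex,
               shots = shots, sampleRate = world@sampleRate,
               emiRxAcq = emiRxAcq, emiRxChar = emiRxChar,
               emiBands = emiBands(world))

  rec <- new("AcquisitionRecord", protocol = protocol, lines = lines,
             rxAcq = mri + noiseAcq + emiRxAcq,
             rxChar = noiseChar + emiRxChar,
             sensAcq = sensAcqE + sensAcqN, sensChar = sensCharE + sensCharN,
             charTimes = charTimes, shieldedTwin = NULL, meta = meta)

  if (shieldedTwin) {
    mt <- meta
    mt$emiOn <- FALSE
    mt$emiRxAcq <- matrix(0+0i, nL, nX); mt$emiRxChar <- matrix(0+0i, nCW, nX)
    rec@shieldedTwin <- new("AcquisitionRecord", protocol = protocol,
                            lines = lines, rxAcq = mri + noiseAcq,
                            rxChar = noiseChar, sensAcq = sensAcqN,
                            sensChar = sensCharN, charTimes = charTimes,
                            shieldedTwin = NULL, meta = mt)
  }
  rec
}

## empty EMI world (shielded scans)
emiWorld0 <- function(sampleRate = 5e4)
  emiWorld(list(), couplingModel(list(), list(), sensorNoiseSigma = 0),
           sampleRate)

#' Simulate a 2D spin-echo EPI diffusion scan
#'
#' Single-shot EPI with alternating-polarity readout lines: a configurable
#' odd/even timing mismatch injects a constant-plus-linear phase on the
#' reversed (even) lines — the Nyquist-ghost mechanism — and per-voxel
#' off-resonance from the phantom's field map accumulates phase along the
#' echo train — the geometric-distortion mechanism. Also emits a 3-line
#' non-phase-encoded reference scan (polarity +,-,+) for ghost calibration.
#' One record is returned per diffusion condition (b0, then one b1 per
#' direction).
#'
#' @inheritParams simulateScan
#' @param protocol a `ProtocolConfig` of kind `EPI_DWI_2D`.
#' @param ghostPhase length-2 `(constant, slope)` odd/even phase error in
#'   radians; the slope is per centred readout k-sample.
#' @param distortion simulate field-map phase accrual (requires
#'   `fieldMap(phantom)`).
#' @param adcOverride optional per-direction ADC arrays (anisotropy tests).
#' @return named list of [AcquisitionRecord-class] (`b0`, `b1x`, `b1y`,
#'   `b1z`), each with `meta$reference = list(rx, polarity)` and
#'   `meta$epi = list(ghostPhase, esp, bwPerPixel)`.
#' @export
simulateEpiDwi <- function(phantom, protocol, emiWorld = NULL, seed = 1L,
                           ghostPhase = c(0, 0), distortion = FALSE,
                           shieldedTwin = FALSE, adcOverride = NULL) {
  stopifnot(protocol@kind == "EPI_DWI_2D")
  if (distortion && is.null(phantom@fieldMap))
    stop("distortion simulation requires a phantom field map")
  d <- dim(phantom@labels)
  if (!identical(d[1:2], as.integer(protocol@matrixSize[1:2])))
    stop("protocol matrix must match the phantom slice")

  nFe <- protocol@nX; nPe <- protocol@matrixSize[2L]
  esp <- nFe * protocol@dwell + protocol@echoGap
  bwPerPixel <- 1 / (esp * nPe)   # phase-encode bandwidth per pixel, Hz
  fmap <- if (distortion) phantom@fieldMap[, , 1L] else matrix(0, nFe, nPe)
  trS <- protocol@tr / 1000
  nex <- as.integer(protocol@nex)
  world <- emiWorld %||% emiWorld0()
  emiOn <- length(world@sources) > 0L
  emiSeed <- stageSeed(seed, "emi")
  conds <- list(b0 = 0L, b1x = 1L, b1y = 2L, b1z = 3L)
  scanDur <- length(conds) * nex * trS
  lay <- .windowLayout(protocol)

  ## per-line phase-encode times relative to the echo (k-center) instant
  tLine <- (seq_len(nPe) - 1L - floor(nPe / 2)) * esp
  reversed <- (seq_len(nPe) %% 2L) == 0L
  ## odd/even readout timing mismatch: a constant + linear phase in the
  ## hybrid (readout-space) domain on reversed lines
  ghostRamp <- exp(1i * (ghostPhase[1L] + ghostPhase[2L] * kOffsets(nFe)))
  applyGhost <- function(kline) fftc(ifftc(kline) * ghostRamp)

  kLinesFor <- function(w) {
    ## row m of the 2D DFT of the off-resonance-modulated image
    out <- matrix(0+0i, nPe, nFe)
    for (m in seq_len(nPe)) {
      img <- w[, , 1L] * exp(2i * pi * fmap * tLine[m])
      out[m, ] <- fftc(img)[, m]
    }
    for (m in which(reversed)) out[m, ] <- applyGhost(out[m, ])
    out
  }

  set.seed(stageSeed(seed, "acquisition"))
  recs <- list()
  gGlobal <- 0L
  for (cn in names(conds)) {
    w <- protocolSignalMap(phantom, protocol, direction = conds[[cn]],
                           adcOverride = adcOverride)
    kl <- kLinesFor(w)
    dcPe <- floor(nPe / 2) + 1L
    dcLine <- fftc(w[, , 1L])[, dcPe]   # no off-resonance accrual at t = 0
    ## reference polarity +,-,+ : line 2 is acquired reversed so it carries
    ## the injected odd/even phase once
    refMri <- rbind(dcLine, applyGhost(dcLine), dcLine)

    nL <- nex * nPe
    lines <- data.frame(pe1 = rep(seq_len(nPe), nex), pe2 = 1L,
                        shot = rep(seq_len(nex), each = nPe),
                        echo = rep(seq_len(nPe), nex),
                        nex = rep(seq_len(nex), each = nPe),
                        t0 = NA_real_)
    mri <- matrix(0+0i, nL, nFe)
    for (r in seq_len(nex)) {
      t0 <- (gGlobal + r - 1L) * trS
      rowsIdx <- (r - 1L) * nPe + seq_len(nPe)
      mri[rowsIdx, ] <- kl
      lines$t0[rowsIdx] <- t0 + protocol@te / 1000 + (seq_len(nPe) - 1L) * esp
    }
    noise <- matrix(crnorm(nL * nFe, protocol@rxNoiseSigma), nL, nFe)
    refNoise <- matrix(crnorm(3L * nFe, protocol@rxNoiseSigma), 3L, nFe)

    nCW <- nex * protocol@charCount
    charTimes <- as.vector(vapply(seq_len(nex) - 1L, function(g)
      vapply(seq_len(protocol@charCount), function(m)
        lay$charStart((gGlobal + g) * trS, m), 0),
      numeric(protocol@charCount)))
    noiseChar <- matrix(crnorm(nCW * nFe, protocol@rxNoiseSigma), nCW, nFe)

    emiRxAcq <- matrix(0+0i, nL, nFe)
    sensAE <- array(0+0i, c(nL, nFe, 10L)); sensAN <- sensAE
    for (i in seq_len(nL)) {
      cw <- coupleWindow(world, lines$t0[i], nFe, emiSeed, scanDur)
      emiRxAcq[i, ] <- cw$rx
      sensAE[i, , ] <- cw$sensEmi; sensAN[i, , ] <- cw$sensNoise
    }
    emiRxChar <- matrix(0+0i, nCW, nFe)
    sensCE <- array(0+0i, c(nCW, nFe, 10L)); sensCN <- sensCE
    for (i in seq_len(nCW)) {
      cw <- coupleWindow(world, charTimes[i], nFe, emiSeed, scanDur)
      emiRxChar[i, ] <- cw$rx
      sensCE[i, , ] <- cw$sensEmi; sensCN[i, , ] <- cw$sensNoise
    }
    if (!emiOn) { emiRxAcq[] <- 0+0i; emiRxChar[] <- 0+0i }

    meta <- list(seed = seed, emiOn = emiOn, condition = cn,
                 emiWorldHash = contentHash(world),
                 scanTimeS = nex * trS, sampleRate = world@sampleRate,
                 emiRxAcq = emiRxAcq, emiRxChar = emiRxChar,
                 emiBands = emiBands(world),
                 reference = list(rx = refMri + refNoise,
                                  polarity = c(1L, -1L, 1L)),
                 epi = list(ghostPhase = ghostPhase, esp = esp,
                            bwPerPixel = bwPerPixel, reversed = reversed,
                            distortion = distortion))
    rec <- new("AcquisitionRecord", protocol = protocol, lines = lines,
               rxAcq = mri + noise + emiRxAcq, rxChar = noiseChar + emiRxChar,
               sensAcq = sensAE + sensAN, sensChar = sensCE + sensCN,
               charTimes = charTimes, shieldedTwin = NULL, meta = meta)
    if (shieldedTwin) {
      mt <- meta; mt$emiOn <- FALSE
      mt$emiRxAcq[] <- 0+0i; mt$emiRxChar[] <- 0+0i
      rec@shieldedTwin <- new("AcquisitionRecord", protocol = protocol,
                              lines = lines, rxAcq = mri + noise,
                              rxChar = noiseChar, sensAcq = sensAN,
                              sensChar = sensCN, charTimes = charTimes,
                              shieldedTwin = NULL, meta = mt)
    }
    recs[[cn]] <- rec
    gGlobal <- gGlobal + nex
  }
  recs
}

#' @describeIn simulateScan number of acquired FE lines (all repeats).
#' @param record an `AcquisitionRecord`.
#' @export
nLines <- function(record) nrow(record@lines)

#' @describeIn simulateScan number of EMI characterization windows.
#' @export
nCharWindows <- function(record) nrow(record@rxChar)

#' @describeIn simulateScan the EMI-free twin (or `NULL`).
#' @export
shieldedTwin <- function(record) record@shieldedTwin

#' @describeIn simulateScan receive-coil acquisition-window lines
#'   (complex matrix, lines x nX).
#' @export
rxAcquisition <- function(record) record@rxAcq

#' @describeIn simulateScan receive-coil characterization windows.
#' @export
rxCharacterization <- function(record) record@rxChar

setMethod("show", "AcquisitionRecord", function(object) {
  p <- object@protocol
  cat(sprintf("AcquisitionRecord: %s, matrix %s, ETL %g, NEX %g\n",
              p@kind, paste(p@matrixSize, collapse = "x"), p@etl, p@nex))
  cat(sprintf("  %d FE lines, %d characterization windows of %d samples\n",
              nrow(object@lines), nrow(object@rxChar), p@nX))
  cat(sprintf("  scan time %.1f s (char-window overhead %.2f s), EMI %s, twin %s\n",
              object@meta$scanTimeS, object@meta$charOverheadS %||% 0,
              if (isTRUE(object@meta$emiOn)) "on" else "off",
              if (is.null(object@shieldedTwin)) "absent" else "attached"))
})

#' Save / load an acquisition record
#'
#' Records are plain serialized R objects (`.rds`).
#'
#' @param record an [AcquisitionRecord-class].
#' @param path file path.
#' @export
saveRecord <- function(record, path) {
  saveRDS(record, path)
  invisible(path)
}

#' @rdname saveRecord
#' @export
loadRecord <- function(path) readRDS(path)
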