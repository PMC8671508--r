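## Cartesian Fourier reconstruction: NEX averaging onto the k-space grid,
## zero-pad display interpolation, EPI Nyquist-ghost and geometric-
## distortion correction, and the diffusion (ADC) pipeline. All steps are
## deterministic.

#' Average NEX repeats onto the k-space grid
#'
#' Places the complex mean across repeats of every sampled phase-encode at
#' its k-space coordinate. For EPI records the odd/even line-reversal
#' bookkeeping has already been applied at simulation time, so lines are
#' grid-ready.
#'
#' @param record an [AcquisitionRecord-class] (cancelled or not).
#' @return a [KSpaceVolume-class].
#' @export
averageNex <- function(record) {
  p <- record@protocol
  d <- as.integer(p@matrixSize)
  ks <- array(0+0i, d)
  cnt <- array(0L, d[2:3])
  key <- paste(record@lines$pe1, record@lines$pe2)
  for (k in unique(key)) {
    rows <- which(key == k)
    i1 <- record@lines$pe1[rows[1L]]; i2 <- record@lines$pe2[rows[1L]]
    nGot <- length(rows)
    if (nGot != p@nex)
      stop(sprintf("missing NEX repeat at phase encode (%d, %d): have %d of %g",
                   i1, i2, nGot, p@nex))
    ks[, i1, i2] <- .colMeansComplex(record@rxAcq[rows, , drop = FALSE])
    cnt[i1, i2] <- nGot
  }
  mask <- cnt > 0L
  new("KSpaceVolume", data = ks, mask = mask,
      voxelSize = c(p@fov[1L] / d[1L], p@fov[2L] / d[2L],
                    if (d[3L] > 1L) p@fov[3L] / d[3L] else p@sliceThickness),
      nex = p@nex)
}

.colMeansComplex <- function(m) {
  complex(real = colMeans(Re(m)), imaginary = colMeans(Im(m)))
}

#' Cartesian FT reconstruction with zero-pad display interpolation
#'
#' Embeds the k-space volume centred in a grid enlarged by integer pad
#' factors (DC stays at 0-based index floor(N/2)), inverse-FFTs with the
#' unitary centred convention, and takes the magnitude. Amplitudes are
#' rescaled by `sqrt(prod(pad))` so image values at the original voxel
#' centres are preserved; display voxel size is acquisition size divided by
#' the pad factor, e.g. 2 x 2 x 10 mm with pad (2,2,2) displays at
#' 1 x 1 x 5 mm.
#'
#' @param kvol a [KSpaceVolume-class].
#' @param padFactors integer length-3 zero-pad factors (>= 1).
#' @return an [ImageVolume-class].
#' @export
reconCartesian <- function(kvol, padFactors = c(1L, 1L, 1L)) {
  padFactors <- as.integer(padFactors)
  stopifnot(length(padFactors) == 3L, all(padFactors >= 1L))
  d <- dim(kvol@data)
  dPad <- d * padFactors
  big <- array(0+0i, dPad)
  off <- floor(dPad / 2) - floor(d / 2)   # keeps DC at floor(N/2)
  big[off[1L] + seq_len(d[1L]), off[2L] + seq_len(d[2L]),
      off[3L] + seq_len(d[3L])] <- kvol@data
  img <- ifftc(big) * sqrt(prod(padFactors))
  new("ImageVolume", data = Mod(img),
      voxelSize = kvol@voxelSize / padFactors,
      meta = list(padFactors = padFactors, nex = kvol@nex))
}

#' @describeIn reconCartesian image array accessor.
#' @param image an `ImageVolume`.
#' @export
imageData <- function(image) image@data

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d x %d, display voxel %.3g x %.3g x %.3g mm\n",
              d[1L], d[2L], d[3L], object@voxelSize[1L], object@voxelSize[2L],
              object@voxelSize[3L]))
})

setMethod("show", "KSpaceVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("KSpaceVolume: %d x %d x %d, %d/%d phase encodes sampled, NEX %g\n",
              d[1L], d[2L], d[3L], sum(object@mask), prod(d[2:3]), object@nex))
})

#' Write a reconstructed image as NIfTI
#'
#' @param image an [ImageVolume-class].
#' @param path output path.
#' @export
writeImageNifti <- function(image, path) {
  img <- RNifti::asNifti(image@data, pixdim = image@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' EPI Nyquist-ghost correction from a 3-line reference scan
#'
#' Estimates the constant-plus-linear phase mismatch between odd and even
#' (reversed) readout lines in the hybrid readout-space domain — a
#' magnitude-weighted least-squares fit of the phase difference between the
#' reference scan's reversed line and the mean of its two non-reversed
#' neighbours — and removes it from every reversed line of the EPI k-space.
#'
#' @param record an EPI [AcquisitionRecord-class] (its `meta$reference`
#'   holds the non-phase-encoded reference scan).
#' @return the record with corrected `rxAcq` lines; the estimated
#'   `(constant, slope)` is stored in `meta$epi$ghostFit`.
#' @export
epiGhostCorrect <- function(record) {
  ref <- record@meta$reference
  if (is.null(ref)) stop("reference scan missing from record metadata")
  p <- record@protocol
  nFe <- p@nX
  ## hybrid space: inverse FFT along the readout axis
  hyb <- t(apply(ref$rx, 1L, ifftc))
  odd <- 0.5 * (hyb[1L, ] + hyb[3L, ])
  evn <- hyb[2L, ]
  ratio <- evn * Conj(odd)
  wgt <- Mod(ratio)
  phi <- Arg(ratio)
  ## unwrap before the weighted linear fit
  phi <- .unwrapPhase(phi)
  x <- seq_len(nFe) - 1L - floor(nFe / 2)   # image-space position index
  fit <- stats::lm.wfit(cbind(1, x), phi, w = wgt)
  ab <- fit$coefficients
  corr <- exp(-1i * (ab[1L] + ab[2L] * x))
  rev <- record@meta$epi$reversed[record@lines$pe1]
  if (any(rev)) {
    hybData <- t(apply(record@rxAcq[rev, , drop = FALSE], 1L, ifftc))
    hybData <- sweep(hybData, 2L, corr, `*`)
    record@rxAcq[rev, ] <- t(apply(hybData, 1L, fftc))
  }
  ## keep the reference scan consistent (correction is then idempotent:
  ## re-estimating on a corrected record gives ~0)
  record@meta$reference$rx[2L, ] <- fftc(ifftc(ref$rx[2L, ]) * corr)
  record@meta$epi$ghostFit <- unname(ab)
  record
}

.unwrapPhase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Geometric distortion correction from a known field map
#'
#' Shifts each voxel along the phase-encode axis by
#' `-offResonance / bandwidthPerPixel` pixels with linear interpolation.
#' Uses the simulator's true field map (self-consistent test world);
#' field-map estimation from data is out of scope.
#'
#' @param image an [ImageVolume-class] (EPI magnitude image).
#' @param fieldMapHz off-resonance map (Hz) on the image grid.
#' @param bwPerPixel phase-encode bandwidth per pixel, Hz (from
#'   `meta$epi$bwPerPixel`, scaled by any display zero-padding).
#' @return corrected [ImageVolume-class].
#' @export
distortionCorrect <- function(image, fieldMapHz, bwPerPixel) {
  img <- image@data
  d <- dim(img)
  out <- img
  ## off-resonance f displaces a voxel by -f/bw pixels along PE; resample
  ## the distorted image at the displaced position to undo it
  shift <- fieldMapHz / bwPerPixel
  for (k in seq_len(d[3L])) for (i in seq_len(d[1L])) {
    src <- seq_len(d[2L]) - shift[i, , k]
    out[i, , k] <- stats::approx(seq_len(d[2L]), img[i, , k], xout = src,
                                 rule = 2)$y
  }
  new("ImageVolume", data = out, voxelSize = image@voxelSize,
      meta = c(image@meta, list(distortionCorrected = TRUE)))
}

#' Isotropic DWI combination and ADC mapping
#'
#' Combines the three orthogonal-direction b1 magnitude images by geometric
#' mean (so the combined ADC is the arithmetic mean of per-direction ADCs)
#' and computes the ADC map from the b0/isotropic-b1 pair. Voxels outside
#' the tissue mask, or noise-dominated ones, are set to `NA`.
#'
#' @param b0 an [ImageVolume-class] (b = 0).
#' @param b1x,b1y,b1z per-direction b1 images.
#' @param b diffusion weighting of the b1 images, s/mm^2.
#' @param mask logical array; default keeps voxels where b0 exceeds 5% of
#'   its maximum.
#' @return list with `iso` ([ImageVolume-class]) and `adc` (array, mm^2/s,
#'   `NA` outside the mask).
#' @export
adcPipeline <- function(b0, b1x, b1y, b1z, b, mask = NULL) {
  s0 <- b0@data
  if (is.null(mask)) mask <- s0 > 0.05 * max(s0)
  iso <- array(0, dim(s0))
  ok <- mask & b1x@data > 0 & b1y@data > 0 & b1z@data > 0 & s0 > 0
  iso[ok] <- isotropicCombine(b1x@data[ok], b1y@data[ok], b1z@data[ok])
  adc <- array(NA_real_, dim(s0))
  adc[ok] <- adcFromPair(s0[ok], iso[ok], b1 = b)
  list(iso = new("ImageVolume", data = iso, voxelSize = b0@voxelSize,
                 meta = c(b0@meta, list(combined = "geometric mean"))),
       adc = adc)
}
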