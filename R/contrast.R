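## Closed-form steady-state signal models for the four 0.055 T protocols,
## plus Stejskal-Tanner diffusion math. All are pure functions of tissue and
## protocol parameters; T2* is taken equal to T2 (the <250 ppm field
## homogeneity at 0.055 T makes intravoxel dephasing negligible at these
## voxel sizes).

#' Spoiled GRE steady-state (Ernst) signal
#'
#' `pd * sin(fa) * (1 - E1) / (1 - E1*cos(fa)) * exp(-te/t2)` with
#' `E1 = exp(-tr/t1)`. Used for the T1-weighted protocol
#' (TR/TE = 52/13 ms, FA = 40 degrees).
#'
#' @param pd proton density (relative).
#' @param t1,t2 relaxation times, ms.
#' @param tr,te repetition and echo time, ms.
#' @param fa flip angle, degrees.
#' @return signal amplitude (relative units). Vectorized over tissues.
#' @examples
#' greSignal(1, 330, 110, 52, 13, 40)
#' @export
greSignal <- function(pd, t1, t2, tr, te, fa) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("relaxation times must be positive")
  stopifnot(tr > 0, te > 0, fa >= 0, fa <= 180)
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  pd * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te / t2)
}

#' FSE saturation-recovery signal at the effective TE
#'
#' `pd * (1 - exp(-tr/t1)) * exp(-te/t2)`. With TR/TE = 1500/202 ms this is
#' the T2-weighted contrast; with TR/TE = 500/129 ms the short TR saturates
#' the long-T1 CSF, giving the FLAIR-like CSF-suppressed contrast without an
#' inversion pulse.
#'
#' @inheritParams greSignal
#' @return signal amplitude (relative units). Vectorized over tissues.
#' @examples
#' fseSignal(1, 4000, 2000, 500, 129)   # CSF, FLAIR-like: suppressed
#' fseSignal(0.9, 330, 110, 500, 129)   # GM: retained
#' @export
fseSignal <- function(pd, t1, t2, tr, te) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("relaxation times must be positive")
  stopifnot(tr > 0, te > 0)
  pd * (1 - exp(-tr / t1)) * exp(-te / t2)
}

#' Stejskal-Tanner b-value and the gradient amplitude it requires
#'
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)`, returned in s/mm^2.
#' `gradientForB()` inverts the relation for the gradient amplitude, the
#' feasibility check against a scanner's maximum gradient (15 mT/m here).
#'
#' @param gAmp gradient amplitude in T/m.
#' @param smallDelta gradient duration (delta) in s.
#' @param bigDelta gradient separation (Delta) in s.
#' @param gamma proton gyromagnetic ratio, rad s^-1 T^-1.
#' @return `stejskalTannerB`: b in s/mm^2; `gradientForB`: gradient in T/m.
#' @examples
#' gradientForB(500, 30e-3, 49e-3) * 1000  # mT/m for the DWI protocol
#' @export
stejskalTannerB <- function(gAmp, smallDelta, bigDelta, gamma = 2.675e8) {
  if (bigDelta <= smallDelta / 3) stop("need bigDelta > smallDelta/3")
  stopifnot(all(gAmp >= 0), smallDelta > 0)
  ## gamma^2 G^2 delta^2 (Delta - delta/3) is in s/m^2; 1 s/m^2 = 1e-6 s/mm^2
  gamma^2 * gAmp^2 * smallDelta^2 * (bigDelta - smallDelta / 3) * 1e-6
}

#' @rdname stejskalTannerB
#' @param b target diffusion weighting, s/mm^2.
#' @export
gradientForB <- function(b, smallDelta, bigDelta, gamma = 2.675e8) {
  if (bigDelta <= smallDelta / 3) stop("need bigDelta > smallDelta/3")
  stopifnot(b >= 0)
  sqrt(b * 1e6 / (gamma^2 * smallDelta^2 * (bigDelta - smallDelta / 3)))
}

#' Monoexponential diffusion attenuation and its inverse
#'
#' `dwiSignal` applies `s0 * exp(-b * adc)`; `adcFromPair` recovers the ADC
#' from a b0/b1 magnitude pair as `log(s_b0/s_b1) / (b1 - b0)`;
#' `isotropicCombine` merges three orthogonal-direction b1 images by
#' geometric mean, so the ADC of the combined image is the arithmetic mean
#' (trace/3) of the per-direction ADCs.
#'
#' @param s0 unweighted signal (must be > 0).
#' @param adc apparent diffusion coefficient, mm^2/s.
#' @param b diffusion weighting, s/mm^2.
#' @return attenuated signal / ADC map / combined signal. All vectorized.
#' @examples
#' s1 <- dwiSignal(1, 1e-3, 500)
#' adcFromPair(1, s1, 500)
#' @export
dwiSignal <- function(s0, adc, b) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  stopifnot(all(adc >= 0), all(b >= 0))
  s0 * exp(-b * adc)
}

#' @rdname dwiSignal
#' @param sB0,sB1 magnitudes at b0 and b1 (must be > 0; callers floor
#'   noise-dominated voxels first).
#' @param b1,b0 the two b-values, `b1 > b0 >= 0`.
#' @export
adcFromPair <- function(sB0, sB1, b1, b0 = 0) {
  if (any(sB0 <= 0) || any(sB1 <= 0))
    stop("magnitudes must be positive (floor noise-dominated voxels)")
  stopifnot(b1 > b0, b0 >= 0)
  log(sB0 / sB1) / (b1 - b0)
}

#' @rdname dwiSignal
#' @param sX,sY,sZ positive per-direction b1 magnitudes.
#' @export
isotropicCombine <- function(sX, sY, sZ) {
  if (any(sX <= 0) || any(sY <= 0) || any(sZ <= 0))
    stop("combine inputs must be positive")
  (sX * sY * sZ)^(1 / 3)
}

#' Per-voxel signal weight map for a protocol
#'
#' Maps every phantom voxel through the protocol's closed-form signal model
#' (including diffusion attenuation for DWI along a given direction).
#'
#' @param phantom a [Phantom-class].
#' @param protocol a [ProtocolConfig-class].
#' @param direction for `EPI_DWI_2D`: 0 for the b0 image or 1..3 for the b1
#'   diffusion directions (isotropic ADC model makes them equivalent unless
#'   per-direction ADCs are supplied via `adcOverride`).
#' @param adcOverride optional list of per-direction ADC arrays (mm^2/s)
#'   replacing the phantom's isotropic ADC, for anisotropy experiments.
#' @return numeric array of signal amplitudes, phantom-shaped.
#' @export
protocolSignalMap <- function(phantom, protocol, direction = 0L,
                              adcOverride = NULL) {
  tt <- phantom@tissues
  idx <- as.integer(phantom@labels) + 1L
  base <- switch(protocol@kind,
    GRE3D = greSignal(tt$pd, tt$t1, tt$t2, protocol@tr, protocol@te, protocol@fa),
    FSE3D = ,
    FLAIR_LIKE_FSE3D = fseSignal(tt$pd, tt$t1, tt$t2, protocol@tr, protocol@te),
    EPI_DWI_2D = fseSignal(tt$pd, tt$t1, tt$t2, protocol@tr, protocol@te))
  w <- array(base[idx], dim = dim(phantom@labels))
  if (protocol@kind == "EPI_DWI_2D" && direction > 0L) {
    b <- protocol@diffusion$b
    adc <- if (!is.null(adcOverride)) adcOverride[[direction]]
           else tissueParameterMap(phantom, "adc")
    pos <- w > 0
    w[pos] <- w[pos] * exp(-b * adc[pos])
  }
  w
}
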