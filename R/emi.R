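## EMI source waveforms (complex baseband at the 2.32 MHz carrier) and their
## linear coupling into the receive coil and the ten sensing coils. All
## frequencies are Hz offsets within the receive bandwidth (default sampling
## rate 50 kHz). Every waveform is reproducible from (seed, window start).

#' Construct an EMI source
#'
#' @param kind `"broadband"`, `"swept"`, `"tone"` or `"powerline_harmonics"`.
#' @param amplitude source rms amplitude (relative units; the receive-coil
#'   EMI std for a unit-norm coupling filter).
#' @param band length-2 Hz band for broadband sources, or the harmonic range
#'   kept for powerline sources.
#' @param freq tone offset in Hz.
#' @param sweep length-2 start/end Hz offset of a linear sweep traversed
#'   over the scan.
#' @param fundamental powerline fundamental, Hz.
#' @param drift `NULL` or list `(rate_hz, depth)` for slow amplitude
#'   modulation.
#' @param seedOffset integer distinguishing this source's RNG stream.
#' @return an [EMISource-class].
#' @export
emiSource <- function(kind, amplitude = 1, band = c(-5e3, 5e3), freq = 1e3,
                      sweep = c(-2e4, 2e4), fundamental = 50, drift = NULL,
                      seedOffset = 1L) {
  new("EMISource", kind = kind, amplitude = amplitude, band = band,
      freq = freq, sweep = sweep, fundamental = fundamental, drift = drift,
      seedOffset = as.integer(seedOffset))
}

#' @rdname emiSource
#' @param rxTaps list of complex FIR vectors (one per source), receive coil.
#' @param sensTaps list of 10 x L complex matrices (one per source).
#' @param sensorNoiseSigma per-sample complex noise std on sensing coils.
#' @export
couplingModel <- function(rxTaps, sensTaps, sensorNoiseSigma = 3e-4,
                          drift = NULL) {
  new("CouplingModel", rxTaps = rxTaps, sensTaps = sensTaps,
      sensorNoiseSigma = sensorNoiseSigma, drift = drift)
}

#' @rdname emiSource
#' @param sources list of `EMISource` objects.
#' @param coupling a [CouplingModel-class].
#' @param sampleRate baseband sampling rate, Hz.
#' @export
emiWorld <- function(sources, coupling, sampleRate = 5e4) {
  new("EMIWorld", sources = sources, coupling = coupling,
      sampleRate = sampleRate)
}

## run expr under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

## deterministic per-source fixed phases without touching the RNG
.hashPhase <- function(k, offset) {
  v <- sin(k * 12.9898 + offset * 78.233) * 43758.5453
  2 * pi * (v - floor(v))
}

#' Generate one segment of an EMI source waveform
#'
#' Deterministic kinds (tone, swept, powerline harmonics) are continuous-
#' phase functions of absolute time, so adjacent segments join smoothly.
#' Broadband sources are seeded band-limited complex white noise, drawn
#' independently per window from a stream keyed by `(seed, source,
#' window-start sample index)`.
#'
#' @param source an [EMISource-class].
#' @param tStart segment start time, s (absolute scan time).
#' @param nSamples samples to generate.
#' @param dwell sample spacing, s.
#' @param scanDuration total scan duration, s (sets the sweep rate).
#' @param seed base seed of the EMI stage.
#' @return complex vector of `nSamples` baseband samples.
#' @export
genSourceSegment <- function(source, tStart, nSamples, dwell,
                             scanDuration = 1, seed = 1L) {
  stopifnot(dwell > 0, nSamples >= 1)
  nyq <- 1 / (2 * dwell)
  t <- tStart + (seq_len(nSamples) - 1L) * dwell
  A <- source@amplitude
  switch(source@kind,
    tone = {
      if (abs(source@freq) > nyq) stop("tone offset outside the Nyquist band")
      A * exp(1i * (2 * pi * source@freq * t + .hashPhase(1, source@seedOffset)))
    },
    swept = {
      if (any(abs(source@sweep) > nyq)) stop("sweep band outside Nyquist")
      f1 <- source@sweep[1L]; f2 <- source@sweep[2L]
      ## linear chirp f(t) = f1 + (f2 - f1) t / T; continuous phase
      ph <- 2 * pi * (f1 * t + (f2 - f1) * t^2 / (2 * scanDuration))
      A * exp(1i * (ph + .hashPhase(1, source@seedOffset)))
    },
    powerline_harmonics = {
      f0 <- source@fundamental
      kmax <- floor(min(max(abs(source@band)), nyq) / f0)
      if (kmax < 1L) stop("no harmonic lies inside the band")
      k <- c(-(kmax:1), 1:kmax)
      amp <- 1 / abs(k)
      amp <- amp / sqrt(sum(amp^2)) * A   # total rms = A
      ph <- .hashPhase(k, source@seedOffset)
      drop(exp(1i * outer(t, k * f0 * 2 * pi)) %*% (amp * exp(1i * ph)))
    },
    broadband = {
      if (any(abs(source@band) > nyq)) stop("band outside the Nyquist interval")
      startIdx <- round(tStart / dwell)
      wseed <- (abs(seed) %% 100003) * 20011 + source@seedOffset * 509 +
        (startIdx %% 99991)
      withSeed(wseed, {
        w <- crnorm(nSamples)
        f <- kOffsets(nSamples) / (nSamples * dwell)
        keep <- f >= source@band[1L] & f <= source@band[2L]
        if (!any(keep)) stop("band too narrow for this window length")
        W <- fftc(w)
        W[!keep] <- 0
        x <- ifftc(W)
        x / sqrt(mean(Mod(x)^2)) * A
      })
    },
    stop("unknown source kind"))
}

## slow amplitude drift factor of a source at times t
.driftGain <- function(drift, t) {
  if (is.null(drift)) return(1)
  1 + drift$depth * sin(2 * pi * drift$rate_hz * t)
}

#' Coupled EMI for one sampling window
#'
#' Generates every source's segment, pushes it through the per-(source,
#' channel) FIR filters, and returns the receive-coil EMI, the sensing-coil
#' EMI, and an independent sensor-noise realization (kept separate so a
#' shielded twin can reuse the identical noise with EMI off). The receive
#' channel carries no sensor noise; its thermal noise is added by the
#' acquisition stage.
#'
#' @param world an [EMIWorld-class] (may have zero sources).
#' @param tStart window start time, s.
#' @param nSamples samples in the window.
#' @param seed base seed of the EMI stage.
#' @param scanDuration total scan duration, s.
#' @return list with `rx` (complex `nSamples`), `sensEmi`
#'   (`nSamples` x 10), `sensNoise` (`nSamples` x 10).
#' @export
coupleWindow <- function(world, tStart, nSamples, seed = 1L,
                         scanDuration = 1) {
  dwell <- 1 / world@sampleRate
  rx <- complex(nSamples)
  sens <- matrix(0+0i, nSamples, 10L)
  cp <- world@coupling
  t <- tStart + (seq_len(nSamples) - 1L) * dwell
  for (si in seq_along(world@sources)) {
    src <- world@sources[[si]]
    seg <- genSourceSegment(src, tStart, nSamples, dwell, scanDuration, seed)
    seg <- seg * .driftGain(src@drift, t)
    if (si > length(cp@rxTaps)) stop("missing coupling filter for source ", si)
    rx <- rx + firApply(cp@rxTaps[[si]], seg) * .driftGain(cp@drift, t)
    st <- cp@sensTaps[[si]]
    for (c in 1:10)
      sens[, c] <- sens[, c] + firApply(st[c, ], seg)
  }
  noise <- matrix(0+0i, nSamples, 10L)
  if (cp@sensorNoiseSigma > 0) {
    startIdx <- round(tStart / dwell)
    nseed <- (abs(seed) %% 100003) * 20029 + (startIdx %% 99991) + 31L
    noise <- withSeed(nseed,
      matrix(crnorm(nSamples * 10L, cp@sensorNoiseSigma), nSamples, 10L))
  }
  list(rx = rx, sensEmi = sens, sensNoise = noise)
}

## fixed deterministic sensing gains: near-unit magnitude, spread phases
.defaultSensGains <- function(shift = 0) {
  c <- 1:10
  (0.7 + 0.06 * ((c * 3 + shift) %% 10)) * exp(2i * pi * (c / 10 + shift / 7))
}

#' Ready-made EMI worlds
#'
#' `standardEmiWorld()` is the default test condition: a broadband source
#' (rms 0.03 in the receive coil, band -15 to -5 kHz) plus 50 Hz powerline
#' harmonics (rms 0.015, harmonics to 2 kHz), coupled through fixed FIR
#' filters; with the default receiver noise std 0.01 the EMI-to-receiver-
#' noise power ratio is about 11. `sweptEmiWorld()` replaces the broadband
#' source with a linear sweep traversing -20 to +20 kHz over the scan (the
#' dynamic-EMI condition). `ltiWorld()` is a noiseless, single-broadband-
#' source world with single-tap sensing couplings, in which the receive-coil
#' EMI is an exact FIR function of the sensing coils — the analytic ground
#' truth for the linear canceller.
#'
#' @param sampleRate baseband sampling rate, Hz.
#' @param emiScale multiplier on all source amplitudes (0 silences EMI).
#' @return an [EMIWorld-class].
#' @export
standardEmiWorld <- function(sampleRate = 5e4, emiScale = 1) {
  src <- list(
    emiSource("broadband", amplitude = 0.03 * emiScale,
              band = c(-15e3, -5e3), seedOffset = 1L),
    emiSource("powerline_harmonics", amplitude = 0.015 * emiScale,
              band = c(-2e3, 2e3), fundamental = 50, seedOffset = 2L))
  rxTaps <- list(
    { h <- c(0.85 + 0.30i, 0.22 - 0.12i, 0.05 + 0.02i); h / sqrt(sum(Mod(h)^2)) },
    { h <- c(0.90 - 0.25i, -0.18 + 0.08i); h / sqrt(sum(Mod(h)^2)) })
  sensTaps <- list(matrix(.defaultSensGains(0), ncol = 1L),
                   matrix(.defaultSensGains(3), ncol = 1L))
  emiWorld(src, couplingModel(rxTaps, sensTaps, sensorNoiseSigma = 3e-4),
           sampleRate)
}

#' @rdname standardEmiWorld
#' @export
sweptEmiWorld <- function(sampleRate = 5e4, emiScale = 1) {
  src <- list(
    emiSource("swept", amplitude = 0.03 * emiScale, sweep = c(-2e4, 2e4),
              seedOffset = 4L),
    emiSource("powerline_harmonics", amplitude = 0.015 * emiScale,
              band = c(-2e3, 2e3), fundamental = 50, seedOffset = 5L))
  rxTaps <- list(
    { h <- c(0.80 + 0.35i, 0.20 + 0.10i); h / sqrt(sum(Mod(h)^2)) },
    { h <- c(0.90 - 0.25i, -0.18 + 0.08i); h / sqrt(sum(Mod(h)^2)) })
  sensTaps <- list(matrix(.defaultSensGains(1), ncol = 1L),
                   matrix(.defaultSensGains(4), ncol = 1L))
  emiWorld(src, couplingModel(rxTaps, sensTaps, sensorNoiseSigma = 3e-4),
           sampleRate)
}

#' @rdname standardEmiWorld
#' @param rxTapLength receive-coil FIR length in the LTI world.
#' @export
ltiWorld <- function(sampleRate = 5e4, emiScale = 1, rxTapLength = 4L) {
  src <- list(emiSource("broadband", amplitude = 0.05 * emiScale,
                        band = c(-1.2e4, 8e3), seedOffset = 7L))
  h <- (0.9^(seq_len(rxTapLength) - 1L)) *
    exp(1i * 0.7 * (seq_len(rxTapLength) - 1L))
  rxTaps <- list(h / sqrt(sum(Mod(h)^2)))
  sensTaps <- list(matrix(.defaultSensGains(2), ncol = 1L))
  emiWorld(src, couplingModel(rxTaps, sensTaps, sensorNoiseSigma = 0),
           sampleRate)
}

#' EMI frequency bands of a world (for suppression metrics)
#'
#' @param world an [EMIWorld-class].
#' @return list of length-2 Hz intervals, one per source.
#' @export
emiBands <- function(world) {
  lapply(world@sources, function(s)
    switch(s@kind,
           broadband = s@band,
           swept = range(s@sweep),
           tone = c(s@freq, s@freq),
           powerline_harmonics = c(-min(max(abs(s@band)), 1e9),
                                   min(max(abs(s@band)), 1e9)) ))
}

setMethod("show", "EMIWorld", function(object) {
  cat(sprintf("EMIWorld: %d source(s), sampling %.3g kHz\n",
              length(object@sources), object@sampleRate / 1000))
  for (s in object@sources)
    cat(sprintf("  - %s, rms %.3g\n", s@kind, s@amplitude))
  cat(sprintf("  sensing sensor noise sigma %.3g, rx drift %s\n",
              object@coupling@sensorNoiseSigma,
              if (is.null(object@coupling@drift)) "off" else "on"))
})
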