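## S4 classes for the simulator and canceller. Validity methods encode the
## structural invariants each downstream stage relies on.

#' Labelled digital phantom
#'
#' A 3D integer label grid plus a per-tissue parameter table (proton density,
#' T1, T2, ADC at 0.055 T) and an optional off-resonance field map in Hz.
#' Label 0 is background with zero proton density.
#'
#' @slot labels 3D integer array of tissue indices (0 = background).
#' @slot tissues data.frame with columns `name`, `pd`, `t1` (ms), `t2` (ms),
#'   `adc` (mm^2/s); row `i + 1` describes label `i`.
#' @slot voxelSize numeric length-3, acquisition voxel size in mm.
#' @slot fieldMap `NULL` or numeric array of off-resonance (Hz) matching
#'   `labels` in shape.
#' @export
setClass("Phantom",
  representation(labels = "array", tissues = "data.frame",
                 voxelSize = "numeric", fieldMap = "ANY"))

setValidity("Phantom", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  need <- c("name", "pd", "t1", "t2", "adc")
  if (!all(need %in% names(object@tissues)))
    msg <- c(msg, "tissues must have columns name, pd, t1, t2, adc")
  labs <- sort(unique(as.integer(object@labels)))
  if (length(labs) && (min(labs) < 0L || max(labs) > nrow(object@tissues) - 1L))
    msg <- c(msg, "every label must have a tissues row (label i -> row i+1)")
  if (nrow(object@tissues)) {
    tt <- object@tissues
    if (tt$pd[1L] != 0)
      msg <- c(msg, "label 0 must be background with pd = 0")
    body <- tt[-1L, , drop = FALSE]
    if (nrow(body)) {
      if (any(body$pd <= 0 | body$pd > 1))
        msg <- c(msg, "tissue pd must lie in (0, 1]")
      if (any(body$t1 <= 0) || any(body$t2 <= 0))
        msg <- c(msg, "relaxation times must be positive")
      if (any(body$t2 > body$t1))
        msg <- c(msg, "t2 must not exceed t1")
      if (any(body$adc < 0))
        msg <- c(msg, "adc must be non-negative")
    }
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
  if (!is.null(object@fieldMap) &&
      !identical(dim(object@fieldMap), dim(object@labels)))
    msg <- c(msg, "fieldMap must match the label grid shape")
  if (length(msg)) msg else TRUE
})

#' Scan protocol configuration
#'
#' Sequence kind and all timing/encoding parameters of one acquisition:
#' repetition/echo time, flip angle, echo train length, averages, matrix,
#' field of view, readout sampling, dual-window characterization settings and
#' optional diffusion encoding.
#'
#' @slot kind one of `"GRE3D"`, `"FSE3D"`, `"FLAIR_LIKE_FSE3D"`, `"EPI_DWI_2D"`.
#' @slot tr,te repetition and echo time in ms.
#' @slot fa flip angle in degrees (GRE excitation; FSE uses 90/180).
#' @slot etl echo train length (echoes per excitation).
#' @slot nex number of averaged excitations.
#' @slot matrixSize integer length-3 `(n_fe, n_pe1, n_pe2)`.
#' @slot fov numeric length-3 field of view in mm.
#' @slot sliceThickness acquisition slice thickness in mm.
#' @slot nX readout samples per FE line (equals `matrixSize[1]`).
#' @slot dwell readout dwell time in s.
#' @slot charCount EMI characterization windows per TR.
#' @slot echoGap dead time between acquisition windows in s.
#' @slot elliptic use elliptic 2D phase-encode masking.
#' @slot rxNoiseSigma receiver thermal noise std per complex sample
#'   (relative units).
#' @slot diffusion `NULL` or a list with `b` (s/mm^2), `bigDelta`/`smallDelta`
#'   (ms) and `directions` (3-column matrix of unit vectors).
#' @export
setClass("ProtocolConfig",
  representation(kind = "character", tr = "numeric", te = "numeric",
                 fa = "numeric", etl = "numeric", nex = "numeric",
                 matrixSize = "integer", fov = "numeric",
                 sliceThickness = "numeric", nX = "integer",
                 dwell = "numeric", charCount = "integer",
                 echoGap = "numeric", elliptic = "logical",
                 rxNoiseSigma = "numeric", diffusion = "ANY"))

sequenceKinds <- c("GRE3D", "FSE3D", "FLAIR_LIKE_FSE3D", "EPI_DWI_2D")

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (!object@kind %in% sequenceKinds)
    msg <- c(msg, paste("kind must be one of", paste(sequenceKinds, collapse = ", ")))
  if (object@tr <= 0 || object@te <= 0 || object@te >= object@tr)
    msg <- c(msg, "need 0 < te < tr (ms)")
  if (object@fa < 0 || object@fa > 180)
    msg <- c(msg, "flip angle must lie in [0, 180] degrees")
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 1L))
    msg <- c(msg, "matrixSize must be 3 positive integers")
  if (object@nX != object@matrixSize[1L])
    msg <- c(msg, "nX must equal the frequency-encode matrix size")
  if (object@dwell <= 0) msg <- c(msg, "dwell must be positive (s)")
  if (object@etl < 1 || object@nex < 1 || object@charCount < 1L)
    msg <- c(msg, "etl, nex and charCount must be >= 1")
  ## time-overhead constraint: MRI acquisition windows plus characterization
  ## windows must fit within one TR
  win <- object@nX * object@dwell + object@echoGap
  budget <- object@te / 1000 + object@etl * win + object@charCount * win
  if (budget > object@tr / 1000)
    msg <- c(msg, sprintf(
      paste("TR (%g ms) too short for the acquisition plus EMI characterization",
            "windows (%.1f ms): the characterization time-overhead raises the",
            "shortest possible TR"), object@tr, budget * 1000))
  if (ceiling(object@charCount / 2) * win > object@te / 1000)
    msg <- c(msg, paste("the pre-excitation characterization windows do not",
                        "fit before TE; reduce charCount"))
  if (!is.null(object@diffusion)) {
    d <- object@diffusion
    if (is.null(d$b) || d$b < 0) msg <- c(msg, "diffusion b must be >= 0")
    if (!is.null(d$bigDelta) && !is.null(d$smallDelta) &&
        d$bigDelta <= d$smallDelta / 3)
      msg <- c(msg, "diffusion needs bigDelta > smallDelta/3")
  }
  if (length(msg)) msg else TRUE
})

#' One EMI source
#'
#' Complex-baseband interference waveform description. Frequencies are Hz
#' offsets from the 2.32 MHz carrier; all must lie within +/- sampleRate/2.
#'
#' @slot kind `"broadband"`, `"swept"`, `"tone"` or `"powerline_harmonics"`.
#' @slot amplitude source rms amplitude (relative units).
#' @slot band numeric length-2 band (Hz offsets) for broadband sources; for
#'   `powerline_harmonics` the band limits which harmonics are kept.
#' @slot freq tone offset (Hz) for `"tone"`.
#' @slot sweep numeric length-2 start/end offset (Hz) of a linear sweep
#'   traversed over the scan duration.
#' @slot fundamental powerline fundamental in Hz (default 50).
#' @slot drift `NULL` or list `(rate_hz, depth)` describing slow sinusoidal
#'   amplitude modulation over scan time.
#' @slot seedOffset per-source RNG stream offset.
#' @export
setClass("EMISource",
  representation(kind = "character", amplitude = "numeric", band = "numeric",
                 freq = "numeric", sweep = "numeric", fundamental = "numeric",
                 drift = "ANY", seedOffset = "integer"))

setValidity("EMISource", function(object) {
  msg <- character()
  if (!object@kind %in% c("broadband", "swept", "tone", "powerline_harmonics"))
    msg <- c(msg, "unknown EMI source kind")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Linear EMI coupling model
#'
#' Per-(source, channel) complex FIR taps mapping each source waveform into
#' the receive coil (channel 0) and the ten sensing coils, plus independent
#' sensor noise on the sensing channels and optional slow gain drift.
#'
#' @slot rxTaps list (one per source) of complex FIR tap vectors for the
#'   receive coil.
#' @slot sensTaps list (one per source) of 10-row complex matrices; row c is
#'   the FIR for sensing coil c.
#' @slot sensorNoiseSigma complex-Gaussian noise std per sensing-coil sample.
#' @slot drift `NULL` or list `(rate_hz, depth)`: multiplicative gain
#'   `1 + depth*sin(2*pi*rate_hz*t)` on the receive-coil coupling.
#' @export
setClass("CouplingModel",
  representation(rxTaps = "list", sensTaps = "list",
                 sensorNoiseSigma = "numeric", drift = "ANY"))

setValidity("CouplingModel", function(object) {
  msg <- character()
  if (length(object@rxTaps) != length(object@sensTaps))
    msg <- c(msg, "rxTaps and sensTaps must have one entry per source")
  for (m in object@sensTaps)
    if (!is.matrix(m) || nrow(m) != 10L)
      msg <- c(msg, "each sensTaps entry must be a 10-row complex matrix")
  if (any(vapply(object@rxTaps, length, 1L) < 1L))
    msg <- c(msg, "FIR filters need length >= 1")
  if (object@sensorNoiseSigma < 0)
    msg <- c(msg, "sensorNoiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EMI world: sources plus coupling
#'
#' @slot sources list of [EMISource-class] objects.
#' @slot coupling a [CouplingModel-class].
#' @slot sampleRate complex-baseband sampling rate in Hz (receive bandwidth).
#' @export
setClass("EMIWorld",
  representation(sources = "list", coupling = "CouplingModel",
                 sampleRate = "numeric"))

setValidity("EMIWorld", function(object) {
  msg <- character()
  if (length(object@coupling@rxTaps) != length(object@sources))
    msg <- c(msg, "coupling must define taps for every source")
  nyq <- object@sampleRate / 2
  for (s in object@sources) {
    f <- switch(s@kind,
                broadband = s@band, swept = s@sweep, tone = s@freq,
                powerline_harmonics = s@band)
    if (length(f) && any(abs(f) > nyq))
      msg <- c(msg, "source band outside the Nyquist interval")
  }
  if (length(msg)) msg else TRUE
})

#' Raw dual-window multichannel acquisition
#'
#' Everything one simulated scan produced: per-FE-line receive and sensing
#' data for both the MRI acquisition windows and the EMI characterization
#' windows, the k-space bookkeeping, and (optionally) an EMI-free shielded
#' twin sharing the identical MRI signal and receiver-noise realizations.
#'
#' @slot protocol the [ProtocolConfig-class] used.
#' @slot lines data.frame, one row per acquired FE line (all NEX repeats):
#'   `pe1`, `pe2` (1-based k-space indices), `shot`, `echo`, `nex`, `t0`
#'   (window start, s).
#' @slot rxAcq complex matrix, lines x nX: receive coil, acquisition windows.
#' @slot rxChar complex matrix, characterization windows x nX.
#' @slot sensAcq complex array lines x nX x 10: sensing coils, acquisition
#'   windows.
#' @slot sensChar complex array windows x nX x 10.
#' @slot charTimes numeric, start time (s) of each characterization window.
#' @slot shieldedTwin `NULL` or an `AcquisitionRecord` with EMI amplitude
#'   forced to zero, same MRI signal and receiver noise.
#' @slot meta list: seeds, EMI-world hash, scan-time accounting, EPI
#'   reference scan, ground-truth EMI replay.
#' @export
setClass("AcquisitionRecord",
  representation(protocol = "ProtocolConfig", lines = "data.frame",
                 rxAcq = "matrix", rxChar = "matrix", sensAcq = "array",
                 sensChar = "array", charTimes = "numeric",
                 shieldedTwin = "ANY", meta = "list"))

setValidity("AcquisitionRecord", function(object) {
  msg <- character()
  if (nrow(object@rxAcq) != nrow(object@lines))
    msg <- c(msg, "rxAcq must have one row per bookkeeping line")
  if (ncol(object@rxAcq) != object@protocol@nX)
    msg <- c(msg, "rxAcq must have nX columns")
  if (!identical(dim(object@sensAcq)[1:2], dim(object@rxAcq)) ||
      dim(object@sensAcq)[3L] != 10L)
    msg <- c(msg, "sensAcq must be lines x nX x 10")
  if (nrow(object@rxChar) != length(object@charTimes))
    msg <- c(msg, "one start time per characterization window")
  if (!is.null(object@shieldedTwin) &&
      !is(object@shieldedTwin, "AcquisitionRecord"))
    msg <- c(msg, "shieldedTwin must be NULL or an AcquisitionRecord")
  if (length(msg)) msg else TRUE
})

#' Training configuration for the CNN canceller
#'
#' Defaults follow the per-scan training recipe: 85/15 train/validation
#' split, batch 16, 20 epochs, Adam with beta1 = 0.9, beta2 = 0.999 and
#' initial learning rate 5e-4.
#'
#' @slot split numeric length-2 train/validation fractions.
#' @slot batch examples per optimizer step.
#' @slot epochs passes over the training set.
#' @slot lr initial learning rate.
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot seed RNG seed for split, initialization and shuffling.
#' @export
setClass("TrainConfig",
  representation(split = "numeric", batch = "integer", epochs = "integer",
                 lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (length(object@split) != 2L || any(object@split <= 0) ||
      abs(sum(object@split) - 1) > 1e-9)
    msg <- c(msg, "split must be two positive fractions summing to 1")
  if (object@batch < 1L) msg <- c(msg, "batch must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@lr <= 0) msg <- c(msg, "lr must be positive")
  if (length(msg)) msg else TRUE
})

#' Trained five-layer CNN EMI canceller
#'
#' Convolutional blocks with kernel sizes 11x11, 9x9, 5x5, 1x1, 7x7 and
#' channel counts 128, 64, 32, 32, 2; blocks 1-4 are convolution + batch
#' normalization + ReLU, block 5 convolution only. Input is nX x 10 x 2
#' (readout samples x sensing coils x real/imag), output nX x 2; the 10-wide
#' coil axis of the last feature map is averaged to produce the output.
#'
#' @slot net list of layer parameter matrices and batch-norm statistics as
#'   produced by the C++ training core.
#' @slot arch list: kernel sizes, channel counts, input geometry, coil-axis
#'   reduction rule.
#' @slot scales named numeric: input/target normalization constants computed
#'   on the training portion only.
#' @slot history data.frame with per-epoch `train` and `val` MSE.
#' @slot config the [TrainConfig-class] used.
#' @slot trainedOn content hash of the record whose characterization data
#'   trained this model (per-scan training contract).
#' @export
setClass("CancellerModel",
  representation(net = "list", arch = "list", scales = "numeric",
                 history = "data.frame", config = "TrainConfig",
                 trainedOn = "character"))

#' Linear least-squares baseline canceller
#'
#' Complex FIR coefficients (one length-L filter per sensing coil) fitted by
#' regularized least squares on the characterization windows; the analytic
#' oracle the CNN is compared against in time-invariant worlds.
#'
#' @slot coef complex matrix 10 x L, row c = filter for sensing coil c.
#' @slot taps filter length L.
#' @slot reg ridge regularization weight.
#' @slot trainedOn content hash of the training record.
#' @export
setClass("LinearCanceller",
  representation(coef = "matrix", taps = "integer", reg = "numeric",
                 trainedOn = "character"))

setValidity("LinearCanceller", function(object) {
  if (object@taps < 1L) "taps must be >= 1" else TRUE
})

#' Cartesian k-space volume
#'
#' @slot data complex 3D array (fe x pe1 x pe2); unsampled entries exactly 0.
#' @slot mask logical pe1 x pe2 sampling mask.
#' @slot voxelSize acquisition voxel size (mm).
#' @slot nex averages completed per sampled line.
#' @export
setClass("KSpaceVolume",
  representation(data = "array", mask = "matrix", voxelSize = "numeric",
                 nex = "numeric"))

setValidity("KSpaceVolume", function(object) {
  msg <- character()
  if (!is.complex(object@data) || length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a complex 3D array")
  d <- dim(object@data)
  if (!identical(dim(object@mask), d[2:3]))
    msg <- c(msg, "mask must be pe1 x pe2")
  flat <- object@data
  dim(flat) <- c(d[1L], d[2L] * d[3L])
  unsamp <- flat[, !as.vector(object@mask), drop = FALSE]
  if (length(unsamp) && any(unsamp != 0))
    msg <- c(msg, "unsampled k-space entries must be exactly 0")
  if (length(msg)) msg else TRUE
})

#' Reconstructed magnitude image volume
#'
#' @slot data non-negative 3D array.
#' @slot voxelSize display voxel size (mm).
#' @slot meta provenance list (protocol/canceller hashes, pad factors).
#' @export
setClass("ImageVolume",
  representation(data = "array", voxelSize = "numeric", meta = "list"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (any(object@data < 0)) msg <- c(msg, "magnitude image must be non-negative")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' EMI-suppression metrics report
#'
#' @slot spectra data.frame (condition, freq Hz, magnitude): magnitude-
#'   averaged FE-line spectra for contaminated / cancelled / shielded arms.
#' @slot sigmaBg named numeric: background-noise std per condition.
#' @slot suppressionDb EMI-band power reduction, dB.
#' @slot shieldedDeviation |sigma_cancelled - sigma_shielded| / sigma_shielded.
#' @slot pass5pct TRUE iff shieldedDeviation <= 0.05.
#' @slot meta list of settings used.
#' @export
setClass("MetricsReport",
  representation(spectra = "data.frame", sigmaBg = "numeric",
                 suppressionDb = "numeric", shieldedDeviation = "numeric",
                 pass5pct = "logical", meta = "list"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (any(object@sigmaBg < 0)) msg <- c(msg, "sigmaBg must be >= 0")
  if (length(object@shieldedDeviation) &&
      object@shieldedDeviation < 0)
    msg <- c(msg, "shieldedDeviation must be >= 0")
  if (length(object@shieldedDeviation) && length(object@pass5pct) &&
      !identical(object@pass5pct, object@shieldedDeviation <= 0.05))
    msg <- c(msg, "pass5pct must equal (shieldedDeviation <= 0.05)")
  if (length(msg)) msg else TRUE
})
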