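## Workflow layer: run configuration, seed fan-out, provenance, and the
## one-command pipeline simulate -> train -> cancel -> reconstruct ->
## evaluate. A thin command-line wrapper over these functions ships in
## inst/cli/ulfemi.R.

#' Build a run configuration
#'
#' Bundles phantom, protocol, EMI world, training and reconstruction
#' settings plus a single seed that fans out deterministically to every
#' stage (see `stageSeed` scheme in the package vignette). The default is
#' the desk-scale dual-window FSE condition: 64 x 64 single slice, ETL 8,
#' NEX 2, 16 characterization windows per TR (256 in total), standard
#' broadband + 50 Hz-harmonic EMI world.
#'
#' @param phantom a [Phantom-class].
#' @param protocol a [ProtocolConfig-class].
#' @param emiWorld an [EMIWorld-class] or `NULL` (shielded run).
#' @param train a [TrainConfig-class]; its seed is overridden by `seed`.
#' @param padFactors display zero-pad factors.
#' @param canceller `"cnn"` or `"linear"`.
#' @param linTaps,linReg linear-canceller settings.
#' @param seed run seed.
#' @param outDir `NULL` or a directory for artifacts (record, images,
#'   report), each stamped with the config hash.
#' @return a `RunConfig` list (class `"ulfemi_run_config"`).
#' @export
runConfig <- function(phantom = makePhantom(c(64L, 64L, 1L)),
                      protocol = protocolT2wFse(matrixSize = c(64L, 64L, 1L),
                                                etl = 8L, nex = 2L,
                                                charCount = 16L,
                                                elliptic = FALSE),
                      emiWorld = standardEmiWorld(),
                      train = trainConfig(),
                      padFactors = c(2L, 2L, 1L),
                      canceller = c("cnn", "linear"),
                      linTaps = 5L, linReg = 1e-10,
                      seed = 1L, outDir = NULL) {
  canceller <- match.arg(canceller)
  cfg <- list(phantom = phantom, protocol = protocol, emiWorld = emiWorld,
              train = train, padFactors = as.integer(padFactors),
              canceller = canceller, linTaps = as.integer(linTaps),
              linReg = linReg, seed = as.integer(seed), outDir = outDir)
  cfg$hash <- contentHash(cfg[c("protocol", "padFactors", "canceller",
                                "seed")])
  class(cfg) <- "ulfemi_run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' The file may specify `protocol` (preset name + overrides), `phantom`
#' (gridShape, voxelSize, lesion), `emiWorld` (`"standard"`, `"swept"`,
#' `"lti"`, `"none"`), `train`, `canceller`, `padFactors` and `seed`;
#' anything omitted takes the [runConfig()] default.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @param seed optional seed override.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("phantom", "protocol", "emiWorld", "train",
                               "canceller", "padFactors", "seed", "outDir"))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$phantom)) {
    p <- raw$phantom
    args$phantom <- makePhantom(
      gridShape = p$gridShape %||% c(64L, 64L, 1L),
      voxelSize = p$voxelSize %||% c(2, 2, 10),
      lesionSpec = p$lesion, fieldMapHz = p$fieldMapHz %||% 0,
      seed = raw$seed %||% 1L)
  }
  if (!is.null(raw$protocol)) {
    pr <- raw$protocol
    maker <- switch(pr$preset %||% "t2w",
                    t1w = protocolT1wGre, t2w = protocolT2wFse,
                    flair = protocolFlairFse, dwi = protocolDwiEpi,
                    stop("protocol.preset must be t1w/t2w/flair/dwi"))
    extra <- pr[setdiff(names(pr), "preset")]
    if (!is.null(extra$matrixSize)) extra$matrixSize <- as.integer(extra$matrixSize)
    args$protocol <- do.call(maker, extra)
  }
  if (!is.null(raw$emiWorld))
    args$emiWorld <- switch(raw$emiWorld,
                            standard = standardEmiWorld(),
                            swept = sweptEmiWorld(), lti = ltiWorld(),
                            none = NULL,
                            stop("emiWorld must be standard/swept/lti/none"))
  if (!is.null(raw$train))
    args$train <- do.call(trainConfig, raw$train)
  for (f in c("canceller", "outDir"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$padFactors)) args$padFactors <- as.integer(raw$padFactors)
  args$seed <- as.integer(seed %||% raw$seed %||% 1L)
  if (is.null(raw$emiWorld)) args$emiWorld <- standardEmiWorld()
  else if (identical(raw$emiWorld, "none")) args["emiWorld"] <- list(NULL)
  do.call(runConfig, args)
}

#' Simulate a raw acquisition from a run configuration
#'
#' Wraps [simulateScan()], logs scan-time accounting (shots x NEX x TR plus
#' the characterization-window overhead) and optionally writes the record
#' (with its shielded twin) to `outDir`.
#'
#' @param config a `RunConfig` from [runConfig()] / [readRunConfig()].
#' @param quiet suppress the log line.
#' @return an [AcquisitionRecord-class] with shielded twin attached.
#' @export
cmdSimulate <- function(config, quiet = FALSE) {
  rec <- simulateScan(config$phantom, config$protocol, config$emiWorld,
                      seed = config$seed, shieldedTwin = TRUE)
  rec@meta$configHash <- config$hash
  if (!quiet)
    message(sprintf(
      "simulated %s: %d shots x NEX %g x TR %g ms = %.1f s scan (+%.2f s EMI characterization overhead)",
      config$protocol@kind, rec@meta$shots, config$protocol@nex,
      config$protocol@tr, rec@meta$scanTimeS, rec@meta$charOverheadS))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    saveRecord(rec, file.path(config$outDir,
                              sprintf("record_%s.rds", config$hash)))
  }
  rec
}

#' Run the full EMI-cancellation pipeline
#'
#' simulate -> assemble training data -> train canceller -> cancel ->
#' average -> reconstruct -> evaluate against the shielded twin. With
#' `canceller = "linear"` the least-squares baseline replaces the CNN.
#'
#' @param config a `RunConfig`.
#' @param quiet suppress per-stage log lines.
#' @return list with `record`, `cancelled`, `model`, `images` (named list of
#'   [ImageVolume-class]: contaminated/cancelled/shielded) and `report`
#'   (a [MetricsReport-class]).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3L]
  rec <- cmdSimulate(config, quiet = quiet)
  say("[simulate] %.1fs", proc.time()[3L] - t0)

  shd <- shieldedTwin(rec)
  if (!isTRUE(rec@meta$emiOn)) {
    say("[evaluate] EMI absent: shielded-only run")
    img <- reconCartesian(averageNex(rec), config$padFactors)
    rep <- suppressionReport(rec, rec, shd, config$phantom, config$padFactors)
    return(list(record = rec, cancelled = rec, model = NULL,
                images = list(shielded = img), report = rep))
  }

  t1 <- proc.time()[3L]
  tc <- config$train
  tc@seed <- config$seed
  model <- if (config$canceller == "cnn") {
    tr <- assembleTraining(rec, tc)
    m <- trainCnn(tr, tc)
    say("[train] CNN val MSE %.3g -> %.3g, %.1fs",
        m@history$val[1L], m@history$val[nrow(m@history)],
        proc.time()[3L] - t1)
    m
  } else {
    m <- fitLinearCanceller(rec, taps = config$linTaps, reg = config$linReg)
    say("[train] linear canceller, %d taps, %.1fs", config$linTaps,
        proc.time()[3L] - t1)
    m
  }

  t2 <- proc.time()[3L]
  clean <- cancelEmi(rec, model)
  say("[cancel] %.1fs", proc.time()[3L] - t2)

  t3 <- proc.time()[3L]
  imgs <- list(
    contaminated = reconCartesian(averageNex(rec), config$padFactors),
    cancelled = reconCartesian(averageNex(clean), config$padFactors),
    shielded = reconCartesian(averageNex(shd), config$padFactors))
  rep <- suppressionReport(clean, rec, shd, config$phantom, config$padFactors)
  say("[recon+metrics] %.1fs; suppression %.1f dB, shielded deviation %.2f%% (%s)",
      proc.time()[3L] - t3, rep@suppressionDb, 100 * rep@shieldedDeviation,
      if (rep@pass5pct) "PASS" else "FAIL")

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(imgs))
      writeImageNifti(imgs[[nm]],
                      file.path(config$outDir,
                                sprintf("%s_%s.nii.gz", nm, config$hash)))
    writeReport(rep, file.path(config$outDir,
                               sprintf("report_%s.json", config$hash)))
  }
  list(record = rec, cancelled = clean, model = model, images = imgs,
       report = rep)
}
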