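## Per-scan EMI cancellation: training-set assembly from characterization
## windows, the five-layer CNN (C++ core), per-FE-line prediction and
## subtraction, and a regularized linear least-squares baseline that is
## exact in time-invariant noiseless worlds (the analytic oracle).

#' @rdname trainCnn
#' @param split train/validation fractions (default 0.85/0.15).
#' @param batch examples per Adam step (default 16).
#' @param epochs training passes (default 20).
#' @param lr initial learning rate (default 5e-4).
#' @param beta1,beta2 Adam moment decays (defaults 0.9 / 0.999).
#' @param seed training seed (split, init, shuffling).
#' @export
trainConfig <- function(split = c(0.85, 0.15), batch = 16L, epochs = 20L,
                        lr = 5e-4, beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  new("TrainConfig", split = split, batch = as.integer(batch),
      epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
      seed = as.integer(seed))
}

## structural hash of the data a model may be trained/applied on: used to
## enforce the per-scan training contract
recordHash <- function(record) {
  ch <- record@rxChar
  contentHash(list(dim(ch), sum(Re(ch)), sum(Im(ch)),
                   sum(Re(record@sensChar)), sum(Im(record@sensChar)),
                   record@protocol@kind, record@protocol@matrixSize,
                   record@meta$seed %||% NA))
}

## complex (N, H, 10) stack -> real array (2, H*10, N), p = h + H*(w-1)
.stackToChannels <- function(stack) {
  d <- dim(stack)
  perm <- aperm(stack, c(2L, 3L, 1L))         # H x 10 x N
  out <- array(0, c(2L, d[2L] * d[3L], d[1L]))
  dim(perm) <- c(d[2L] * d[3L], d[1L])
  out[1L, , ] <- Re(perm)
  out[2L, , ] <- Im(perm)
  out
}

## complex (N, H) lines -> (2, H, N)
.linesToChannels <- function(m) {
  out <- array(0, c(2L, ncol(m), nrow(m)))
  out[1L, , ] <- t(Re(m))
  out[2L, , ] <- t(Im(m))
  out
}

#' Assemble CNN training data from characterization windows
#'
#' Examples are (sensing stack nX x 10 x 2, receive window nX x 2) pairs
#' drawn exclusively from the EMI characterization windows — which contain
#' no MRI signal by construction — and split 85/15 into train/validation by
#' a seeded random partition. Input and target normalization constants are
#' computed on the training portion only.
#'
#' @param record an [AcquisitionRecord-class] with at least 20
#'   characterization windows.
#' @param config a [TrainConfig-class].
#' @return list with `train`, `val` (each `x` (2, nX*10, n), `y` (2, nX, n),
#'   `idx`), `scales` (named: `x`, `y`) and `recordHash`.
#' @export
assembleTraining <- function(record, config = trainConfig()) {
  nW <- nrow(record@rxChar)
  if (nW < 20L)
    stop("only ", nW, " characterization windows; need >= 20 - increase NEX ",
         "or the number of characterization windows per TR (charCount)")
  set.seed(stageSeed(config@seed, "split"))
  nVal <- round(nW * config@split[2L])
  valIdx <- sort(sample.int(nW, nVal))
  trIdx <- setdiff(seq_len(nW), valIdx)

  x <- .stackToChannels(record@sensChar)
  y <- .linesToChannels(record@rxChar)
  xScale <- stats::sd(as.vector(x[, , trIdx]))
  yScale <- stats::sd(as.vector(y[, , trIdx]))
  if (xScale == 0) xScale <- 1
  if (yScale == 0) yScale <- 1
  list(train = list(x = x[, , trIdx, drop = FALSE] / xScale,
                    y = y[, , trIdx, drop = FALSE] / yScale, idx = trIdx),
       val = list(x = x[, , valIdx, drop = FALSE] / xScale,
                  y = y[, , valIdx, drop = FALSE] / yScale, idx = valIdx),
       scales = c(x = xScale, y = yScale),
       dwell = record@protocol@dwell,
       recordHash = recordHash(record))
}

#' Train the five-layer CNN EMI canceller
#'
#' Blocks 1-4 are convolution + batch normalization + ReLU, block 5
#' convolution only; kernel sizes 11x11, 9x9, 5x5, 1x1, 7x7 with 128, 64,
#' 32, 32, 2 channels; same-padding on both axes preserves the nX x 10 map
#' and the final two-channel map is averaged across the coil axis. Runs
#' exactly `epochs` passes of Adam (MSE loss) at the configured batch size
#' and returns the final-epoch model with its per-epoch loss history (the
#' validation loss is also recorded before the first step, as epoch 0).
#'
#' @param training output of [assembleTraining()].
#' @param config a [TrainConfig-class].
#' @return a [CancellerModel-class].
#' @export
trainCnn <- function(training, config = trainConfig()) {
  H <- dim(training$train$y)[2L]
  W <- 10L
  set.seed(stageSeed(config@seed, "init"))
  ## training augmentation consistent with the linear coupling model:
  ## random global phases, pairwise superposition, and a +/-400 Hz
  ## frequency jitter (as a per-sample phase ramp)
  jitter <- 2 * pi * 400 * (training$dwell %||% 2e-5)
  fit <- .cnn_train(training$train$x, training$train$y,
                    training$val$x, training$val$y,
                    H, W, config@epochs, config@batch,
                    config@lr, config@beta1, config@beta2, jitter)
  hist <- data.frame(epoch = 0:config@epochs,
                     train = c(NA_real_, fit$train_loss),
                     val = fit$val_loss)
  new("CancellerModel", net = fit$layers,
      arch = list(kernels = c(11L, 9L, 5L, 1L, 7L),
                  channels = c(128L, 64L, 32L, 32L, 2L),
                  nX = H, coils = W,
                  coilReduction = "mean over the 10-wide coil axis"),
      scales = training$scales, history = hist, config = config,
      trainedOn = training$recordHash)
}

#' @describeIn trainCnn per-epoch train/validation MSE.
#' @param model a `CancellerModel`.
#' @export
trainingHistory <- function(model) model@history

setMethod("show", "CancellerModel", function(object) {
  h <- object@history
  cat("CancellerModel: five-layer CNN (11/9/5/1/7 kernels, 128/64/32/32/2 channels)\n")
  cat(sprintf("  input %d x %d x 2, output %d x 2; %s\n", object@arch$nX,
              object@arch$coils, object@arch$nX, object@arch$coilReduction))
  cat(sprintf("  val MSE: %.3g (epoch 0) -> %.3g (epoch %d)\n",
              h$val[1L], h$val[nrow(h)], nrow(h) - 1L))
})

#' Predict the receive-coil EMI from a sensing stack
#'
#' Pure function of (model, input): applies the trained CNN in inference
#' mode (batch normalization uses running statistics) to one or more
#' sensing stacks and reassembles the two real output channels into complex
#' FE lines.
#'
#' @param model a [CancellerModel-class].
#' @param stack complex `nX x 10` matrix (one FE line) or `n x nX x 10`
#'   array.
#' @return complex vector `nX` (single stack) or matrix `n x nX`.
#' @export
predictEmi <- function(model, stack) {
  single <- length(dim(stack)) == 2L
  if (single) {
    if (!identical(dim(stack), c(model@arch$nX, 10L)))
      stop("sensing stack must be ", model@arch$nX, " x 10")
    stack <- array(stack, c(1L, dim(stack)))
  } else if (dim(stack)[2L] != model@arch$nX || dim(stack)[3L] != 10L) {
    stop("sensing stack must be n x ", model@arch$nX, " x 10")
  }
  x <- .stackToChannels(stack) / model@scales[["x"]]
  out <- .cnn_predict(model@net, x, model@arch$nX, model@arch$coils)
  pred <- t(out[1L, , , drop = TRUE] + 1i * out[2L, , , drop = TRUE])
  if (dim(stack)[1L] == 1L) pred <- matrix(pred, nrow = 1L)
  pred <- pred * model@scales[["y"]]
  if (single) drop(pred) else pred
}

#' Cancel EMI on every FE line of a record
#'
#' Replaces each acquisition-window FE line by (receive - predicted EMI).
#' Subtraction happens before any NEX averaging; sensing data, the
#' characterization windows and the shielded twin are left untouched. The
#' model must have been trained on this record's characterization data
#' (per-scan training).
#'
#' @param record an [AcquisitionRecord-class].
#' @param model a [CancellerModel-class] or [LinearCanceller-class].
#' @return the cleaned record (`meta$cancelled` marks the canceller hash).
#' @export
cancelEmi <- function(record, model) {
  if (missing(model) || is.null(model)) stop("a trained canceller is required")
  if (!identical(model@trainedOn, recordHash(record)))
    stop("per-scan training contract: this model was not trained on this ",
         "record's characterization data")
  pred <- if (is(model, "LinearCanceller"))
    .linearPredict(model, record@sensAcq) else predictEmi(model, record@sensAcq)
  record@rxAcq <- record@rxAcq - pred
  record@meta$cancelled <- class(model)[1L]
  record@meta$cancellerHash <- contentHash(model@trainedOn)
  record
}

## lagged-regressor matrix for (windows x nX x 10) sensing data
.lagDesign <- function(sens, taps) {
  d <- dim(sens)
  nW <- d[1L]; nX <- d[2L]
  A <- matrix(0+0i, nW * nX, 10L * taps)
  for (l in seq_len(taps)) {
    ## within-window causal lags; samples before the window are zero
    idx <- seq_len(nX - l + 1L)
    for (c in 1:10) {
      col <- matrix(0+0i, nW, nX)
      col[, idx + l - 1L] <- sens[, idx, c]
      A[, c + 10L * (l - 1L)] <- as.vector(t(col))
    }
  }
  A
}

#' Linear least-squares baseline canceller
#'
#' Fits one length-`taps` complex FIR filter per sensing coil by (optionally
#' ridge-regularized) least squares mapping lagged sensing samples to the
#' receive samples over all characterization windows. In a noiseless
#' time-invariant coupling world this canceller is exact, which makes it the
#' analytic oracle the CNN is compared against.
#'
#' @param record an [AcquisitionRecord-class].
#' @param taps FIR length per coil.
#' @param reg ridge weight (0 = plain least squares; rank-deficient designs
#'   then raise an error).
#' @return a [LinearCanceller-class].
#' @export
fitLinearCanceller <- function(record, taps = 5L, reg = 0) {
  taps <- as.integer(taps)
  if (taps < 1L) stop("taps must be >= 1")
  A <- .lagDesign(record@sensChar, taps)
  b <- as.vector(t(record@rxChar))
  G <- crossprod(Conj(A), A) + diag(reg, ncol(A))
  rhs <- crossprod(Conj(A), b)
  theta <- tryCatch(solve(G, rhs), error = function(e)
    stop("rank-deficient design with reg = 0; supply a positive ",
         "regularization weight (", conditionMessage(e), ")"))
  new("LinearCanceller",
      coef = matrix(theta, nrow = 10L, ncol = taps),
      taps = taps, reg = reg, trainedOn = recordHash(record))
}

.linearPredict <- function(lc, sens) {
  d <- dim(sens)
  pred <- matrix(0+0i, d[1L], d[2L])
  for (i in seq_len(d[1L]))
    for (c in 1:10)
      pred[i, ] <- pred[i, ] + firApply(lc@coef[c, ], sens[i, , c])
  pred
}

#' @describeIn fitLinearCanceller predicted receive-coil EMI for a sensing
#'   stack (complex `nX x 10` matrix or `n x nX x 10` array).
#' @param lc a `LinearCanceller`.
#' @param stack sensing data.
#' @export
predictLinear <- function(lc, stack) {
  if (length(dim(stack)) == 2L)
    drop(.linearPredict(lc, array(stack, c(1L, dim(stack)))))
  else .linearPredict(lc, stack)
}

#' @describeIn fitLinearCanceller apply the linear canceller to every FE
#'   line (mirrors [cancelEmi()]).
#' @param record an `AcquisitionRecord`.
#' @export
applyLinearCanceller <- function(lc, record) cancelEmi(record, lc)

#' Validation residual of the optimal linear filter on a training split
#'
#' Solves the same regularized least-squares problem as
#' [fitLinearCanceller()] but on an assembled training split, returning the
#' mean squared error on the validation portion in the CNN's normalized
#' units — the oracle figure `trainCnn()` results are compared against.
#'
#' @param training output of [assembleTraining()].
#' @param taps FIR length.
#' @param reg ridge weight.
#' @return validation MSE (normalized units).
#' @export
linearOracleValMse <- function(training, taps = 1L, reg = 0) {
  toComplex <- function(a) {
    H10 <- dim(a)[2L]
    z <- a[1L, , , drop = TRUE] + 1i * a[2L, , , drop = TRUE]
    if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
    z  # (H*10) x n or H x n
  }
  H <- dim(training$train$y)[2L]
  mk <- function(part) {
    z <- toComplex(part$x)          # (H*10) x n
    n <- ncol(z)
    sens <- array(0+0i, c(n, H, 10L))
    for (i in seq_len(n)) sens[i, , ] <- matrix(z[, i], H, 10L)
    y <- t(toComplex(part$y))       # n x H
    list(sens = sens, y = y)
  }
  tr <- mk(training$train); va <- mk(training$val)
  A <- .lagDesign(tr$sens, as.integer(taps))
  b <- as.vector(t(tr$y))
  G <- crossprod(Conj(A), A) + diag(reg, ncol(A))
  theta <- solve(G, crossprod(Conj(A), b))
  lc <- new("LinearCanceller", coef = matrix(theta, 10L, as.integer(taps)),
            taps = as.integer(taps), reg = reg, trainedOn = "split")
  pred <- .linearPredict(lc, va$sens)
  resid <- va$y - pred
  ## same normalized units as the CNN's MSE: two real channels of H samples
  mean(c(Re(resid), Im(resid))^2)
}
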