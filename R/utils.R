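## Internal numerical utilities: centred orthonormal FFTs, seed fan-out,
## lightweight content hashing for provenance.

#' @useDynLib ulfemi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Centred-DFT convention used throughout the package: DC sits at (0-based)
## index floor(N/2) on every axis, and both transforms carry 1/sqrt(N) so the
## pair is unitary (Parseval holds exactly).

fftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    if (n < 2L) return(x)
    k <- floor(n / 2)
    return(x[c((k + 1L):n, 1L:k)])
  }
  idx <- lapply(d, function(n) {
    if (n < 2L) return(1L)
    k <- floor(n / 2)
    c((k + 1L):n, 1L:k)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    if (n < 2L) return(x)
    k <- ceiling(n / 2)
    return(x[c((k + 1L):n, 1L:k)])
  }
  idx <- lapply(d, function(n) {
    if (n < 2L) return(1L)
    k <- ceiling(n / 2)
    c((k + 1L):n, 1L:k)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## Unitary centred forward / inverse FFT (vector or n-d array).
fftc <- function(x) {
  n <- if (is.null(dim(x))) length(x) else prod(dim(x))
  fftShift(stats::fft(ifftShift(x))) / sqrt(n)
}

ifftc <- function(x) {
  n <- if (is.null(dim(x))) length(x) else prod(dim(x))
  out <- fftShift(stats::fft(ifftShift(x), inverse = TRUE)) / sqrt(n)
  out
}

## Centred k-space index offsets for an axis of length n: idx - floor(n/2).
kOffsets <- function(n) seq_len(n) - 1L - floor(n / 2)

## Deterministic per-stage seed fan-out: a single run seed is mapped to
## sub-seeds by a counter so stages can be re-run in isolation. Kept below
## 2^31 - 1 for R's 32-bit integer seeds.
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(phantom = 11L, emi = 23L, acquisition = 37L, split = 53L,
               init = 71L, train = 89L, recon = 101L, metrics = 113L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer((abs(seed) %% 1000003L) * 1000L + off)
}

## FNV-1a over a serialized object; enough for provenance tags (not crypto).
contentHash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Causal complex FIR filtering within a finite window (zero initial state):
## y[n] = sum_l h[l] x[n - l + 1]. Hand-rolled because stats::filter does not
## handle complex input.
firApply <- function(h, x) {
  L <- length(h)
  n <- length(x)
  y <- h[1L] * x
  if (L > 1L) {
    for (l in 2L:L) {
      if (l > n) break
      y[l:n] <- y[l:n] + h[l] * x[1L:(n - l + 1L)]
    }
  }
  y
}

## Circular complex Gaussian noise, std `sigma` per complex sample
## (i.e. real/imag parts each sigma/sqrt(2)).
crnorm <- function(n, sigma = 1) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
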