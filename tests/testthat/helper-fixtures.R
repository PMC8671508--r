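# Shared fixtures: small, fast configurations used across test files.
# All fixtures are built in code at test time; nothing is read from disk.

smallPhantom <- function(n = 64L, ...) makePhantom(c(n, n, 1L), ...)

# desk-scale dual-window FSE: 64x64 single slice, ETL 8, NEX 2,
# 16 characterization windows per TR (256 total)
deskFseProtocol <- function(n = 64L, nex = 2L, charCount = 16L, ...) {
  protocolT2wFse(matrixSize = c(n, n, 1L), etl = 8L, nex = nex,
                 charCount = charCount, elliptic = FALSE, ...)
}

# noiseless shielded protocol for exactness checks
noiselessProtocol <- function(n = 64L, ...)
  deskFseProtocol(n = n, nex = 1L, charCount = 4L, rxNoiseSigma = 0, ...)

# world with a single instantaneous (1-tap) coupling per channel and low
# sensor noise: the scalar-coupling condition with a finite linear-oracle
# residual set by the noise floor
scalarCouplingWorld <- function(sensorNoiseSigma = 3e-4) {
  w <- ltiWorld(rxTapLength = 1L)
  w@coupling@sensorNoiseSigma <- sensorNoiseSigma
  w
}

# naive O(N*L) causal FIR convolution, the independent oracle for firApply
# and the coupling path
naiveFir <- function(h, x) {
  n <- length(x)
  y <- complex(n)
  for (i in seq_len(n))
    for (l in seq_len(min(length(h), i)))
      y[i] <- y[i] + h[l] * x[i - l + 1L]
  y
}

# hand-built record whose characterization windows hold prescribed receive
# and sensing data (for canceller identifiability tests); acquisition
# windows mirror the characterization data
syntheticRecord <- function(rxChar, sensChar, seed = 0L) {
  nW <- nrow(rxChar); H <- ncol(rxChar)
  prot <- protocolConfig("FSE3D", tr = 1500, te = 202, etl = 1L, nex = 1L,
                         matrixSize = c(H, as.integer(nW), 1L),
                         charCount = 1L, rxNoiseSigma = 0)
  lines <- data.frame(pe1 = seq_len(nW), pe2 = 1L, shot = seq_len(nW),
                      echo = 1L, nex = 1L, t0 = (seq_len(nW) - 1) * 1.5)
  new("AcquisitionRecord", protocol = prot, lines = lines,
      rxAcq = rxChar, rxChar = rxChar, sensAcq = sensChar,
      sensChar = sensChar, charTimes = (seq_len(nW) - 1) * 1.5 + 1.4,
      shieldedTwin = NULL,
      meta = list(seed = seed, emiOn = TRUE, emiBands = list(c(-2.5e4, 2.5e4))))
}

crnormArr <- function(dims, sigma = 1, seed = 1L) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims), sd = sigma / sqrt(2)),
                imaginary = rnorm(prod(dims), sd = sigma / sqrt(2))), dims)
}

# spoiled steady-state Bloch isochromat oracle for the GRE signal: iterate
# excitation + T1 recovery with perfect spoiling until steady state
blochGreOracle <- function(pd, t1, t2, tr, te, fa, iters = 5000L) {
  a <- fa * pi / 180
  mz <- 1
  for (i in seq_len(iters))
    mz <- 1 + (mz * cos(a) - 1) * exp(-tr / t1)
  pd * mz * sin(a) * exp(-te / t2)
}
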