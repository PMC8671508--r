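test_that("training sets are split 85/15 from characterization windows only", {
  sens <- crnormArr(c(100L, 16L, 10L), seed = 1L)
  rx <- crnormArr(c(100L, 16L), seed = 2L)
  rec <- syntheticRecord(rx, sens)
  tr <- assembleTraining(rec, trainConfig(seed = 3L))
  expect_equal(length(tr$train$idx), 85L)
  expect_equal(length(tr$val$idx), 15L)
  # disjoint partition covering all windows
  expect_length(intersect(tr$train$idx, tr$val$idx), 0L)
  expect_setequal(c(tr$train$idx, tr$val$idx), 1:100)
  # examples are exactly the (scaled) characterization data: window k of the
  # validation set reproduces rxChar[k, ]
  k <- tr$val$idx[1L]
  y <- tr$val$y[1L, , 1L] + 1i * tr$val$y[2L, , 1L]
  expect_equal(y * tr$scales[["y"]], rx[k, ], tolerance = 1e-12)
  x <- tr$val$x[1L, , 1L] + 1i * tr$val$x[2L, , 1L]
  expect_equal(matrix(x, 16L, 10L) * tr$scales[["x"]], sens[k, , ],
               tolerance = 1e-12)
})

test_that("too few characterization windows is a actionable error", {
  sens <- crnormArr(c(12L, 16L, 10L), seed = 1L)
  rec <- syntheticRecord(crnormArr(c(12L, 16L), seed = 2L), sens)
  expect_error(assembleTraining(rec), "NEX|charCount")
})

test_that("all-zero training data yields a zero model", {
  H <- 16L
  rec <- syntheticRecord(array(0+0i, c(24L, H)), array(0+0i, c(24L, H, 10L)))
  tc <- trainConfig(seed = 1L, epochs = 2L)
  m <- trainCnn(assembleTraining(rec, tc), tc)
  h <- trainingHistory(m)
  expect_lt(tail(h$val, 1L), 1e-8)
  pred <- predictEmi(m, array(0+0i, c(H, 10L)))
  expect_lt(max(Mod(pred)), 1e-6)
})

test_that("CNN training is seeded-deterministic and improves on epoch 0", {
  set.seed(99)   # unrelated ambient RNG state must not matter
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 8L)
  rec <- simulateScan(ph, prot, standardEmiWorld(), seed = 6L,
                      shieldedTwin = FALSE)
  tc <- trainConfig(seed = 6L, epochs = 3L)
  m1 <- trainCnn(assembleTraining(rec, tc), tc)
  m2 <- trainCnn(assembleTraining(rec, tc), tc)
  expect_equal(trainingHistory(m1)$val, trainingHistory(m2)$val,
               tolerance = 1e-12)
  h <- trainingHistory(m1)
  expect_lt(tail(h$val, 1L), h$val[1L])   # beats the untrained network
})

test_that("predictEmi validates stack shapes and is pure", {
  H <- 16L
  rec <- syntheticRecord(crnormArr(c(24L, H), seed = 4L),
                         crnormArr(c(24L, H, 10L), seed = 5L))
  tc <- trainConfig(seed = 2L, epochs = 1L)
  m <- trainCnn(assembleTraining(rec, tc), tc)
  expect_error(predictEmi(m, array(0+0i, c(H, 9L))), "10")
  s <- rec@sensChar[1L, , ]
  expect_identical(predictEmi(m, s), predictEmi(m, s))
  # batched and single-stack paths agree to single-precision rounding
  # (inference runs in float32; chunked GEMMs may round differently)
  expect_equal(predictEmi(m, rec@sensChar)[1L, ], predictEmi(m, s),
               tolerance = 1e-5)
})

test_that("a zero canceller leaves the record unchanged; per-scan training is enforced", {
  H <- 16L
  rec <- syntheticRecord(crnormArr(c(24L, H), seed = 6L),
                         crnormArr(c(24L, H, 10L), seed = 7L))
  tc <- trainConfig(seed = 2L, epochs = 1L)
  m <- trainCnn(assembleTraining(rec, tc), tc)
  # null out every parameter: predictions become exactly zero
  for (l in seq_along(m@net)) {
    m@net[[l]]$W[] <- 0; m@net[[l]]$b[] <- 0
    if (!is.null(m@net[[l]]$gamma)) {
      m@net[[l]]$gamma[] <- 0; m@net[[l]]$beta[] <- 0
      m@net[[l]]$rmean[] <- 0; m@net[[l]]$rvar[] <- 1
    }
  }
  clean <- cancelEmi(rec, m)
  expect_equal(clean@rxAcq, rec@rxAcq, tolerance = 1e-12)
  # applying to a different record violates the per-scan contract
  other <- syntheticRecord(crnormArr(c(24L, H), seed = 8L),
                           crnormArr(c(24L, H, 10L), seed = 9L))
  expect_error(cancelEmi(other, m), "per-scan")
})

test_that("linear canceller solves trivial and known-taps systems exactly", {
  H <- 32L; nW <- 30L
  sens <- crnormArr(c(nW, H, 10L), seed = 10L)
  # receive = 2 x (coil 1), single tap
  rec <- syntheticRecord(2 * sens[, , 1L], sens)
  lc <- fitLinearCanceller(rec, taps = 1L, reg = 0)
  expect_equal(lc@coef[1L, 1L], 2 + 0i, tolerance = 1e-10)
  expect_lt(max(Mod(lc@coef[-1L, ])), 1e-10)
  clean <- applyLinearCanceller(lc, rec)
  expect_lt(max(Mod(clean@rxAcq)), 1e-10)
  # ground-truth 4-tap coupling per coil, no noise -> taps recovered
  set.seed(11)
  taps <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 10L, 4L)
  rx <- matrix(0+0i, nW, H)
  for (i in seq_len(nW)) for (c in 1:10)
    rx[i, ] <- rx[i, ] + naiveFir(taps[c, ], sens[i, , c])
  rec2 <- syntheticRecord(rx, sens)
  lc2 <- fitLinearCanceller(rec2, taps = 4L, reg = 0)
  expect_lt(max(Mod(lc2@coef - taps)) / max(Mod(taps)), 1e-6)
})

test_that("rank-deficient designs error without regularization", {
  H <- 16L; nW <- 24L
  sens <- crnormArr(c(nW, H, 10L), seed = 12L)
  sens[, , 2L] <- sens[, , 1L]   # collinear coils
  rec <- syntheticRecord(sens[, , 1L], sens)
  expect_error(fitLinearCanceller(rec, taps = 1L, reg = 0), "rank|singular")
  lc <- fitLinearCanceller(rec, taps = 1L, reg = 1e-10)
  clean <- applyLinearCanceller(lc, rec)
  expect_lt(max(Mod(clean@rxAcq)), 1e-6)
})

test_that("the linear residual floor grows monotonically with sensor noise", {
  H <- 32L; nW <- 40L
  base <- crnormArr(c(nW, H, 10L), seed = 13L)
  rx <- 1.5 * base[, , 1L] - 0.5i * base[, , 4L]
  resid <- vapply(c(0, 1e-2, 5e-2, 2e-1), function(sig) {
    noisy <- base + crnormArr(c(nW, H, 10L), sigma = sig, seed = 14L)
    rec <- syntheticRecord(rx, noisy)
    lc <- fitLinearCanceller(rec, taps = 1L, reg = 1e-12)
    clean <- applyLinearCanceller(lc, rec)
    mean(Mod(clean@rxAcq)^2)
  }, 0)
  expect_true(all(diff(resid) > 0))
  expect_lt(resid[1L], 1e-20)
})

test_that("linear canceller restores a noiseless LTI world to the shielded twin", {
  ph <- smallPhantom(32L)
  prot <- deskFseProtocol(n = 32L, nex = 1L, charCount = 8L, rxNoiseSigma = 0)
  rec <- simulateScan(ph, prot, ltiWorld(), seed = 3L)
  lc <- fitLinearCanceller(rec, taps = 8L, reg = 1e-12)
  clean <- applyLinearCanceller(lc, rec)
  relEnergy <- sum(Mod(clean@rxAcq - shieldedTwin(rec)@rxAcq)^2) /
    sum(Mod(rec@meta$emiRxAcq)^2)
  expect_lt(relEnergy, 1e-8)
})
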