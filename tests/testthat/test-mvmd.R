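test_that("analytic half spectrum locates tones and is linear", {
  fs <- 100; N <- 1000
  t <- (0:(N - 1)) / fs
  x <- cos(2 * pi * 10 * t)
  st <- analyticHalfSpectrum(multichannelSignal(x, fs), mirrorExtend = FALSE)
  mag <- Mod(st$xHat[1, ])
  expect_equal(st$omegaGrid[which.max(mag)], 0.1)   # 10 Hz / 100 Hz

  # zero signal -> all-zero spectra
  z <- analyticHalfSpectrum(multichannelSignal(matrix(0, 1, 64), 64),
                            mirrorExtend = FALSE)
  expect_true(all(z$xHat == 0))

  # channel 2 = 2 x channel 1 -> spectra scale by exactly 2
  two <- analyticHalfSpectrum(multichannelSignal(rbind(x, 2 * x), fs),
                              mirrorExtend = FALSE)
  expect_equal(two$xHat[2, ], 2 * two$xHat[1, ])

  # direct DFT oracle on a short random signal
  set.seed(4)
  y <- rnorm(32)
  sty <- analyticHalfSpectrum(multichannelSignal(y, 32),
                              mirrorExtend = FALSE)
  k <- 0:16
  oracle <- vapply(k, function(kk)
    sum(y * exp(-2i * pi * kk * (0:31) / 32)), complex(1))
  expect_equal(sty$xHat[1, ], oracle, tolerance = 1e-12)

  # mirror extension doubles the grid
  stm <- analyticHalfSpectrum(multichannelSignal(y, 32), mirrorExtend = TRUE)
  expect_equal(stm$Tlen, 64L)
  expect_error(analyticHalfSpectrum(multichannelSignal(
    matrix(c(1, Inf, 2, 3), 1, 4), 4)), "finite")
})

test_that("mode update follows the Wiener filter on a toy spectrum", {
  # K = 1, lambda = 0, 4-bin spectrum: u = x / (1 + 2*alpha*(w - w1)^2)
  st <- makeSpectralState(K = 1, C = 1, Fbins = 4, seed = 2)
  st$uHat[] <- 0 + 0i
  st$omega <- 0.25
  alpha <- 100
  up <- updateModes(st, alpha)
  expected <- st$xHat[1, ] / (1 + 2 * alpha * (st$omegaGrid - 0.25)^2)
  expect_equal(up$uHat[1, 1, ], expected, tolerance = 1e-12)

  # at w = wk the denominator is 1: u equals the residual exactly
  atCenter <- which(st$omegaGrid == 0.25)
  expect_equal(up$uHat[1, 1, atCenter], st$xHat[1, atCenter])

  # alpha -> infinity kills everything off-center
  upBig <- updateModes(st, 1e12)
  offCenter <- st$omegaGrid != 0.25
  expect_true(all(Mod(upBig$uHat[1, 1, offCenter]) < 1e-9))
  expect_equal(upBig$uHat[1, 1, atCenter], st$xHat[1, atCenter])

  expect_error(updateModes(st, 0), "positive")
  expect_error(updateModes(st, -5), "positive")
})

test_that("mode updates are sequential in k", {
  # mode 2's update must see mode 1's NEW value: residual for k=2 is
  # x - u1_new + lambda/2, hand-computed here
  st <- makeSpectralState(K = 2, C = 1, Fbins = 6, seed = 3)
  alpha <- 50
  up <- updateModes(st, alpha)
  d1 <- 1 + 2 * alpha * (st$omegaGrid - st$omega[1])^2
  d2 <- 1 + 2 * alpha * (st$omegaGrid - st$omega[2])^2
  u1new <- (st$xHat[1, ] - st$uHat[2, 1, ]) / d1
  u2new <- (st$xHat[1, ] - u1new) / d2
  expect_equal(up$uHat[1, 1, ], u1new, tolerance = 1e-12)
  expect_equal(up$uHat[2, 1, ], u2new, tolerance = 1e-12)
})

test_that("center-frequency update is the power-weighted mean", {
  # concentrated in one bin -> omega equals that bin
  st <- makeSpectralState(K = 1, C = 1, Fbins = 8, seed = 5)
  st$uHat[] <- 0 + 0i
  st$uHat[1, 1, 5] <- 3 + 1i
  up <- updateCenterFreqs(st)
  expect_equal(up$omega[1], st$omegaGrid[5])

  # two equal-power bins at 0.1 and 0.3 -> 0.2
  st2 <- makeSpectralState(K = 1, C = 1, Fbins = 6, seed = 5)
  st2$omegaGrid <- seq(0, 0.5, by = 0.1)
  st2$uHat[] <- 0 + 0i
  st2$uHat[1, 1, 2] <- 2 + 0i    # 0.1
  st2$uHat[1, 1, 4] <- 0 + 2i    # 0.3, same power
  expect_equal(updateCenterFreqs(st2)$omega[1], 0.2)

  # random 8-bin spectra, 2 channels: brute-force weighted mean
  st3 <- makeSpectralState(K = 2, C = 2, Fbins = 8, seed = 6)
  up3 <- updateCenterFreqs(st3)
  for (k in 1:2) {
    num <- 0; den <- 0
    for (cc in 1:2) {
      pw <- Mod(st3$uHat[k, cc, ])^2
      num <- num + sum(st3$omegaGrid * pw)
      den <- den + sum(pw)
    }
    expect_equal(up3$omega[k], num / den, tolerance = 1e-12)
  }

  # all-zero mode spectrum: frozen with a warning
  st4 <- makeSpectralState(K = 2, C = 1, Fbins = 8, seed = 7)
  st4$uHat[2, , ] <- 0 + 0i
  old <- st4$omega[2]
  expect_warning(up4 <- updateCenterFreqs(st4), "frozen")
  expect_equal(up4$omega[2], old)
})

test_that("dual ascent follows the residual", {
  st <- makeSpectralState(K = 2, C = 2, Fbins = 8, seed = 8)
  # tau = 0 leaves duals identically zero
  expect_equal(updateDuals(st, tau = 0)$lambdaHat, st$lambdaHat)

  # exact reconstruction -> lambda unchanged for any tau
  stx <- st
  stx$xHat <- apply(stx$uHat, c(2, 3), sum)
  expect_equal(updateDuals(stx, tau = 0.7)$lambdaHat, stx$lambdaHat)

  # tau = 1, single-bin residual r -> lambda increases by r
  st1 <- makeSpectralState(K = 1, C = 1, Fbins = 4, seed = 9)
  st1$uHat[] <- 0 + 0i
  st1$xHat[] <- 0 + 0i
  st1$xHat[1, 2] <- 3 - 2i
  up <- updateDuals(st1, tau = 1)
  expect_equal(up$lambdaHat[1, 2], 3 - 2i)
  expect_true(all(up$lambdaHat[1, -2] == 0))
})

test_that("convergence statistic matches brute force and guards zeros", {
  u <- array(complex(real = rnorm(2 * 2 * 8), imaginary = rnorm(2 * 2 * 8)),
             c(2, 2, 8))
  expect_equal(hasConverged(u, u, 1e-7)$statistic, 0)
  expect_true(hasConverged(u, u, 1e-7)$converged)

  # curr = 2 * prev: each of the K*C terms is exactly 1
  res <- hasConverged(u, 2 * u, 1e-7)
  expect_equal(res$statistic, 2 * 2)
  expect_false(res$converged)

  # random perturbation: brute-force double sum
  set.seed(10)
  d <- array(complex(real = rnorm(2 * 2 * 8, sd = 0.01),
                     imaginary = rnorm(2 * 2 * 8, sd = 0.01)), c(2, 2, 8))
  stat <- hasConverged(u, u + d, 1e-7)$statistic
  brute <- 0
  for (k in 1:2) for (cc in 1:2)
    brute <- brute + sum(Mod(d[k, cc, ])^2) / sum(Mod(u[k, cc, ])^2)
  expect_equal(stat, brute, tolerance = 1e-12)

  # zero-norm previous modes contribute 0
  uz <- u; uz[1, 1, ] <- 0 + 0i
  expect_lt(hasConverged(uz, u, 1e-7)$statistic, brute + 3)

  expect_error(hasConverged(u, u[, , 1:4], 1e-7), "shape")
})

test_that("decompose recovers shared tones within 0.5 Hz", {
  g <- twoToneFixture(snrDb = 20, seed = 7)
  ms <- mvmdDecompose(g$signal, mvmdConfig(K = 2))
  expect_true(ms@converged)
  expect_equal(centerFreqs(ms), c(10, 25), tolerance = 0.5 / 10)
  expect_lt(max(abs(centerFreqs(ms) - c(10, 25))), 0.5)
  expect_equal(dim(modeArray(ms)), c(2L, 2L, 512L))

  # FFT peak oracle agrees mode by mode
  for (k in 1:2) {
    pk <- fftPeakHz(modeArray(ms)[k, 1, ], 128)
    expect_lt(abs(pk - c(10, 25)[k]), 0.5)
  }
})

test_that("decompose handles degenerate inputs per contract", {
  # zero signal -> all-zero modes
  z <- multichannelSignal(matrix(0, 2, 64), 64)
  msz <- suppressWarnings(mvmdDecompose(z, mvmdConfig(K = 3)))
  expect_true(all(modeArray(msz) == 0))

  # K >= N/2 rejected
  expect_error(mvmdDecompose(multichannelSignal(matrix(rnorm(16), 2, 8), 8),
                             mvmdConfig(K = 4)), "N/2")

  # max_iter reached: still returns, converged = FALSE
  g <- twoToneFixture()
  ms <- mvmdDecompose(g$signal, mvmdConfig(K = 2, maxIter = 3))
  expect_false(ms@converged)
  expect_equal(ms@nIter, 3L)
  expect_s4_class(ms, "ModeSet")
})

test_that("a 2-channel epoch with K=4 yields 8 IMF component series", {
  g <- twoToneFixture()
  ms <- mvmdDecompose(g$signal, mvmdConfig(K = 4, maxIter = 60))
  d <- dim(modeArray(ms))
  expect_equal(d[1] * d[2], 8L)
  expect_equal(length(centerFreqs(ms)), 4L)
  # mode alignment: exactly one center frequency per mode index
  expect_false(is.unsorted(centerFreqs(ms)))
})

test_that("decompose is scale- and channel-permutation-equivariant", {
  g <- twoToneFixture(snrDb = Inf, seed = 7)
  base <- mvmdDecompose(g$signal, mvmdConfig(K = 2))

  scaled <- mvmdDecompose(multichannelSignal(5 * samples(g$signal), 128),
                          mvmdConfig(K = 2))
  expect_equal(modeArray(scaled), 5 * modeArray(base), tolerance = 1e-10)
  expect_equal(centerFreqs(scaled), centerFreqs(base), tolerance = 1e-10)

  perm <- mvmdDecompose(multichannelSignal(samples(g$signal)[2:1, ], 128),
                        mvmdConfig(K = 2))
  expect_equal(modeArray(perm), modeArray(base)[, 2:1, ], tolerance = 1e-12)
  expect_equal(centerFreqs(perm), centerFreqs(base))
})

test_that("noiseless band-limited input reconstructs within 5 percent", {
  g <- twoToneFixture(snrDb = Inf, seed = 7)
  ms <- mvmdDecompose(g$signal, mvmdConfig(K = 2, alpha = 2000))
  expect_true(ms@converged)
  recon <- apply(modeArray(ms), c(2, 3), sum)
  relerr <- sqrt(sum((samples(g$signal) - recon)^2) /
                 sum(samples(g$signal)^2))
  expect_lte(relerr, 0.05)
})

test_that("convergence statistic has a non-increasing tail", {
  for (seed in c(7, 8)) {
    g <- twoToneFixture(snrDb = 20, seed = seed)
    ms <- mvmdDecompose(g$signal,
                        mvmdConfig(K = 2, tol = 1e-30, maxIter = 40))
    tail10 <- utils::tail(ms@history, 10)
    expect_true(all(diff(tail10) <= 1e-9))
  }
})

test_that("C=1 decomposition matches the independent VMD oracle", {
  set.seed(13)
  fs <- 64; N <- 256
  t <- (0:(N - 1)) / fs
  x <- cos(2 * pi * 5 * t) + 0.7 * cos(2 * pi * 18 * t) +
    0.05 * rnorm(N)
  ms <- mvmdDecompose(multichannelSignal(x, fs),
                      mvmdConfig(K = 2, tol = 1e-10))
  orc <- vmdOracle(x, K = 2, alpha = 2000, tol = 1e-10)
  rms <- sqrt(mean((modeArray(ms)[, 1, ] - orc$modes)^2))
  expect_lt(rms, 1e-6)
  expect_equal(centerFreqs(ms), orc$omega * fs, tolerance = 1e-8)

  # and on a longer signal at the N <= 512 bound
  y <- cos(2 * pi * 8 * (0:511) / 128) + 0.5 * cos(2 * pi * 30 * (0:511) / 128)
  ms2 <- mvmdDecompose(multichannelSignal(y, 128),
                       mvmdConfig(K = 2, tol = 1e-10))
  orc2 <- vmdOracle(y, K = 2, alpha = 2000, tol = 1e-10)
  expect_lt(sqrt(mean((modeArray(ms2)[, 1, ] - orc2$modes)^2)), 1e-6)
})

test_that("mode table dump is channel-major plain text", {
  g <- twoToneFixture()
  ms <- mvmdDecompose(g$signal, mvmdConfig(K = 2, maxIter = 40))
  f <- tempfile(fileext = ".tsv")
  writeModeTable(ms, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(ncol(tab), 4L)          # K*C columns
  expect_equal(nrow(tab), 512L)
  expect_equal(names(tab), c("ch1_imf1", "ch1_imf2", "ch2_imf1", "ch2_imf2"))
  expect_equal(tab$ch2_imf1, modeArray(ms)[1, 2, ], tolerance = 1e-6)
})
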