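# Shared fixtures and independent oracles for the test suite.

# Two-channel / two-tone fixture of the decomposition studies:
# shared 10 Hz and 25 Hz oscillators, fs = 128, N = 512.
twoToneFixture <- function(snrDb = 20, seed = 7) {
  genMultichannelTones(toneSpec(freqs = c(10, 25), channels = 2, fs = 128,
                                duration = 4, snrDb = snrDb, seed = seed))
}

# Independently coded single-channel VMD fixed-point iteration, used as
# the C = 1 reduction oracle. Full-length spectrum representation with the
# negative half zeroed (a different layout from the package's
# half-spectrum state), same variational updates and the same two-phase
# scheme: center-frequency estimation on the mirror-extended grid, final
# synthesis on the original support with frozen frequencies.
vmdOracle <- function(x, K, alpha = 2000, tau = 0, tol = 1e-7,
                      maxIter = 500, mirror = TRUE) {
  N <- length(x)

  runFixedPoint <- function(sig, omega, updateOmega) {
    Tlen <- length(sig)
    freqs <- (0:(Tlen - 1)) / Tlen
    pos <- which(freqs <= 0.5)               # nonnegative-frequency bins
    fx <- stats::fft(sig)
    fpos <- rep(0 + 0i, Tlen)
    fpos[pos] <- fx[pos]
    u <- matrix(0 + 0i, K, Tlen)
    lam <- rep(0 + 0i, Tlen)
    n <- 0L
    while (n < maxIter) {
      n <- n + 1L
      uprev <- u
      for (k in seq_len(K)) {
        sumOther <- if (K > 1L) colSums(u[-k, , drop = FALSE])
                    else rep(0 + 0i, Tlen)
        resid <- fpos - sumOther + lam / 2
        u[k, ] <- 0 + 0i
        u[k, pos] <- resid[pos] /
          (1 + 2 * alpha * (freqs[pos] - omega[k])^2)
      }
      if (updateOmega) {
        for (k in seq_len(K)) {
          pw <- Mod(u[k, pos])^2
          if (sum(pw) > 0)
            omega[k] <- sum(freqs[pos] * pw) / sum(pw)
        }
      }
      if (tau > 0)
        lam[pos] <- lam[pos] +
          tau * (fpos[pos] - colSums(u[, pos, drop = FALSE]))
      stat <- 0
      for (k in seq_len(K)) {
        np <- sum(Mod(uprev[k, pos])^2)
        if (np > 0) stat <- stat + sum(Mod(u[k, pos] - uprev[k, pos])^2) / np
      }
      if (stat < tol && n > 1L) break
    }
    list(u = u, omega = omega, pos = pos, Tlen = Tlen)
  }

  synthesize <- function(u, pos, Tlen) {
    even <- Tlen %% 2L == 0L
    Fb <- length(pos)
    t(apply(u, 1L, function(uh) {
      half <- uh[pos]
      full <- if (even) c(half, Conj(rev(half[2:(Fb - 1L)])))
              else      c(half, Conj(rev(half[2:Fb])))
      Re(stats::fft(full, inverse = TRUE)) / Tlen
    }))
  }

  omega0 <- (seq_len(K) - 0.5) * 0.5 / K
  if (mirror) {
    hl <- N %/% 2L
    hr <- N - hl
    ext <- c(x[hl:1], x, x[N:(N - hr + 1L)])
    est <- runFixedPoint(ext, omega0, updateOmega = TRUE)
    fin <- runFixedPoint(x, est$omega, updateOmega = FALSE)
  } else {
    fin <- runFixedPoint(x, omega0, updateOmega = TRUE)
  }
  modes <- synthesize(fin$u, fin$pos, fin$Tlen)[, seq_len(N), drop = FALSE]
  ord <- order(fin$omega)
  list(modes = modes[ord, , drop = FALSE], omega = fin$omega[ord])
}

# Dominant-frequency oracle: FFT peak location in Hz.
fftPeakHz <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1L)]
  mag[1L] <- 0                               # ignore DC
  (which.max(mag) - 1L) * fs / n
}

# Band power via the raw periodogram, independent of the package STFT.
bandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  p <- Mod(stats::fft(x))^2 / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}

# Random but valid SpectralState for operator-level tests.
makeSpectralState <- function(K, C, Fbins, seed = 1) {
  set.seed(seed)
  structure(list(
    xHat = matrix(complex(real = rnorm(C * Fbins),
                          imaginary = rnorm(C * Fbins)), C, Fbins),
    uHat = array(complex(real = rnorm(K * C * Fbins),
                         imaginary = rnorm(K * C * Fbins)),
                 c(K, C, Fbins)),
    lambdaHat = matrix(0 + 0i, C, Fbins),
    omega = sort(runif(K, 0, 0.5)),
    omegaGrid = seq(0, 0.5, length.out = Fbins),
    Tlen = 2L * (Fbins - 1L), nOrig = 2L * (Fbins - 1L), fs = 1,
    mirrored = FALSE), class = "SpectralState")
}
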