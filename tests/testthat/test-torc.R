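test_that("makeTorcSet produces paper-faithful TORC ensembles", {
  torcs <- makeTorcSet(30, seed = 7)
  expect_length(torcs, 30)
  for (tc in torcs) {
    expect_s4_class(tc, "TORC")
    expect_equal(nrow(tc@components), 6)
    expect_true(all(tc@components$density >= 0))
    expect_true(all(tc@components$density <= 1.4))
    expect_false(anyDuplicated(abs(tc@components$velocity)) > 0)
    expect_true(tc@duration >= 1 && tc@duration <= 2)
  }
  ## harmonic velocity families 4-24 and 8-48 Hz
  vmax <- vapply(torcs, function(tc) max(abs(tc@components$velocity)),
                 numeric(1))
  expect_setequal(unique(vmax), c(24, 48))
  ## seeding contract
  again <- makeTorcSet(30, seed = 7)
  expect_identical(lapply(torcs, slot, "components"),
                   lapply(again, slot, "components"))
  expect_error(makeTorcSet(0, seed = 1), "positive")
})

test_that("ripple envelope evaluates the superposition exactly", {
  cmp <- data.frame(amplitude = 1, velocity = 4, density = 1, phase = 0)
  ## cos(2*pi*(4 * 0.25 + 1 * 0.5)) = cos(3*pi) = -1
  expect_equal(rippleEnvelope(cmp, t = 0.25, x = 0.5)[1, 1], -1)
  ## density 0 removes the channel dependence
  flat <- data.frame(amplitude = 1, velocity = 4, density = 0, phase = 0)
  env <- rippleEnvelope(flat, t = seq(0, 1, 0.01), x = seq(0, 5, 0.5))
  expect_equal(env, matrix(cos(2 * pi * 4 * seq(0, 1, 0.01)),
                           nrow(env), ncol(env)), tolerance = 1e-12)
  ## zero amplitudes give a zero envelope
  z <- data.frame(amplitude = 0, velocity = 4, density = 1, phase = 1)
  expect_true(all(rippleEnvelope(z, t = 0:10 / 10, x = 0:4) == 0))
})

test_that("dynamicSpectrum sampling, Nyquist guard and linearity", {
  tc <- makeTorcSet(1, seed = 2, durations = 1.5)[[1]]
  ds <- dynamicSpectrum(tc, timeStep = 0.002)
  expect_equal(nrow(values(ds)), ceiling(1.5 / 0.002))
  expect_true(all(is.finite(values(ds))))
  expect_equal(diff(octaveCoords(ds)),
               rep(5 / 14, 14), tolerance = 1e-12)
  ## too-coarse step names the limiting velocity
  vmax <- max(abs(tc@components$velocity))
  expect_error(dynamicSpectrum(tc, timeStep = 1), as.character(vmax))
  ## linear in component amplitudes: sum of per-ripple spectra
  parts <- lapply(seq_len(6), function(i) {
    one <- tc
    one@components <- tc@components[i, ]
    values(dynamicSpectrum(one))
  })
  expect_equal(Reduce(`+`, parts), values(ds), tolerance = 1e-10)
  ## velocities are harmonics of 4 Hz, so a 1 s envelope covers whole
  ## ripple periods and every channel averages to zero
  tc1 <- makeTorcSet(1, seed = 9, durations = 1)[[1]]
  expect_lt(max(abs(colMeans(values(dynamicSpectrum(tc1))))), 1e-10)
})

test_that("waveform rendering respects duration, range and Nyquist", {
  tc <- makeTorcSet(1, seed = 4, durations = 1)[[1]]
  wav <- renderWaveform(tc, seed = 5)
  expect_true(max(abs(wav)) <= 1)
  expect_equal(length(wav), 48000, tolerance = 1)
  expect_error(renderWaveform(tc, sampleRate = 20000, seed = 5),
               "Nyquist")
  ## unmodulated carriers when all ripple amplitudes are zero
  tc0 <- tc
  tc0@components$amplitude <- rep(0, 6)
  wav0 <- renderWaveform(tc0, seed = 5)
  expect_true(max(abs(wav0)) <= 1)
  expect_equal(length(wav0), 48000, tolerance = 1)
})

test_that("a rendered single ripple modulates the periphery at its velocity", {
  ## one upward ripple at 6 Hz; the audio-path channel envelopes must be
  ## dominated by a 6 Hz component
  tc <- makeTorcSet(1, seed = 8, durations = 1)[[1]]
  tc@components <- data.frame(amplitude = 1, velocity = 6, density = 0.6,
                              phase = 0)
  wav <- renderWaveform(tc, seed = 3)
  r <- driveRate(wav, bank15)
  env <- r$rate[, 8] - mean(r$rate[, 8])
  spec <- Mod(fft(env))[2:40]                  # 1..39 Hz at 1 s duration
  expect_equal(which.max(spec), 6, tolerance = 1)
})

test_that("phi kernel symmetry and agreement with an FFT oracle", {
  dspecs <- lapply(makeTorcSet(3, seed = 6, nChannels = 4, octaves = 3,
                               durations = 1), dynamicSpectrum)
  phi <- phiKernel(dspecs, maxLag = 0.04)
  ## definition symmetry Phi(tau, x, x') = Phi(-tau, x', x)
  L <- (length(phi@lags) - 1) / 2
  for (u in 0:L)
    expect_equal(phi@full[L + 1 + u, , ], t(phi@full[L + 1 - u, , ]),
                 tolerance = 1e-10)
  ## independent FFT-based cross-correlation oracle, channel pair (1, 3)
  S <- values(dspecs[[1]])
  Tn <- nrow(S)
  pad <- 2^ceiling(log2(2 * Tn))
  f1 <- fft(c(S[, 1], rep(0, pad - Tn)))
  f3 <- fft(c(S[, 3], rep(0, pad - Tn)))
  cc <- Re(fft(f1 * Conj(f3), inverse = TRUE)) / pad
  ## cc[1 + u] = sum_t S[t, 1] S[t - u, 3] for u >= 0
  direct <- phiKernel(dspecs[1], maxLag = 0.04)
  for (u in 0:L)
    expect_equal(direct@full[L + 1 + u, 1, 3], cc[1 + u],
                 tolerance = 1e-8 * max(abs(cc)))
  ## degenerate ensemble
  z <- dspecs[[1]]
  z@values[] <- 0
  expect_true(all(phiKernel(list(z), maxLag = 0.02)@full == 0))
  ## mismatched axes are rejected
  other <- dynamicSpectrum(makeTorcSet(1, seed = 1)[[1]])
  expect_error(phiKernel(list(dspecs[[1]], other)), "share")
})
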