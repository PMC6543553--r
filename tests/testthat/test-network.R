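test_that("genome decoding: amplitudes, signs, and the 0-50 ms delay map", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(c(0L, 3L, 0L, -2L, 0L, 0L, 0L, 0L, 0L), 3, 3),
              istr = c(5L, -1L, 0L), idel = c(-5L, 0L, 5L))
  cfg <- decodeGenome(g, bank3)
  ## delay endpoints and midpoint of the linear code map
  expect_equal(cfg$inDelay, c(0, 25, 50))
  ## maximum conductance at the extreme code
  expect_equal(cfg$inAmp[1], neuronParams()$gm)
  expect_equal(cfg$inAmp[2], neuronParams()$gm / 5)
  expect_equal(cfg$inSign, c(1L, -1L, 0L))
  ## code 0 instantiates no synapse
  expect_equal(cfg$Wsign[1, 1], 0L)
  expect_equal(cfg$Wamp[1, 1], 0)
  ## signs select the reversal branch
  expect_equal(cfg$Wsign[2, 1], 1L)
  expect_equal(cfg$Wsign[1, 2], -1L)
  ## tonotopic distance-proportional cortico-cortical delay
  oct <- log2(channelFreqs(bank3) / 500)
  expect_equal(cfg$ccDelay, 2 + 3 * abs(outer(oct, oct, "-")))
  ## out-of-range codes are rejected
  expect_error(genome(matrix(6L, 3, 3), integer(3), integer(3)), "-5")
})

test_that("alpha conductance has the exact peak and gate", {
  expect_equal(alphaCurrent(0, 1), 0)
  expect_equal(alphaCurrent(-3, 1), 0)
  ## argmax at taus, peak amplitude * exp(-1)
  tt <- seq(0, 20, 0.001)
  y <- alphaCurrent(tt, amplitude = 3, taus = 2)
  expect_equal(tt[which.max(y)], 2, tolerance = 0.002)
  expect_equal(max(y), 3 * exp(-1), tolerance = 1e-6)
})

test_that("passive membrane relaxes exactly along the closed form", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(0L, 3, 3), integer(3), integer(3))
  cfg <- decodeGenome(g, bank3)
  rec <- simulateNetwork(cfg, durationMs = 50, traceV = TRUE, v0 = -60)
  p <- neuronParams()
  tt <- (0:(nrow(rec@vtrace) - 1)) * p$dt
  vexp <- p$vrest + (-60 - p$vrest) * exp(-tt / p$taum)
  expect_equal(rec@vtrace[, 1], vexp, tolerance = 1e-9)
  ## at rest with no input the membrane is a fixed point
  rec0 <- simulateNetwork(cfg, durationMs = 30, traceV = TRUE)
  expect_true(all(rec0@vtrace == p$vrest))
  expect_equal(sum(lengths(spikeTimes(rec0))), 0)
})

test_that("single excitatory input: PSP shape and transmission delay", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(0L, 3, 3), istr = c(0L, 3L, 0L),
              idel = c(0L, -4L, 0L))                  # 5 ms delay
  cfg <- decodeGenome(g, bank3)
  tr <- new("DischargeTrain", events = list(numeric(0), 0.010,
                                            numeric(0)),
            duration = 0.06, cf = channelFreqs(bank3))
  rec <- simulateNetwork(cfg, tr, traceV = TRUE)
  v <- rec@vtrace[, 2]
  p <- neuronParams()
  ## depolarizing PSP: rises above rest in the 2-10 ms after arrival
  ## (event 10 ms + 5 ms delay -> steps after 15 ms)
  arrive <- 15 / p$dt + 1
  expect_true(all(v[seq_len(arrive)] == p$vrest))
  win <- v[(arrive + 2 / p$dt):(arrive + 10 / p$dt)]
  expect_true(max(win) > p$vrest + 1)
  expect_true(max(v) < p$vth)                          # subthreshold PSP
})

test_that("strong input chain spikes only after events plus delay", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(0L, 3, 3), istr = c(0L, 5L, 0L),
              idel = c(0L, -4L, 0L))
  cfg <- decodeGenome(g, bank3)
  ev <- c(0.010, 0.0112, 0.020, 0.0212, 0.040, 0.0411)  # summating pairs
  tr <- new("DischargeTrain",
            events = list(numeric(0), ev, numeric(0)),
            duration = 0.08, cf = channelFreqs(bank3))
  rec <- simulateNetwork(cfg, tr)
  spk <- spikeTimes(rec, 2)
  expect_gt(length(spk), 0)
  ## every cortical spike follows some peripheral event by >= 5 ms
  for (s in spk)
    expect_true(any(s - (ev * 1000 + 5) >= 0 & s - (ev * 1000 + 5) < 10))
  expect_equal(sum(lengths(spikeTimes(rec)[-2])), 0)
})

test_that("tonic drive produces calibrated baseline firing that rises with input", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(0L, 3, 3), istr = c(0L, 5L, 0L),
              idel = c(0L, -4L, 0L))
  cfg <- decodeGenome(g, bank3, tonic = tonicForRate(10))
  silent <- simulateNetwork(cfg, durationMs = 2000)
  rate0 <- length(spikeTimes(silent, 1)) / 2
  expect_equal(rate0, 10, tolerance = 0.2)
  ## driven epochs raise the rate of the neuron with input
  tr <- generateDischarges(rateSignal(rep(200, 1000)), seed = 3)
  tr3 <- new("DischargeTrain",
             events = list(numeric(0), spikeTimes(tr, 1), numeric(0)),
             duration = 2, cf = channelFreqs(bank3))
  driven <- simulateNetwork(cfg, tr3)
  expect_gt(length(spikeTimes(driven, 2)) / 2, rate0 * 1.5)
})

test_that("refractory period, determinism, sign flip and dt convergence", {
  ds <- dynamicSpectrum(torcs5[[1]])
  r <- driveRate(ds, bank5)
  tr <- generateDischarges(r, seed = 17)
  cfg <- decodeGenome(truthGenome, bank5, tonic = tonicForRate(10))
  rec <- simulateNetwork(cfg, tr)
  ## no inter-spike interval below the refractory period
  for (i in seq_len(5)) {
    isi <- diff(spikeTimes(rec, i))
    if (length(isi)) expect_true(all(isi >= neuronParams()$refractory))
  }
  ## determinism
  expect_identical(spikeTimes(rec),
                   spikeTimes(simulateNetwork(cfg, tr)))
  ## flipping an excitatory synapse to inhibitory cannot increase the
  ## postsynaptic spike count
  gPlus <- genome(matrix(0L, 5, 5), istr = c(0L, 0L, 5L, 4L, 0L),
                  idel = c(0L, 0L, -4L, -4L, 0L))
  gPlus@W[4, 3] <- 3L
  gMinus <- gPlus
  gMinus@W[4, 3] <- -3L
  nPlus <- length(spikeTimes(simulateNetwork(
    decodeGenome(gPlus, bank5, tonic = tonicForRate(10)), tr), 3))
  nMinus <- length(spikeTimes(simulateNetwork(
    decodeGenome(gMinus, bank5, tonic = tonicForRate(10)), tr), 3))
  expect_lte(nMinus, nPlus)
  ## halving dt changes total spike count by < 5%
  pFine <- neuronParams(dt = 0.125)
  recFine <- simulateNetwork(decodeGenome(truthGenome, bank5, pars = pFine,
                                          tonic = tonicForRate(10, pFine)),
                             tr)
  n0 <- sum(lengths(spikeTimes(rec)))
  n1 <- sum(lengths(spikeTimes(recFine)))
  expect_lt(abs(n1 - n0) / n0, 0.05)
})

test_that("short simulations warn when delays exceed the duration", {
  bank3 <- cfGrid(3, 500, 2000)
  g <- genome(matrix(0L, 3, 3), istr = c(0L, 1L, 0L),
              idel = c(5L, 5L, 5L))                    # 50 ms delays
  cfg <- decodeGenome(g, bank3)
  expect_warning(simulateNetwork(cfg, durationMs = 10), "delay")
})
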