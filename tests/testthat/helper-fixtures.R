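# Shared fixtures, built once per test run. Everything is generated in
# code; the reduced 5-neuron problem (10 one-second TORCs, one stochastic
# repetition, 120 ms lag window) is the desk-scale configuration used for
# fitting and sensitivity tests.

bank15 <- cfGrid()
bank5 <- cfGrid(5, 500, 8000)

torcs5 <- makeTorcSet(10, seed = 3, nChannels = 5, octaves = 4,
                      durations = 1)

ctxReduced <- makeEvalContext(bank5, torcs5, seed = 21, reps = 1,
                              estCfg = estimationConfig(lagSpan = 120))

# reduced-scale ground truth: excitatory cochlear input to neuron 3
# (5 ms transmission delay), lateral inhibition from neuron 4
truthGenome <- local({
  W <- matrix(0L, 5, 5)
  W[4, 3] <- -4L
  genome(W, istr = c(0L, 0L, 5L, 4L, 0L), idel = c(0L, 0L, -4L, -4L, 0L))
})

singleInputGenome <- genome(matrix(0L, 5, 5),
                            istr = c(0L, 0L, 5L, 0L, 0L),
                            idel = c(0L, 0L, -4L, 0L, 0L))

# full-scale context (30 TORCs x 4 repetitions on the 15-channel bank),
# built lazily and cached because several files need it
.ctxFullCache <- new.env(parent = emptyenv())
ctxFull <- function() {
  if (is.null(.ctxFullCache$ctx)) {
    .ctxFullCache$torcs <- makeTorcSet(30, seed = 1)
    .ctxFullCache$ctx <- makeEvalContext(bank15, .ctxFullCache$torcs,
                                         seed = 11, reps = 4)
  }
  .ctxFullCache$ctx
}

# single-channel rate wrapper for the Poisson generator
rateSignal <- function(lambda, timeStep = 0.002) {
  list(rate = matrix(lambda, ncol = 1), timeStep = timeStep, cf = 1000)
}

# a tiny deterministic STRF for mask/cost/io tests
toySTRF <- function(values, lagStep = 2, cf = bank15@cf) {
  new("STRF", values = values, lagStep = lagStep,
      channelFreqs = cf[seq_len(ncol(values))])
}
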