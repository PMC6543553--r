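## Cortical network: integer genome decoding and the integrate-and-fire
## simulation (numerical core in src/lif.cpp).

#' Cortical neuron parameters
#'
#' Membrane and synapse constants of the integrate-and-fire cortical
#' neuron. The membrane obeys
#' \deqn{\tau_m dv/dt = (v_{rest} - v) + R_m g_{syn}(t)(v_{rev} - v) + tonic,}
#' with alpha-shaped synaptic conductances peaking \code{taus} ms after
#' each event. Synaptic drive is conductance-based: the driving force is
#' \code{(v_rev - v)}, with the excitatory reversal at \code{vE} and the
#' inhibitory at \code{vI}, so positive synaptic codes depolarize
#' (EPSPs) and negative codes hyperpolarize (IPSPs). After a spike the
#' membrane resets to \code{vK}, the after-hyperpolarization potential.
#'
#' Threshold, reset and refractory period are modeling defaults of this
#' package (declared, not tuned): \code{vth = -50} mV, reset to
#' \code{vK = -90} mV, \code{refractory = 1} ms.
#'
#' @param taum membrane time constant (ms).
#' @param vrest resting potential (mV).
#' @param Rm membrane resistance (MOhm).
#' @param vE,vI excitatory / inhibitory reversal potentials (mV).
#' @param vK reset / after-hyperpolarization potential (mV).
#' @param gm synaptic conductance scale per unit code (uS).
#' @param taus synaptic time constant (ms).
#' @param dt integration step (ms).
#' @param vth spike threshold (mV).
#' @param refractory absolute refractory period (ms).
#' @param tonic constant depolarizing drive (mV added to the leak
#'   equilibrium; 0 = off). See [tonicForRate()].
#' @return named list of parameters.
#' @export
#' @examples
#' neuronParams()$taum
neuronParams <- function(taum = 10, vrest = -70, Rm = 4, vE = -30,
                         vI = -90, vK = -90, gm = 2, taus = 2,
                         dt = 0.25, vth = -50, refractory = 1,
                         tonic = 0) {
  stopifnot(vK <= vrest, vrest < vth, vth < vE, dt > 0, taum > 0, taus > 0)
  list(taum = taum, vrest = vrest, Rm = Rm, vE = vE, vI = vI, vK = vK,
       gm = gm, taus = taus, dt = dt, vth = vth, refractory = refractory,
       tonic = tonic)
}

#' Tonic drive that yields a given silent firing rate
#'
#' Closed form from the deterministic leaky integrator: with constant
#' drive the period in silence is
#' \code{refractory + taum * log((vinf - vK)/(vinf - vth))}, so the drive
#' needed for \code{rate} Hz is \code{vinf - vrest} with
#' \code{vinf = (D*vth - vK)/(D - 1)}, \code{D = exp((1000/rate -
#' refractory)/taum)}.
#'
#' @param rate target firing rate in silence (Hz).
#' @param pars neuron parameters ([neuronParams()]).
#' @return tonic drive in mV.
#' @export
#' @examples
#' tonicForRate(10)
tonicForRate <- function(rate, pars = neuronParams()) {
  .assertScalar(rate, "rate")
  t <- 1000 / rate - pars$refractory
  D <- exp(t / pars$taum)
  vinf <- (D * pars$vth - pars$vK) / (D - 1)
  vinf - pars$vrest
}

#' Construct a genome
#'
#' @param W n x n integer matrix of cortico-cortical synaptic codes
#'   (row = presynaptic, column = postsynaptic), entries in \code{-5..5}.
#' @param istr integer(n) peripheral input strength codes.
#' @param idel integer(n) peripheral input delay codes.
#' @return a [Genome-class].
#' @export
#' @examples
#' g <- genome(matrix(0L, 3, 3), istr = c(0L, 5L, 0L), idel = c(0L, -4L, 0L))
genome <- function(W, istr, idel) {
  new("Genome", W = matrix(as.integer(round(W)), nrow(W), ncol(W)),
      istr = as.integer(round(istr)), idel = as.integer(round(idel)))
}

#' Rebuild a genome from its flat gene vector
#'
#' Gene order is column-major \code{W}, then \code{istr}, then \code{idel}
#' (the order used by the genetic algorithm and by [genomeVector()]).
#'
#' @param genes integer vector of length \code{n^2 + 2n}.
#' @param n number of neurons.
#' @return a [Genome-class].
#' @export
genomeFromVector <- function(genes, n) {
  stopifnot(length(genes) == n^2 + 2L * n)
  genome(matrix(genes[seq_len(n^2)], n, n),
         genes[n^2 + seq_len(n)],
         genes[n^2 + n + seq_len(n)])
}

#' Random genome
#'
#' Every gene uniform over the integer codes \code{-5..5}.
#'
#' @param n number of neurons.
#' @param seed integer seed.
#' @return a [Genome-class].
#' @export
randomGenome <- function(n, seed) {
  genes <- withr::with_seed(as.integer(seed),
                            sample(-5:5, n^2 + 2L * n, replace = TRUE))
  genomeFromVector(genes, n)
}

#' Labels of the genome parameters
#'
#' @param n number of neurons.
#' @return character vector: \code{"W[i,j]"} (synapse i to j) in
#'   column-major order, then \code{"istr[i]"}, then \code{"idel[i]"}.
#' @export
genomeLabels <- function(n) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  c(sprintf("W[%d,%d]", ij$i, ij$j),
    sprintf("istr[%d]", seq_len(n)),
    sprintf("idel[%d]", seq_len(n)))
}

#' Decode an integer genome into a runnable network configuration
#'
#' Synaptic codes scale the maximum conductance: amplitude
#' \code{gm * |code| / 5} (uS), so the extreme codes -5/+5 reach \code{gm}
#' and single synaptic events stay subthreshold -- cortical firing requires
#' temporal summation of synaptic potentials. The code sign selects the
#' reversal potential (excitatory for positive, inhibitory for negative);
#' code 0 means no synapse. Peripheral input
#' delay codes map linearly to \code{25 + 5 * idel} ms, so the codes
#' \code{-5..5} span the 0--50 ms transmission-delay range.
#' Cortico-cortical transmission delays are proportional to the tonotopic
#' separation of the two neurons:
#' \code{ccDelayBase + ccDelaySlope * |octave distance|} ms, reflecting
#' the distance-dependent latency of intracortical transmission along the
#' tonotopic axis.
#'
#' @param g a [Genome-class].
#' @param bank a [ChannelBank-class] with one channel per neuron.
#' @param pars neuron parameters ([neuronParams()]).
#' @param ccDelayBase,ccDelaySlope cortico-cortical delay intercept (ms)
#'   and slope (ms per octave of CF separation).
#' @param delayOverride optional numeric(n); non-NA entries replace the
#'   decoded peripheral delay (ms) of that neuron (used by diagnostic
#'   scenarios that need delays outside the codable 0--50 ms range).
#' @param tonic optional numeric: constant drive (mV) per neuron (recycled);
#'   defaults to \code{pars$tonic}.
#' @return a \code{NetworkConfig}: a list with elements \code{Wamp},
#'   \code{Wsign}, \code{ccDelay} (ms), \code{inAmp}, \code{inSign},
#'   \code{inDelay} (ms), \code{tonic}, \code{pars}, \code{cf}.
#' @export
#' @examples
#' g <- genome(matrix(0L, 3, 3), istr = c(0L, 5L, 0L), idel = c(0L, -4L, 0L))
#' cfg <- decodeGenome(g, cfGrid(3, 500, 2000))
#' cfg$inDelay   # code -4 -> 5 ms
decodeGenome <- function(g, bank, pars = neuronParams(),
                         ccDelayBase = 2, ccDelaySlope = 3,
                         delayOverride = NULL, tonic = pars$tonic) {
  stopifnot(is(g, "Genome"), is(bank, "ChannelBank"))
  validObject(g)
  n <- nrow(g@W)
  if (length(bank@cf) != n)
    stop("channel bank size must match the genome's neuron count")
  oct <- log2(bank@cf / bank@cf[1])
  ccDelay <- ccDelayBase + ccDelaySlope * abs(outer(oct, oct, "-"))
  inDelay <- 25 + 5 * as.numeric(g@idel)
  if (!is.null(delayOverride)) {
    stopifnot(length(delayOverride) == n)
    keep <- !is.na(delayOverride)
    inDelay[keep] <- delayOverride[keep]
  }
  structure(list(
    Wamp    = abs(g@W) / 5 * pars$gm,
    Wsign   = matrix(as.integer(sign(g@W)), n, n),
    ccDelay = ccDelay,
    inAmp   = abs(g@istr) / 5 * pars$gm,
    inSign  = as.integer(sign(g@istr)),
    inDelay = inDelay,
    tonic   = rep_len(tonic, n),
    pars    = pars,
    cf      = bank@cf
  ), class = "NetworkConfig")
}

#' Alpha synaptic conductance time course
#'
#' \code{amplitude * (t/taus) * exp(-t/taus)} for \code{t > 0}, zero
#' otherwise; peaks at \code{t = taus} with value \code{amplitude * exp(-1)}.
#'
#' @param t time since the synaptic event (ms); vectorized.
#' @param amplitude peak-scale amplitude (uS).
#' @param taus synaptic time constant (ms).
#' @return conductance values (uS).
#' @export
#' @examples
#' alphaCurrent(2, amplitude = 1, taus = 2)  # exp(-1)
alphaCurrent <- function(t, amplitude, taus = 2) {
  ifelse(t > 0, amplitude * (t / taus) * exp(-t / taus), 0)
}

#' Simulate the cortical network
#'
#' Fixed-step (default 0.25 ms) event-queue simulation of the fully
#' interconnected integrate-and-fire network. Peripheral channel c drives
#' cortical neuron c one-to-one, with the decoded per-neuron transmission
#' delay; cortico-cortical spikes arrive after the decoded tonotopic
#' delay. The simulation is deterministic: identical (config, inputs)
#' always yield an identical [SpikeRecord-class] (all stochasticity lives
#' in the peripheral discharge generator).
#'
#' @param config a \code{NetworkConfig} from [decodeGenome()].
#' @param inputs a [DischargeTrain-class] on the matching channel bank
#'   (times in seconds), or NULL for silence.
#' @param durationMs simulated time (ms); defaults to the input duration.
#' @param traceV record membrane-potential traces (default FALSE).
#' @param v0 initial membrane potential(s), mV; default \code{vrest}.
#' @return a [SpikeRecord-class] (spike times in ms).
#' @export
#' @examples
#' g <- genome(matrix(0L, 3, 3), istr = c(0L, 5L, 0L), idel = c(0L, -4L, 0L))
#' cfg <- decodeGenome(g, cfGrid(3, 500, 2000))
#' tr <- new("DischargeTrain", events = list(numeric(0), c(0.01, 0.02),
#'           numeric(0)), duration = 0.1, cf = cfGrid(3, 500, 2000)@cf)
#' simulateNetwork(cfg, tr)
simulateNetwork <- function(config, inputs = NULL, durationMs = NULL,
                            traceV = FALSE, v0 = NULL) {
  stopifnot(inherits(config, "NetworkConfig"))
  n <- nrow(config$Wamp)
  if (is.null(inputs)) {
    events <- rep(list(numeric(0)), n)
    if (is.null(durationMs)) stop("durationMs required when inputs is NULL")
  } else {
    stopifnot(is(inputs, "DischargeTrain"))
    if (length(inputs@events) != n)
      stop("input discharge train must have one channel per neuron")
    events <- lapply(inputs@events, function(e) e * 1000)  # s -> ms
    if (is.null(durationMs)) durationMs <- inputs@duration * 1000
  }
  maxDelay <- max(c(config$inDelay, config$ccDelay))
  if (durationMs < maxDelay)
    warning(sprintf("duration (%g ms) is shorter than the longest delay (%g ms)",
                    durationMs, maxDelay))
  pars <- config$pars
  if (is.null(v0)) v0 <- pars$vrest
  v0 <- rep_len(as.numeric(v0), n)
  res <- lifSimulateCpp(config$Wamp, config$Wsign, config$ccDelay,
                        config$inAmp, config$inSign, config$inDelay,
                        events, durationMs, pars, traceV, v0,
                        config$tonic)
  new("SpikeRecord", spikes = res$spikes, duration = durationMs,
      vtrace = res$vtrace, dt = pars$dt)
}
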