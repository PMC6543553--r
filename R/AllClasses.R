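## Central S4 containers. Everything downstream (periphery, network, STRF
## estimation, GA) speaks in terms of these classes; configuration objects
## (neuronParams, gaConfig, estimationConfig, ...) are plain named lists
## built by constructor functions.

#' TORC stimulus specification
#'
#' A temporally orthogonal ripple combination (TORC): the superposition of
#' a small number of moving spectral ripples, each a sinusoidal envelope of
#' density \eqn{\epsilon} (cycles/octave) drifting along the log-frequency
#' axis at velocity \eqn{\omega} (Hz) with phase \eqn{\phi} and amplitude
#' \eqn{a}. Within one TORC all ripple velocities are distinct in absolute
#' value, which makes their envelopes temporally orthogonal and the
#' ensemble autocorrelation close to a delta -- the property that licenses
#' plain reverse-correlation STRF estimation.
#'
#' @slot components data.frame with columns \code{amplitude} (>= 0),
#'   \code{velocity} (Hz, signed: negative drifts downward),
#'   \code{density} (cycles/octave, >= 0) and \code{phase} (radians).
#' @slot duration numeric(1), stimulus duration in seconds.
#' @slot fmin numeric(1), lowest channel frequency (Hz) of the spectral axis.
#' @slot octaves numeric(1), octave span of the spectral axis.
#' @slot nChannels integer(1), number of log-spaced spectral channels.
#' @slot id character(1) identifier.
#' @seealso [makeTorcSet()], [dynamicSpectrum()]
#' @exportClass TORC
setClass("TORC",
  representation(
    components = "data.frame",
    duration   = "numeric",
    fmin       = "numeric",
    octaves    = "numeric",
    nChannels  = "integer",
    id         = "character"
  )
)

setValidity("TORC", function(object) {
  cmp <- object@components
  need <- c("amplitude", "velocity", "density", "phase")
  if (!all(need %in% names(cmp)))
    return(sprintf("components must have columns %s",
                   paste(need, collapse = ", ")))
  if (any(cmp$amplitude < 0)) return("ripple amplitudes must be >= 0")
  if (any(cmp$density < 0)) return("ripple densities must be >= 0")
  av <- abs(cmp$velocity)
  if (anyDuplicated(av))
    return("ripple |velocities| within a TORC must be pairwise distinct")
  if (length(object@duration) != 1L || object@duration <= 0)
    return("duration must be a single positive number")
  if (object@nChannels < 2L) return("nChannels must be >= 2")
  if (object@fmin <= 0 || object@octaves <= 0)
    return("fmin and octaves must be positive")
  TRUE
})

#' Dynamic spectrum of a stimulus
#'
#' The time-varying spectral envelope \eqn{S(t, x)} of a stimulus, sampled
#' on a regular time grid and a uniform octave axis \eqn{x} (octaves above
#' the lowest channel frequency). This is the common currency between
#' stimulus synthesis and reverse-correlation STRF estimation.
#'
#' @slot values numeric matrix, time bin x channel.
#' @slot timeStep numeric(1), envelope sampling step in seconds.
#' @slot channelFreqs numeric, channel center frequencies in Hz (log-spaced).
#' @slot octave numeric, octave coordinate x of each channel.
#' @exportClass DynamicSpectrum
setClass("DynamicSpectrum",
  representation(
    values        = "matrix",
    timeStep      = "numeric",
    channelFreqs  = "numeric",
    octave        = "numeric"
  )
)

setValidity("DynamicSpectrum", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (ncol(object@values) != length(object@channelFreqs))
    return("ncol(values) must match length(channelFreqs)")
  if (length(object@octave) != length(object@channelFreqs))
    return("octave and channelFreqs lengths differ")
  if (object@timeStep <= 0) return("timeStep must be positive")
  dx <- diff(object@octave)
  if (length(dx) && diff(range(dx)) > 1e-9 * max(abs(dx)))
    return("octave coordinates must be uniformly spaced")
  TRUE
})

#' Tonotopic channel bank
#'
#' Center frequencies of the peripheral (auditory nerve) channels, evenly
#' spaced on a logarithmic frequency axis. Each peripheral channel drives
#' exactly one cortical neuron, so the bank also fixes the cortical
#' tonotopy.
#'
#' @slot cf numeric, strictly increasing center frequencies (Hz),
#'   geometrically spaced.
#' @seealso [cfGrid()]
#' @exportClass ChannelBank
setClass("ChannelBank", representation(cf = "numeric"))

setValidity("ChannelBank", function(object) {
  cf <- object@cf
  if (length(cf) < 2L) return("need at least two channels")
  if (any(cf <= 0) || any(diff(cf) <= 0))
    return("cf must be positive and strictly increasing")
  r <- cf[-1] / cf[-length(cf)]
  if (diff(range(r)) > 1e-9 * max(r))
    return("cf must be geometrically (log-)spaced")
  TRUE
})

#' Peripheral discharge trains
#'
#' Stochastic auditory-nerve event times per channel, the output of the
#' discharge generator of the peripheral front end.
#'
#' @slot events list of numeric vectors, one per channel; strictly
#'   increasing event times in seconds, all within \code{[0, duration]}.
#' @slot duration numeric(1), seconds.
#' @slot cf numeric, channel center frequencies (Hz).
#' @seealso [generateDischarges()]
#' @exportClass DischargeTrain
setClass("DischargeTrain",
  representation(events = "list", duration = "numeric", cf = "numeric")
)

setValidity("DischargeTrain", function(object) {
  if (length(object@events) != length(object@cf))
    return("one event vector per channel required")
  for (i in seq_along(object@events)) {
    ev <- object@events[[i]]
    if (length(ev)) {
      if (any(diff(ev) <= 0))
        return(sprintf("channel %d: event times must be strictly increasing", i))
      if (ev[1] < 0 || ev[length(ev)] > object@duration + 1e-9)
        return(sprintf("channel %d: event times outside [0, duration]", i))
    }
  }
  TRUE
})

#' Integer-coded network genome
#'
#' The search object of the genetic algorithm: every synaptic parameter of
#' the cortical network coded as an integer in \code{-5..5}. Positive codes
#' are excitatory, negative inhibitory, zero means no synapse. For an
#' n-neuron network the genome has \eqn{n^2 + 2n} genes; with the default
#' 15 neurons that is 255 (225 cortico-cortical weights plus 15 input
#' strengths plus 15 input-delay codes).
#'
#' @slot W integer matrix (n x n), cortico-cortical synaptic codes; row =
#'   presynaptic neuron, column = postsynaptic neuron.
#' @slot istr integer(n), peripheral input strength codes.
#' @slot idel integer(n), peripheral input delay codes (decoded linearly to
#'   a 0--50 ms transmission delay, see [decodeGenome()]).
#' @seealso [decodeGenome()], [randomGenome()], [genomeVector()]
#' @exportClass Genome
setClass("Genome",
  representation(W = "matrix", istr = "integer", idel = "integer")
)

setValidity("Genome", function(object) {
  n <- nrow(object@W)
  if (ncol(object@W) != n) return("W must be square")
  if (length(object@istr) != n || length(object@idel) != n)
    return("istr and idel must have length nrow(W)")
  g <- c(object@W, object@istr, object@idel)
  if (any(g != round(g))) return("genome entries must be integers")
  if (any(g < -5L) || any(g > 5L))
    return("genome entries must lie in [-5, 5]")
  TRUE
})

#' Cortical spike record
#'
#' Spike times of every neuron in a network simulation, with optional
#' membrane-potential traces.
#'
#' @slot spikes list of numeric vectors, one per neuron; sorted spike times
#'   in ms. Inter-spike intervals never fall below the refractory period.
#' @slot duration numeric(1), simulated time in ms.
#' @slot vtrace matrix or NULL-like empty matrix; membrane potential
#'   (mV) per time step (rows, including the initial state) and neuron
#'   (columns), present when tracing was requested.
#' @slot dt numeric(1), integration step in ms.
#' @seealso [simulateNetwork()]
#' @exportClass SpikeRecord
setClass("SpikeRecord",
  representation(spikes = "list", duration = "numeric",
                 vtrace = "matrix", dt = "numeric")
)

#' Spectrotemporal receptive field
#'
#' A lag x frequency-channel matrix describing how a neuron's firing rate
#' responds to stimulus spectral energy at each frequency and time lag; the
#' linear kernel estimated by reverse correlation. The lag axis starts at
#' zero.
#'
#' @slot values numeric matrix, lag bin x channel.
#' @slot lagStep numeric(1), lag step in ms.
#' @slot channelFreqs numeric, channel center frequencies (Hz).
#' @seealso [reverseCorrelate()], [strfCost()], [significanceMask()]
#' @exportClass STRF
setClass("STRF",
  representation(values = "matrix", lagStep = "numeric",
                 channelFreqs = "numeric")
)

setValidity("STRF", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (ncol(object@values) != length(object@channelFreqs))
    return("ncol(values) must match length(channelFreqs)")
  if (object@lagStep <= 0) return("lagStep must be positive")
  TRUE
})

#' Stimulus-ensemble spectrotemporal autocorrelation
#'
#' The kernel \eqn{\Phi(\tau, x', x)}: cross-correlation between channel
#' pairs of the ensemble's dynamic spectra, averaged over stimuli. For a
#' TORC ensemble it collapses to a function of the channel difference
#' \eqn{x - x'} concentrated at zero lag and zero difference, which is what
#' reduces reverse correlation to a simple convolution.
#'
#' @slot full numeric array, lag x channel x channel;
#'   \code{full[l, xp, x]} is \eqn{\Phi(\tau_l, x', x)}.
#' @slot lags numeric, lag values in seconds (symmetric around 0).
#' @slot collapsed numeric matrix, lag x channel difference (averaged over
#'   channel pairs at the same difference).
#' @slot channelDiff integer, signed channel-index differences for the
#'   columns of \code{collapsed}.
#' @seealso [phiKernel()]
#' @exportClass PhiKernel
setClass("PhiKernel",
  representation(full = "array", lags = "numeric",
                 collapsed = "matrix", channelDiff = "integer")
)

#' Perturbation sensitivity profile
#'
#' Normalized sensitivity of the fit cost to one-step perturbations of each
#' genome parameter: how much the significance-weighted STRF cost changes
#' when the parameter is moved by plus or minus one code step from the
#' fitted optimum. Scores are nonnegative and sum to one (when any score is
#' nonzero).
#'
#' @slot scores numeric, one score per genome parameter.
#' @slot labels character, parameter labels (\code{"W[i,j]"},
#'   \code{"istr[i]"}, \code{"idel[i]"}).
#' @seealso [sensitivityProfile()], [averageProfiles()], [importantParams()]
#' @exportClass SensitivityProfile
setClass("SensitivityProfile",
  representation(scores = "numeric", labels = "character")
)

setValidity("SensitivityProfile", function(object) {
  if (length(object@scores) != length(object@labels))
    return("scores and labels lengths differ")
  if (any(object@scores < -1e-12)) return("scores must be nonnegative")
  TRUE
})
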