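## Synthetic ground-truth scenarios: canonical single- and two-neuron
## genomes whose STRFs have known qualitative features, used to validate
## the forward pipeline and as fitting targets standing in for recorded
## STRFs (which are not distributed with the package).

#' Names of the built-in diagnostic scenarios
#' @return character vector of valid [makeScenario()] names.
#' @export
scenarioNames <- function() {
  c("excit_5k", "excit_2k5", "inhib_5k", "excit_5k_delay55",
    "lateral_inhib", "lateral_excit", "tonic_demo", "chirp_demo")
}

#' Build a diagnostic scenario
#'
#' Each scenario is a ground-truth [Genome-class] (single-input scenarios
#' use the maximal strength code 5, giving robust STRFs at short
#' simulation budgets) plus checkable predicates on the STRF estimated
#' from its own pipeline output:
#' \describe{
#'   \item{excit_5k}{excitatory cochlear input to the neuron tuned nearest
#'     5 kHz; positive STRF peak in that channel.}
#'   \item{excit_2k5}{as above at 2.5 kHz; the peak moves with the tuning.}
#'   \item{inhib_5k}{inhibitory cochlear input at 5 kHz (tonic firing
#'     reveals the suppression); negative STRF region in that channel.}
#'   \item{excit_5k_delay55}{excitatory input at 5 kHz with the
#'     cochlea-to-cortex transmission delay raised from 5 to 55 ms (an
#'     explicit delay override: 55 ms lies outside the codable 0--50 ms
#'     range); the STRF peak shifts ~50 ms later than excit_5k.}
#'   \item{lateral_inhib}{recorded neuron driven at 8 kHz; a second neuron
#'     driven at 3 kHz inhibits it; negative secondary region at 3 kHz,
#'     later than the 8 kHz primary (intracortical transmission delay).}
#'   \item{lateral_excit}{as above with an excitatory lateral connection
#'     from a 1.5 kHz neuron; positive secondary region at 1.5 kHz.}
#'   \item{tonic_demo}{excitatory input at 5 kHz plus tonic drive;
#'     baseline firing in silence, rate increase under stimulation.}
#'   \item{chirp_demo}{no genome; uses [chirpSignal()] to check that
#'     peripheral channels activate in center-frequency order.}
#' }
#'
#' @param name one of [scenarioNames()].
#' @param bank a [ChannelBank-class] (default [cfGrid()]).
#' @return list with \code{name}, \code{genome}, \code{tonic} (mV),
#'   \code{delayOverride}, \code{recordNeuron}, \code{channels} (named
#'   channel indices used), and \code{expect} (named list of feature
#'   parameters for the predicates).
#' @export
#' @examples
#' sc <- makeScenario("excit_5k")
#' sc$recordNeuron
makeScenario <- function(name, bank = cfGrid()) {
  if (!name %in% scenarioNames())
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(scenarioNames(), collapse = ", ")))
  n <- length(bank@cf)
  zeroW <- matrix(0L, n, n)
  ch <- function(f) nearestChannel(f, bank)
  base <- function(rec, istrCode = 5L, idelCode = -4L) {
    istr <- integer(n); idel <- integer(n)
    istr[rec] <- istrCode
    idel[rec] <- idelCode          # code -4 -> 5 ms transmission delay
    list(W = zeroW, istr = istr, idel = idel)
  }
  sc <- switch(name,
    excit_5k = {
      rec <- ch(5000)
      b <- base(rec)
      list(genome = genome(b$W, b$istr, b$idel), tonic = 0,
           delayOverride = NULL, recordNeuron = rec,
           channels = c(primary = rec),
           expect = list(sign = 1))
    },
    excit_2k5 = {
      rec <- ch(2500)
      b <- base(rec)
      list(genome = genome(b$W, b$istr, b$idel), tonic = 0,
           delayOverride = NULL, recordNeuron = rec,
           channels = c(primary = rec),
           expect = list(sign = 1))
    },
    inhib_5k = {
      rec <- ch(5000)
      b <- base(rec, istrCode = -5L)
      list(genome = genome(b$W, b$istr, b$idel),
           tonic = tonicForRate(30), delayOverride = NULL,
           recordNeuron = rec, channels = c(primary = rec),
           expect = list(sign = -1))
    },
    excit_5k_delay55 = {
      rec <- ch(5000)
      b <- base(rec)
      ov <- rep(NA_real_, n); ov[rec] <- 55
      list(genome = genome(b$W, b$istr, b$idel), tonic = 0,
           delayOverride = ov, recordNeuron = rec,
           channels = c(primary = rec),
           expect = list(sign = 1, delayShift = 50))
    },
    lateral_inhib = {
      rec <- ch(8000); lat <- ch(3000)
      b <- base(rec)
      b$istr[lat] <- 5L; b$idel[lat] <- -4L
      W <- zeroW; W[lat, rec] <- -5L
      list(genome = genome(W, b$istr, b$idel),
           tonic = tonicForRate(30), delayOverride = NULL,
           recordNeuron = rec,
           channels = c(primary = rec, secondary = lat),
           expect = list(sign = 1, secondarySign = -1))
    },
    lateral_excit = {
      rec <- ch(8000); lat <- ch(1500)
      b <- base(rec)
      b$istr[lat] <- 5L; b$idel[lat] <- -4L
      W <- zeroW; W[lat, rec] <- 5L
      list(genome = genome(W, b$istr, b$idel), tonic = 0,
           delayOverride = NULL, recordNeuron = rec,
           channels = c(primary = rec, secondary = lat),
           expect = list(sign = 1, secondarySign = 1))
    },
    tonic_demo = {
      rec <- ch(5000)
      b <- base(rec)
      list(genome = genome(b$W, b$istr, b$idel),
           tonic = tonicForRate(10), delayOverride = NULL,
           recordNeuron = rec, channels = c(primary = rec),
           expect = list(sign = 1, tonicRate = 10))
    },
    chirp_demo = {
      list(genome = NULL, tonic = 0, delayOverride = NULL,
           recordNeuron = NA_integer_, channels = integer(0),
           expect = list(ascending = TRUE))
    })
  c(list(name = name, bank = bank), sc)
}

#' Forward-simulate a scenario into a target STRF
#'
#' Runs the scenario's ground-truth genome through the full pipeline
#' (periphery -> network -> reverse correlation) using the given
#' evaluation context and returns the estimated STRF, e.g. for use as a
#' fitting target. The generating context (and hence its seeds) is
#' recorded in the result's attributes so recovery tests can reuse or vary
#' it.
#'
#' @param scenario from [makeScenario()].
#' @param ctx an \code{EvalContext} built on the scenario's bank (its
#'   \code{tonic} is overridden by the scenario's).
#' @return an [STRF-class] with attributes \code{recordNeuron} and
#'   \code{seed}.
#' @export
makeTarget <- function(scenario, ctx) {
  stopifnot(inherits(ctx, "EvalContext"))
  if (is.null(scenario$genome))
    stop(sprintf("scenario '%s' has no network genome", scenario$name))
  ctx$tonic <- scenario$tonic
  strf <- genomeStrf(scenario$genome, ctx, scenario$recordNeuron,
                     delayOverride = scenario$delayOverride)
  attr(strf, "recordNeuron") <- scenario$recordNeuron
  attr(strf, "seed") <- ctx$seed
  strf
}

#' Log-frequency chirp audio signal
#'
#' A tone sweeping from \code{f0} to \code{f1} linearly in log frequency
#' (constant octaves per second), used to verify that peripheral channels
#' activate in center-frequency order.
#'
#' @param f0,f1 start and end frequencies (Hz), inside the bank span.
#' @param duration seconds.
#' @param sampleRate audio sample rate (Hz, default 48000).
#' @return numeric audio vector in \code{[-1, 1]} with a \code{sampleRate}
#'   attribute.
#' @export
#' @examples
#' chirp <- chirpSignal(500, 16000, 0.5)
chirpSignal <- function(f0, f1, duration, sampleRate = 48000) {
  stopifnot(f0 > 0, f1 > 0, f0 != f1, duration > 0)
  ns <- round(duration * sampleRate)
  tt <- (seq_len(ns) - 1) / sampleRate
  r <- f1 / f0
  ## instantaneous frequency f0 * r^(t/T); phase is its time integral
  phase <- 2 * pi * f0 * duration / log(r) * (r^(tt / duration) - 1)
  sig <- sin(phase)
  attr(sig, "sampleRate") <- sampleRate
  sig
}
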