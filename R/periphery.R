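## Tonotopic peripheral front end: band-pass channelization of the
## stimulus into nonnegative drive rates, followed by an inhomogeneous
## Poisson discharge generator. The essential operation of the auditory
## periphery for STRF work is band-pass filtering into tonotopic channels;
## this front end keeps that operation and the discrete (Poisson) synaptic
## drive, and any substitute periphery returning a DischargeTrain on the
## same ChannelBank plugs into the cortical network unchanged.

#' Log-spaced tonotopic channel bank
#'
#' @param n number of channels (default 15).
#' @param fmin,fmax frequency bounds in Hz (defaults 500 and 16000: a
#'   5-octave tonotopic span).
#' @return a [ChannelBank-class] whose center frequencies form a geometric
#'   progression from \code{fmin} to \code{fmax} inclusive.
#' @export
#' @examples
#' cfGrid()                     # 15 channels, 0.5-16 kHz
#' channelFreqs(cfGrid(5, 500, 8000))
cfGrid <- function(n = 15L, fmin = 500, fmax = 16000) {
  if (n < 2L) stop("'n' must be >= 2")
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax")
  new("ChannelBank", cf = fmin * (fmax / fmin)^((0:(n - 1)) / (n - 1)))
}

#' Peripheral rate parameters
#'
#' @param rSpont spontaneous rate in events/s (default 20, a medium level
#'   of spontaneous activity).
#' @param rGain driven rate per unit envelope, events/s (default 150).
#' @param rMax saturation rate, events/s (default 400).
#' @param lowpass envelope low-pass cutoff (Hz) for the audio path
#'   (default 250).
#' @param gammatoneOrder filter order for the audio path (default 4).
#' @return named list of rate parameters.
#' @export
ratePars <- function(rSpont = 20, rGain = 150, rMax = 400,
                     lowpass = 250, gammatoneOrder = 4L) {
  list(rSpont = rSpont, rGain = rGain, rMax = rMax,
       lowpass = lowpass, gammatoneOrder = gammatoneOrder)
}

#' Instantaneous drive rate of each peripheral channel
#'
#' For a [DynamicSpectrum-class] input, each bank channel reads the
#' spectrum channel nearest its center frequency (on the octave axis) and
#' maps the half-wave rectified envelope affinely to a rate:
#' \code{lambda = rSpont + rGain * max(0, S)}, clipped to
#' \code{[0, rMax]}. For an audio-vector input (attribute
#' \code{sampleRate} required), the signal is passed through a gammatone
#' filter at each center frequency, half-wave rectified, low-pass filtered,
#' square-root compressed and peak-normalized before the same affine map.
#'
#' @param stimulus a [DynamicSpectrum-class], or a numeric audio vector
#'   with a \code{sampleRate} attribute.
#' @param bank a [ChannelBank-class].
#' @param pars rate parameters from [ratePars()].
#' @param timeStep output rate grid step (s) for the audio path
#'   (default 0.002).
#' @return list with elements \code{rate} (time bin x channel matrix,
#'   events/s), \code{timeStep} (s) and \code{cf}.
#' @export
#' @examples
#' ds <- dynamicSpectrum(makeTorcSet(1, seed = 1)[[1]])
#' r <- driveRate(ds, cfGrid())
#' range(r$rate)
driveRate <- function(stimulus, bank, pars = ratePars(),
                      timeStep = 0.002) {
  stopifnot(is(bank, "ChannelBank"))
  cf <- bank@cf
  if (is(stimulus, "DynamicSpectrum")) {
    fr <- stimulus@channelFreqs
    if (min(cf) < min(fr) * (1 - 1e-9) || max(cf) > max(fr) * (1 + 1e-9))
      stop("channel bank lies outside the stimulus frequency span")
    idx <- vapply(cf, function(f) which.min(abs(log2(fr / f))), integer(1))
    env <- stimulus@values[, idx, drop = FALSE]
    dt <- stimulus@timeStep
  } else if (is.numeric(stimulus)) {
    fs <- attr(stimulus, "sampleRate")
    if (is.null(fs)) stop("audio input needs a 'sampleRate' attribute")
    env <- .audioEnvelopes(stimulus, fs, cf, pars, timeStep)
    dt <- timeStep
  } else stop("stimulus must be a DynamicSpectrum or an audio vector")

  rate <- pars$rSpont + pars$rGain * pmax(env, 0)
  rate <- pmin(pmax(rate, 0), pars$rMax)
  list(rate = rate, timeStep = dt, cf = cf)
}

## Gammatone-bank envelope extraction for raw audio. FIR gammatone
## (truncated impulse response t^(o-1) e^(-2 pi b t) cos(2 pi f t) with
## b = 1.019 ERB(f)), applied by FFT convolution; half-wave rectification,
## 4th-order Butterworth low-pass, square-root compression, peak
## normalization across the bank, then binned to the rate grid.
.audioEnvelopes <- function(sig, fs, cf, pars, timeStep) {
  ns <- length(sig)
  tbin <- pmin(floor((seq_len(ns) - 0.5) / (fs * timeStep)) + 1,
               ceiling(ns / (fs * timeStep)))
  nb <- max(tbin)
  bf <- signal::butter(4, min(0.99, pars$lowpass / (fs / 2)), type = "low")
  env <- matrix(0, nb, length(cf))
  for (k in seq_along(cf)) {
    f <- cf[k]
    erb <- 24.7 * (4.37 * f / 1000 + 1)
    b <- 1.019 * erb
    tir <- seq(0, 4 / b, by = 1 / fs)
    ir <- tir^(pars$gammatoneOrder - 1) * exp(-2 * pi * b * tir) *
      cos(2 * pi * f * tir)
    ir <- ir / sum(abs(ir))
    y <- convolve(sig, rev(ir), type = "open")[seq_len(ns)]
    y <- pmax(0, y)                                   # half-wave rectify
    y <- signal::filtfilt(bf, y)                      # low-pass
    y <- sqrt(pmax(0, y))                             # compress
    env[, k] <- vapply(split(y, tbin), mean, numeric(1))
  }
  pk <- max(env)
  if (pk > 0) env <- env / pk
  env
}

#' Generate stochastic discharge trains from channel rates
#'
#' Per-channel inhomogeneous Poisson event generation by thinning against
#' the channel's maximum rate, with an optional absolute dead time applied
#' sequentially (refractoriness of the discharge generator). Deterministic
#' for a fixed seed.
#'
#' @param rate output of [driveRate()] (or any list with \code{rate},
#'   \code{timeStep}, \code{cf}); rates are treated as piecewise constant
#'   over each grid bin.
#' @param seed integer seed.
#' @param deadTime absolute dead time in seconds (default 0.00075); set to
#'   0 for exact Poisson statistics.
#' @return a [DischargeTrain-class].
#' @export
#' @examples
#' ds <- dynamicSpectrum(makeTorcSet(1, seed = 1)[[1]])
#' tr <- generateDischarges(driveRate(ds, cfGrid()), seed = 7)
#' tr
generateDischarges <- function(rate, seed, deadTime = 0.00075) {
  if (missing(seed)) stop("'seed' must be supplied")
  lam <- rate$rate
  if (any(lam < 0) || !all(is.finite(lam))) stop("rates must be finite and >= 0")
  dt <- rate$timeStep
  dur <- nrow(lam) * dt
  events <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(ncol(lam)), function(ch) {
      lmax <- max(lam[, ch])
      if (lmax <= 0) return(numeric(0))
      n <- rpois(1, lmax * dur)
      if (n == 0) return(numeric(0))
      cand <- sort(runif(n, 0, dur))
      bins <- pmin(floor(cand / dt) + 1, nrow(lam))
      keep <- runif(n) < lam[cbind(bins, ch)] / lmax
      ev <- unique(cand[keep])
      if (deadTime > 0 && length(ev) > 1) {
        out <- ev[1]
        last <- ev[1]
        for (t in ev[-1]) {
          if (t - last >= deadTime) {
            out <- c(out, t)
            last <- t
          }
        }
        ev <- out
      }
      ev
    })
  })
  new("DischargeTrain", events = events, duration = dur, cf = rate$cf)
}
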