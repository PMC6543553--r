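## TORC stimulus synthesis and the ensemble autocorrelation kernel.

#' Build a set of TORC stimuli
#'
#' Synthesizes the specification of a TORC ensemble. Each TORC superposes
#' \code{nRipples} moving ripples whose velocities are the harmonics
#' \eqn{k \Delta\omega}, k = 1..nRipples, of a per-TORC base rate
#' \eqn{\Delta\omega}; distinct harmonics make the ripple envelopes
#' temporally orthogonal within a TORC. Base rates alternate through
#' \code{baseRates} across the set (the default \{4, 8\} Hz gives sets
#' spanning 4--24 Hz and 8--48 Hz), drift direction alternates within each
#' TORC, ripple densities are drawn uniformly from
#' \code{[0, maxDensity]} cycles/octave and phases uniformly from
#' \code{[0, 2*pi)}. Durations cycle through \code{durations} seconds.
#'
#' @param nTorcs number of TORCs (a standard recording set uses 30).
#' @param seed integer seed; the same seed reproduces the set exactly.
#' @param nChannels,fmin,octaves spectral axis: \code{nChannels} log-spaced
#'   channels starting at \code{fmin} Hz and spanning \code{octaves}
#'   octaves (defaults match the 15-channel, 0.5--16 kHz periphery).
#' @param durations numeric vector of durations (s), recycled over the set;
#'   values in \code{[1, 2]} s match standard recording practice.
#' @param baseRates per-TORC ripple base rates (Hz), recycled.
#' @param nRipples ripples per TORC (default 6).
#' @param maxDensity upper bound of the ripple density range (cycles/octave,
#'   default 1.4).
#' @return list of [TORC-class] objects.
#' @export
#' @examples
#' torcs <- makeTorcSet(4, seed = 1)
#' torcs[[1]]
makeTorcSet <- function(nTorcs, seed, nChannels = 15L, fmin = 500,
                        octaves = 5, durations = c(1, 2),
                        baseRates = c(4, 8), nRipples = 6L,
                        maxDensity = 1.4) {
  if (length(nTorcs) != 1L || !is.finite(nTorcs) || nTorcs < 1)
    stop("'nTorcs' must be a positive count")
  if (missing(seed)) stop("'seed' must be supplied")
  nTorcs <- as.integer(nTorcs)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nTorcs), function(i) {
      base <- baseRates[((i - 1L) %% length(baseRates)) + 1L]
      k <- seq_len(nRipples)
      vel <- base * k * rep_len(c(1, -1), nRipples)
      new("TORC",
          components = data.frame(
            amplitude = rep(1, nRipples),
            velocity  = vel,
            density   = runif(nRipples, 0, maxDensity),
            phase     = runif(nRipples, 0, 2 * pi)
          ),
          duration  = durations[((i - 1L) %% length(durations)) + 1L],
          fmin      = fmin,
          octaves   = octaves,
          nChannels = as.integer(nChannels),
          id        = sprintf("torc_%02d", i))
    })
  })
}

#' Evaluate a ripple superposition envelope at arbitrary points
#'
#' The raw envelope \eqn{S(t, x) = \sum_i a_i \cos(2\pi(\omega_i t +
#' \epsilon_i x) + \phi_i)}. Exposed separately from [dynamicSpectrum()] so
#' the envelope can be checked at exact \code{(t, x)} points independent of
#' any sampling grid. \code{t} and \code{x} are recycled against each other
#' if one is scalar; otherwise evaluated elementwise on the outer grid.
#'
#' @param components data.frame with columns amplitude, velocity, density,
#'   phase (as in the \code{components} slot of a [TORC-class]).
#' @param t time(s) in seconds.
#' @param x octave coordinate(s).
#' @return matrix \code{length(t) x length(x)} of envelope values.
#' @export
#' @examples
#' cmp <- data.frame(amplitude = 1, velocity = 4, density = 1, phase = 0)
#' rippleEnvelope(cmp, t = 0.25, x = 0.5)  # cos(3*pi) = -1
rippleEnvelope <- function(components, t, x) {
  out <- matrix(0, length(t), length(x))
  for (i in seq_len(nrow(components))) {
    a   <- components$amplitude[i]
    w   <- components$velocity[i]
    eps <- components$density[i]
    phi <- components$phase[i]
    out <- out + a * cos(outer(2 * pi * w * t,
                               2 * pi * eps * x, "+") + phi)
  }
  out
}

#' Dynamic spectrum of a TORC
#'
#' Samples the ripple-superposition envelope on a regular time grid (bin
#' centers) and the TORC's log-spaced channel axis. The time step must
#' resolve the fastest ripple: \code{timeStep <= 1 / (2 * max |velocity|)}.
#' The amplitude scale follows the unit-amplitude convention of
#' [makeTorcSet()]; reverse correlation is scale-normalized downstream, so
#' the absolute envelope scale is arbitrary.
#'
#' @param spec a [TORC-class].
#' @param timeStep envelope sampling step in seconds (default 0.002, i.e.
#'   250 Hz, above twice the fastest default ripple velocity of 48 Hz).
#' @return a [DynamicSpectrum-class] with \code{ceiling(duration/timeStep)}
#'   rows.
#' @export
#' @examples
#' ds <- dynamicSpectrum(makeTorcSet(1, seed = 1)[[1]])
#' dim(values(ds))
dynamicSpectrum <- function(spec, timeStep = 0.002) {
  stopifnot(is(spec, "TORC"))
  .assertScalar(timeStep, "timeStep")
  vmax <- max(abs(spec@components$velocity))
  if (vmax > 0 && timeStep > 1 / (2 * vmax))
    stop(sprintf(
      "timeStep %g s is too coarse for ripple velocity %g Hz (need <= %g s)",
      timeStep, vmax, 1 / (2 * vmax)))
  nt <- ceiling(spec@duration / timeStep)
  tt <- (seq_len(nt) - 0.5) * timeStep
  x  <- .octaveAxis(spec@nChannels, spec@octaves)
  vals <- rippleEnvelope(spec@components, tt, x)
  new("DynamicSpectrum",
      values = vals, timeStep = timeStep,
      channelFreqs = spec@fmin * 2^x, octave = x)
}

#' Render a TORC as an audio waveform
#'
#' Standard ripple-stimulus rendering: a bank of log-spaced tone carriers
#' with fixed random phases, each amplitude-modulated by the envelope of
#' the nearest spectral channel. The envelope is applied as
#' \code{(1 + m * S / max|S|) / 2} with modulation depth \code{m}, clipped
#' at zero so modulation stays nonnegative, and the summed signal is
#' peak-normalized to \code{[-1, 1]}.
#'
#' @param spec a [TORC-class].
#' @param carriersPerOctave carrier density (default 20).
#' @param sampleRate audio sample rate in Hz (default 48000); must be at
#'   least twice the highest carrier frequency.
#' @param seed integer seed for the carrier phases.
#' @param depth modulation depth \code{m} in \code{[0, 1]} (default 0.9).
#' @param envelopeStep envelope sampling step (s) used internally.
#' @return numeric vector of audio samples in \code{[-1, 1]} with
#'   attributes \code{sampleRate}.
#' @export
#' @examples
#' wav <- renderWaveform(makeTorcSet(1, seed = 1)[[1]], seed = 2)
#' range(wav)
renderWaveform <- function(spec, carriersPerOctave = 20L,
                           sampleRate = 48000, seed, depth = 0.9,
                           envelopeStep = 0.002) {
  stopifnot(is(spec, "TORC"))
  if (missing(seed)) stop("'seed' must be supplied")
  fmax <- spec@fmin * 2^spec@octaves
  if (sampleRate < 2 * fmax)
    stop(sprintf("sampleRate %g Hz is below the Nyquist rate of the top carrier (%g Hz)",
                 sampleRate, 2 * fmax))
  nCar <- as.integer(round(carriersPerOctave * spec@octaves)) + 1L
  xc   <- seq(0, spec@octaves, length.out = nCar)
  fc   <- spec@fmin * 2^xc
  ns   <- round(spec@duration * sampleRate)
  tt   <- (seq_len(ns) - 1) / sampleRate

  ds  <- dynamicSpectrum(spec, envelopeStep)
  smax <- max(abs(ds@values))
  env  <- if (smax > 0) ds@values / smax else ds@values
  tEnv <- (seq_len(nrow(env)) - 0.5) * envelopeStep
  ## nearest spectral channel per carrier
  chan <- vapply(xc, function(x) which.min(abs(ds@octave - x)), integer(1))

  phases <- withr::with_seed(as.integer(seed), runif(nCar, 0, 2 * pi))
  sig <- numeric(ns)
  for (j in seq_len(nCar)) {
    ej <- approx(tEnv, env[, chan[j]], xout = tt, rule = 2)$y
    amp <- pmax(0, (1 + depth * ej) / 2)
    sig <- sig + amp * sin(2 * pi * fc[j] * tt + phases[j])
  }
  peak <- max(abs(sig))
  if (peak > 0) sig <- sig / peak
  attr(sig, "sampleRate") <- sampleRate
  sig
}

#' Spectrotemporal autocorrelation of a stimulus ensemble
#'
#' Computes \eqn{\Phi(\tau, x', x) = \langle \sum_t S(t, x') S(t - \tau, x)
#' \rangle}, the lagged channel-pair product of the dynamic spectra
#' averaged over the ensemble, together with its channel-difference
#' collapsed form. For a TORC ensemble the collapsed kernel is concentrated
#' at zero lag and zero channel difference, which is what justifies
#' estimating STRFs by per-channel power-normalized reverse correlation
#' instead of a full deconvolution.
#'
#' @param dspecs list of [DynamicSpectrum-class] objects sharing channel
#'   axis and time step.
#' @param maxLag maximum lag in seconds (default 0.25).
#' @return a [PhiKernel-class].
#' @export
#' @examples
#' ds <- lapply(makeTorcSet(2, seed = 1), dynamicSpectrum)
#' phi <- phiKernel(ds, maxLag = 0.05)
phiKernel <- function(dspecs, maxLag = 0.25) {
  stopifnot(length(dspecs) >= 1)
  ref <- dspecs[[1]]
  for (d in dspecs) {
    stopifnot(is(d, "DynamicSpectrum"))
    if (abs(d@timeStep - ref@timeStep) > 1e-12 ||
        length(d@channelFreqs) != length(ref@channelFreqs) ||
        max(abs(d@octave - ref@octave)) > 1e-9)
      stop("all dynamic spectra must share channel axis and time step")
  }
  dt <- ref@timeStep
  L  <- as.integer(floor(maxLag / dt))
  nc <- length(ref@channelFreqs)
  lagsIdx <- (-L):L
  full <- array(0, dim = c(length(lagsIdx), nc, nc))
  for (d in dspecs) {
    S <- d@values
    Tn <- nrow(S)
    for (li in seq_along(lagsIdx)) {
      u <- lagsIdx[li]
      ## Phi(u, x', x) = sum_t S[t, x'] S[t - u, x]
      if (u >= 0) {
        if (u < Tn)
          full[li, , ] <- full[li, , ] +
            crossprod(S[(1 + u):Tn, , drop = FALSE],
                      S[1:(Tn - u), , drop = FALSE])
      } else {
        v <- -u
        if (v < Tn)
          full[li, , ] <- full[li, , ] +
            crossprod(S[1:(Tn - v), , drop = FALSE],
                      S[(1 + v):Tn, , drop = FALSE])
      }
    }
  }
  full <- full / length(dspecs)
  diffs <- (-(nc - 1L)):(nc - 1L)
  collapsed <- matrix(0, length(lagsIdx), length(diffs))
  for (di in seq_along(diffs)) {
    dd <- diffs[di]
    pairs <- which(outer(seq_len(nc), seq_len(nc),
                         function(x, xp) x - xp) == dd, arr.ind = TRUE)
    ## full is indexed [lag, x', x]; diff is x - x'
    acc <- 0
    for (r in seq_len(nrow(pairs)))
      acc <- acc + full[, pairs[r, 2], pairs[r, 1]]
    collapsed[, di] <- acc / nrow(pairs)
  }
  new("PhiKernel", full = full, lags = lagsIdx * dt,
      collapsed = collapsed, channelDiff = as.integer(diffs))
}
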