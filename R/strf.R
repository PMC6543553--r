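## Reverse-correlation STRF estimation, significance masking and the
## significance-weighted cost used for model fitting.

#' STRF estimation configuration
#'
#' @param lagSpan lag window length in ms (default 250; the STRF covers
#'   lags 0..lagSpan).
#' @param lagStep lag step in ms; must equal the envelope time step
#'   (default 2).
#' @param normalization \code{"power"} (divide each channel by the
#'   ensemble's per-channel envelope power -- the TORC
#'   autocorrelation-is-a-delta reduction) or \code{"raw"}.
#' @return named list.
#' @export
estimationConfig <- function(lagSpan = 250, lagStep = 2,
                             normalization = c("power", "raw")) {
  stopifnot(lagSpan >= lagStep, lagStep > 0)
  list(lagSpan = lagSpan, lagStep = lagStep,
       normalization = match.arg(normalization))
}

#' Estimate an STRF by reverse correlation
#'
#' Computes \eqn{C(\tau, x) = (1/T) \sum_{spikes} S(t_{spike} - \tau, x)},
#' accumulated over stimuli and repetitions: the average stimulus envelope
#' preceding each spike. Spike times are binned to the envelope grid;
#' lags reaching before stimulus onset contribute nothing. With
#' \code{normalization = "power"} each channel is divided by the
#' ensemble's per-channel mean envelope power \eqn{(1/T)\sum_t S(t,x)^2},
#' which for a TORC ensemble (whose autocorrelation is concentrated at
#' zero lag and zero channel difference, see [phiKernel()]) recovers the
#' STRF up to that diagonal approximation.
#'
#' @param dspecs list of [DynamicSpectrum-class] objects (shared axes).
#' @param responses responses aligned to stimulus onsets: a list parallel
#'   to \code{dspecs}. With \code{type = "spikes"} (default) each element
#'   is a numeric vector of spike times in seconds, or a list of such
#'   vectors (one per repetition); with \code{type = "rate"} each element
#'   is a rate vector on the envelope grid (same length as the spectrum's
#'   time axis).
#' @param cfg an [estimationConfig()].
#' @param type how to interpret \code{responses} (see above).
#' @return an [STRF-class].
#' @export
#' @examples
#' ds <- lapply(makeTorcSet(2, seed = 1, durations = 1), dynamicSpectrum)
#' resp <- list(c(0.1, 0.5), c(0.2, 0.3, 0.9))
#' reverseCorrelate(ds, resp, estimationConfig(lagSpan = 100))
reverseCorrelate <- function(dspecs, responses, cfg = estimationConfig(),
                             type = c("spikes", "rate")) {
  type <- match.arg(type)
  stopifnot(length(dspecs) == length(responses), length(dspecs) >= 1)
  ref <- dspecs[[1]]
  dt <- ref@timeStep
  if (abs(cfg$lagStep / 1000 - dt) > 1e-12)
    stop("cfg$lagStep must equal the envelope time step")
  nLag <- as.integer(round(cfg$lagSpan / cfg$lagStep)) + 1L
  nc <- length(ref@channelFreqs)
  acc <- matrix(0, nLag, nc)
  Ttot <- 0
  power <- numeric(nc)

  for (s in seq_along(dspecs)) {
    S <- dspecs[[s]]@values
    Tn <- nrow(S)
    if (nLag - 1L >= Tn)
      stop("lag span exceeds the stimulus duration")
    if (abs(dspecs[[s]]@timeStep - dt) > 1e-12 ||
        ncol(S) != nc)
      stop("all dynamic spectra must share channel axis and time step")
    resp <- responses[[s]]
    if (type == "rate") {
      if (!is.numeric(resp) || length(resp) != Tn)
        stop("rate responses must match the envelope time axis")
      nrep <- 1L
      acc <- acc + .lagCorr(S, resp, nLag)
    } else {
      if (!is.list(resp)) resp <- list(resp)
      nrep <- length(resp)
      for (rep in seq_along(resp)) {
        st <- resp[[rep]]
        if (length(st) && any(diff(st) < 0))
          stop("spike times must be sorted")
        r <- tabulate(pmin(pmax(floor(st / dt) + 1, 1L), Tn), nbins = Tn)
        acc <- acc + .lagCorr(S, r, nLag)
      }
    }
    Ttot <- Ttot + Tn * dt * nrep
    power <- power + colSums(S^2) * dt * nrep
  }
  vals <- acc / Ttot
  if (cfg$normalization == "power") {
    p <- power / Ttot
    p[p <= 0] <- 1
    vals <- sweep(vals, 2, p, "/")
  }
  new("STRF", values = vals, lagStep = cfg$lagStep,
      channelFreqs = ref@channelFreqs)
}

## C[l, x] = sum_t S[t - l, x] * r[t], lags l = 0..nLag-1 (bins)
.lagCorr <- function(S, r, nLag) {
  Tn <- nrow(S)
  out <- matrix(0, nLag, ncol(S))
  nz <- which(r != 0)
  if (!length(nz)) return(out)
  for (l in 0:(nLag - 1L)) {
    tt <- nz[nz > l]
    if (length(tt))
      out[l + 1L, ] <- crossprod(S[tt - l, , drop = FALSE], r[tt])
  }
  out
}

#' Significance mask of an STRF
#'
#' A point is significant when it lies at least 3 standard deviations from
#' the mean of the whole STRF (two-sided, so inhibitory regions can be
#' significant). Significant points receive weight 1 in the fit cost,
#' non-significant points weight 0.1. A constant STRF (zero s.d.) yields
#' an empty mask.
#'
#' @param strf an [STRF-class].
#' @param nsd significance threshold in standard deviations (default 3).
#' @return list with logical matrix \code{mask} and numeric matrix
#'   \code{weights} (entries 1 where significant, 0.1 elsewhere).
#' @export
#' @examples
#' m <- matrix(0, 20, 15); m[5, 9] <- 10
#' s <- new("STRF", values = m, lagStep = 2, channelFreqs = cfGrid()@cf)
#' sum(significanceMask(s)$mask)
significanceMask <- function(strf, nsd = 3) {
  stopifnot(is(strf, "STRF"))
  v <- strf@values
  s <- sd(v)
  mask <- if (is.na(s) || s == 0) {
    matrix(FALSE, nrow(v), ncol(v))
  } else {
    abs(v - mean(v)) >= nsd * s
  }
  list(mask = mask, weights = ifelse(mask, 1, 0.1))
}

#' Significance-weighted cost between a model and a target STRF
#'
#' The cost is \eqn{\sum |M - E| \cdot sig(E)} with \eqn{sig} the
#' significance weights of the \emph{target} (1 on significant points,
#' 0.1 elsewhere). By default the STRFs are compared on their native
#' scale, which is meaningful whenever model and target are estimated by
#' the same reverse-correlation pipeline from the same stimulus ensemble
#' (as in all fitting contexts of this package) and keeps the cost
#' sensitive to input-gain changes. Set \code{normalize = TRUE} to
#' compare shapes only (both normalized to unit maximum absolute value),
#' e.g. against a target on an incommensurate amplitude scale.
#'
#' @param model,target congruent [STRF-class] objects (same lag and
#'   channel axes).
#' @param normalize normalize both to unit max |value| first (default
#'   FALSE).
#' @return scalar cost (0 for identical STRFs).
#' @export
strfCost <- function(model, target, normalize = FALSE) {
  stopifnot(is(model, "STRF"), is(target, "STRF"))
  if (!all(dim(model@values) == dim(target@values)))
    stop("model and target STRFs must have identical dimensions")
  if (abs(model@lagStep - target@lagStep) > 1e-9 ||
      max(abs(log(model@channelFreqs / target@channelFreqs))) > 1e-9)
    stop("model and target STRFs must share lag and channel axes")
  M <- model@values
  E <- target@values
  if (normalize) {
    if (max(abs(M)) > 0) M <- M / max(abs(M))
    if (max(abs(E)) > 0) E <- E / max(abs(E))
  }
  w <- significanceMask(new("STRF", values = E, lagStep = target@lagStep,
                            channelFreqs = target@channelFreqs))$weights
  sum(abs(M - E) * w)
}

#' Best frequency of an STRF
#'
#' The channel frequency carrying the maximum positive STRF value (the
#' frequency producing the largest spiking response); ties resolve to the
#' lower channel index.
#'
#' @param strf an [STRF-class].
#' @return best frequency in Hz.
#' @export
bestFrequency <- function(strf) {
  stopifnot(is(strf, "STRF"))
  v <- strf@values
  if (all(v <= 0))
    stop("best frequency undefined: STRF has no positive values")
  ch <- which(v == max(v), arr.ind = TRUE)
  strf@channelFreqs[min(ch[, "col"])]
}

#' Heatmap of an STRF
#'
#' @param strf an [STRF-class].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plotStrf <- function(strf, main = "STRF", ...) {
  v <- strf@values
  lim <- max(abs(v), 1e-12)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  lags <- (seq_len(nrow(v)) - 1) * strf@lagStep
  graphics::image(lags, log2(strf@channelFreqs), v, zlim = c(-lim, lim),
                  col = pal, xlab = "lag (ms)",
                  ylab = "frequency (log2 Hz)", main = main, ...)
  invisible(v)
}
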