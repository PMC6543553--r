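#' @name accessors
#' @title Accessors for strfnet S4 classes
#'
#' @description Slot access for the package's containers goes through these
#' accessors rather than \code{@}: \code{values()} returns the numeric
#' matrix of a [DynamicSpectrum-class] or [STRF-class]; \code{timeStep()}
#' and \code{lagStep()} the sampling steps; \code{channelFreqs()} the
#' channel center frequencies of a spectrum, STRF or [ChannelBank-class];
#' \code{octaveCoords()} the octave axis; \code{spikeTimes()} the
#' per-neuron spike times (ms) of a [SpikeRecord-class] or the per-channel
#' event times (s) of a [DischargeTrain-class]; \code{genomeVector()} /
#' \code{nNeurons()} the flat integer vector and neuron count of a
#' [Genome-class]; \code{sensScores()} the scores of a
#' [SensitivityProfile-class].
#'
#' @param x object.
#' @param i optional neuron/channel index for \code{spikeTimes}.
#' @return See description.
#' @aliases values timeStep lagStep channelFreqs octaveCoords spikeTimes
#'   genomeVector nNeurons sensScores
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setGeneric("lagStep", function(x) standardGeneric("lagStep"))
#' @rdname accessors
#' @export
setGeneric("channelFreqs", function(x) standardGeneric("channelFreqs"))
#' @rdname accessors
#' @export
setGeneric("octaveCoords", function(x) standardGeneric("octaveCoords"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x, i) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("genomeVector", function(x) standardGeneric("genomeVector"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("sensScores", function(x) standardGeneric("sensScores"))

#' @rdname accessors
setMethod("values", "DynamicSpectrum", function(x) x@values)
#' @rdname accessors
setMethod("values", "STRF", function(x) x@values)
#' @rdname accessors
setMethod("timeStep", "DynamicSpectrum", function(x) x@timeStep)
#' @rdname accessors
setMethod("lagStep", "STRF", function(x) x@lagStep)
#' @rdname accessors
setMethod("channelFreqs", "DynamicSpectrum", function(x) x@channelFreqs)
#' @rdname accessors
setMethod("channelFreqs", "STRF", function(x) x@channelFreqs)
#' @rdname accessors
setMethod("channelFreqs", "ChannelBank", function(x) x@cf)
#' @rdname accessors
setMethod("channelFreqs", "DischargeTrain", function(x) x@cf)
#' @rdname accessors
setMethod("octaveCoords", "DynamicSpectrum", function(x) x@octave)
#' @rdname accessors
setMethod("octaveCoords", "ChannelBank",
          function(x) log2(x@cf / x@cf[1]))
#' @rdname accessors
setMethod("spikeTimes", "SpikeRecord", function(x, i) {
  if (missing(i)) x@spikes else x@spikes[[i]]
})
#' @rdname accessors
setMethod("spikeTimes", "DischargeTrain", function(x, i) {
  if (missing(i)) x@events else x@events[[i]]
})
#' @rdname accessors
setMethod("genomeVector", "Genome",
          function(x) c(as.integer(x@W), x@istr, x@idel))
#' @rdname accessors
setMethod("nNeurons", "Genome", function(x) nrow(x@W))
#' @rdname accessors
setMethod("nNeurons", "SpikeRecord", function(x) length(x@spikes))
#' @rdname accessors
setMethod("sensScores", "SensitivityProfile", function(x) {
  stats::setNames(x@scores, x@labels)
})

setMethod("show", "TORC", function(object) {
  cat(sprintf("TORC '%s': %d ripples, %.3g s, %d channels over %g octaves from %g Hz\n",
              object@id, nrow(object@components), object@duration,
              object@nChannels, object@octaves, object@fmin))
  cat(sprintf("  velocities (Hz): %s\n",
              paste(signif(object@components$velocity, 3), collapse = ", ")))
  cat(sprintf("  densities (cyc/oct): %s\n",
              paste(signif(object@components$density, 3), collapse = ", ")))
})

setMethod("show", "DynamicSpectrum", function(object) {
  cat(sprintf("DynamicSpectrum: %d time bins x %d channels, dt = %g ms, %g-%g Hz\n",
              nrow(object@values), ncol(object@values),
              1000 * object@timeStep, min(object@channelFreqs),
              max(object@channelFreqs)))
})

setMethod("show", "ChannelBank", function(object) {
  cat(sprintf("ChannelBank: %d channels, %g-%g Hz (log-spaced)\n",
              length(object@cf), object@cf[1], object@cf[length(object@cf)]))
})

setMethod("show", "DischargeTrain", function(object) {
  cat(sprintf("DischargeTrain: %d channels, %.3g s, %d events\n",
              length(object@events), object@duration,
              sum(lengths(object@events))))
})

setMethod("show", "Genome", function(object) {
  n <- nrow(object@W)
  cat(sprintf("Genome: %d neurons, %d genes (%d weights + %d input strengths + %d delays)\n",
              n, n^2 + 2L * n, n^2, n, n))
  cat(sprintf("  nonzero cortico-cortical synapses: %d\n", sum(object@W != 0L)))
})

setMethod("show", "SpikeRecord", function(object) {
  cat(sprintf("SpikeRecord: %d neurons, %g ms, %d spikes\n",
              length(object@spikes), object@duration,
              sum(lengths(object@spikes))))
})

setMethod("show", "STRF", function(object) {
  cat(sprintf("STRF: %d lags (0-%g ms, step %g ms) x %d channels\n",
              nrow(object@values),
              (nrow(object@values) - 1) * object@lagStep, object@lagStep,
              ncol(object@values)))
})

setMethod("show", "PhiKernel", function(object) {
  cat(sprintf("PhiKernel: %d lags x %d x %d channels (collapsed: %d diffs)\n",
              length(object@lags), dim(object@full)[2], dim(object@full)[3],
              length(object@channelDiff)))
})

setMethod("show", "SensitivityProfile", function(object) {
  top <- order(object@scores, decreasing = TRUE)[seq_len(min(3, length(object@scores)))]
  cat(sprintf("SensitivityProfile: %d parameters; top: %s\n",
              length(object@scores),
              paste(sprintf("%s (%.3f)", object@labels[top],
                            object@scores[top]), collapse = ", ")))
})
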