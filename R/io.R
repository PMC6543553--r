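## Plain-text persistence for every pipeline artifact. All formats are
## delimited text with '#'-prefixed header lines; readers validate
## structure and report the offending line on failure.

.headerValue <- function(lines, key, file) {
  hit <- grep(sprintf("^# %s:", key), lines)
  if (!length(hit))
    stop(sprintf("%s: missing '# %s:' header", file, key))
  sub(sprintf("^# %s:\\s*", key), "", lines[hit[1]])
}

#' Read and write STRF matrices
#'
#' Delimited text: header lines give the lag step (ms) and channel
#' frequencies (Hz); the body is the lag x channel matrix, one lag per
#' row.
#'
#' @param strf an [STRF-class].
#' @param file path.
#' @return \code{readStrf} returns an [STRF-class]; \code{writeStrf}
#'   returns \code{file} invisibly.
#' @export
writeStrf <- function(strf, file) {
  stopifnot(is(strf, "STRF"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# strfnet STRF v1",
               sprintf("# lagStepMs: %.17g", strf@lagStep),
               sprintf("# channelFreqsHz: %s",
                       paste(sprintf("%.17g", strf@channelFreqs),
                             collapse = " "))), con)
  write.table(strf@values, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname writeStrf
#' @export
readStrf <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# strfnet STRF", lines[1]))
    stop(sprintf("%s: not an strfnet STRF file (line 1)", file))
  lagStep <- as.numeric(.headerValue(lines, "lagStepMs", file))
  cf <- as.numeric(strsplit(.headerValue(lines, "channelFreqsHz", file),
                            "\\s+")[[1]])
  body <- lines[!grepl("^#", lines)]
  vals <- as.matrix(read.table(text = body, sep = "\t"))
  dimnames(vals) <- NULL
  if (ncol(vals) != length(cf))
    stop(sprintf("%s: %d channels in header but %d data columns",
                 file, length(cf), ncol(vals)))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-finite value at data row %d, column %d",
                 file, bad[1], bad[2]))
  }
  new("STRF", values = vals, lagStep = lagStep, channelFreqs = cf)
}

#' Read and write spike / discharge event files
#'
#' Two-column tab-delimited text (unit index, event time), sorted within
#' unit. [SpikeRecord-class] times are in ms; [DischargeTrain-class] times
#' in seconds (the unit is recorded in the header).
#'
#' @param x a [SpikeRecord-class] or [DischargeTrain-class].
#' @param file path.
#' @return \code{readSpikes} returns an object of the class named in the
#'   file header; writers return \code{file} invisibly.
#' @export
writeSpikes <- function(x, file) {
  if (is(x, "SpikeRecord")) {
    kind <- "SpikeRecord"; unit <- "ms"
    ev <- x@spikes; dur <- x@duration; extra <- sprintf("# dtMs: %.17g", x@dt)
  } else if (is(x, "DischargeTrain")) {
    kind <- "DischargeTrain"; unit <- "s"
    ev <- x@events; dur <- x@duration
    extra <- sprintf("# cfHz: %s", paste(sprintf("%.17g", x@cf),
                                         collapse = " "))
  } else stop("x must be a SpikeRecord or DischargeTrain")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# strfnet %s v1", kind),
               sprintf("# units: %d", length(ev)),
               sprintf("# duration (%s): %.17g", unit, dur), extra), con)
  df <- data.frame(unit = rep(seq_along(ev), lengths(ev)),
                   time = unlist(ev))
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# strfnet (SpikeRecord|DischargeTrain)",
                               lines[1]))
    stop(sprintf("%s: not an strfnet spike file (line 1)", file))
  kind <- sub("^# strfnet (\\w+).*", "\\1", lines[1])
  nUnits <- as.integer(.headerValue(lines, "units", file))
  dur <- as.numeric(sub(".*:\\s*", "",
                        lines[grep("^# duration", lines)[1]]))
  bodyIdx <- which(!grepl("^#", lines) & nzchar(lines))
  ev <- rep(list(numeric(0)), nUnits)
  if (length(bodyIdx)) {
    df <- read.table(text = lines[bodyIdx], sep = "\t",
                     col.names = c("unit", "time"))
    if (any(df$unit < 1 | df$unit > nUnits)) {
      bad <- which(df$unit < 1 | df$unit > nUnits)[1]
      stop(sprintf("%s: unit index out of range at line %d", file,
                   bodyIdx[bad]))
    }
    for (u in unique(df$unit)) {
      tms <- df$time[df$unit == u]
      if (any(diff(tms) <= 0)) {
        bad <- which(df$unit == u)[which(diff(tms) <= 0)[1] + 1L]
        stop(sprintf("%s: unsorted event times for unit %d at line %d",
                     file, u, bodyIdx[bad]))
      }
      ev[[u]] <- tms
    }
  }
  if (kind == "SpikeRecord") {
    dt <- as.numeric(.headerValue(lines, "dtMs", file))
    new("SpikeRecord", spikes = ev, duration = dur,
        vtrace = matrix(0, 0, 0), dt = dt)
  } else {
    cf <- as.numeric(strsplit(.headerValue(lines, "cfHz", file),
                              "\\s+")[[1]])
    new("DischargeTrain", events = ev, duration = dur, cf = cf)
  }
}

#' Read and write integer genomes
#'
#' Structured text: the neuron count, the n x n weight matrix (row =
#' presynaptic neuron), and the input strength and delay code vectors.
#' Out-of-range entries are rejected with their row and column.
#'
#' @param g a [Genome-class].
#' @param file path.
#' @return \code{readGenome} returns a [Genome-class]; \code{writeGenome}
#'   returns \code{file} invisibly.
#' @export
writeGenome <- function(g, file) {
  stopifnot(is(g, "Genome"))
  n <- nNeurons(g)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# strfnet Genome v1", sprintf("# neurons: %d", n),
               "# W (rows = presynaptic neuron):"), con)
  write.table(g@W, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("# istr:\n%s", paste(g@istr, collapse = "\t")), con)
  writeLines(sprintf("# idel:\n%s", paste(g@idel, collapse = "\t")), con)
  invisible(file)
}

#' @rdname writeGenome
#' @export
readGenome <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# strfnet Genome", lines[1]))
    stop(sprintf("%s: not an strfnet genome file (line 1)", file))
  n <- as.integer(.headerValue(lines, "neurons", file))
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) != n + 2L)
    stop(sprintf("%s: expected %d data lines, found %d", file, n + 2L,
                 length(body)))
  parseRow <- function(lineNo) {
    v <- suppressWarnings(as.numeric(strsplit(lines[lineNo], "\t")[[1]]))
    if (any(is.na(v)))
      stop(sprintf("%s: malformed number at line %d", file, lineNo))
    v
  }
  W <- do.call(rbind, lapply(body[seq_len(n)], parseRow))
  istr <- parseRow(body[n + 1L])
  idel <- parseRow(body[n + 2L])
  all <- rbind(W, istr, idel)
  bad <- which(all < -5 | all > 5 | all != round(all), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: out-of-range genome entry at row %d, column %d",
                 file, bad[1, 1], bad[1, 2]))
  }
  genome(W, istr, idel)
}

#' Read and write sensitivity profiles
#'
#' Two-column tab-delimited text: parameter label, normalized score.
#'
#' @param profile a [SensitivityProfile-class].
#' @param file path.
#' @return \code{readProfile} returns a [SensitivityProfile-class];
#'   \code{writeProfile} returns \code{file} invisibly.
#' @export
writeProfile <- function(profile, file) {
  stopifnot(is(profile, "SensitivityProfile"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# strfnet SensitivityProfile v1", con)
  write.table(data.frame(profile@labels,
                         sprintf("%.17g", profile@scores)),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname writeProfile
#' @export
readProfile <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# strfnet SensitivityProfile", lines[1]))
    stop(sprintf("%s: not an strfnet profile file (line 1)", file))
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                   col.names = c("label", "score"))
  new("SensitivityProfile", scores = df$score,
      labels = as.character(df$label))
}

#' Write a dynamic spectrum as delimited text
#'
#' Header gives the time step (s) and channel frequencies (Hz); body is
#' the time x channel matrix.
#'
#' @param ds a [DynamicSpectrum-class].
#' @param file path.
#' @return \code{readDynamicSpectrum} returns a [DynamicSpectrum-class];
#'   the writer returns \code{file} invisibly.
#' @export
writeDynamicSpectrum <- function(ds, file) {
  stopifnot(is(ds, "DynamicSpectrum"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# strfnet DynamicSpectrum v1",
               sprintf("# timeStepS: %.17g", ds@timeStep),
               sprintf("# channelFreqsHz: %s",
                       paste(sprintf("%.17g", ds@channelFreqs),
                             collapse = " "))), con)
  write.table(ds@values, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname writeDynamicSpectrum
#' @export
readDynamicSpectrum <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# strfnet DynamicSpectrum", lines[1]))
    stop(sprintf("%s: not an strfnet dynamic-spectrum file (line 1)", file))
  dt <- as.numeric(.headerValue(lines, "timeStepS", file))
  cf <- as.numeric(strsplit(.headerValue(lines, "channelFreqsHz", file),
                            "\\s+")[[1]])
  vals <- as.matrix(read.table(text = lines[!grepl("^#", lines)],
                               sep = "\t"))
  dimnames(vals) <- NULL
  new("DynamicSpectrum", values = vals, timeStep = dt,
      channelFreqs = cf, octave = log2(cf / cf[1]))
}

#' Write an audio vector as a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE writer (no audio package is required at run time).
#' Samples are clipped to \code{[-1, 1]} and quantized to 16 bits.
#'
#' @param sig numeric samples in \code{[-1, 1]} with a \code{sampleRate}
#'   attribute (or pass \code{sampleRate}).
#' @param file path.
#' @param sampleRate sample rate override (Hz).
#' @return \code{file}, invisibly.
#' @export
writeWav <- function(sig, file, sampleRate = attr(sig, "sampleRate")) {
  if (is.null(sampleRate)) stop("sampleRate required")
  pcm <- as.integer(round(pmin(1, pmax(-1, sig)) * 32767))
  con <- file(file, "wb")
  on.exit(close(con))
  dataBytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(file)
}

#' Write a state-comparison edge list
#'
#' One row per (edge, state): param, type, pre, post, state, mean, sd,
#' solid -- the textual form of the network diagram.
#'
#' @param comparison result of [buildDiagram()] or
#'   [runStateComparison()]\code{$diagram}.
#' @param file path.
#' @return \code{file}, invisibly.
#' @export
writeDiagram <- function(comparison, file) {
  write.table(comparison$edges, file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}
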