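## Perturbation sensitivity analysis of fitted genomes and extraction of
## the passive-versus-behavioral network diagrams.

#' Perturbation sensitivity profile of a fitted genome
#'
#' Each of the genome's parameters is sequentially increased and decreased
#' by one code step from the fitted solution and the change of the
#' significance-weighted cost is measured. The raw score of a parameter is
#' the mean absolute cost change of the two one-step perturbations
#' (out-of-bounds perturbations at codes -5 or +5 are skipped, leaving the
#' single feasible one); scores are normalized to sum to one. The
#' evaluation context is deterministic, so the profile is a pure function
#' of (genome, target, ctx).
#'
#' @param g fitted [Genome-class].
#' @param target target [STRF-class].
#' @param ctx an \code{EvalContext} from [makeEvalContext()].
#' @param recordNeuron optional recorded-neuron override.
#' @param bounds integer gene bounds (default \code{c(-5, 5)}).
#' @return a [SensitivityProfile-class].
#' @export
sensitivityProfile <- function(g, target, ctx, recordNeuron = NULL,
                               bounds = c(-5L, 5L)) {
  stopifnot(is(g, "Genome"))
  n <- nNeurons(g)
  if (is.null(recordNeuron))
    recordNeuron <- nearestChannel(bestFrequency(target), ctx$bank)
  genes <- genomeVector(g)
  c0 <- evaluateGenome(g, target, ctx, recordNeuron)
  raw <- vapply(seq_along(genes), function(p) {
    deltas <- numeric(0)
    for (step in c(1L, -1L)) {
      val <- genes[p] + step
      if (val < bounds[1] || val > bounds[2]) next
      gp <- genes
      gp[p] <- val
      cp <- evaluateGenome(genomeFromVector(gp, n), target, ctx,
                           recordNeuron)
      deltas <- c(deltas, abs(cp - c0))
    }
    mean(deltas)
  }, numeric(1))
  tot <- sum(raw)
  new("SensitivityProfile",
      scores = if (tot > 0) raw / tot else raw,
      labels = genomeLabels(n))
}

#' Average sensitivity profiles across repeats
#'
#' Element-wise mean of congruent profiles, renormalized to sum to one.
#' Averaging across independent GA repeats suppresses parameters that were
#' sensitive only by chance in one solution of the degenerate
#' high-dimensional fit.
#'
#' @param profiles non-empty list of congruent
#'   [SensitivityProfile-class] objects.
#' @return a [SensitivityProfile-class].
#' @export
averageProfiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  lab <- profiles[[1]]@labels
  for (p in profiles) {
    stopifnot(is(p, "SensitivityProfile"))
    if (!identical(p@labels, lab)) stop("profiles are not congruent")
  }
  m <- rowMeans(vapply(profiles, slot, numeric(length(lab)), "scores"))
  tot <- sum(m)
  new("SensitivityProfile", scores = if (tot > 0) m / tot else m,
      labels = lab)
}

#' Top-k most sensitive parameters
#'
#' @param profile a [SensitivityProfile-class].
#' @param k how many labels (default 2, the rule used to flag parameters
#'   as important).
#' @return character vector of parameter labels, highest score first; ties
#'   resolve to the lower parameter index.
#' @export
importantParams <- function(profile, k = 2L) {
  stopifnot(is(profile, "SensitivityProfile"), k >= 1)
  k <- min(as.integer(k), length(profile@scores))
  ord <- order(-profile@scores, seq_along(profile@scores))
  profile@labels[ord[seq_len(k)]]
}

## internal: parse a parameter label into its edge
.paramEdge <- function(label) {
  if (grepl("^W\\[", label)) {
    ij <- as.integer(strsplit(gsub("[^0-9,]", "", label), ",")[[1]])
    list(type = "synapse", pre = ij[1], post = ij[2],
         neurons = unique(ij))
  } else {
    i <- as.integer(gsub("[^0-9]", "", label))
    list(type = if (grepl("^istr", label)) "input" else "delay",
         pre = NA_integer_, post = i, neurons = i)
  }
}

## internal: integer value of a labeled parameter in a genome
.paramValue <- function(g, label) {
  e <- .paramEdge(label)
  switch(e$type,
         synapse = g@W[e$pre, e$post],
         input   = g@istr[e$post],
         delay   = g@idel[e$post])
}

#' Build the passive-versus-behavioral network diagram
#'
#' The diagram contains every parameter that is in the top \code{k} of the
#' averaged sensitivity profile of either state, plus context parameters
#' that trace the flow of information from the sound signal to the
#' recorded neuron: the cochlear input to every neuron appearing in an
#' important parameter, the synapse from each such neuron to the recorded
#' neuron, and the recorded neuron's own cochlear input. Every edge is
#' annotated, per state, with the mean and standard deviation of its
#' integer value across the fitted repeats, and flagged solid in a state
#' when it is among that state's top-k parameters (dashed otherwise).
#'
#' @param genomes named list with elements \code{passive} and
#'   \code{behavioral}, each a list of fitted [Genome-class] objects (equal
#'   repeat counts, >= 2 for a defined s.d.).
#' @param profiles named list with elements \code{passive} and
#'   \code{behavioral}, each the averaged [SensitivityProfile-class] of
#'   that state.
#' @param recordNeuron index of the recorded neuron.
#' @param k how many top parameters count as important per state
#'   (default 2).
#' @return a \code{StateComparison}: list with \code{edges} (data.frame:
#'   param, type, pre, post, state, mean, sd, solid), \code{top}
#'   (per-state top-k labels) and \code{recordNeuron}.
#' @export
buildDiagram <- function(genomes, profiles, recordNeuron, k = 2L) {
  states <- c("passive", "behavioral")
  stopifnot(all(states %in% names(genomes)),
            all(states %in% names(profiles)))
  if (length(genomes$passive) != length(genomes$behavioral))
    stop("passive and behavioral repeat counts differ")
  top <- lapply(profiles[states], importantParams, k = k)
  important <- unique(unlist(top))

  ## context parameters: trace the path sound -> ... -> recorded neuron
  neurons <- unique(c(unlist(lapply(important,
                                    function(l) .paramEdge(l)$neurons)),
                      recordNeuron))
  context <- c(sprintf("istr[%d]", neurons),
               sprintf("W[%d,%d]",
                       setdiff(neurons, recordNeuron),
                       recordNeuron))
  params <- unique(c(important, context))

  rows <- do.call(rbind, lapply(params, function(p) {
    e <- .paramEdge(p)
    do.call(rbind, lapply(states, function(st) {
      vals <- vapply(genomes[[st]], .paramValue, numeric(1), label = p)
      data.frame(param = p, type = e$type,
                 pre = if (is.na(e$pre)) 0L else e$pre, post = e$post,
                 state = st, mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 solid = p %in% top[[st]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  list(edges = rows, top = top, recordNeuron = recordNeuron)
}
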