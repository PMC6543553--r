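## Elitist genetic algorithm over integer genomes, minimizing the
## significance-weighted STRF cost. Populations are stored as integer
## matrices (one genome per row, column-major W then istr then idel).

#' Genetic algorithm configuration
#'
#' Each generation is sorted by cost; the best \code{elite} genomes pass
#' unchanged, \code{nCross} offspring are built by uniform per-gene
#' crossover of parent pairs sampled from the best \code{parents}, and
#' \code{nMut} offspring by copying a random parent and resampling each
#' gene with probability \code{mutRate}. The composition must satisfy
#' \code{elite + nCross + nMut = popSize}. Defaults are the full-scale
#' settings (population 1000, 40 elite, 100 parents, 480 + 480 offspring,
#' 100 generations); [gaConfigReduced()] gives a desk-scale preset.
#'
#' @param popSize population size.
#' @param elite number of elite genomes copied unchanged.
#' @param parents size of the parent pool (best genomes).
#' @param nCross crossover offspring per generation.
#' @param nMut mutation offspring per generation.
#' @param generations number of generations.
#' @param bounds inclusive integer gene bounds.
#' @param mutRate per-gene resampling probability for mutation offspring.
#' @return named list.
#' @export
gaConfig <- function(popSize = 1000L, elite = 40L, parents = 100L,
                     nCross = 480L, nMut = 480L, generations = 100L,
                     bounds = c(-5L, 5L), mutRate = 0.05) {
  if (elite + nCross + nMut != popSize)
    stop("elite + nCross + nMut must equal popSize")
  if (parents > popSize) stop("parent pool larger than population")
  list(popSize = as.integer(popSize), elite = as.integer(elite),
       parents = as.integer(parents), nCross = as.integer(nCross),
       nMut = as.integer(nMut), generations = as.integer(generations),
       bounds = as.integer(bounds), mutRate = mutRate)
}

#' @rdname gaConfig
#' @export
gaConfigReduced <- function(popSize = 60L, elite = 4L, parents = 10L,
                            nCross = 28L, nMut = 28L, generations = 15L,
                            bounds = c(-5L, 5L), mutRate = 0.05) {
  gaConfig(popSize, elite, parents, nCross, nMut, generations, bounds,
           mutRate)
}

#' Random initial population
#'
#' @param cfg a [gaConfig()].
#' @param nNeurons network size (genome length is
#'   \code{nNeurons^2 + 2 * nNeurons}).
#' @param seed integer seed.
#' @return integer matrix, one genome per row; every gene uniform over the
#'   integer bounds.
#' @export
initPopulation <- function(cfg, nNeurons, seed) {
  ng <- nNeurons^2 + 2L * nNeurons
  withr::with_seed(as.integer(seed), {
    matrix(sample(seq(cfg$bounds[1], cfg$bounds[2]),
                  cfg$popSize * ng, replace = TRUE),
           nrow = cfg$popSize, ncol = ng)
  })
}

#' Build the (cached, deterministic) evaluation context for fitting
#'
#' Precomputes everything a genome evaluation reuses: the TORC dynamic
#' spectra on the bank's channel grid, the peripheral discharge trains for
#' every stimulus and repetition, and the estimation configuration. The
#' peripheral discharge seeds are fixed here, once, so every genome is
#' evaluated against the identical stochastic input and the cost landscape
#' is deterministic -- without this, elitism would be meaningless under
#' re-evaluation noise.
#'
#' @param bank a [ChannelBank-class]; one neuron per channel.
#' @param torcs list of [TORC-class] (e.g. [makeTorcSet()]); their channel
#'   axis should match the bank.
#' @param seed integer seed for the peripheral discharges.
#' @param reps stochastic repetitions of each TORC (default 4).
#' @param estCfg an [estimationConfig()].
#' @param pars neuron parameters ([neuronParams()]).
#' @param rateP peripheral rate parameters ([ratePars()]).
#' @param tonic constant cortical drive in mV (default
#'   \code{tonicForRate(10, pars)}: fitting runs use tonically firing
#'   neurons, which respond more robustly).
#' @param timeStep envelope step (s).
#' @param deadTime peripheral dead time (s).
#' @return an \code{EvalContext} list used by [evaluateGenome()], [runGA()]
#'   and [sensitivityProfile()].
#' @export
makeEvalContext <- function(bank, torcs, seed, reps = 4L,
                            estCfg = estimationConfig(),
                            pars = neuronParams(), rateP = ratePars(),
                            tonic = tonicForRate(10, pars),
                            timeStep = 0.002, deadTime = 0.00075) {
  stopifnot(is(bank, "ChannelBank"), length(torcs) >= 1)
  dspecs <- lapply(torcs, dynamicSpectrum, timeStep = timeStep)
  seeds <- deriveSeeds(seed, length(torcs) * reps)
  k <- 0L
  discharges <- lapply(seq_along(torcs), function(s) {
    rate <- driveRate(dspecs[[s]], bank, rateP, timeStep)
    lapply(seq_len(reps), function(r) {
      k <<- k + 1L
      generateDischarges(rate, seed = seeds[k], deadTime = deadTime)
    })
  })
  structure(list(bank = bank, dspecs = dspecs, discharges = discharges,
                 reps = as.integer(reps), estCfg = estCfg, pars = pars,
                 tonic = tonic, seed = as.integer(seed)),
            class = "EvalContext")
}

#' Forward-simulate a genome and estimate its STRF
#'
#' Runs decode -> network simulation (over every stimulus and repetition in
#' the context) -> reverse correlation for the recorded neuron.
#'
#' @param g a [Genome-class].
#' @param ctx an \code{EvalContext} from [makeEvalContext()].
#' @param recordNeuron index of the neuron whose spikes are reverse
#'   correlated.
#' @param delayOverride optional per-neuron peripheral delay override (ms),
#'   see [decodeGenome()].
#' @return an [STRF-class].
#' @export
genomeStrf <- function(g, ctx, recordNeuron, delayOverride = NULL) {
  stopifnot(inherits(ctx, "EvalContext"))
  cfg <- decodeGenome(g, ctx$bank, ctx$pars, delayOverride = delayOverride,
                      tonic = ctx$tonic)
  responses <- lapply(seq_along(ctx$dspecs), function(s) {
    lapply(ctx$discharges[[s]], function(tr) {
      rec <- simulateNetwork(cfg, tr)
      spikeTimes(rec, recordNeuron) / 1000  # ms -> s
    })
  })
  reverseCorrelate(ctx$dspecs, responses, ctx$estCfg)
}

#' Evaluate the fit cost of a genome against a target STRF
#'
#' The recorded neuron is the one whose channel center frequency matches
#' the target's best frequency (the neuron-selection rule used when
#' matching recordings); the cost is the significance-weighted STRF
#' distance of [strfCost()]. Deterministic given the context.
#'
#' @param g a [Genome-class] (or flat integer gene vector).
#' @param target target [STRF-class].
#' @param ctx an \code{EvalContext}.
#' @param recordNeuron optional override of the recorded-neuron index.
#' @return scalar cost.
#' @export
evaluateGenome <- function(g, target, ctx, recordNeuron = NULL) {
  if (!is(g, "Genome"))
    g <- genomeFromVector(g, length(ctx$bank@cf))
  if (is.null(recordNeuron))
    recordNeuron <- nearestChannel(bestFrequency(target), ctx$bank)
  strfCost(genomeStrf(g, ctx, recordNeuron), target)
}

#' Produce the next GA generation
#'
#' Stable ascending sort by (cost, index); elite copied verbatim;
#' crossover offspring take each gene from one of two parents drawn
#' uniformly without replacement from the parent pool; mutation offspring
#' copy one parent and resample each gene with probability
#' \code{cfg$mutRate} uniformly within bounds.
#'
#' @param population integer matrix (one genome per row).
#' @param costs numeric vector aligned with the rows.
#' @param cfg a [gaConfig()].
#' @param seed integer seed for the operators.
#' @return integer matrix of the same dimensions.
#' @export
nextGeneration <- function(population, costs, cfg, seed) {
  stopifnot(nrow(population) == length(costs))
  if (nrow(population) < cfg$parents)
    stop("population smaller than the parent pool")
  ord <- order(costs)                      # stable: ties keep row order
  pop <- population[ord, , drop = FALSE]
  ng <- ncol(pop)
  pool <- pop[seq_len(cfg$parents), , drop = FALSE]
  withr::with_seed(as.integer(seed), {
    cross <- matrix(0L, cfg$nCross, ng)
    for (o in seq_len(cfg$nCross)) {
      pr <- sample.int(cfg$parents, 2L)
      pick <- runif(ng) < 0.5
      cross[o, ] <- ifelse(pick, pool[pr[1], ], pool[pr[2], ])
    }
    mut <- matrix(0L, cfg$nMut, ng)
    for (o in seq_len(cfg$nMut)) {
      child <- pool[sample.int(cfg$parents, 1L), ]
      hit <- runif(ng) < cfg$mutRate
      if (any(hit))
        child[hit] <- sample(seq(cfg$bounds[1], cfg$bounds[2]),
                             sum(hit), replace = TRUE)
      mut[o, ] <- child
    }
    rbind(pop[seq_len(cfg$elite), , drop = FALSE], cross, mut)
  })
}

#' Fit a genome to a target STRF with the elitist genetic algorithm
#'
#' @param target target [STRF-class].
#' @param cfg a [gaConfig()] (use [gaConfigReduced()] for desk-scale runs).
#' @param ctx an \code{EvalContext} from [makeEvalContext()].
#' @param seed integer seed (drives initialization and the per-generation
#'   operators).
#' @param recordNeuron optional recorded-neuron override (defaults to the
#'   target's best-frequency channel).
#' @param verbose print per-generation best/median cost.
#' @param checkpointDir optional directory; per-generation best genome and
#'   cost history are written there.
#' @return a \code{FitResult} list: \code{bestGenome} ([Genome-class]),
#'   \code{bestCost}, \code{history} (data.frame of per-generation best and
#'   median cost; best is non-increasing by elitism), \code{evaluations},
#'   \code{seed}.
#' @export
runGA <- function(target, cfg, ctx, seed, recordNeuron = NULL,
                  verbose = FALSE, checkpointDir = NULL) {
  stopifnot(is(target, "STRF"), inherits(ctx, "EvalContext"))
  n <- length(ctx$bank@cf)
  if (is.null(recordNeuron))
    recordNeuron <- nearestChannel(bestFrequency(target), ctx$bank)
  seeds <- deriveSeeds(seed, cfg$generations + 1L)
  pop <- initPopulation(cfg, n, seeds[1])
  evalPop <- function(p) apply(p, 1L, function(genes)
    evaluateGenome(genomeFromVector(genes, n), target, ctx, recordNeuron))
  costs <- evalPop(pop)
  nEval <- nrow(pop)
  bestIdx <- which.min(costs)
  bestGenes <- pop[bestIdx, ]
  bestCost <- costs[bestIdx]
  hist <- data.frame(generation = 0L, best = bestCost,
                     median = median(costs))
  for (gen in seq_len(cfg$generations)) {
    pop <- nextGeneration(pop, costs, cfg, seeds[gen + 1L])
    ## elite rows keep their (deterministic) costs; only offspring are new
    costs <- c(sort(costs)[seq_len(cfg$elite)],
               evalPop(pop[-seq_len(cfg$elite), , drop = FALSE]))
    nEval <- nEval + nrow(pop) - cfg$elite
    i <- which.min(costs)
    if (costs[i] < bestCost) {
      bestCost <- costs[i]
      bestGenes <- pop[i, ]
    }
    hist <- rbind(hist, data.frame(generation = gen, best = bestCost,
                                   median = median(costs)))
    if (verbose)
      message(sprintf("gen %3d  best %.4f  median %.4f", gen, bestCost,
                      median(costs)))
    if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
      writeGenome(genomeFromVector(bestGenes, n),
                  file.path(checkpointDir, "best_genome.txt"))
      write.table(hist, file.path(checkpointDir, "history.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(bestGenome = genomeFromVector(bestGenes, n), bestCost = bestCost,
       history = hist, evaluations = nEval, seed = as.integer(seed),
       recordNeuron = recordNeuron)
}
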