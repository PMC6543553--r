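## Top-level pipeline: repeated GA fits + sensitivity analyses for two
## recording states, averaged profiles, and the comparison diagram.

#' Fit and compare the passive and behavioral states
#'
#' For each state, runs \code{repeats} independent GA fits of the state's
#' target STRF (different GA seeds, identical deterministic evaluation
#' context), computes the perturbation sensitivity profile of each fitted
#' genome, averages the profiles, and extracts the top-k important
#' parameters; then builds the cross-state network diagram. All sub-seeds
#' derive from \code{seed} via [deriveSeeds()], so a rerun with the same
#' master seed reproduces every number exactly.
#'
#' @param passiveTarget,behavioralTarget congruent [STRF-class] targets.
#' @param ctx an \code{EvalContext} from [makeEvalContext()].
#' @param gaCfg a [gaConfig()] / [gaConfigReduced()].
#' @param seed master seed.
#' @param repeats GA/sensitivity repeats per state (default 5).
#' @param k top parameters per state counted as important (default 2).
#' @param outDir optional directory; fitted genomes, profiles, the
#'   averaged profiles, the edge list and a run manifest are written there.
#' @param verbose print GA progress.
#' @return list with \code{fits} and \code{profiles} (per state, one per
#'   repeat), \code{avgProfiles}, \code{top} (per-state top-k),
#'   \code{perRepeatTop} (per state, per repeat), \code{diagram}
#'   ([buildDiagram()] result) and \code{recordNeuron}.
#' @export
runStateComparison <- function(passiveTarget, behavioralTarget, ctx,
                               gaCfg, seed, repeats = 5L, k = 2L,
                               outDir = NULL, verbose = FALSE) {
  stopifnot(is(passiveTarget, "STRF"), is(behavioralTarget, "STRF"))
  if (!all(dim(passiveTarget@values) == dim(behavioralTarget@values)) ||
      abs(passiveTarget@lagStep - behavioralTarget@lagStep) > 1e-9)
    stop("passive and behavioral targets are not congruent")
  states <- list(passive = passiveTarget, behavioral = behavioralTarget)
  recordNeuron <- nearestChannel(bestFrequency(passiveTarget), ctx$bank)
  seeds <- matrix(deriveSeeds(seed, 2L * repeats), nrow = 2L)

  fits <- profiles <- list()
  for (si in seq_along(states)) {
    st <- names(states)[si]
    fits[[st]] <- lapply(seq_len(repeats), function(r) {
      runGA(states[[si]], gaCfg, ctx, seed = seeds[si, r],
            recordNeuron = recordNeuron, verbose = verbose)
    })
    profiles[[st]] <- lapply(fits[[st]], function(f)
      sensitivityProfile(f$bestGenome, states[[si]], ctx,
                         recordNeuron = recordNeuron))
  }
  avg <- lapply(profiles, averageProfiles)
  genomes <- lapply(fits, function(fs) lapply(fs, `[[`, "bestGenome"))
  diagram <- buildDiagram(genomes, avg, recordNeuron, k = k)
  perRepeatTop <- lapply(profiles, function(ps)
    lapply(ps, importantParams, k = k))

  res <- list(fits = fits, profiles = profiles, avgProfiles = avg,
              top = diagram$top, perRepeatTop = perRepeatTop,
              diagram = diagram, recordNeuron = recordNeuron,
              seed = as.integer(seed))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (st in names(states)) {
      for (r in seq_len(repeats)) {
        writeGenome(genomes[[st]][[r]],
                    file.path(outDir, sprintf("%s_genome_%d.txt", st, r)))
        writeProfile(profiles[[st]][[r]],
                     file.path(outDir, sprintf("%s_profile_%d.txt", st, r)))
      }
      writeProfile(avg[[st]], file.path(outDir,
                                        sprintf("%s_profile_avg.txt", st)))
    }
    writeDiagram(diagram, file.path(outDir, "diagram_edges.tsv"))
    manifest <- c(
      sprintf("package: strfnet %s",
              as.character(utils::packageVersion("strfnet"))),
      sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      sprintf("masterSeed: %d", as.integer(seed)),
      sprintf("contextSeed: %d", ctx$seed),
      sprintf("repeats: %d", repeats),
      sprintf("recordNeuron: %d", recordNeuron),
      sprintf("gaConfig: %s",
              paste(sprintf("%s=%s", names(gaCfg),
                            vapply(gaCfg, function(x)
                              paste(x, collapse = ","), character(1))),
                    collapse = " ")))
    writeLines(manifest, file.path(outDir, "manifest.txt"))
  }
  res
}
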