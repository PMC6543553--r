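test_that("sensitivity profiles: length, normalization, null parameters", {
  ## 15-neuron genome -> profile over all 255 parameters; use a tiny
  ## stimulus context to keep the 510 perturbation evaluations cheap
  torcs2 <- makeTorcSet(2, seed = 13, durations = 1)
  ctx <- makeEvalContext(bank15, torcs2, seed = 5, reps = 1, tonic = 0,
                         estCfg = estimationConfig(lagSpan = 100))
  g <- genome(matrix(0L, 15, 15),
              istr = c(rep(0L, 7), 5L, rep(0L, 7)),
              idel = c(rep(0L, 7), -4L, rep(0L, 7)))
  tg <- genomeStrf(g, ctx, 8)
  prof <- sensitivityProfile(g, tg, ctx, recordNeuron = 8)
  expect_s4_class(prof, "SensitivityProfile")
  expect_length(prof@scores, 255)
  expect_equal(sum(prof@scores), 1)
  expect_true(all(prof@scores >= 0))
  sc <- sensScores(prof)
  ## with no tonic drive, neurons 1 and 2 never fire: a synapse between
  ## them cannot change any spike, so its score is exactly 0
  expect_equal(sc[["W[1,2]"]], 0)
  ## the sole input's strength and delay carry nonzero sensitivity
  expect_gt(sc[["istr[8]"]], 0)
  expect_gt(sc[["idel[8]"]], 0)
})

test_that("profile averaging is an element-wise renormalized mean", {
  mk <- function(s) new("SensitivityProfile", scores = s / sum(s),
                        labels = genomeLabels(2))
  p1 <- mk(c(1, 0, 0, 0, 3, 0, 0, 0))
  p2 <- mk(c(0, 2, 0, 0, 0, 0, 2, 0))
  expect_equal(averageProfiles(list(p1, p1))@scores, p1@scores)
  avg <- averageProfiles(list(p1, p2))
  ## disjoint supports union
  expect_setequal(which(avg@scores > 0), c(1, 2, 5, 7))
  expect_equal(sum(avg@scores), 1)
  expect_error(averageProfiles(list()), "empty")
  ## law of large numbers: the mean of 5 copies under zero-mean jitter is
  ## closer to the original than a single jittered copy
  p0 <- mk(1:8)
  set.seed(10)
  jitter1 <- function() {
    s <- p0@scores + runif(8, -0.02, 0.02)
    new("SensitivityProfile", scores = s / sum(s), labels = p0@labels)
  }
  one <- jitter1()
  five <- averageProfiles(replicate(5, jitter1()))
  expect_lt(sum(abs(five@scores - p0@scores)),
            sum(abs(one@scores - p0@scores)))
})

test_that("importantParams ranks with index tie-breaking", {
  prof <- new("SensitivityProfile",
              scores = c(0.1, 0.4, 0.1, 0.3, 0.1, 0, 0, 0),
              labels = genomeLabels(2))
  expect_equal(importantParams(prof, 2), genomeLabels(2)[c(2, 4)])
  expect_length(importantParams(prof, 100), 8)
  ## exact ties resolve to the lower parameter index
  tied <- new("SensitivityProfile", scores = c(0.5, 0.5, rep(0, 6)),
              labels = genomeLabels(2))
  expect_equal(importantParams(tied, 1), genomeLabels(2)[1])
  ## a top input-strength parameter is reported first
  inp <- new("SensitivityProfile",
             scores = c(rep(0.05, 4), 0.6, rep(0.04, 3)),
             labels = genomeLabels(2))
  expect_equal(importantParams(inp, 1), "istr[1]")
})

test_that("buildDiagram applies the context rules and repeat statistics", {
  mkGenome <- function(w43, istr3) {
    W <- matrix(0L, 5, 5)
    W[4, 3] <- w43
    genome(W, istr = c(0L, 0L, istr3, 4L, 0L),
           idel = c(0L, 0L, -4L, -4L, 0L))
  }
  mkProf <- function(topLabels) {
    labs <- genomeLabels(5)
    s <- rep(0.001, length(labs))
    s[match(topLabels, labs)] <- c(0.5, 0.4)
    new("SensitivityProfile", scores = s / sum(s), labels = labs)
  }
  gen <- list(passive = list(mkGenome(-4L, 5L), mkGenome(-4L, 5L)),
              behavioral = list(mkGenome(0L, 3L), mkGenome(0L, 5L)))
  prof <- list(passive = mkProf(c("W[4,3]", "istr[3]")),
               behavioral = mkProf(c("istr[3]", "idel[3]")))
  d <- buildDiagram(gen, prof, recordNeuron = 3)
  ed <- d$edges
  ## important synapse 4->3 present and solid only in the passive state
  expect_true(all(c("W[4,3]", "istr[3]", "idel[3]") %in% ed$param))
  expect_true(ed$solid[ed$param == "W[4,3]" & ed$state == "passive"])
  expect_false(ed$solid[ed$param == "W[4,3]" & ed$state == "behavioral"])
  ## context: cochlear input to neuron 4 (it appears in W[4,3]) and to the
  ## recorded neuron
  expect_true("istr[4]" %in% ed$param)
  expect_true("istr[3]" %in% ed$param)
  ## repeat statistics: means and sds across fitted repeats
  expect_equal(ed$mean[ed$param == "W[4,3]" & ed$state == "passive"], -4)
  expect_equal(ed$sd[ed$param == "W[4,3]" & ed$state == "passive"], 0)
  expect_equal(ed$mean[ed$param == "istr[3]" & ed$state == "behavioral"],
               4)
  expect_equal(ed$sd[ed$param == "istr[3]" & ed$state == "behavioral"],
               sd(c(3, 5)))
  ## pure function: identical inputs give identical output
  expect_identical(d, buildDiagram(gen, prof, recordNeuron = 3))
  ## repeat-count mismatch is rejected
  gen2 <- gen
  gen2$behavioral <- gen2$behavioral[1]
  expect_error(buildDiagram(gen2, prof, recordNeuron = 3), "repeat")
})

test_that("lateral synapses onto the recorded neuron appear as context edges", {
  ## important parameter W[4,3] with recorded neuron 1: context must
  ## include the edge 3 -> 1 and cochlear input to 4 and to 1
  labs <- genomeLabels(5)
  s <- rep(0, length(labs))
  s[match("W[4,3]", labs)] <- 0.6
  s[match("istr[2]", labs)] <- 0.4
  prof <- new("SensitivityProfile", scores = s, labels = labs)
  g <- genome(matrix(0L, 5, 5), integer(5), integer(5))
  d <- buildDiagram(list(passive = list(g, g), behavioral = list(g, g)),
                    list(passive = prof, behavioral = prof),
                    recordNeuron = 1)
  expect_true(all(c("W[3,1]", "W[4,1]", "istr[4]", "istr[3]", "istr[1]",
                    "istr[2]", "W[2,1]") %in% d$edges$param))
})
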