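test_that("reverse correlation basics: empty, errors, and linearity", {
  dspecs <- lapply(torcs5[1:3], dynamicSpectrum)
  cfg <- estimationConfig(lagSpan = 100)
  ## no spikes -> zero STRF
  z <- reverseCorrelate(dspecs, rep(list(numeric(0)), 3), cfg)
  expect_true(all(values(z) == 0))
  ## mismatched lag grid and over-long lag span are rejected
  expect_error(reverseCorrelate(dspecs, rep(list(numeric(0)), 3),
                                estimationConfig(lagSpan = 100,
                                                 lagStep = 5)),
               "envelope")
  expect_error(reverseCorrelate(dspecs, rep(list(numeric(0)), 3),
                                estimationConfig(lagSpan = 1500)),
               "duration")
  expect_error(reverseCorrelate(dspecs, list(c(0.5, 0.2), numeric(0),
                                             numeric(0)), cfg),
               "sorted")
  ## linearity in the response (raw mode): the STRF of a merged spike
  ## train equals the sum of the separate STRFs
  raw <- estimationConfig(lagSpan = 100, normalization = "raw")
  s1 <- list(c(0.2, 0.5), c(0.1), numeric(0))
  s2 <- list(c(0.3), c(0.4, 0.6), c(0.15))
  merged <- mapply(function(a, b) sort(c(a, b)), s1, s2,
                   SIMPLIFY = FALSE)
  sum12 <- values(reverseCorrelate(dspecs, s1, raw)) +
    values(reverseCorrelate(dspecs, s2, raw))
  expect_equal(values(reverseCorrelate(dspecs, merged, raw)), sum12,
               tolerance = 1e-12)
})

test_that("delaying every spike shifts the STRF along the lag axis", {
  dspecs <- lapply(torcs5, dynamicSpectrum)
  cfg <- estimationConfig(lagSpan = 100, normalization = "raw")
  set.seed(31)
  spikes <- lapply(dspecs, function(d)
    sort(runif(40, 0.1, nrow(values(d)) * 0.002 - 0.1)))
  delayed <- lapply(spikes, `+`, 0.02)                # +20 ms = 10 bins
  a <- values(reverseCorrelate(dspecs, spikes, cfg))
  b <- values(reverseCorrelate(dspecs, delayed, cfg))
  ## rows 1..(n-10) of the original appear at rows 11..n of the delayed
  expect_equal(b[11:nrow(b), ], a[1:(nrow(a) - 10), ], tolerance = 1e-9)
})

test_that("constant-rate responses to zero-mean TORCs give a null STRF", {
  dspecs <- lapply(makeTorcSet(10, seed = 12, durations = 1),
                   dynamicSpectrum)
  cfg <- estimationConfig(lagSpan = 100, normalization = "raw")
  ## deterministic constant-rate response: one spike every 10 ms
  spikes <- lapply(dspecs, function(d) seq(0.105, 0.995, by = 0.01))
  est <- values(reverseCorrelate(dspecs, spikes, cfg))
  ## shuffled-spike noise floor: random spike times, same count
  set.seed(44)
  floorMax <- max(vapply(1:10, function(i) {
    sh <- lapply(dspecs, function(d) sort(runif(90, 0.105, 0.995)))
    max(abs(values(reverseCorrelate(dspecs, sh, cfg))))
  }, numeric(1)))
  expect_lt(max(abs(est)), floorMax)
})

test_that("significance mask follows the 3-sd rule with 1/0.1 weights", {
  ## constant STRF: zero sd -> empty mask, all weights 0.1
  m0 <- significanceMask(toySTRF(matrix(2, 20, 15)))
  expect_false(any(m0$mask))
  expect_true(all(m0$weights == 0.1))
  ## single outlier in a zero matrix is significant
  v <- matrix(0, 20, 15)
  v[7, 9] <- 10
  m1 <- significanceMask(toySTRF(v))
  expect_true(m1$mask[7, 9])
  expect_equal(sum(m1$mask), 1)
  expect_setequal(unique(as.vector(m1$weights)), c(1, 0.1))
  ## two-sided: a strong negative point is significant too
  v[3, 2] <- -10
  m2 <- significanceMask(toySTRF(v))
  expect_true(m2$mask[3, 2])
})

test_that("the significance-weighted cost evaluates exactly", {
  set.seed(5)
  v <- matrix(rnorm(20 * 15, sd = 0.1), 20, 15)
  v[7, 9] <- 10                                       # significant point
  target <- toySTRF(v)
  expect_equal(strfCost(target, target), 0)
  ## +2 on the significant point costs 2 * 1
  m <- v
  m[7, 9] <- m[7, 9] + 2
  expect_equal(strfCost(toySTRF(m), target), 2)
  ## +2 on a non-significant point costs 2 * 0.1
  m <- v
  m[1, 1] <- m[1, 1] + 2
  expect_equal(strfCost(toySTRF(m), target), 0.2)
  ## congruence checks
  expect_error(strfCost(toySTRF(matrix(0, 5, 15)), target), "dimensions")
  ## normalized mode ignores a pure gain difference
  sc <- toySTRF(3 * v)
  expect_equal(strfCost(sc, target, normalize = TRUE), 0)
  expect_gt(strfCost(sc, target), 0)
})

test_that("best frequency picks the maximal positive channel with tie rule", {
  v <- matrix(0, 10, 15)
  v[4, 9] <- 5
  expect_equal(bestFrequency(toySTRF(v)), bank15@cf[9])
  v[6, 3] <- 5                                        # tie with channel 9
  expect_equal(bestFrequency(toySTRF(v)), bank15@cf[3])
  expect_error(bestFrequency(toySTRF(matrix(-1, 4, 4))), "positive")
})
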