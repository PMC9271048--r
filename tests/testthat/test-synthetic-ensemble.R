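test_that("state sampling honours degenerate occupancies, determinism and the stationary law", {
  allPC <- sampleStates(syntheticEnsembleSpec(500L, 1.0, persistence = 0,
                                              seed = 1L))
  expect_true(all(allPC@stateSequence))
  expect_equal(allPC@realizedOccupancy, 1)

  nonePC <- sampleStates(syntheticEnsembleSpec(500L, 0.0, persistence = 0,
                                               seed = 1L))
  expect_false(any(nonePC@stateSequence))

  # degenerate chain with persistence is rejected
  expect_error(syntheticEnsembleSpec(10L, 1.0, persistence = 0.5, seed = 1L),
               "strictly in \\(0, 1\\)")

  # determinism
  a <- sampleStates(syntheticEnsembleSpec(1000L, 0.33, seed = 7L))
  b <- sampleStates(syntheticEnsembleSpec(1000L, 0.33, seed = 7L))
  expect_identical(a@stateSequence, b@stateSequence)

  # law of large numbers at n = 100,000 (i.i.d. chain, 3-sigma binomial)
  big <- sampleStates(syntheticEnsembleSpec(100000L, 0.33, persistence = 0,
                                            seed = 19L))
  expect_lt(abs(big@realizedOccupancy - 0.33),
            3 * sqrt(0.33 * 0.67 / 100000))
})

test_that("embedding realizes sampled distances inside the state bounds and matches the truth", {
  spec <- syntheticEnsembleSpec(300L, 0.4, persistence = 0.5, seed = 23L)
  crit <- serAttackCriterion()
  sim <- generateEnsemble(spec, crit)
  s <- computeDistanceSeries(sim$ensemble, crit)
  states <- sim$truth@stateSequence
  dists <- spec@stateDistributions
  for (lab in c("D_5C_OG", "D_NE2_HG")) {
    v <- distanceValues(s)[, lab]
    pc <- dists$pc[[lab]]; non <- dists$nonpc[[lab]]
    expect_true(all(v[states] >= pc[3] - 1e-9 & v[states] <= pc[4] + 1e-9))
    expect_true(all(v[!states] >= non[3] - 1e-9 & v[!states] <= non[4] + 1e-9))
  }
  # classification of the emitted ensemble reproduces the truth exactly
  expect_identical(classifyPC(s, crit), states)
  # fixed pseudo-bonds are realized exactly (embed-then-measure fidelity)
  oghg <- computeDistanceSeries(sim$ensemble, list(
    distanceDefinition("oghg", atomQuery("OG", resSeq = 95),
                       atomQuery("HG", resSeq = 95))))
  expect_lt(max(abs(distanceValues(oghg)[, 1] - 0.96)), 1e-6)
})

test_that("generation is byte-deterministic given the seed", {
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  writeEnsemble(generateEnsemble(
    syntheticEnsembleSpec(10L, 0.3, seed = 99L))$ensemble, f1)
  writeEnsemble(generateEnsemble(
    syntheticEnsembleSpec(10L, 0.3, seed = 99L))$ensemble, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and sampleStates agrees with the sequence used by generateEnsemble
  spec <- syntheticEnsembleSpec(200L, 0.3, seed = 55L)
  expect_identical(sampleStates(spec)@stateSequence,
                   generateEnsemble(spec)$truth@stateSequence)
})

test_that("state persistence maps to lag-1 autocorrelation monotonically", {
  ac1 <- function(x) {
    x <- as.numeric(x)
    cor(x[-length(x)], x[-1])
  }
  acs <- vapply(c(0, 0.5, 0.9), function(rho)
    ac1(sampleStates(syntheticEnsembleSpec(
      20000L, 0.33, persistence = rho, seed = 37L))@stateSequence),
    numeric(1))
  expect_true(acs[1] < acs[2] && acs[2] < acs[3])
  expect_equal(acs[2], 0.5, tolerance = 0.05)
  expect_equal(acs[3], 0.9, tolerance = 0.05)
})

test_that("occupancy recovery respects the effective-sample-size bound", {
  n <- 10000L
  crit <- serAttackCriterion()
  for (rho in c(0, 0.5)) {
    for (pi in c(0.192, 0.33)) {
      sim <- generateEnsemble(syntheticEnsembleSpec(
        n, pi, persistence = rho, seed = 211L + round(1000 * pi) + 10L * rho))
      p <- pPC(estimatePPC(classifyPC(
        computeDistanceSeries(sim$ensemble, crit), crit)))
      neff <- n * (1 - rho) / (1 + rho)
      expect_lt(abs(p / 100 - pi), 3 * sqrt(pi * (1 - pi) / neff))
    }
  }
})

test_that("infeasible truncation bounds and inconsistent state distributions are rejected", {
  sd <- privconf:::.DEFAULT_STATE_DISTRIBUTIONS
  sd$pc$D_5C_OG <- c(mean = 2.8, sd = 0.3, lo = 3.7, hi = 1.6)
  expect_error(syntheticEnsembleSpec(10L, 0.3, stateDistributions = sd,
                                     seed = 1L), "infeasible")
  # PC bounds outside the window violate the generator contract
  sd2 <- privconf:::.DEFAULT_STATE_DISTRIBUTIONS
  sd2$pc$D_5C_OG <- c(mean = 4, sd = 0.3, lo = 1.0, hi = 5.0)
  expect_error(generateEnsemble(
    syntheticEnsembleSpec(10L, 0.3, stateDistributions = sd2, seed = 1L)),
    "inside its window")
  # non-PC state fully inside the windows cannot encode the state
  sd3 <- privconf:::.DEFAULT_STATE_DISTRIBUTIONS
  sd3$nonpc$D_5C_OG <- c(mean = 2.8, sd = 0.3, lo = 1.6, hi = 3.7)
  expect_error(generateEnsemble(
    syntheticEnsembleSpec(10L, 0.3, stateDistributions = sd3, seed = 1L)),
    "outside its window")
})

test_that("the fixture suite reproduces the reported occupancy regimes", {
  dir <- file.path(tempdir(), "privconf-fixtures")
  manifest <- makeFixtureSuite(dir)
  expect_true(all(file.exists(manifest$ensemble)))
  expect_true(file.exists(file.path(dir, "ser_attack_criterion.json")))
  crit <- serAttackCriterion()
  ppcs <- vapply(manifest$ensemble, function(p) {
    e <- readEnsemble(p)
    pPC(estimatePPC(classifyPC(computeDistanceSeries(e, crit), crit)))
  }, numeric(1))
  expect_equal(unname(ppcs[manifest$occupancy == 0]), 0)
  expect_equal(unname(ppcs[manifest$occupancy == 1]), 100)
  # middle regimes within the markov-chain tolerance at the default n = 2000
  mid <- manifest$occupancy > 0 & manifest$occupancy < 1
  neff <- 2000 * (1 - 0.5) / (1 + 0.5)
  expect_true(all(abs(ppcs[mid] / 100 - manifest$occupancy[mid]) <=
                    3 * sqrt(manifest$occupancy[mid] *
                             (1 - manifest$occupancy[mid]) / neff)))
  # ground-truth CSV agrees with classification of the written ensemble
  truth <- read.csv(manifest$truth[manifest$occupancy == 0.33])
  e <- readEnsemble(manifest$ensemble[manifest$occupancy == 0.33])
  mask <- classifyPC(computeDistanceSeries(e, crit), crit)
  expect_identical(as.integer(mask), truth$pc_state)
})
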