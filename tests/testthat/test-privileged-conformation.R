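seriesFromMatrix <- function(values, labels) {
  colnames(values) <- labels
  new("GeometrySeries", values = values)
}

test_that("distance series match hand-placed separations and naive recomputation", {
  ens <- toyTriadEnsemble(dNe2Hg = 2.5, nFrames = 2L)
  defs <- list(
    distanceDefinition("d_og_hg", atomQuery("OG", resSeq = 95),
                       atomQuery("HG", resSeq = 95)),
    distanceDefinition("d_hg_ne2", atomQuery("HG", resSeq = 95),
                       atomQuery("NE2", resSeq = 246)))
  s <- computeDistanceSeries(ens, defs)
  expect_equal(nFrames(s), 2L)
  expect_equal(unname(distanceValues(s)[, "d_og_hg"]), c(0.96, 0.96))
  expect_equal(unname(distanceValues(s)[, "d_hg_ne2"]), c(2.5, 2.5))

  # duplicate definitions under distinct labels give identical columns
  dup <- computeDistanceSeries(ens, c(defs, list(
    distanceDefinition("d_og_hg2", atomQuery("OG", resSeq = 95),
                       atomQuery("HG", resSeq = 95)))))
  expect_identical(unname(distanceValues(dup)[, "d_og_hg"]),
                   unname(distanceValues(dup)[, "d_og_hg2"]))

  # unresolvable selection fails before computing anything
  expect_error(
    computeDistanceSeries(ens, list(
      distanceDefinition("bad", atomQuery("XX", resSeq = 95),
                         atomQuery("OG", resSeq = 95)))),
    "no atom matches")

  # 100-frame synthetic ensemble: series equals per-frame brute force
  sim <- generateEnsemble(syntheticEnsembleSpec(100L, 0.3, seed = 5L))
  crit <- serAttackCriterion()
  s2 <- computeDistanceSeries(sim$ensemble, crit)
  idx <- vapply(c("C5P", "OG"), function(nm)
    which(topology(sim$ensemble)$name == nm), integer(1))
  brute <- vapply(getFrames(sim$ensemble), function(f)
    naiveDistance(f[idx[1], ], f[idx[2], ]), numeric(1))
  expect_equal(unname(distanceValues(s2)[, "D_5C_OG"]), brute,
               tolerance = 1e-12)
})

test_that("PC classification uses closed windows over all members", {
  crit <- serAttackCriterion()
  vals <- rbind(
    c(2.0, 2.5),   # inside both -> PC
    c(3.9, 2.5),   # D_5C_OG outside -> not PC
    c(3.8, 3.5),   # exactly on both upper bounds -> PC (closed interval)
    c(1.5, 1.6),   # exactly on both lower bounds -> PC
    c(2.0, 3.51))  # D_NE2_HG outside
  s <- seriesFromMatrix(vals, c("D_5C_OG", "D_NE2_HG"))
  expect_equal(classifyPC(s, crit), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(classifyPC(seriesFromMatrix(vals, c("A", "B")), crit),
               "absent")
})

test_that("occupancy estimation is the exact frame fraction", {
  expect_equal(pPC(estimatePPC(c(TRUE, FALSE, TRUE, TRUE))), 75)
  expect_equal(pPC(estimatePPC(rep(FALSE, 137))), 0)
  mask <- rep(c(TRUE, FALSE), c(330, 670))
  expect_equal(pPC(estimatePPC(mask)), 33.0)
  expect_error(estimatePPC(logical(0)), "at least one")
  res <- estimatePPC(mask, "ser-attack")
  expect_equal(res@nPC, 330L)
  expect_identical(pcMask(res), mask)
})

test_that("moving-block bootstrap CI behaves on degenerate, i.i.d. and reseeded input", {
  expect_equal(bootstrapCI(rep(TRUE, 200), blockLength = 10, seed = 1),
               c(100, 100))
  # i.i.d. mask with blockLength 1 brackets the binomial percentile interval
  set.seed(9)
  mask <- runif(1000) < 0.3
  ci <- bootstrapCI(mask, blockLength = 1, nBoot = 2000, seed = 3)
  phat <- mean(mask)
  binom <- 100 * qbinom(c(0.025, 0.975), 1000, phat) / 1000
  expect_lt(abs(ci[1] - binom[1]), 1.0)
  expect_lt(abs(ci[2] - binom[2]), 1.0)
  expect_true(ci[1] <= 100 * phat && ci[2] >= 100 * phat)
  # determinism
  expect_identical(bootstrapCI(mask, blockLength = 25, seed = 11),
                   bootstrapCI(mask, blockLength = 25, seed = 11))
  expect_error(bootstrapCI(mask, blockLength = 2000, seed = 1), "exceeds")
  expect_error(bootstrapCI(mask, blockLength = 10, nBoot = 10, seed = 1),
               ">= 100")
})

test_that("H-bond summaries match direct statistics", {
  s <- seriesFromMatrix(cbind(rep(2, 10)), "D_OD1_HD1")
  out <- hbondSummary(s, "D_OD1_HD1")
  expect_equal(out$mean, 2)
  expect_equal(out$median, 2)
  expect_equal(out$sd, 0)
  expect_equal(out$fraction_below, 1)

  s2 <- seriesFromMatrix(cbind(c(1.8, 2.2)), "D_OD1_HD1")
  out2 <- hbondSummary(s2, "D_OD1_HD1")
  expect_equal(out2$mean, 2)
  expect_equal(out2$fraction_below, 1)

  # 500-frame synthetic ensemble vs brute-force statistics
  sim <- generateEnsemble(syntheticEnsembleSpec(500L, 0.4, seed = 13L))
  hb <- computeDistanceSeries(sim$ensemble, triadHBondDefinitions())
  out3 <- hbondSummary(hb, c("D_OD1_HD1", "D_OD2_HD1"))
  for (lab in c("D_OD1_HD1", "D_OD2_HD1")) {
    v <- distanceValues(hb)[, lab]
    row <- out3[out3$label == lab, ]
    expect_equal(row$mean, sum(v) / length(v), tolerance = 1e-12)
    expect_equal(row$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
    expect_equal(row$fraction_below, sum(v <= 2.5) / length(v))
  }
  expect_error(hbondSummary(hb, character(0)), "non-empty")
  expect_error(hbondSummary(hb, "nope"), "absent")
})

test_that("triad survey measures HG-NE2, falls back to OG-NE2 and records row errors", {
  structs <- list(
    good = toyTriadEnsemble(dNe2Hg = 2.0),
    noH = toyTriadEnsemble(dNe2Hg = 2.0, withHG = FALSE),
    far = toyTriadEnsemble(dNe2Hg = 4.2))
  out <- triadSurvey(structs)
  expect_equal(out$atom_pair, c("HG-NE2", "OG-NE2", "HG-NE2"))
  expect_equal(out$fallback, c(FALSE, TRUE, FALSE))
  expect_equal(out$in_window, c(TRUE, TRUE, FALSE))
  expect_equal(out$distance[1], 2.0)
  expect_equal(out$distance[2], 2.96)  # OG is 0.96 A behind HG on the axis

  # a structure missing the His does not abort the survey
  broken <- toyTriadEnsemble()
  keep <- topology(broken)$resSeq != 246L
  broken <- ensemble(topology(broken)[keep, ],
                     lapply(getFrames(broken),
                            function(f) f[keep, , drop = FALSE]))
  out2 <- triadSurvey(list(bad = broken, good = toyTriadEnsemble()))
  expect_match(out2$error[1], "no atom matches")
  expect_true(is.na(out2$distance[1]))
  expect_equal(out2$in_window[2], TRUE)

  # survey equals composed pair_distance calls over synthetic structures
  sims <- lapply(1:5, function(k)
    generateEnsemble(syntheticEnsembleSpec(1L, 0.5, persistence = 0,
                                           seed = 100L + k))$ensemble)
  out3 <- triadSurvey(sims)
  manual <- vapply(sims, function(e)
    pairDistance(getFrames(e)[[1]],
                 selectAtom(e, atomQuery("HG", resSeq = 95)),
                 selectAtom(e, atomQuery("NE2", resSeq = 246))),
    numeric(1))
  expect_equal(out3$distance, manual, tolerance = 1e-12)
})

test_that("occupancy is window-monotone, permutation-invariant and bounded", {
  set.seed(21)
  vals <- cbind(runif(400, 1, 6), runif(400, 1, 5))
  s <- seriesFromMatrix(vals, c("D_5C_OG", "D_NE2_HG"))
  base <- serAttackCriterion()
  p0 <- pPC(estimatePPC(classifyPC(s, base)))
  for (rep in 1:10) {
    wider <- base
    i <- sample(2, 1)
    wider@members$lo[i] <- wider@members$lo[i] - runif(1, 0, 1)
    wider@members$hi[i] <- wider@members$hi[i] + runif(1, 0, 1)
    p1 <- pPC(estimatePPC(classifyPC(s, wider)))
    expect_gte(p1, p0)
    expect_true(p1 >= 0 && p1 <= 100)
  }
  # permutation invariance of the point estimate
  perm <- sample(400)
  s2 <- seriesFromMatrix(vals[perm, ], c("D_5C_OG", "D_NE2_HG"))
  expect_equal(pPC(estimatePPC(classifyPC(s2, base))), p0)
})

test_that("one-call analysis applies burn-in and stride and carries a CI", {
  sim <- generateEnsemble(syntheticEnsembleSpec(400L, 0.3, seed = 8L))
  res <- computePPC(sim$ensemble, serAttackCriterion(), seed = 2L,
                    blockLength = 20L, nBoot = 200L)
  expect_s4_class(res, "PCResult")
  ci <- ciBounds(res)
  expect_true(ci["lo"] <= pPC(res) && ci["hi"] >= pPC(res))
  # burn-in discards the first half; stride 2 halves again
  res2 <- computePPC(sim$ensemble, serAttackCriterion(), burnIn = 0.5,
                     stride = 2L, ci = FALSE)
  expect_equal(length(pcMask(res2)), 100L)
  full <- classifyPC(computeDistanceSeries(sim$ensemble,
                                           serAttackCriterion()),
                     serAttackCriterion())
  expect_identical(pcMask(res2), full[seq(201, 400, by = 2)])
})
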