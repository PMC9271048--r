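test_that("tanimoto similarity matches its definition and the bit-loop oracle", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0, 0), c(0, 0, 0)), 1.0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(8:64, 1)
    a <- rbinom(n, 1, 0.4); b <- rbinom(n, 1, 0.4)
    expect_equal(tanimoto(a, b), loopTanimoto(a, b), tolerance = 1e-12)
    # symmetry, bounds, self-identity
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_true(tanimoto(a, b) >= 0 && tanimoto(a, b) <= 1)
    expect_equal(tanimoto(a, a), 1.0)
  }
  # similarity 1 iff identical (non-zero vectors)
  a <- c(1, 0, 1, 0); b <- c(1, 0, 1, 1)
  expect_lt(tanimoto(a, b), 1)
})

test_that("multi-query ranking aggregates by max and matches exhaustive enumeration", {
  lib <- randomFingerprints(200, 32, seed = 11)
  # plant an exact copy of a query in the library
  qbits <- fingerprintBits(lib)[17, , drop = FALSE]
  queries <- fingerprintLibrary(c("Q1", "Q2"),
                                rbind(qbits, rbinom(32, 1, 0.3)))
  rk <- rankByQueries(lib, queries, cascadeConfig(topNPerQuery = 100))
  expect_equal(rk$ranked$score[1], 1.0)
  planted <- recordIds(lib)[17]
  expect_true(planted %in% rk$ranked$id[rk$ranked$score == 1.0])

  # aggregate = max over per-query similarities; top-100 equals brute force
  bits <- fingerprintBits(lib)
  qb <- fingerprintBits(queries)
  bruteScore <- vapply(seq_len(nrow(bits)), function(i)
    max(loopTanimoto(bits[i, ], qb[1, ]), loopTanimoto(bits[i, ], qb[2, ])),
    numeric(1))
  ord <- order(-bruteScore, recordIds(lib))
  expect_equal(rk$ranked$id, recordIds(lib)[ord])
  expect_equal(rk$ranked$score, bruteScore[ord], tolerance = 1e-12)
  top100 <- rk$ranked$id[1:100]
  expect_setequal(top100, recordIds(lib)[ord][1:100])
  # per-query top lists are ranked by that query alone
  oq <- order(-vapply(seq_len(nrow(bits)), function(i)
    loopTanimoto(bits[i, ], qb[2, ]), numeric(1)), recordIds(lib))
  expect_equal(rk$perQueryTop[[2]]$id, recordIds(lib)[oq][1:100])
  # bit-length mismatch anywhere is an error
  expect_error(rankByQueries(lib, fingerprintLibrary("Q", rbind(rep(1, 16)))),
               "mismatch")
})

test_that("Taylor-Butina clustering matches the reference implementation", {
  # distinct fingerprints at threshold 0 -> all singletons
  lib <- randomFingerprints(12, 24, seed = 4)
  cl0 <- butinaCluster(lib, 0)
  expect_equal(lengths(cl0), setNames(rep(1L, 12), names(cl0)))
  # two identical fingerprints cluster together at any threshold
  twin <- fingerprintLibrary(c("A", "B"), rbind(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(sort(butinaCluster(twin, 0)[[1]]), c("A", "B"))
  expect_error(butinaCluster(twin, 1.5), "\\[0, 1\\]")

  # reference equivalence on small random pools across thresholds
  for (seed in 1:4) {
    pool <- randomFingerprints(sample(10:20, 1), 24, seed = 100 + seed)
    for (thr in c(0.2, 0.5, 0.8)) {
      got <- butinaCluster(pool, thr)
      ref <- refButina(recordIds(pool), fingerprintBits(pool), thr)
      expect_identical(got, ref)
    }
  }
})

test_that("clustering covers the pool exactly once and shrinks with looser thresholds", {
  pool <- randomFingerprints(40, 32, seed = 8)
  prev <- Inf
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cl <- butinaCluster(pool, thr)
    members <- unlist(cl, use.names = FALSE)
    expect_setequal(members, recordIds(pool))
    expect_equal(anyDuplicated(members), 0L)
    expect_lte(length(cl), prev)
    prev <- length(cl)
  }
})

test_that("center selection takes the largest clusters with score/id tie-breaks", {
  clusters <- list(c1 = c("c1", "x1", "x2"), c2 = c("c2", "x3", "x4"),
                   c3 = c("c3", "x5"))
  cfg <- cascadeConfig(nCenters = 10)
  expect_equal(length(selectCenters(clusters, cfg)), 3L)
  # equal sizes: order by score, then ascending id
  scores <- c(c1 = 0.4, c2 = 0.9, c3 = 0.1)
  expect_equal(selectCenters(clusters, cascadeConfig(nCenters = 2), scores),
               c("c2", "c1"))
  tied <- list(b = c("b", "x"), a = c("a", "y"))
  expect_equal(selectCenters(tied, cascadeConfig(nCenters = 2)),
               c("a", "b"))

  # hand-worked 15-record pool: three planted motifs + noise
  set.seed(5)
  motif <- function(on) { v <- rep(0L, 24); v[on] <- 1L; v }
  bits <- rbind(
    motif(1:8), motif(c(1:7, 9)), motif(c(1:6, 9, 10)), motif(c(1:8, 10)),
    motif(c(1:7, 11)), motif(c(1:8, 12)),                    # 6 near motif A
    motif(13:18), motif(c(13:17, 19)), motif(c(13:18, 20)),
    motif(c(13:16, 19, 20)),                                 # 4 near motif B
    motif(21:24), motif(c(21:23, 1)),                        # 2 near motif C
    motif(c(2, 9, 14)), motif(c(5, 19, 22)), motif(c(7, 11, 20)))  # noise
  pool <- fingerprintLibrary(sprintf("P%02d", 1:15), bits)
  cl <- butinaCluster(pool, 0.5)
  centers <- selectCenters(cl, cascadeConfig(nCenters = 3))
  sizes <- sort(lengths(cl), decreasing = TRUE)
  expect_equal(unname(lengths(cl)[centers]), unname(sizes[1:3]))
  # the two dominant planted families head the list
  expect_true(all(c(TRUE, TRUE) ==
    (substr(centers[1:2], 1, 3) %in% sprintf("P%02d", 1:10))))
})

test_that("the full cascade is deterministic and honours its config", {
  lib <- randomFingerprints(300, 48, seed = 21)
  queries <- randomFingerprints(13, 48, seed = 22)
  cfg <- cascadeConfig(topNPerQuery = 100, poolRankCut = 130,
                       nCenters = 10, clusterThreshold = 0.6)
  r1 <- runCascade(lib, queries, cfg)
  r2 <- runCascade(lib, queries, cfg)
  expect_identical(r1@centers, r2@centers)
  expect_identical(r1@clusters, r2@clusters)
  expect_equal(nrow(r1@rankedPool), 100L)
  expect_equal(nrow(r1@triageList), 130L)
  expect_lte(length(r1@centers), 10L)
  expect_true(all(r1@centers %in% r1@rankedPool$id))
  # per-query pooling mode unions the per-query top lists
  cfgPQ <- cascadeConfig(topNPerQuery = 20, poolMode = "per-query")
  rPQ <- runCascade(lib, queries, cfgPQ)
  un <- unique(unlist(lapply(rPQ@perQueryTop, function(d) d$id)))
  expect_setequal(rPQ@rankedPool$id, un)
})

test_that("fingerprint TSV reading handles bit strings and hex", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# library", "A\t10110011", "B\tb3", "C\t00000000"), f)
  lib <- readFingerprintTSV(f)
  expect_equal(nBits(lib), 8L)
  expect_equal(fingerprintBits(lib)[1, ], c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  # hex b3 = 1011 0011, identical to record A
  expect_equal(fingerprintBits(lib)[2, ], fingerprintBits(lib)[1, ])
  expect_equal(sum(fingerprintBits(lib)[3, ]), 0L)
  writeLines(c("A\t0101", "B\t01"), f)
  expect_error(readFingerprintTSV(f), "share one bit length")
  writeLines(c("A 0101"), f)
  expect_error(readFingerprintTSV(f), "id<TAB>fingerprint")
})
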