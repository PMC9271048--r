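# Independent oracles and fixture builders.  Everything here is coded
# separately from the package implementation so the tests compare two
# routes to the same quantity.

# -- geometry ---------------------------------------------------------------

# naive scalar Euclidean distance
naiveDistance <- function(p, q) {
  sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
}

# frame-by-frame window count, coded independently of classifyPC/estimatePPC
bruteForcePPCPercent <- function(ens, criterion) {
  top <- topology(ens)
  m <- criterion@members
  findAtom <- function(name, resSeq, resName, chain) {
    hit <- top$name == name
    if (!is.na(resSeq)) hit <- hit & top$resSeq == resSeq
    if (!is.na(resName)) hit <- hit & top$resName == resName
    if (!is.na(chain)) hit <- hit & top$chain == chain
    which(hit)
  }
  nPC <- 0L
  for (f in getFrames(ens)) {
    ok <- TRUE
    for (i in seq_len(nrow(m))) {
      a <- findAtom(m$nameA[i], m$resSeqA[i], m$resNameA[i], m$chainA[i])
      b <- findAtom(m$nameB[i], m$resSeqB[i], m$resNameB[i], m$chainB[i])
      d <- naiveDistance(f[a, ], f[b, ])
      if (d < m$lo[i] || d > m$hi[i]) { ok <- FALSE; break }
    }
    if (ok) nPC <- nPC + 1L
  }
  100 * nPC / nFrames(ens)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# hand-placed two-residue toy structure: Ser95 (OG, HG) + His246 (NE2),
# with chosen OG->HG and HG->NE2 separations along the x axis
toyTriadEnsemble <- function(dNe2Hg = 2.0, nFrames = 1L, withHG = TRUE) {
  top <- data.frame(
    serial = 1:3,
    name = c("OG", "HG", "NE2"),
    resName = c("SER", "SER", "HIS"),
    resSeq = c(95L, 95L, 246L),
    chain = "A",
    element = c("O", "H", "N"),
    stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96 + dNe2Hg, 0, 0))
  if (!withHG) {
    top <- top[-2L, ]
    top$serial <- seq_len(nrow(top))
    coords <- coords[-2L, , drop = FALSE]
  }
  ensemble(top, replicate(nFrames, coords, simplify = FALSE),
           provenance = "toy triad")
}

# -- screening --------------------------------------------------------------

# bit-loop Tanimoto
loopTanimoto <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (k in seq_along(a)) {
    if (a[k] == 1L && b[k] == 1L) inter <- inter + 1L
    if (a[k] == 1L || b[k] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) return(1)
  inter / uni
}

# independently coded Taylor-Butina reference: neighbour lists at
# distance <= threshold, repeatedly take the unassigned record with most
# unassigned neighbours (ties by ascending id) as a center
refButina <- function(ids, bits, threshold) {
  n <- length(ids)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    sim[i, j] <- loopTanimoto(bits[i, ], bits[j, ])
  neigh <- lapply(seq_len(n), function(i)
    setdiff(which(1 - sim[i, ] <= threshold), i))
  left <- rep(TRUE, n)
  clusters <- list()
  while (any(left)) {
    cand <- which(left)
    cnt <- sapply(cand, function(i) sum(left[neigh[[i]]]))
    ordc <- cand[order(-cnt, ids[cand])]
    ctr <- ordc[1L]
    mem <- c(ctr, neigh[[ctr]][left[neigh[[ctr]]]])
    left[mem] <- FALSE
    clusters[[ids[ctr]]] <- ids[mem]
  }
  clusters
}

randomFingerprints <- function(n, nbits, density = 0.3, seed = 1) {
  set.seed(seed)
  fingerprintLibrary(sprintf("FP%04d", seq_len(n)),
                     matrix(rbinom(n * nbits, 1, density), n))
}

# -- peptide masses ---------------------------------------------------------

# standard monoisotopic residue masses (5-decimal published table) --
# deliberately a different data source than the package's elemental sums
ORACLE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

# brute-force b/y series from the oracle residue table; mods is a named
# numeric vector position -> mass addition
oracleIons <- function(sequence, mods = numeric(0)) {
  aa <- strsplit(sequence, "")[[1]]
  m <- ORACLE_RESIDUE_MASS[aa]
  if (length(mods))
    m[as.integer(names(mods))] <- m[as.integer(names(mods))] + mods
  n <- length(m)
  b <- y <- numeric(n - 1)
  for (i in seq_len(n - 1)) b[i] <- sum(m[1:i]) + ORACLE_PROTON
  for (j in seq_len(n - 1))
    y[j] <- sum(m[(n - j + 1):n]) + ORACLE_WATER + ORACLE_PROTON
  list(b = b, y = y, neutral = sum(m) + ORACLE_WATER)
}

randomPeptide <- function(len) {
  paste(sample(names(ORACLE_RESIDUE_MASS), len, replace = TRUE),
        collapse = "")
}

# -- assay ------------------------------------------------------------------

# closed-form simple-regression slope and its standard error
olsSlopeSE <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (length(x) - 2) / sum((x - mean(x))^2))
  c(slope = b, se = se)
}

fourPL <- function(conc, mid, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(mid) - log10(conc))))
}
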