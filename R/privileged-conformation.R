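#' Define a monitored distance
#'
#' @param label unique label for the distance (e.g. \code{"D_5C_OG"}).
#' @param atomA,atomB [atomQuery()] selections for the two atoms.
#' @return a distance definition usable in [computeDistanceSeries()] and
#'   [pcCriterion()].
#' @export
distanceDefinition <- function(label, atomA, atomB) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  list(label = label, atomA = atomA, atomB = atomB)
}

.memberRow <- function(def, lo = NA_real_, hi = NA_real_) {
  data.frame(label = def$label,
             nameA = def$atomA$name, resSeqA = def$atomA$resSeq,
             resNameA = def$atomA$resName, chainA = def$atomA$chain,
             nameB = def$atomB$name, resSeqB = def$atomB$resSeq,
             resNameB = def$atomB$resName, chainB = def$atomB$chain,
             lo = lo, hi = hi, stringsAsFactors = FALSE)
}

.rowToDef <- function(m) {
  distanceDefinition(
    m$label,
    atomQuery(m$nameA, resSeq = m$resSeqA, resName = m$resNameA,
              chain = m$chainA),
    atomQuery(m$nameB, resSeq = m$resSeqB, resName = m$resNameB,
              chain = m$chainB))
}

#' Build a privileged-conformation criterion
#'
#' A frame is classified as a privileged conformation (PC) iff every member
#' distance lies in its closed window \code{[lo, hi]} (boundary values count
#' as inside).
#'
#' @param name criterion name.
#' @param members list of \code{list(def = distanceDefinition,
#'   window = c(lo, hi))} entries.
#' @return a [PCCriterion].
#' @seealso [serAttackCriterion()], [hisAttackCriterion()]
#' @export
pcCriterion <- function(name, members) {
  rows <- lapply(members, function(m) {
    w <- m$window
    if (length(w) != 2L) stop("each member needs window = c(lo, hi)")
    .memberRow(m$def, lo = w[1L], hi = w[2L])
  })
  methods::new("PCCriterion", name = name, members = do.call(rbind, rows))
}

#' Serine-attack privileged-conformation criterion
#'
#' Nucleophilic attack of the serine OG on the 5'C carbonyl carbon of the
#' D-ring: \code{D_5C_OG} (ligand 5'C to Ser OG) within 1.5--3.8 A and
#' \code{D_NE2_HG} (His NE2 to Ser HG) within 1.6--3.5 A.
#'
#' @param serResSeq serine residue number (default 95, ShHTL7 numbering).
#' @param hisResSeq histidine residue number (default 246).
#' @param ligResName ligand residue code carrying the D-ring (default
#'   \code{"LIG"}).
#' @param ligC5Name,chain atom name of the ligand 5'C (default
#'   \code{"C5P"}) and optional chain restriction.
#' @return a [PCCriterion].
#' @export
serAttackCriterion <- function(serResSeq = 95L, hisResSeq = 246L,
                               ligResName = "LIG", ligC5Name = "C5P",
                               chain = NA) {
  pcCriterion("ser-attack", list(
    list(def = distanceDefinition(
           "D_5C_OG",
           atomQuery(ligC5Name, resName = ligResName, chain = chain),
           atomQuery("OG", resSeq = serResSeq, chain = chain)),
         window = c(1.5, 3.8)),
    list(def = distanceDefinition(
           "D_NE2_HG",
           atomQuery("NE2", resSeq = hisResSeq, chain = chain),
           atomQuery("HG", resSeq = serResSeq, chain = chain)),
         window = c(1.6, 3.5))))
}

#' Histidine-attack privileged-conformation criterion
#'
#' The alternative hydrolysis route: direct nucleophilic attack of the His
#' NE2 on the 2'C of the D-ring.  \code{D_2C_NE2} within 1.5--3.8 A and
#' \code{D_NE2_HG} within 1.6--3.5 A.
#'
#' @inheritParams serAttackCriterion
#' @param ligC2Name atom name of the ligand 2'C (default \code{"C2P"}).
#' @return a [PCCriterion].
#' @export
hisAttackCriterion <- function(serResSeq = 95L, hisResSeq = 246L,
                               ligResName = "LIG", ligC2Name = "C2P",
                               chain = NA) {
  pcCriterion("his-attack", list(
    list(def = distanceDefinition(
           "D_2C_NE2",
           atomQuery(ligC2Name, resName = ligResName, chain = chain),
           atomQuery("NE2", resSeq = hisResSeq, chain = chain)),
         window = c(1.5, 3.8)),
    list(def = distanceDefinition(
           "D_NE2_HG",
           atomQuery("NE2", resSeq = hisResSeq, chain = chain),
           atomQuery("HG", resSeq = serResSeq, chain = chain)),
         window = c(1.6, 3.5))))
}

#' Catalytic-triad H-bond diagnostic definitions
#'
#' The His--Asp hydrogen-bond distances \code{D_OD1_HD1} and
#' \code{D_OD2_HD1} monitored alongside (not inside) the PC criterion.
#'
#' @param hisResSeq,aspResSeq residue numbers (defaults 246 and 217).
#' @param chain optional chain restriction.
#' @return list of distance definitions for [computeDistanceSeries()].
#' @export
triadHBondDefinitions <- function(hisResSeq = 246L, aspResSeq = 217L,
                                  chain = NA) {
  list(
    distanceDefinition("D_OD1_HD1",
                       atomQuery("OD1", resSeq = aspResSeq, chain = chain),
                       atomQuery("HD1", resSeq = hisResSeq, chain = chain)),
    distanceDefinition("D_OD2_HD1",
                       atomQuery("OD2", resSeq = aspResSeq, chain = chain),
                       atomQuery("HD1", resSeq = hisResSeq, chain = chain)))
}

#' Compute per-frame distance series
#'
#' Resolves every selection against the topology first (any unresolvable
#' selection is an error before computation starts), then evaluates every
#' definition in every frame.
#'
#' @param ensemble an [Ensemble].
#' @param defs a list of [distanceDefinition()]s, or a [PCCriterion] whose
#'   member definitions are used.
#' @return a [GeometrySeries] with one row per frame and one labelled
#'   column per definition, frame order preserved.
#' @export
computeDistanceSeries <- function(ensemble, defs) {
  stopifnot(methods::is(ensemble, "Ensemble"))
  if (methods::is(defs, "PCCriterion"))
    defs <- lapply(seq_len(nrow(defs@members)),
                   function(i) .rowToDef(defs@members[i, ]))
  if (!length(defs)) stop("no distance definitions supplied")
  labels <- vapply(defs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("distance labels must be unique")
  idxA <- vapply(defs, function(d) selectAtom(ensemble, d$atomA), integer(1))
  idxB <- vapply(defs, function(d) selectAtom(ensemble, d$atomB), integer(1))
  vals <- vapply(ensemble@frames, function(f) {
    sqrt(rowSums((f[idxA, , drop = FALSE] - f[idxB, , drop = FALSE])^2))
  }, numeric(length(defs)))
  vals <- if (length(defs) == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(vals) <- labels
  methods::new("GeometrySeries", values = vals)
}

#' Classify frames against a privileged-conformation criterion
#'
#' @param series a [GeometrySeries] containing every criterion label.
#' @param criterion a [PCCriterion].
#' @return logical per-frame mask: \code{TRUE} iff all member distances lie
#'   in their closed windows.
#' @export
classifyPC <- function(series, criterion) {
  stopifnot(methods::is(series, "GeometrySeries"),
            methods::is(criterion, "PCCriterion"))
  m <- criterion@members
  missing <- setdiff(m$label, colnames(series@values))
  if (length(missing))
    stop("criterion label(s) absent from series: ",
         paste(missing, collapse = ", "))
  mask <- rep(TRUE, nrow(series@values))
  for (i in seq_len(nrow(m))) {
    v <- series@values[, m$label[i]]
    mask <- mask & v >= m$lo[i] & v <= m$hi[i]
  }
  mask
}

#' Estimate the privileged-conformation occupancy
#'
#' \eqn{P_{PC} = 100 \cdot n_{PC} / n_{frames}} over a classification mask.
#'
#' @param mask logical per-frame PC mask (no NA).
#' @param criterionName name recorded in the result.
#' @return a [PCResult] without confidence interval.
#' @examples
#' pPC(estimatePPC(c(TRUE, FALSE, TRUE, TRUE)))  # 75
#' @export
estimatePPC <- function(mask, criterionName = "pc") {
  if (!length(mask)) stop("mask must contain at least one frame")
  if (anyNA(mask)) stop("mask must not contain NA")
  mask <- as.logical(mask)
  n <- length(mask)
  nPC <- sum(mask)
  methods::new("PCResult", mask = mask, nPC = as.integer(nPC),
               pPC = 100 * nPC / n, ciLo = NA_real_, ciHi = NA_real_,
               criterionName = criterionName)
}

#' Moving-block bootstrap confidence interval for P_PC
#'
#' Resamples the (autocorrelated) classification mask in overlapping
#' moving blocks of \code{blockLength} frames, recomputes the occupancy in
#' each replicate, and returns the 2.5/97.5 percentile interval in
#' percent.  Deterministic given \code{seed}.
#'
#' @param mask logical per-frame PC mask.
#' @param blockLength block length in frames (default 50; use 1 for
#'   independent frames).
#' @param nBoot number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed (mandatory).
#' @return numeric \code{c(lo, hi)} in percent.
#' @export
bootstrapCI <- function(mask, blockLength = 50L, nBoot = 1000L, seed) {
  if (missing(seed)) stop("bootstrapCI requires an explicit seed")
  n <- length(mask)
  if (n < 1L) stop("mask must contain at least one frame")
  blockLength <- as.integer(blockLength)
  nBoot <- as.integer(nBoot)
  if (blockLength < 1L) stop("blockLength must be >= 1")
  if (blockLength > n)
    stop(sprintf("blockLength (%d) exceeds the number of frames (%d)",
                 blockLength, n))
  if (nBoot < 100L) stop("nBoot must be >= 100")
  x <- as.numeric(mask)
  nBlocks <- ceiling(n / blockLength)
  starts <- seq_len(n - blockLength + 1L)
  # precomputed block means make each replicate mean a mean of block means
  # (exact when blockLength divides n; the trailing partial block is
  # handled by trimming the concatenated series to n frames)
  reps <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      s <- sample(starts, nBlocks, replace = TRUE)
      idx <- as.vector(outer(0:(blockLength - 1L), s, `+`))[seq_len(n)]
      mean(x[idx])
    }, numeric(1))
  })
  unname(100 * stats::quantile(reps, c(0.025, 0.975), names = FALSE,
                               type = 7))
}

#' One-call privileged-conformation occupancy analysis
#'
#' Computes the criterion distance series, classifies frames, estimates
#' P_PC and (optionally) attaches a moving-block bootstrap CI.  An optional
#' burn-in fraction and frame stride are applied before classification.
#'
#' @param ensemble an [Ensemble].
#' @param criterion a [PCCriterion].
#' @param burnIn fraction of initial frames to discard (default 0).
#' @param stride keep every stride-th frame (default 1).
#' @param ci compute a bootstrap CI? (default TRUE when \code{seed} given).
#' @param blockLength,nBoot,seed passed to [bootstrapCI()].
#' @return a [PCResult].
#' @export
computePPC <- function(ensemble, criterion, burnIn = 0, stride = 1L,
                       ci = !missing(seed), blockLength = 50L,
                       nBoot = 1000L, seed) {
  stopifnot(burnIn >= 0, burnIn < 1, stride >= 1L)
  series <- computeDistanceSeries(ensemble, criterion)
  mask <- classifyPC(series, criterion)
  keep <- seq.int(floor(burnIn * length(mask)) + 1L, length(mask), by = stride)
  mask <- mask[keep]
  res <- estimatePPC(mask, criterionName = criterion@name)
  if (ci) {
    bounds <- bootstrapCI(mask, blockLength = min(blockLength, length(mask)),
                          nBoot = nBoot, seed = seed)
    res@ciLo <- min(bounds[1L], res@pPC)
    res@ciHi <- max(bounds[2L], res@pPC)
  }
  res
}

#' Summarize monitored hydrogen-bond distances
#'
#' Mean, median, SD and the fraction of frames at or below an H-bond
#' distance threshold for each requested label (used for the His--Asp
#' \code{D_OD1_HD1}/\code{D_OD2_HD1} diagnostics, which are expected to
#' sit around 2 A in a stable triad).
#'
#' @param series a [GeometrySeries].
#' @param labels labels to summarize (must be present in the series).
#' @param threshold H-bond distance cutoff in Angstrom (default 2.5).
#' @return data.frame with columns \code{label}, \code{mean},
#'   \code{median}, \code{sd}, \code{fraction_below}.
#' @export
hbondSummary <- function(series, labels, threshold = 2.5) {
  stopifnot(methods::is(series, "GeometrySeries"))
  if (!length(labels)) stop("labels must be non-empty")
  missing <- setdiff(labels, colnames(series@values))
  if (length(missing))
    stop("label(s) absent from series: ", paste(missing, collapse = ", "))
  rows <- lapply(labels, function(lab) {
    v <- series@values[, lab]
    data.frame(label = lab, mean = mean(v), median = stats::median(v),
               sd = stats::sd(v), fraction_below = mean(v <= threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Survey catalytic-triad geometry across crystal structures
#'
#' For each single-frame structure, measures the Ser HG -- His NE2
#' distance and flags whether it falls in the closed 1.6--3.5 A window.
#' When the structure lacks the serine HG (no hydrogens deposited), the
#' heavy-atom OG--NE2 distance is used instead and flagged explicitly.  A
#' structure missing a triad residue produces a row-level error message
#' and the survey continues.
#'
#' @param structures list of single-frame [Ensemble]s (named, optionally).
#' @param serResSeq,hisResSeq triad residue numbers (defaults 95, 246).
#' @param window closed acceptance window in Angstrom (default
#'   \code{c(1.6, 3.5)}).
#' @return data.frame with columns \code{structure}, \code{distance},
#'   \code{atom_pair}, \code{fallback}, \code{in_window}, \code{error}.
#' @export
triadSurvey <- function(structures, serResSeq = 95L, hisResSeq = 246L,
                        window = c(1.6, 3.5)) {
  nm <- names(structures) %||% as.character(seq_along(structures))
  nm[!nzchar(nm)] <- as.character(which(!nzchar(nm)))
  rows <- lapply(seq_along(structures), function(k) {
    ens <- structures[[k]]
    row <- data.frame(structure = nm[k], distance = NA_real_,
                      atom_pair = NA_character_, fallback = NA,
                      in_window = NA, error = NA_character_,
                      stringsAsFactors = FALSE)
    out <- tryCatch({
      ne2 <- selectAtom(ens, atomQuery("NE2", resSeq = hisResSeq))
      hg <- tryCatch(selectAtom(ens, atomQuery("HG", resSeq = serResSeq)),
                     error = function(e) NA_integer_)
      fallback <- is.na(hg)
      donor <- if (fallback)
        selectAtom(ens, atomQuery("OG", resSeq = serResSeq)) else hg
      d <- pairDistance(ens@frames[[1L]], donor, ne2)
      row$distance <- d
      row$atom_pair <- if (fallback) "OG-NE2" else "HG-NE2"
      row$fallback <- fallback
      row$in_window <- d >= window[1L] && d <= window[2L]
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
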