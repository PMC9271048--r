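#' @import methods
NULL

.TOPOLOGY_COLS <- c("serial", "name", "resName", "resSeq", "chain", "element")

#' Conformational ensemble of a fixed topology
#'
#' An \code{Ensemble} holds an ordered set of frames (conformations) that
#' share one atom topology, the unit consumed by all geometry analysis.
#' The topology is a data frame with one row per atom and columns
#' \code{serial}, \code{name}, \code{resName}, \code{resSeq}, \code{chain}
#' and \code{element}; each frame is an \code{n x 3} numeric matrix of
#' coordinates in Angstrom, in topology order.
#'
#' Residue numbering follows the PDB convention (1-based, kept verbatim);
#' hydrogens are never reconstructed, so H-explicit distances such as
#' HG--NE2 require an H-explicit input.
#'
#' @slot topology data.frame of atom identities (one row per atom).
#' @slot frames list of n_atoms x 3 numeric coordinate matrices (Angstrom).
#' @slot provenance free-text label describing the origin of the ensemble.
#'
#' @seealso [readEnsemble()], [writeEnsemble()], [selectAtom()],
#'   [computeDistanceSeries()]
#' @exportClass Ensemble
setClass("Ensemble",
  slots = c(topology = "data.frame", frames = "list", provenance = "character")
)

setValidity("Ensemble", function(object) {
  top <- object@topology
  if (!all(.TOPOLOGY_COLS %in% names(top)))
    return(paste("topology must have columns:",
                 paste(.TOPOLOGY_COLS, collapse = ", ")))
  if (nrow(top) < 1L) return("topology must contain at least one atom")
  if (any(!nzchar(top$element))) return("every atom needs a non-empty element")
  key <- paste(top$chain, top$resSeq, top$name)
  if (anyDuplicated(key))
    return("(chain, resSeq, name) must be unique within a topology")
  if (length(object@frames) < 1L) return("an ensemble needs at least one frame")
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.matrix(f) || !is.numeric(f) ||
        nrow(f) != nrow(top) || ncol(f) != 3L)
      return(sprintf("frame %d is not an %d x 3 numeric matrix", i, nrow(top)))
    if (!all(is.finite(f)))
      return(sprintf("frame %d contains non-finite coordinates", i))
  }
  TRUE
})

#' Per-frame reaction-geometry distance series
#'
#' A \code{GeometrySeries} is a frames-by-labels matrix of distances
#' (Angstrom), one column per monitored distance definition, one row per
#' ensemble frame.
#'
#' @slot values numeric matrix (n_frames x n_labels) with labelled columns.
#' @exportClass GeometrySeries
setClass("GeometrySeries", slots = c(values = "matrix"))

setValidity("GeometrySeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(colnames(v)) || any(!nzchar(colnames(v))))
    return("every column must carry a distance label")
  if (anyDuplicated(colnames(v))) return("distance labels must be unique")
  if (nrow(v) < 1L) return("a series needs at least one frame")
  if (!all(is.finite(v))) return("distances must be finite")
  TRUE
})

#' Privileged-conformation criterion
#'
#' A named set of (distance definition, closed window) members.  A frame is
#' a privileged conformation (PC) iff every member distance lies inside its
#' closed interval \code{[lo, hi]}.  The two built-in criteria follow the
#' serine-attack definition (D_5'C-OG in 1.5--3.8 A and D_NE2-HG in
#' 1.6--3.5 A) and the alternative histidine-attack definition
#' (D_2'C-NE2 in 1.5--3.8 A and D_NE2-HG in 1.6--3.5 A).
#'
#' @slot name criterion name (e.g. \code{"ser-attack"}).
#' @slot members data.frame with one row per member: \code{label},
#'   selection fields for both atoms (\code{nameA}, \code{resSeqA},
#'   \code{resNameA}, \code{chainA}, and the B counterparts; \code{NA}
#'   fields are wildcards) and window bounds \code{lo}, \code{hi} (Angstrom).
#'
#' @seealso [pcCriterion()], [serAttackCriterion()], [hisAttackCriterion()],
#'   [classifyPC()]
#' @exportClass PCCriterion
setClass("PCCriterion",
  slots = c(name = "character", members = "data.frame")
)

setValidity("PCCriterion", function(object) {
  m <- object@members
  need <- c("label", "nameA", "resSeqA", "resNameA", "chainA",
            "nameB", "resSeqB", "resNameB", "chainB", "lo", "hi")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) < 1L) return("a criterion needs at least one member")
  if (anyDuplicated(m$label)) return("member labels must be distinct")
  if (any(!is.finite(m$lo)) || any(!is.finite(m$hi)))
    return("window bounds must be finite")
  if (any(m$lo < 0)) return("window lower bounds must be >= 0")
  if (any(m$lo >= m$hi)) return("each window needs lo < hi")
  TRUE
})

#' Privileged-conformation occupancy result
#'
#' Frame classification mask plus the occupancy statistic
#' \eqn{P_{PC} = 100 \cdot n_{PC} / n_{frames}} (percent) and an optional
#' moving-block bootstrap percentile confidence interval.
#'
#' @slot mask per-frame logical PC classification.
#' @slot nPC number of PC frames.
#' @slot pPC occupancy percentage in [0, 100].
#' @slot ciLo,ciHi bootstrap CI bounds (percent); \code{NA} when no CI
#'   was requested.
#' @slot criterionName name of the criterion that produced the mask.
#' @seealso [estimatePPC()], [bootstrapCI()], [computePPC()]
#' @exportClass PCResult
setClass("PCResult",
  slots = c(mask = "logical", nPC = "integer", pPC = "numeric",
            ciLo = "numeric", ciHi = "numeric", criterionName = "character")
)

setValidity("PCResult", function(object) {
  n <- length(object@mask)
  if (n < 1L) return("mask must contain at least one frame")
  if (anyNA(object@mask)) return("mask must not contain NA")
  if (object@nPC != sum(object@mask)) return("nPC must equal sum(mask)")
  expect <- 100 * object@nPC / n
  if (abs(object@pPC - expect) > 1e-9)
    return("pPC must equal 100 * nPC / n_frames")
  if (!is.na(object@ciLo) && !is.na(object@ciHi)) {
    if (object@ciLo > object@pPC + 1e-9 || object@ciHi < object@pPC - 1e-9)
      return("the confidence interval must contain pPC")
  }
  TRUE
})

#' Specification of a synthetic two-state triad/ligand ensemble
#'
#' Parameters of the seeded generator that emulates an autocorrelated
#' receptor--ligand trajectory: a two-state (PC-competent vs displaced)
#' Markov chain with stationary PC occupancy \code{piPC} and per-step
#' persistence \code{rho}, and per-state truncated-Gaussian distance
#' distributions for each monitored label.
#'
#' @slot nFrames number of frames to generate.
#' @slot piPC target stationary PC occupancy in [0, 1].
#' @slot persistence probability of re-using the current state per step,
#'   in [0, 1); lag-1 autocorrelation of the state indicator.
#' @slot stateDistributions list with elements \code{pc} and \code{nonpc};
#'   each a named list label -> \code{c(mean, sd, lo, hi)} (Angstrom).
#' @slot seed integer seed; all sampling is deterministic given it.
#' @seealso [syntheticEnsembleSpec()], [sampleStates()], [generateEnsemble()]
#' @exportClass SyntheticEnsembleSpec
setClass("SyntheticEnsembleSpec",
  slots = c(nFrames = "integer", piPC = "numeric", persistence = "numeric",
            stateDistributions = "list", seed = "integer")
)

setValidity("SyntheticEnsembleSpec", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@piPC < 0 || object@piPC > 1) return("piPC must lie in [0, 1]")
  if (object@persistence < 0 || object@persistence >= 1)
    return("persistence must lie in [0, 1)")
  if (object@persistence > 0 && (object@piPC <= 0 || object@piPC >= 1))
    return("piPC must lie strictly in (0, 1) when persistence > 0")
  sd <- object@stateDistributions
  if (!all(c("pc", "nonpc") %in% names(sd)))
    return("stateDistributions needs elements 'pc' and 'nonpc'")
  for (state in c("pc", "nonpc")) {
    for (lab in names(sd[[state]])) {
      p <- sd[[state]][[lab]]
      if (length(p) != 4L || anyNA(p))
        return(sprintf("%s/%s must be c(mean, sd, lo, hi)", state, lab))
      if (p[2L] <= 0) return(sprintf("%s/%s needs sd > 0", state, lab))
      if (p[3L] >= p[4L])
        return(sprintf("%s/%s has infeasible truncation (lo >= hi)",
                       state, lab))
    }
  }
  TRUE
})

#' Ground-truth state sequence of a synthetic ensemble
#'
#' @slot stateSequence per-frame logical, \code{TRUE} for the PC state.
#' @slot realizedOccupancy fraction of frames in the PC state.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(stateSequence = "logical", realizedOccupancy = "numeric")
)

setValidity("GroundTruth", function(object) {
  if (length(object@stateSequence) < 1L) return("empty state sequence")
  if (anyNA(object@stateSequence)) return("state sequence must not contain NA")
  if (abs(object@realizedOccupancy - mean(object@stateSequence)) > 1e-12)
    return("realizedOccupancy must equal mean(stateSequence)")
  TRUE
})

#' Fingerprint library (or query set)
#'
#' Fixed-length binary fingerprints with unique identifiers, the unit the
#' Tanimoto screening cascade consumes.  All records share one bit length.
#'
#' @slot ids character vector of unique record identifiers.
#' @slot bits integer 0/1 matrix, one row per record, one column per bit.
#' @seealso [fingerprintLibrary()], [readFingerprintTSV()], [tanimoto()],
#'   [rankByQueries()]
#' @exportClass FingerprintLibrary
setClass("FingerprintLibrary",
  slots = c(ids = "character", bits = "matrix")
)

setValidity("FingerprintLibrary", function(object) {
  if (length(object@ids) < 1L) return("library must contain >= 1 record")
  if (anyDuplicated(object@ids)) return("record ids must be unique")
  b <- object@bits
  if (!is.matrix(b) || nrow(b) != length(object@ids))
    return("bits must be a matrix with one row per id")
  if (ncol(b) < 1L) return("fingerprints need n_bits >= 1")
  if (!all(b %in% c(0L, 1L))) return("bits must be 0/1")
  TRUE
})

#' Result of the hierarchical screening cascade
#'
#' @slot rankedPool data.frame of pool members with aggregate Tanimoto
#'   scores, sorted by descending score (ties by ascending id).
#' @slot perQueryTop list of per-query top-n data.frames.
#' @slot clusters named list of character id vectors; names are the
#'   Taylor-Butina cluster centers.
#' @slot centers ids of the selected cluster centers.
#' @slot triageList data.frame of the top pool_rank_cut records retained
#'   for manual structure-based triage.
#' @seealso [runCascade()]
#' @exportClass CascadeResult
setClass("CascadeResult",
  slots = c(rankedPool = "data.frame", perQueryTop = "list",
            clusters = "list", centers = "character",
            triageList = "data.frame")
)

setValidity("CascadeResult", function(object) {
  pool <- object@rankedPool$id
  members <- unlist(object@clusters, use.names = FALSE)
  if (length(members) && !all(members %in% pool))
    return("cluster members must belong to the ranked pool")
  if (length(members) && anyDuplicated(members))
    return("each pool member must be assigned to exactly one cluster")
  if (length(object@centers) &&
      !all(object@centers %in% names(object@clusters)))
    return("centers must be cluster centers")
  TRUE
})

#' Peptide with covalent elemental-formula modifications
#'
#' A tryptic peptide given as an uppercase one-letter sequence with its
#' protein-level start residue number and zero or more modifications, each
#' a pure elemental-formula mass addition (e.g. the butenolide-derived
#' C5H5O2 adduct on the catalytic histidine) keyed by 1-based position
#' within the peptide.
#'
#' @slot sequence uppercase one-letter amino-acid string (20 standard
#'   residues).
#' @slot startResSeq protein residue number of the first peptide residue.
#' @slot modifications named list: position (as character) -> elemental
#'   formula (named integer vector of element counts).
#' @seealso [modifiedPeptide()], [peptideMass()], [fragmentIons()],
#'   [mapModifiedResidue()]
#' @exportClass ModifiedPeptide
setClass("ModifiedPeptide",
  slots = c(sequence = "character", startResSeq = "integer",
            modifications = "list")
)

setValidity("ModifiedPeptide", function(object) {
  seqs <- object@sequence
  if (length(seqs) != 1L || !nzchar(seqs)) return("sequence must be one non-empty string")
  letters1 <- strsplit(seqs, "")[[1L]]
  if (!all(letters1 %in% names(.RESIDUE_FORMULAS)))
    return("sequence must use the 20 standard one-letter residue codes")
  idx <- as.integer(names(object@modifications))
  if (length(object@modifications)) {
    if (anyNA(idx) || any(idx < 1L) || any(idx > nchar(seqs)))
      return("modification indices must be 1-based positions within the peptide")
    for (f in object@modifications) {
      msg <- .checkFormula(f)
      if (!isTRUE(msg)) return(msg)
    }
  }
  TRUE
})

#' Singly charged b/y fragment-ion series
#'
#' Monoisotopic m/z values (charge 1+) of the b and y ions of a peptide,
#' with any covalent modification mass included in every fragment that
#' contains the modified residue.  For a peptide of length n both series
#' have n - 1 entries and satisfy the complementarity identity
#' \eqn{b_i + y_{n-i} = M + 2 m_{proton}}.
#'
#' @slot b m/z of b1..b(n-1) at charge 1+.
#' @slot y m/z of y1..y(n-1) at charge 1+.
#' @slot neutralMass neutral monoisotopic peptide mass M (Da).
#' @slot sequence the peptide sequence the series belongs to.
#' @seealso [fragmentIons()], [matchPeaks()]
#' @exportClass IonSeries
setClass("IonSeries",
  slots = c(b = "numeric", y = "numeric", neutralMass = "numeric",
            sequence = "character")
)

setValidity("IonSeries", function(object) {
  n <- nchar(object@sequence)
  if (length(object@b) != n - 1L || length(object@y) != n - 1L)
    return("b and y series must have length(sequence) - 1 entries")
  if (!all(is.finite(object@b)) || !all(is.finite(object@y)))
    return("ion m/z values must be finite")
  TRUE
})
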