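#' @describeIn Ensemble number of frames.
#' @param x an \code{Ensemble}.
#' @export
setMethod("nFrames", "Ensemble", function(x) length(x@frames))

#' @describeIn Ensemble atom topology data.frame.
#' @export
setMethod("topology", "Ensemble", function(x) x@topology)

#' @describeIn Ensemble list of coordinate matrices.
#' @export
setMethod("getFrames", "Ensemble", function(x) x@frames)

#' @describeIn Ensemble provenance label.
#' @export
setMethod("provenance", "Ensemble", function(x) x@provenance)

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d atoms, %d frame(s)\n",
              nrow(object@topology), length(object@frames)))
  res <- unique(paste0(object@topology$resName, object@topology$resSeq))
  cat("  residues:", paste(utils::head(res, 8L), collapse = " "),
      if (length(res) > 8L) "..." else "", "\n")
  cat("  provenance:", object@provenance, "\n")
})

#' @describeIn GeometrySeries number of frames (rows).
#' @param x a \code{GeometrySeries}.
#' @export
setMethod("nFrames", "GeometrySeries", function(x) nrow(x@values))

#' @describeIn GeometrySeries distance matrix (frames x labels).
#' @export
setMethod("distanceValues", "GeometrySeries", function(x) x@values)

#' @describeIn GeometrySeries monitored distance labels.
#' @export
setMethod("distanceLabels", "GeometrySeries", function(x) colnames(x@values))

setMethod("show", "GeometrySeries", function(object) {
  cat(sprintf("GeometrySeries: %d frame(s) x %d distance(s)\n",
              nrow(object@values), ncol(object@values)))
  cat("  labels:", paste(colnames(object@values), collapse = ", "), "\n")
})

#' @describeIn PCCriterion labels of the member distances.
#' @param x a \code{PCCriterion}.
#' @export
setMethod("distanceLabels", "PCCriterion", function(x) x@members$label)

setMethod("show", "PCCriterion", function(object) {
  cat(sprintf("PCCriterion '%s' (%d member(s); closed windows)\n",
              object@name, nrow(object@members)))
  for (i in seq_len(nrow(object@members))) {
    m <- object@members[i, ]
    cat(sprintf("  %-10s in [%.2f, %.2f] A\n", m$label, m$lo, m$hi))
  }
})

#' @describeIn PCResult logical per-frame PC mask.
#' @param x a \code{PCResult}.
#' @export
setMethod("pcMask", "PCResult", function(x) x@mask)

#' @describeIn PCResult occupancy percentage.
#' @export
setMethod("pPC", "PCResult", function(x) x@pPC)

#' @describeIn PCResult bootstrap CI bounds (percent).
#' @export
setMethod("ciBounds", "PCResult", function(x) c(lo = x@ciLo, hi = x@ciHi))

setMethod("show", "PCResult", function(object) {
  n <- length(object@mask)
  cat(sprintf("PCResult ('%s'): P_PC = %.1f%% (%d / %d frames)\n",
              object@criterionName, object@pPC, object@nPC, n))
  if (!is.na(object@ciLo))
    cat(sprintf("  95%% block-bootstrap CI: [%.1f, %.1f]%%\n",
                object@ciLo, object@ciHi))
})

setMethod("show", "SyntheticEnsembleSpec", function(object) {
  cat(sprintf(
    "SyntheticEnsembleSpec: %d frames, pi_PC = %.3f, persistence = %.2f, seed = %d\n",
    object@nFrames, object@piPC, object@persistence, object@seed))
  cat("  labels:", paste(names(object@stateDistributions$pc), collapse = ", "),
      "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames, realized PC occupancy %.4f\n",
              length(object@stateSequence), object@realizedOccupancy))
})

#' @describeIn FingerprintLibrary record identifiers.
#' @param x a \code{FingerprintLibrary}.
#' @export
setMethod("recordIds", "FingerprintLibrary", function(x) x@ids)

#' @describeIn FingerprintLibrary 0/1 bit matrix.
#' @export
setMethod("fingerprintBits", "FingerprintLibrary", function(x) x@bits)

#' @describeIn FingerprintLibrary shared fingerprint length.
#' @export
setMethod("nBits", "FingerprintLibrary", function(x) ncol(x@bits))

#' @describeIn FingerprintLibrary number of records.
#' @export
setMethod("length", "FingerprintLibrary", function(x) length(x@ids))

setMethod("show", "FingerprintLibrary", function(object) {
  cat(sprintf("FingerprintLibrary: %d record(s) x %d bits\n",
              length(object@ids), ncol(object@bits)))
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf(
    "CascadeResult: pool of %d, %d cluster(s), %d selected center(s)\n",
    nrow(object@rankedPool), length(object@clusters),
    length(object@centers)))
  cat("  centers:", paste(object@centers, collapse = ", "), "\n")
})

#' @describeIn ModifiedPeptide one-letter sequence.
#' @param x a \code{ModifiedPeptide}.
#' @export
setMethod("peptideSequence", "ModifiedPeptide", function(x) x@sequence)

setMethod("show", "ModifiedPeptide", function(object) {
  cat(sprintf("ModifiedPeptide %d-%s-%d\n", object@startResSeq,
              object@sequence,
              object@startResSeq + nchar(object@sequence) - 1L))
  for (pos in names(object@modifications)) {
    f <- object@modifications[[pos]]
    cat(sprintf("  +%s at position %s (residue %s)\n",
                formatFormula(f), pos,
                substr(object@sequence, as.integer(pos), as.integer(pos))))
  }
})

#' @describeIn IonSeries peptide sequence.
#' @param x an \code{IonSeries}.
#' @export
setMethod("peptideSequence", "IonSeries", function(x) x@sequence)

#' @describeIn IonSeries b-ion m/z values (1+).
#' @export
setMethod("bIons", "IonSeries", function(x) x@b)

#' @describeIn IonSeries y-ion m/z values (1+).
#' @export
setMethod("yIons", "IonSeries", function(x) x@y)

#' @describeIn IonSeries neutral monoisotopic mass (Da).
#' @export
setMethod("neutralMass", "IonSeries", function(x) x@neutralMass)

setMethod("show", "IonSeries", function(object) {
  cat(sprintf("IonSeries for %s: M = %.4f Da, %d b ions, %d y ions (1+)\n",
              object@sequence, object@neutralMass,
              length(object@b), length(object@y)))
})
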