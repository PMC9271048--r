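#' Number of frames in an object
#'
#' @param x an [Ensemble] or [GeometrySeries].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom topology of an ensemble
#'
#' @param x an [Ensemble].
#' @return data.frame with one row per atom (columns \code{serial},
#'   \code{name}, \code{resName}, \code{resSeq}, \code{chain},
#'   \code{element}).
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinate frames of an ensemble
#'
#' @param x an [Ensemble].
#' @return list of n_atoms x 3 coordinate matrices (Angstrom).
#' @export
setGeneric("getFrames", function(x) standardGeneric("getFrames"))

#' Provenance label of an ensemble
#'
#' @param x an [Ensemble].
#' @return character label.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Distance values of a geometry series
#'
#' @param x a [GeometrySeries].
#' @return numeric matrix, frames by labels (Angstrom).
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' Distance labels of a series or criterion
#'
#' @param x a [GeometrySeries] or [PCCriterion].
#' @return character vector of labels.
#' @export
setGeneric("distanceLabels", function(x) standardGeneric("distanceLabels"))

#' Per-frame privileged-conformation mask
#'
#' @param x a [PCResult].
#' @return logical vector, one entry per frame.
#' @export
setGeneric("pcMask", function(x) standardGeneric("pcMask"))

#' Privileged-conformation occupancy percentage
#'
#' @param x a [PCResult].
#' @return numeric percentage in [0, 100].
#' @export
setGeneric("pPC", function(x) standardGeneric("pPC"))

#' Bootstrap confidence bounds of an occupancy estimate
#'
#' @param x a [PCResult].
#' @return named numeric vector \code{c(lo, hi)} in percent (NA if no CI).
#' @export
setGeneric("ciBounds", function(x) standardGeneric("ciBounds"))

#' Record identifiers
#'
#' @param x a [FingerprintLibrary].
#' @return character vector of ids.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' Fingerprint bit matrix
#'
#' @param x a [FingerprintLibrary].
#' @return integer 0/1 matrix, records by bits.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' Number of fingerprint bits
#'
#' @param x a [FingerprintLibrary].
#' @return integer bit length shared by all records.
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' Peptide sequence string
#'
#' @param x a [ModifiedPeptide] or [IonSeries].
#' @return uppercase one-letter sequence.
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' b-ion m/z series (charge 1+)
#'
#' @param x an [IonSeries].
#' @return numeric vector b1..b(n-1).
#' @export
setGeneric("bIons", function(x) standardGeneric("bIons"))

#' y-ion m/z series (charge 1+)
#'
#' @param x an [IonSeries].
#' @return numeric vector y1..y(n-1).
#' @export
setGeneric("yIons", function(x) standardGeneric("yIons"))

#' Neutral monoisotopic mass
#'
#' @param x an [IonSeries].
#' @return neutral peptide mass in Da.
#' @export
setGeneric("neutralMass", function(x) standardGeneric("neutralMass"))
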