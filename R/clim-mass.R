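# IUPAC atomic masses.  Monoisotopic: mass of the most abundant isotope;
# average: standard atomic weight.
.MONO_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Se = 79.9165213, Na = 22.9897692809,
  K = 38.96370668, Fe = 55.9349375, I = 126.904473
)
.AVG_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  Se = 78.971, Na = 22.990, K = 39.098, Fe = 55.845, I = 126.904
)
.PROTON_MASS <- 1.00727646688
.WATER <- c(H = 2L, O = 1L)

# Residue (= amino acid - water) elemental formulas, 20 standard residues.
.RESIDUE_FORMULAS <- list(
  G = c(C = 2L, H = 3L,  N = 1L, O = 1L),
  A = c(C = 3L, H = 5L,  N = 1L, O = 1L),
  S = c(C = 3L, H = 5L,  N = 1L, O = 2L),
  P = c(C = 5L, H = 7L,  N = 1L, O = 1L),
  V = c(C = 5L, H = 9L,  N = 1L, O = 1L),
  T = c(C = 4L, H = 7L,  N = 1L, O = 2L),
  C = c(C = 3L, H = 5L,  N = 1L, O = 1L, S = 1L),
  L = c(C = 6L, H = 11L, N = 1L, O = 1L),
  I = c(C = 6L, H = 11L, N = 1L, O = 1L),
  N = c(C = 4L, H = 6L,  N = 2L, O = 2L),
  D = c(C = 4L, H = 5L,  N = 1L, O = 3L),
  Q = c(C = 5L, H = 8L,  N = 2L, O = 2L),
  K = c(C = 6L, H = 12L, N = 2L, O = 1L),
  E = c(C = 5L, H = 7L,  N = 1L, O = 3L),
  M = c(C = 5L, H = 9L,  N = 1L, O = 1L, S = 1L),
  H = c(C = 6L, H = 7L,  N = 3L, O = 1L),
  F = c(C = 9L, H = 9L,  N = 1L, O = 1L),
  R = c(C = 6L, H = 12L, N = 4L, O = 1L),
  Y = c(C = 9L, H = 9L,  N = 1L, O = 2L),
  W = c(C = 11L, H = 10L, N = 2L, O = 1L)
)

.checkFormula <- function(formula) {
  if (!length(formula) || is.null(names(formula)))
    return("an elemental formula needs named element counts")
  if (any(!names(formula) %in% names(.MONO_MASS)))
    return(paste("unknown element(s):",
                 paste(setdiff(names(formula), names(.MONO_MASS)),
                       collapse = ", ")))
  if (any(formula < 0) || any(formula != round(formula)))
    return("element counts must be non-negative integers")
  if (sum(formula) == 0) return("formula must have at least one atom")
  TRUE
}

#' Parse an elemental formula string
#'
#' @param x a Hill-style formula such as \code{"C5H5O2"} or \code{"H2O"}
#'   (element symbols with optional counts), or an already-named count
#'   vector which is validated and returned.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("C5H5O2")
#' @export
parseFormula <- function(x) {
  if (is.numeric(x)) {
    msg <- .checkFormula(x)
    if (!isTRUE(msg)) stop(msg)
    out <- x
    storage.mode(out) <- "integer"
    return(out)
  }
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1L]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(x))
    stop("cannot parse formula: ", x)
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, els, sum)
  out <- stats::setNames(as.integer(out), names(out))
  msg <- .checkFormula(out)
  if (!isTRUE(msg)) stop(msg)
  out
}

#' Format an elemental formula for display
#'
#' @param formula named element-count vector.
#' @return character, e.g. \code{"C5H5O2"}.
#' @export
formatFormula <- function(formula) {
  pref <- c("C", "H")
  els <- c(intersect(pref, names(formula)),
           sort(setdiff(names(formula), pref)))
  paste0(vapply(els, function(e) {
    n <- formula[[e]]
    if (n == 0L) "" else if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Mass of an elemental formula
#'
#' Sums tabulated IUPAC atomic masses.  \code{"nominal"} is the
#' integer-rounded monoisotopic mass, the convention behind statements
#' such as a "+94 Da" shift for the C6H6O adduct.
#'
#' @param formula formula string or named count vector (see
#'   [parseFormula()]).
#' @param mode \code{"monoisotopic"} (default), \code{"average"} or
#'   \code{"nominal"}.
#' @return mass in Da.
#' @examples
#' formulaMass("H2O")              # 18.0106
#' formulaMass("C6H6O", "nominal") # 94
#' @export
formulaMass <- function(formula, mode = c("monoisotopic", "average",
                                          "nominal")) {
  mode <- match.arg(mode)
  f <- parseFormula(formula)
  tab <- if (mode == "average") .AVG_MASS else .MONO_MASS
  m <- sum(tab[names(f)] * f)
  if (mode == "nominal") round(m) else m
}

#' Construct a covalently modified peptide
#'
#' @param sequence uppercase one-letter amino-acid string.
#' @param startResSeq protein residue number of the first residue
#'   (default 1).
#' @param modifications named list mapping 1-based peptide positions to
#'   elemental-formula mass additions; formulas may be strings (e.g.
#'   \code{"C5H5O2"}) or named count vectors.
#' @return a [ModifiedPeptide].
#' @examples
#' modifiedPeptide("NLGGPSVVEVMPTEGHLPHLSMPEVTIPVVLR", startResSeq = 231,
#'                 modifications = list(`16` = "C5H5O2"))
#' @export
modifiedPeptide <- function(sequence, startResSeq = 1L,
                            modifications = list()) {
  mods <- lapply(modifications, parseFormula)
  methods::new("ModifiedPeptide", sequence = toupper(sequence),
               startResSeq = as.integer(startResSeq),
               modifications = mods)
}

#' The His246-modified tryptic peptide of ShHTL7
#'
#' The peptide spanning protein residues 231--262
#' (NLGGPSVVEVMPTEGHLPHLSMPEVTIPVVLR) carrying a covalent adduct on the
#' catalytic His246 -- C5H5O2 for the butenolide-derived intermediate of
#' hydrolyzable agonists, C6H6O for the methylene-bridged analog.
#'
#' @param adduct adduct formula (default \code{"C5H5O2"}).
#' @return a [ModifiedPeptide].
#' @export
shhtl7ModifiedPeptide <- function(adduct = "C5H5O2") {
  pep <- modifiedPeptide("NLGGPSVVEVMPTEGHLPHLSMPEVTIPVVLR",
                         startResSeq = 231L)
  idx <- mapModifiedResidue(pep, 246L)
  pep@modifications <- stats::setNames(list(parseFormula(adduct)),
                                       as.character(idx))
  methods::validObject(pep)
  pep
}

.residueMasses <- function(peptide, mode) {
  tab <- if (mode == "average") .AVG_MASS else .MONO_MASS
  letters1 <- strsplit(peptide@sequence, "")[[1L]]
  masses <- vapply(letters1, function(a) {
    f <- .RESIDUE_FORMULAS[[a]]
    sum(tab[names(f)] * f)
  }, numeric(1), USE.NAMES = FALSE)
  for (pos in names(peptide@modifications)) {
    f <- peptide@modifications[[pos]]
    masses[as.integer(pos)] <- masses[as.integer(pos)] +
      sum(tab[names(f)] * f)
  }
  masses
}

#' Neutral mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus all modification masses.
#'
#' @param peptide a [ModifiedPeptide].
#' @param mode \code{"monoisotopic"} (default) or \code{"average"}.
#' @return neutral mass in Da.
#' @examples
#' peptideMass(modifiedPeptide("G"))  # 75.0320
#' @export
peptideMass <- function(peptide, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(peptide, "ModifiedPeptide"))
  tab <- if (mode == "average") .AVG_MASS else .MONO_MASS
  sum(.residueMasses(peptide, mode)) + sum(tab[names(.WATER)] * .WATER)
}

#' Singly charged b/y fragment-ion series
#'
#' \eqn{b_i = \sum_{k \le i} m_k + m_{proton}} and
#' \eqn{y_j = \sum_{k > n-j} m_k + m_{water} + m_{proton}} at charge 1+,
#' with any modification mass included in every fragment containing the
#' modified residue.
#'
#' @param peptide a [ModifiedPeptide] of length >= 2.
#' @return an [IonSeries].
#' @examples
#' ions <- fragmentIons(modifiedPeptide("GG"))
#' bIons(ions)  # 58.0287
#' yIons(ions)  # 76.0393
#' @export
fragmentIons <- function(peptide) {
  stopifnot(methods::is(peptide, "ModifiedPeptide"))
  n <- nchar(peptide@sequence)
  if (n < 2L) stop("fragment ions need a peptide of length >= 2")
  masses <- .residueMasses(peptide, "monoisotopic")
  water <- sum(.MONO_MASS[names(.WATER)] * .WATER)
  pre <- cumsum(masses)
  b <- pre[seq_len(n - 1L)] + .PROTON_MASS
  suf <- rev(cumsum(rev(masses)))
  y <- suf[seq.int(n, 2L)] + water + .PROTON_MASS
  methods::new("IonSeries", b = unname(b), y = unname(y),
               neutralMass = pre[n] + water,
               sequence = peptide@sequence)
}

#' Map a protein residue number to a peptide position
#'
#' @param peptide a [ModifiedPeptide] with a protein-level
#'   \code{startResSeq}.
#' @param targetResSeq protein residue number to locate.
#' @return 1-based position within the peptide, with the residue letter at
#'   that position attached as the \code{residue} attribute.
#' @examples
#' pep <- modifiedPeptide("NLGGPSVVEVMPTEGHLPHLSMPEVTIPVVLR",
#'                        startResSeq = 231)
#' mapModifiedResidue(pep, 246)  # 16, residue "H"
#' @export
mapModifiedResidue <- function(peptide, targetResSeq) {
  stopifnot(methods::is(peptide, "ModifiedPeptide"))
  n <- nchar(peptide@sequence)
  lastRes <- peptide@startResSeq + n - 1L
  if (targetResSeq < peptide@startResSeq || targetResSeq > lastRes)
    stop(sprintf("residue %d outside peptide range %d-%d",
                 targetResSeq, peptide@startResSeq, lastRes))
  idx <- as.integer(targetResSeq - peptide@startResSeq + 1L)
  structure(idx, residue = substr(peptide@sequence, idx, idx))
}

#' Match theoretical fragment ions against an observed peak list
#'
#' Each theoretical b/y ion is matched to its nearest peak; a match within
#' \code{tolPpm} parts-per-million is accepted, otherwise the ion is
#' flagged unmatched.  An empty peak list yields an all-unmatched table.
#'
#' @param series an [IonSeries].
#' @param peaks data.frame (or 2-column matrix) with columns \code{mz} and
#'   \code{intensity}.
#' @param tolPpm matching tolerance in ppm (> 0; default 20).
#' @return data.frame with columns \code{ion}, \code{index},
#'   \code{theoretical_mz}, \code{matched}, \code{observed_mz},
#'   \code{intensity}, \code{ppm_error}.
#' @export
matchPeaks <- function(series, peaks, tolPpm = 20) {
  stopifnot(methods::is(series, "IonSeries"))
  if (tolPpm <= 0) stop("tolPpm must be > 0")
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) >= 2L && !all(c("mz", "intensity") %in% names(peaks)))
    names(peaks)[1:2] <- c("mz", "intensity")
  theo <- data.frame(
    ion = c(sprintf("b%d", seq_along(series@b)),
            sprintf("y%d", seq_along(series@y))),
    index = c(seq_along(series@b), seq_along(series@y)),
    theoretical_mz = c(series@b, series@y),
    stringsAsFactors = FALSE)
  if (!nrow(peaks)) {
    theo$matched <- FALSE
    theo$observed_mz <- NA_real_
    theo$intensity <- NA_real_
    theo$ppm_error <- NA_real_
    return(theo)
  }
  nearest <- vapply(theo$theoretical_mz,
                    function(m) which.min(abs(peaks$mz - m)), integer(1))
  obs <- peaks$mz[nearest]
  ppm <- (obs - theo$theoretical_mz) / theo$theoretical_mz * 1e6
  ok <- abs(ppm) <= tolPpm
  theo$matched <- ok
  theo$observed_mz <- ifelse(ok, obs, NA_real_)
  theo$intensity <- ifelse(ok, peaks$intensity[nearest], NA_real_)
  theo$ppm_error <- ifelse(ok, ppm, NA_real_)
  theo
}

#' Read a two-column peak list
#'
#' Whitespace- or comma-separated \code{m/z intensity} pairs; lines
#' starting with \code{#} are skipped.
#'
#' @param path input file.
#' @return data.frame with columns \code{mz} and \code{intensity}.
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(data.frame(mz = numeric(0),
                                        intensity = numeric(0)))
  tok <- strsplit(lines, "[,[:space:]]+")
  mz <- vapply(tok, function(t) as.numeric(t[1L]), numeric(1))
  intensity <- vapply(tok, function(t)
    if (length(t) >= 2L) as.numeric(t[2L]) else NA_real_, numeric(1))
  if (anyNA(mz)) stop("unparseable m/z value in ", path)
  data.frame(mz = mz, intensity = intensity)
}
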