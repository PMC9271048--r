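#' Construct an ensemble from a topology and coordinate frames
#'
#' @param topology data.frame with columns \code{serial}, \code{name},
#'   \code{resName}, \code{resSeq}, \code{chain}, \code{element}.
#' @param frames list of n_atoms x 3 numeric matrices (Angstrom).
#' @param provenance free-text origin label.
#' @return an [Ensemble].
#' @examples
#' top <- data.frame(serial = 1:2, name = c("OG", "HG"), resName = "SER",
#'                   resSeq = 95L, chain = "A", element = c("O", "H"))
#' ens <- ensemble(top, list(rbind(c(0, 0, 0), c(0.96, 0, 0))))
#' nFrames(ens)
#' @export
ensemble <- function(topology, frames, provenance = "in-memory") {
  topology$serial  <- as.integer(topology$serial)
  topology$resSeq  <- as.integer(topology$resSeq)
  topology$name    <- as.character(topology$name)
  topology$resName <- as.character(topology$resName)
  topology$chain   <- as.character(topology$chain)
  topology$element <- as.character(topology$element)
  rownames(topology) <- NULL
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    dimnames(f) <- NULL
    storage.mode(f) <- "double"
    f
  })
  methods::new("Ensemble", topology = topology, frames = frames,
               provenance = as.character(provenance))
}

# Fixed PDB columns: x 31-38, y 39-46, z 47-54 (1-based, inclusive).
.parsePdbAtomLines <- function(lines) {
  pad <- formatC(lines, width = 80, flag = "-")
  name <- trimws(substr(pad, 13, 16))
  resName <- trimws(substr(pad, 18, 21))
  element <- trimws(substr(pad, 77, 78))
  # fall back to the first alphabetic character of the atom name when the
  # element field is blank (common in minimal/legacy files)
  blank <- !nzchar(element)
  if (any(blank))
    element[blank] <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name[blank])
  data.frame(
    serial  = as.integer(trimws(substr(pad, 7, 11))),
    name    = name,
    resName = resName,
    resSeq  = as.integer(trimws(substr(pad, 23, 26))),
    chain   = substr(pad, 22, 22),
    element = element,
    x = as.numeric(substr(pad, 31, 38)),
    y = as.numeric(substr(pad, 39, 46)),
    z = as.numeric(substr(pad, 47, 54)),
    stringsAsFactors = FALSE
  )
}

.readEnsemblePDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  isModel <- startsWith(lines, "MODEL")
  isEnd   <- startsWith(lines, "ENDMDL")
  isAtom  <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(isAtom)) stop("no ATOM/HETATM records in ", path)

  if (!any(isModel)) {
    at <- .parsePdbAtomLines(lines[isAtom])
    frames <- list(unname(as.matrix(at[, c("x", "y", "z")])))
    topo <- at[, .TOPOLOGY_COLS]
    return(ensemble(topo, frames, provenance = path))
  }

  modelIdx <- which(isModel)
  modelNo <- suppressWarnings(
    as.integer(trimws(substr(lines[modelIdx], 7, 80))))
  modelNo[is.na(modelNo)] <- seq_along(modelIdx)[is.na(modelNo)]
  bounds <- c(modelIdx, length(lines) + 1L)
  frames <- vector("list", length(modelIdx))
  topo <- NULL
  refKey <- NULL
  for (k in seq_along(modelIdx)) {
    span <- seq.int(modelIdx[k] + 1L, bounds[k + 1L] - 1L)
    endHere <- span[isEnd[span]]
    if (length(endHere)) span <- span[span < endHere[1L]]
    sel <- span[isAtom[span]]
    if (!length(sel))
      stop(sprintf("model %d in %s contains no atoms", modelNo[k], path))
    at <- .parsePdbAtomLines(lines[sel])
    key <- paste(at$chain, at$resSeq, at$name)
    if (is.null(topo)) {
      topo <- at[, .TOPOLOGY_COLS]
      refKey <- key
    } else if (length(key) != length(refKey) || any(key != refKey)) {
      stop(sprintf(
        "inconsistent atom records in model %d of %s (expected %d atoms matching model %d)",
        modelNo[k], path, length(refKey), modelNo[1L]))
    }
    frames[[k]] <- unname(as.matrix(at[, c("x", "y", "z")]))
  }
  ensemble(topo, frames, provenance = path)
}

.readEnsembleXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("bad XYZ atom-count line %d in %s", i, path))
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated XYZ frame starting at line %d in %s", i, path))
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "\\s+")
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements) || any(el != elements))
      stop(sprintf("inconsistent atoms in XYZ frame %d of %s",
                   length(frames) + 1L, path))
    frames[[length(frames) + 1L]] <- unname(xyz)
    i <- i + 2L + n
  }
  topo <- data.frame(serial = seq_along(elements), name = elements,
                     resName = "XYZ", resSeq = seq_along(elements),
                     chain = "A", element = elements,
                     stringsAsFactors = FALSE)
  ensemble(topo, frames, provenance = path)
}

#' Read a conformational ensemble
#'
#' Reads a multi-model PDB (frames delimited by MODEL/ENDMDL, coordinates
#' from the fixed columns 31--38/39--46/47--54) or a concatenated
#' multi-frame XYZ file ("atom count / comment / element x y z").  A PDB
#' without MODEL records yields a single-frame ensemble.  Atom identity
#' (chain, resSeq, name) must be identical across models; a mismatch is a
#' format error naming the offending model.
#'
#' @param path input file.
#' @param format \code{"pdb-models"} or \code{"xyz"}.
#' @return an [Ensemble]; frame order preserved.
#' @examples
#' top <- data.frame(serial = 1:2, name = c("OG", "HG"), resName = "SER",
#'                   resSeq = 95L, chain = "A", element = c("O", "H"))
#' ens <- ensemble(top, list(rbind(c(0, 0, 0), c(0.96, 0, 0))))
#' f <- tempfile(fileext = ".pdb")
#' writeEnsemble(ens, f)
#' nFrames(readEnsemble(f))
#' @export
readEnsemble <- function(path, format = c("pdb-models", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "pdb-models" = .readEnsemblePDB(path),
         "xyz" = .readEnsembleXYZ(path))
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.formatPdbAtomLines <- function(top, frame) {
  record <- ifelse(top$resName %in% .AA3, "ATOM  ", "HETATM")
  name <- ifelse(nchar(top$name) <= 3L, sprintf(" %-3s", top$name),
                 sprintf("%-4s", top$name))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, seq_len(nrow(top)), name, top$resName, top$chain,
          top$resSeq, frame[, 1], frame[, 2], frame[, 3], 1.00, 0.00,
          top$element)
}

#' Write an ensemble as a multi-model PDB
#'
#' Emits fixed-width ATOM/HETATM records (HETATM for non-standard residue
#' codes such as ligands), one MODEL/ENDMDL pair per frame with model
#' indices 1..n, and a terminal END record.  Coordinates are written at
#' PDB precision (3 decimals).
#'
#' @param ensemble an [Ensemble].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(methods::is(ensemble, "Ensemble"))
  top <- ensemble@topology
  chunks <- lapply(seq_along(ensemble@frames), function(k)
    c(sprintf("MODEL     %4d", k),
      .formatPdbAtomLines(top, ensemble@frames[[k]]),
      "ENDMDL"))
  out <- c(unlist(chunks), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write an ensemble in concatenated multi-frame XYZ format
#'
#' Each frame is "atom count / comment / element x y z" with coordinates at
#' 6 decimals; frames are concatenated in order.
#'
#' @param ensemble an [Ensemble].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeEnsembleXYZ <- function(ensemble, path) {
  stopifnot(methods::is(ensemble, "Ensemble"))
  top <- ensemble@topology
  chunks <- lapply(seq_along(ensemble@frames), function(k) {
    f <- ensemble@frames[[k]]
    c(as.character(nrow(top)),
      sprintf("frame %d: %s", k, ensemble@provenance),
      sprintf("%-2s %12.6f %12.6f %12.6f",
              top$element, f[, 1], f[, 2], f[, 3]))
  })
  out <- unlist(chunks)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Build an atom selection query
#'
#' Non-\code{NA} fields must all match; a query must resolve to exactly
#' one topology atom.  Protein atoms are usually addressed by
#' \code{resSeq + name}; ligand atoms, whose numbering is not
#' standardized, by \code{resName + name}.
#'
#' @param name atom name (PDB convention, e.g. \code{"OG"}, \code{"NE2"}).
#' @param resSeq residue number (1-based PDB numbering), or \code{NA}.
#' @param resName residue/ligand code, or \code{NA}.
#' @param chain chain identifier, or \code{NA}.
#' @return a query object for [selectAtom()].
#' @examples
#' atomQuery("OG", resSeq = 95)
#' atomQuery("C5P", resName = "LIG")
#' @export
atomQuery <- function(name, resSeq = NA, resName = NA, chain = NA) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(name = name,
       resSeq = if (is.na(resSeq)) NA_integer_ else as.integer(resSeq),
       resName = if (is.na(resName)) NA_character_ else as.character(resName),
       chain = if (is.na(chain)) NA_character_ else as.character(chain))
}

.formatQuery <- function(query) {
  parts <- c(
    if (!is.na(query$chain)) paste0("chain ", query$chain),
    if (!is.na(query$resName)) query$resName,
    if (!is.na(query$resSeq)) paste0("resSeq ", query$resSeq),
    paste0("atom ", query$name))
  paste(parts, collapse = " / ")
}

#' Resolve an atom selection to a topology index
#'
#' @param ensemble an [Ensemble].
#' @param query an [atomQuery()].
#' @return the index of the unique matching atom.  Zero matches raise a
#'   not-found error naming the query; multiple matches raise an ambiguity
#'   error.
#' @export
selectAtom <- function(ensemble, query) {
  stopifnot(methods::is(ensemble, "Ensemble"))
  top <- ensemble@topology
  hit <- top$name == query$name
  if (!is.na(query$resSeq))  hit <- hit & top$resSeq == query$resSeq
  if (!is.na(query$resName)) hit <- hit & top$resName == query$resName
  if (!is.na(query$chain))   hit <- hit & top$chain == query$chain
  idx <- which(hit)
  if (length(idx) == 0L)
    stop("no atom matches selection: ", .formatQuery(query))
  if (length(idx) > 1L)
    stop("ambiguous selection (", length(idx), " atoms match): ",
         .formatQuery(query))
  idx
}

#' Euclidean distance between two atoms of a frame
#'
#' @param frame an n x 3 coordinate matrix (one ensemble frame).
#' @param i,j distinct atom indices into the frame.
#' @return distance in Angstrom.
#' @examples
#' pairDistance(rbind(c(0, 0, 0), c(3, 4, 0)), 1, 2)  # 5
#' @export
pairDistance <- function(frame, i, j) {
  n <- nrow(frame)
  if (i < 1L || i > n || j < 1L || j > n)
    stop(sprintf("atom index out of range (frame has %d atoms)", n))
  if (i == j) stop("pairDistance requires two distinct atoms (i != j)")
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}
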