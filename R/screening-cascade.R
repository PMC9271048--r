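#' Build a fingerprint library
#'
#' @param ids unique record identifiers.
#' @param bits 0/1 matrix with one row per record (all records share one
#'   bit length), or a list of equal-length 0/1 vectors.
#' @return a [FingerprintLibrary].
#' @export
fingerprintLibrary <- function(ids, bits) {
  if (is.list(bits)) bits <- do.call(rbind, bits)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  dimnames(bits) <- NULL
  methods::new("FingerprintLibrary", ids = as.character(ids), bits = bits)
}

.bitsFromString <- function(s, line) {
  if (grepl("^[01]+$", s)) {
    as.integer(strsplit(s, "")[[1L]])
  } else if (grepl("^(0[xX])?[0-9a-fA-F]+$", s)) {
    s <- sub("^0[xX]", "", s)
    nib <- strtoi(strsplit(s, "")[[1L]], base = 16L)
    as.integer(unlist(lapply(nib, function(v)
      bitwAnd(bitwShiftR(v, 3:0), 1L))))
  } else {
    stop(sprintf("line %d: fingerprint is neither a bit string nor hex", line))
  }
}

#' Read a fingerprint library from TSV
#'
#' Expected format: one record per line, \code{id<TAB>fingerprint}, where
#' the fingerprint is either a 0/1 bit string or a hexadecimal string
#' (4 bits per character, most-significant bit first).  Lines starting
#' with \code{#} are skipped.
#'
#' @param path TSV file.
#' @return a [FingerprintLibrary].
#' @export
readFingerprintTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("no fingerprint records in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("line %d of %s: expected id<TAB>fingerprint",
                 keep[bad[1L]], path))
  ids <- vapply(parts, `[[`, "", 1L)
  bits <- lapply(seq_along(parts),
                 function(k) .bitsFromString(trimws(parts[[k]][2L]), keep[k]))
  if (length(unique(lengths(bits))) != 1L)
    stop("all fingerprints in a library must share one bit length")
  fingerprintLibrary(ids, bits)
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T(a, b) = |a \wedge b| / |a \vee b|}, defined as 1 when both
#' vectors are all-zero.
#'
#' @param a,b 0/1 bit vectors of equal length.
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("fingerprint length mismatch (%d vs %d)",
                 length(a), length(b)))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# All-pairs Tanimoto between the rows of two 0/1 matrices, via the
# popcount identity |a v b| = |a| + |b| - |a ^ b|.
.tanimotoMatrix <- function(A, B) {
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  sim
}

#' Screening cascade configuration
#'
#' @param topNPerQuery per-query ranked-list depth (default 100).
#' @param poolRankCut depth of the ranked list retained for manual triage
#'   (default 130).
#' @param nCenters number of cluster centers to select (default 10).
#' @param clusterThreshold Taylor-Butina neighbour threshold as a Tanimoto
#'   distance in [0, 1] (default 0.35).
#' @param poolMode \code{"aggregate"} pools the library-wide top
#'   \code{topNPerQuery} by maximum-over-queries similarity;
#'   \code{"per-query"} pools the union of each query's top
#'   \code{topNPerQuery}.
#' @return configuration list for [runCascade()].
#' @export
cascadeConfig <- function(topNPerQuery = 100L, poolRankCut = 130L,
                          nCenters = 10L, clusterThreshold = 0.35,
                          poolMode = c("aggregate", "per-query")) {
  poolMode <- match.arg(poolMode)
  stopifnot(topNPerQuery >= 1L, poolRankCut >= 1L, nCenters >= 1L,
            clusterThreshold >= 0, clusterThreshold <= 1)
  list(topNPerQuery = as.integer(topNPerQuery),
       poolRankCut = as.integer(poolRankCut),
       nCenters = as.integer(nCenters),
       clusterThreshold = clusterThreshold,
       poolMode = poolMode)
}

#' Rank a library against multiple query fingerprints
#'
#' Each record's aggregate score is its maximum Tanimoto similarity over
#' the queries.  The ranking sorts by descending score with ties broken by
#' ascending id; per-query top-n lists are retained.
#'
#' @param library a [FingerprintLibrary].
#' @param queries a [FingerprintLibrary] of query fingerprints (same bit
#'   length as the library).
#' @param config a [cascadeConfig()].
#' @return list with \code{ranked} (data.frame id, score, rank) and
#'   \code{perQueryTop} (list of per-query data.frames).
#' @export
rankByQueries <- function(library, queries, config = cascadeConfig()) {
  stopifnot(methods::is(library, "FingerprintLibrary"),
            methods::is(queries, "FingerprintLibrary"))
  if (ncol(library@bits) != ncol(queries@bits))
    stop(sprintf("bit-length mismatch: library %d vs queries %d",
                 ncol(library@bits), ncol(queries@bits)))
  sim <- .tanimotoMatrix(library@bits, queries@bits)  # records x queries
  score <- apply(sim, 1L, max)
  ord <- order(-score, library@ids)
  ranked <- data.frame(id = library@ids[ord], score = score[ord],
                       rank = seq_along(ord), stringsAsFactors = FALSE)
  perQueryTop <- lapply(seq_len(ncol(sim)), function(q) {
    oq <- order(-sim[, q], library@ids)
    oq <- oq[seq_len(min(config$topNPerQuery, length(oq)))]
    data.frame(id = library@ids[oq], score = sim[oq, q],
               rank = seq_along(oq), stringsAsFactors = FALSE)
  })
  names(perQueryTop) <- if (length(queries@ids)) queries@ids else NULL
  list(ranked = ranked, perQueryTop = perQueryTop)
}

#' Taylor-Butina sphere-exclusion clustering
#'
#' Neighbour lists are formed at Tanimoto distance (1 - similarity)
#' \code{<= threshold}.  Iteratively, the unassigned record with the most
#' unassigned neighbours becomes a cluster center (ties broken by
#' ascending id) and claims its unassigned neighbours; the process repeats
#' until every record is assigned.  Deterministic.
#'
#' @param pool a [FingerprintLibrary] (e.g. the ranked pool).
#' @param threshold Tanimoto distance threshold in [0, 1].
#' @return named list of character id vectors; each element is one cluster
#'   (center first), named by its center id.
#' @export
butinaCluster <- function(pool, threshold) {
  stopifnot(methods::is(pool, "FingerprintLibrary"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  n <- length(pool@ids)
  sim <- .tanimotoMatrix(pool@bits, pool@bits)
  nb <- (1 - sim) <= threshold
  diag(nb) <- FALSE
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    counts <- vapply(cand, function(i) sum(nb[i, ] & unassigned), integer(1))
    best <- cand[order(-counts, pool@ids[cand])][1L]
    members <- c(best, setdiff(which(nb[best, ] & unassigned), best))
    unassigned[members] <- FALSE
    clusters[[pool@ids[best]]] <- pool@ids[members]
  }
  clusters
}

#' Select cluster centers
#'
#' Returns the centers of the \code{nCenters} largest clusters; ties are
#' broken by higher aggregate score of the center, then ascending id.  If
#' fewer clusters exist, all centers are returned.
#'
#' @param clusters named cluster list from [butinaCluster()].
#' @param config a [cascadeConfig()].
#' @param scores optional named numeric vector of aggregate scores used in
#'   tie-breaking.
#' @return character vector of selected center ids.
#' @export
selectCenters <- function(clusters, config = cascadeConfig(),
                          scores = NULL) {
  if (!length(clusters)) stop("clusters must be non-empty")
  centers <- names(clusters)
  sizes <- lengths(clusters)
  sc <- if (is.null(scores)) rep(0, length(centers))
        else unname(scores[centers])
  sc[is.na(sc)] <- 0
  ord <- order(-sizes, -sc, centers)
  centers[ord][seq_len(min(config$nCenters, length(centers)))]
}

#' Run the hierarchical fingerprint screening cascade
#'
#' Multi-query Tanimoto ranking of the library, pooling of the top-ranked
#' records, Taylor-Butina clustering of the pool and selection of the
#' cluster centers, plus the deeper ranked list retained for manual
#' structure-based triage.
#'
#' @param library a [FingerprintLibrary].
#' @param queries a [FingerprintLibrary] of query fingerprints.
#' @param config a [cascadeConfig()].
#' @return a [CascadeResult].
#' @export
runCascade <- function(library, queries, config = cascadeConfig()) {
  ranking <- rankByQueries(library, queries, config)
  ranked <- ranking$ranked
  poolIds <- if (config$poolMode == "aggregate") {
    ranked$id[seq_len(min(config$topNPerQuery, nrow(ranked)))]
  } else {
    union <- unique(unlist(lapply(ranking$perQueryTop, `[[`, "id")))
    ranked$id[ranked$id %in% union]  # keep aggregate-rank order
  }
  poolIdx <- match(poolIds, library@ids)
  pool <- fingerprintLibrary(poolIds,
                             library@bits[poolIdx, , drop = FALSE])
  clusters <- butinaCluster(pool, config$clusterThreshold)
  scores <- stats::setNames(ranked$score, ranked$id)
  centers <- selectCenters(clusters, config, scores = scores)
  triage <- ranked[seq_len(min(config$poolRankCut, nrow(ranked))), ]
  methods::new("CascadeResult",
               rankedPool = ranked[ranked$id %in% poolIds, ],
               perQueryTop = ranking$perQueryTop,
               clusters = clusters, centers = centers,
               triageList = triage)
}
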