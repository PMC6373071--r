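#' @include AllGenerics.R
NULL

# normalize an edge table: order endpoints lexicographically, drop
# self-loops, collapse duplicates keeping the maximum score
.normalizeEdges <- function(from, to, score) {
    keep <- from != to
    from2 <- pmin(from[keep], to[keep])
    to2 <- pmax(from[keep], to[keep])
    score <- score[keep]
    if (length(from2)) {
        key <- paste(from2, to2, sep = "\r")
        mx <- tapply(score, key, max)
        key1 <- names(mx)
        parts <- strsplit(key1, "\r", fixed = TRUE)
        from2 <- vapply(parts, `[`, character(1), 1L)
        to2 <- vapply(parts, `[`, character(1), 2L)
        score <- as.integer(mx)
    }
    e <- data.frame(from = from2, to = to2, score = as.integer(score),
                    stringsAsFactors = FALSE)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
    e
}

#' Construct a SpeciesNetwork
#'
#' Normalizes the edge table: endpoints ordered lexicographically,
#' self-loops dropped, duplicate pairs collapsed keeping the maximum score.
#'
#' @param speciesId species label.
#' @param edges data.frame with columns from, to, score (integer 0--1000).
#' @param scoreCutoff confidence cutoff already applied (default 0).
#' @return a [SpeciesNetwork-class].
#' @export
SpeciesNetwork <- function(speciesId, edges, scoreCutoff = 0L) {
    e <- .normalizeEdges(as.character(edges$from), as.character(edges$to),
                         edges$score)
    new("SpeciesNetwork", speciesId = as.character(speciesId), edges = e,
        scoreCutoff = as.integer(scoreCutoff))
}

#' Read a two-column network-ID to accession mapping table
#'
#' Whitespace/tab-delimited, optional `#` comments.
#'
#' @param path mapping file path.
#' @return named character vector (names = network IDs, values = accessions).
#' @export
readIdMapping <- function(path) {
    stopifnot(file.exists(path))
    ln <- trimws(readLines(path, warn = FALSE))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    parts <- strsplit(ln, "\\s+")
    bad <- vapply(parts, length, integer(1)) < 2L
    if (any(bad))
        stop("malformed mapping line ", which(bad)[1L], " in ", path)
    structure(vapply(parts, `[`, character(1), 2L),
              names = vapply(parts, `[`, character(1), 1L))
}

#' Read a STRING-style weighted edge list
#'
#' Whitespace- or tab-delimited with at least three columns: id1, id2,
#' combined score (integer 0--1000).  A header line is auto-detected (its
#' third field is non-numeric).  When a `mapping` is given, IDs are
#' translated through it and edges with unmapped endpoints are dropped with
#' a counted warning.  Duplicate pairs keep the maximum score; self-loops
#' are dropped with a warning.
#'
#' @param path edge-list file path.
#' @param speciesId species label.
#' @param mapping optional named character vector (see [readIdMapping()])
#'   or path of a mapping file.
#' @return an unfiltered [SpeciesNetwork-class] (`scoreCutoff` 0).
#' @export
readEdgeList <- function(path, speciesId, mapping = NULL) {
    stopifnot(file.exists(path))
    if (is.character(mapping) && length(mapping) == 1L && is.null(names(mapping)))
        mapping <- readIdMapping(mapping)
    ln <- trimws(readLines(path, warn = FALSE))
    keep <- nzchar(ln) & !startsWith(ln, "#")
    lineno <- which(keep)
    parts <- strsplit(ln[keep], "\\s+")
    if (!length(parts))
        stop("empty edge list: ", path)
    nf <- vapply(parts, length, integer(1))
    if (any(nf < 3L))
        stop("malformed edge list line ", lineno[which(nf < 3L)[1L]],
             " in ", path, ": need id1, id2, score")
    third <- vapply(parts, `[`, character(1), 3L)
    start <- 1L
    if (is.na(suppressWarnings(as.numeric(third[1L])))) start <- 2L  # header
    if (length(parts) < start)
        stop("empty edge list: ", path)
    idx <- start:length(parts)
    from <- vapply(parts[idx], `[`, character(1), 1L)
    to <- vapply(parts[idx], `[`, character(1), 2L)
    scoreChr <- third[idx]
    score <- suppressWarnings(as.numeric(scoreChr))
    bad <- is.na(score) | score != floor(score) | score < 0 | score > 1000
    if (any(bad))
        stop("malformed score '", scoreChr[which(bad)[1L]], "' on line ",
             lineno[idx][which(bad)[1L]], " of ", path,
             " (need integer in [0, 1000])")
    if (!is.null(mapping)) {
        mf <- mapping[from]
        mt <- mapping[to]
        unmapped <- is.na(mf) | is.na(mt)
        if (any(unmapped))
            warning(sum(unmapped), " edge(s) dropped with unmapped IDs in ",
                    basename(path))
        from <- unname(mf[!unmapped])
        to <- unname(mt[!unmapped])
        score <- score[!unmapped]
    }
    nself <- sum(from == to)
    if (nself > 0L)
        warning(nself, " self-loop(s) dropped in ", basename(path))
    SpeciesNetwork(speciesId,
                   data.frame(from = from, to = to, score = score,
                              stringsAsFactors = FALSE))
}

#' Filter a network by confidence score
#'
#' Retains edges with combined score >= `cutoff` (inclusive).
#'
#' @param network a [SpeciesNetwork-class].
#' @param cutoff integer in [0, 1000].
#' @return filtered [SpeciesNetwork-class] with `scoreCutoff` recorded.
#' @export
filterByScore <- function(network, cutoff) {
    stopifnot(is(network, "SpeciesNetwork"))
    if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0 || cutoff > 1000)
        stop("score cutoff must lie in [0, 1000]")
    e <- edges(network)
    e <- e[e$score >= cutoff, , drop = FALSE]
    rownames(e) <- NULL
    new("SpeciesNetwork", speciesId = speciesId(network), edges = e,
        scoreCutoff = as.integer(max(cutoff, network@scoreCutoff)))
}

#' Restrict a network to OPS member proteins
#'
#' Keeps only edges whose both endpoints are members of this species' OPS
#' column.  Idempotent.
#'
#' @param network a [SpeciesNetwork-class].
#' @param ops an [OPSSet-class] containing `speciesId(network)`.
#' @return restricted [SpeciesNetwork-class].
#' @export
restrictToOPS <- function(network, ops) {
    stopifnot(is(network, "SpeciesNetwork"), is(ops, "OPSSet"))
    sp <- speciesId(network)
    if (!sp %in% analysisSpecies(ops))
        stop("species ", sp, " is not part of this OPS set")
    memb <- opsMembers(ops)[[sp]]
    e <- edges(network)
    e <- e[e$from %in% memb & e$to %in% memb, , drop = FALSE]
    rownames(e) <- NULL
    new("SpeciesNetwork", speciesId = sp, edges = e,
        scoreCutoff = network@scoreCutoff)
}
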