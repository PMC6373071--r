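#' @include alignment.R
NULL

#' All-vs-all cross-species similarity matrix
#'
#' Computes the percent identity/similarity of every cross-species protein
#' pair once; both best-hit directions are read from this single matrix, so
#' the two directions can never disagree on a pair's similarity.
#'
#' @param proteomeA,proteomeB [SpeciesProteome-class] objects for two
#'   distinct species.
#' @param params an [AlignmentParams-class].
#' @param mode "identity" (default) or "similarity"; see [seqSimilarity()].
#' @return numeric matrix, rows = accessions of `proteomeA`, columns =
#'   accessions of `proteomeB`.
#' @export
allVsAll <- function(proteomeA, proteomeB, params = alignmentParams(),
                     mode = c("identity", "similarity")) {
    mode <- match.arg(mode)
    stopifnot(is(proteomeA, "SpeciesProteome"), is(proteomeB, "SpeciesProteome"))
    sa <- as.character(sequences(proteomeA))
    sb <- as.character(sequences(proteomeB))
    m <- matrix(NA_real_, nrow = length(sa), ncol = length(sb),
                dimnames = list(names(sa), names(sb)))
    for (i in seq_along(sa))
        for (j in seq_along(sb))
            m[i, j] <- seqSimilarity(sa[[i]], sb[[j]], params, mode)
    m
}

#' Best hits in one direction
#'
#' For each query protein, the subject with maximum similarity.  Ties on
#' the maximum are broken by lexicographic subject accession and flagged.
#'
#' @param simMatrix similarity matrix from [allVsAll()].
#' @param direction "ab" (rows are queries, default) or "ba" (columns are
#'   queries).
#' @return data.frame with columns query, subject, similarity, tie.
#' @export
bestHits <- function(simMatrix, direction = c("ab", "ba")) {
    direction <- match.arg(direction)
    m <- if (direction == "ab") simMatrix else t(simMatrix)
    stopifnot(nrow(m) > 0L, ncol(m) > 0L)
    res <- lapply(seq_len(nrow(m)), function(i) {
        v <- m[i, ]
        mx <- max(v)
        cand <- sort(colnames(m)[v == mx])
        data.frame(query = rownames(m)[i], subject = cand[1L],
                   similarity = mx, tie = length(cand) > 1L,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Reciprocal best hits
#'
#' A pair (p, q) is kept when p's best hit is q, q's best hit is p, and
#' their similarity is at least `cutoff` (inclusive).  Each accession can
#' appear in at most one pair.
#'
#' @param hitsAB,hitsBA best-hit tables from [bestHits()], both computed
#'   from the same [allVsAll()] matrix.
#' @param cutoff percent similarity cutoff (default 30).
#' @param speciesA,speciesB species labels recorded in the result.
#' @param mode label of the similarity mode used (recorded only).
#' @return an [OrthologyMap-class].
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, cutoff = 30,
                               speciesA = "A", speciesB = "B",
                               mode = "identity") {
    stopifnot(cutoff >= 0, cutoff <= 100)
    back <- structure(hitsBA$subject, names = hitsBA$query)
    keep <- !is.na(back[hitsAB$subject]) &
        back[hitsAB$subject] == hitsAB$query &
        hitsAB$similarity >= cutoff
    pairs <- data.frame(accessionA = hitsAB$query[keep],
                        accessionB = hitsAB$subject[keep],
                        similarity = hitsAB$similarity[keep],
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$accessionA), , drop = FALSE]
    rownames(pairs) <- NULL
    new("OrthologyMap", speciesA = speciesA, speciesB = speciesB,
        cutoff = as.numeric(cutoff), mode = mode, pairs = pairs,
        bestHitsAB = hitsAB, bestHitsBA = hitsBA)
}

#' One-call orthology between two proteomes
#'
#' Convenience wrapper: [allVsAll()], both [bestHits()] directions, then
#' [reciprocalBestHits()].
#'
#' @inheritParams allVsAll
#' @param cutoff percent similarity cutoff (default 30).
#' @return an [OrthologyMap-class].
#' @export
orthologyMap <- function(proteomeA, proteomeB, params = alignmentParams(),
                         cutoff = 30, mode = c("identity", "similarity")) {
    mode <- match.arg(mode)
    m <- allVsAll(proteomeA, proteomeB, params, mode)
    reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), cutoff,
                       speciesId(proteomeA), speciesId(proteomeB), mode)
}
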