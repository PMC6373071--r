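#' @include orthology.R
NULL

# partner lookup: named vector acc(species s) -> acc(species t) from the
# OrthologyMap covering the unordered pair {s, t}
.partnerMap <- function(maps, s, t) {
    for (m in maps) {
        if (m@speciesA == s && m@speciesB == t)
            return(structure(m@pairs$accessionB, names = m@pairs$accessionA))
        if (m@speciesA == t && m@speciesB == s)
            return(structure(m@pairs$accessionA, names = m@pairs$accessionB))
    }
    stop("no orthology map for species pair ", s, " / ", t)
}

#' Assemble orthologous protein sets (IPN nodes)
#'
#' An OPS is one protein per analysis species such that every one of the
#' k(k-1)/2 cross-species pairs is a reciprocal best hit: a one-per-species
#' k-clique of the k-partite RBH graph.  Because RBH gives each protein at
#' most one partner per other species, OPS are automatically disjoint.
#' `ops_id`s are assigned "OPS1", "OPS2", ... after sorting on the first
#' species' accession, so runs are diffable.
#'
#' @param orthologyMaps list of [OrthologyMap-class], one per unordered
#'   species pair (k(k-1)/2 maps for k species), all built with the same
#'   alignment parameters and cutoff.
#' @param species ordered character vector of the 2--4 analysis species.
#' @return an [OPSSet-class].
#' @examples
#' # two species: every RBH pair is one OPS
#' @export
buildOPS <- function(orthologyMaps, species) {
    k <- length(species)
    if (k < 2L || k > 4L)
        stop("an analysis spans 2 to 4 species (got ", k, ")")
    if (anyDuplicated(species))
        stop("duplicated species labels")
    prs <- utils::combn(species, 2L, simplify = FALSE)
    pm <- list()
    for (p in prs)
        pm[[paste(p[1L], p[2L], sep = "\r")]] <- .partnerMap(orthologyMaps,
                                                             p[1L], p[2L])
    s1 <- species[1L]
    rows <- list()
    # chain from species 1: the RBH partner in each other species is unique
    # if it exists; then verify closure of all remaining pairs
    first <- pm[[paste(s1, species[2L], sep = "\r")]]
    for (a1 in sort(names(first))) {
        memb <- structure(a1, names = s1)
        ok <- TRUE
        for (t in species[-1L]) {
            cand <- pm[[paste(s1, t, sep = "\r")]][a1]
            if (is.na(cand)) { ok <- FALSE; break }
            memb[t] <- cand
        }
        if (!ok) next
        for (p in prs) {
            if (p[1L] == s1) next
            cand <- pm[[paste(p[1L], p[2L], sep = "\r")]][memb[p[1L]]]
            if (is.na(cand) || cand != memb[p[2L]]) { ok <- FALSE; break }
        }
        if (ok) rows[[length(rows) + 1L]] <- memb
    }
    members <- if (length(rows)) {
        df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        cbind(ops_id = paste0("OPS", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
    } else {
        df <- as.data.frame(setNames(rep(list(character(0)), k), species),
                            stringsAsFactors = FALSE)
        cbind(ops_id = character(0), df, stringsAsFactors = FALSE)
    }
    rownames(members) <- NULL
    new("OPSSet", species = species, members = members)
}

#' Write an OPS node table
#'
#' TSV with `ops_id` and one accession column per species.
#'
#' @param ops an [OPSSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOPS <- function(ops, path) {
    stopifnot(is(ops, "OPSSet"))
    write.table(opsMembers(ops), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
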