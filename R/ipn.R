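#' @include ops.R ppin.R
NULL

# per-species hashed edge lookup "from\rto" (endpoints pre-sorted)
.edgeKeys <- function(network) {
    e <- edges(network)
    if (!nrow(e)) return(character(0))
    paste(e$from, e$to, sep = "\r")
}

#' Coverage of one OPS pair
#'
#' The species in which the two OPS' member proteins interact, and their
#' count.
#'
#' @param ops an [OPSSet-class].
#' @param opsI,opsJ two `ops_id`s.
#' @param networks named list of filtered, OPS-restricted
#'   [SpeciesNetwork-class] objects, one per analysis species.
#' @return list with elements `coverage` (integer) and `species`
#'   (character vector of supporting species).
#' @export
edgeCoverage <- function(ops, opsI, opsJ, networks) {
    stopifnot(is(ops, "OPSSet"))
    sp <- analysisSpecies(ops)
    missingNet <- setdiff(sp, names(networks))
    if (length(missingNet))
        stop("no network supplied for species: ",
             paste(missingNet, collapse = ", "))
    m <- opsMembers(ops)
    ri <- m[m$ops_id == opsI, , drop = FALSE]
    rj <- m[m$ops_id == opsJ, , drop = FALSE]
    if (nrow(ri) != 1L || nrow(rj) != 1L)
        stop("unknown ops_id")
    supp <- character(0)
    for (s in sp) {
        a <- ri[[s]]; b <- rj[[s]]
        key <- paste(min(a, b), max(a, b), sep = "\r")
        if (key %in% .edgeKeys(networks[[s]]))
            supp <- c(supp, s)
    }
    list(coverage = length(supp), species = supp)
}

#' Build the interolog protein network
#'
#' Examines every OPS pair; an IPN edge is drawn when the member proteins
#' interact in at least `coverageCutoff` species (inclusive).  Isolated OPS
#' are kept as nodes.  Networks are score-filtered and OPS-restricted
#' internally if not already.
#'
#' @param ops an [OPSSet-class].
#' @param networks named list of [SpeciesNetwork-class], one per analysis
#'   species.
#' @param coverageCutoff integer in [1, k].
#' @param parameters optional named list of run parameters to record.
#' @return an [IPN-class].
#' @export
buildIPN <- function(ops, networks, coverageCutoff = NULL,
                     parameters = list()) {
    stopifnot(is(ops, "OPSSet"))
    sp <- analysisSpecies(ops)
    k <- length(sp)
    if (is.null(coverageCutoff)) coverageCutoff <- k
    if (length(coverageCutoff) != 1L || is.na(coverageCutoff) ||
        coverageCutoff < 1L || coverageCutoff > k)
        stop("coverage cutoff must lie in [1, ", k, "]")
    missingNet <- setdiff(sp, names(networks))
    if (length(missingNet))
        stop("no network supplied for species: ",
             paste(missingNet, collapse = ", "))
    networks <- lapply(networks[sp], restrictToOPS, ops = ops)
    keys <- lapply(networks, .edgeKeys)
    m <- opsMembers(ops)
    n <- nrow(m)
    out <- list()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                supp <- character(0)
                for (s in sp) {
                    a <- m[[s]][i]; b <- m[[s]][j]
                    key <- paste(min(a, b), max(a, b), sep = "\r")
                    if (key %in% keys[[s]]) supp <- c(supp, s)
                }
                if (length(supp) >= coverageCutoff)
                    out[[length(out) + 1L]] <- data.frame(
                        ops_i = m$ops_id[i], ops_j = m$ops_id[j],
                        coverage = length(supp),
                        supporting_species = paste(supp, collapse = ","),
                        stringsAsFactors = FALSE)
            }
        }
    }
    e <- if (length(out)) do.call(rbind, out)
         else data.frame(ops_i = character(0), ops_j = character(0),
                         coverage = integer(0),
                         supporting_species = character(0),
                         stringsAsFactors = FALSE)
    # at full coverage every IPN edge maps injectively into each species'
    # restricted network, so the IPN cannot outnumber the sparsest of them;
    # below full coverage the IPN is a union across species and no such
    # bound holds in general
    if (coverageCutoff == k) {
        minPPIN <- min(vapply(networks, function(x) nrow(edges(x)),
                              integer(1)))
        stopifnot(nrow(e) <= minPPIN)
    }
    parameters$coverage_cutoff <- as.integer(coverageCutoff)
    new("IPN", nodes = ops, edges = e, parameters = parameters)
}
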