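#' @include interolog-package.R
NULL

#' Alignment parameters
#'
#' Substitution matrix and affine gap penalties for global alignment.  A gap
#' run of length L costs `gapOpen + (L - 1) * gapExtend` (both negative, in
#' matrix units).  Construct with [alignmentParams()].
#'
#' @slot matrixName name of the substitution matrix (e.g. "BLOSUM62").
#' @slot matrix numeric substitution matrix with residue dimnames.
#' @slot gapOpen penalty for the first residue of a gap run (negative).
#' @slot gapExtend penalty for each further gap residue (negative,
#'   `gapOpen <= gapExtend < 0`).
#' @exportClass AlignmentParams
setClass("AlignmentParams",
    representation(matrixName = "character", matrix = "matrix",
                   gapOpen = "numeric", gapExtend = "numeric"))

setValidity("AlignmentParams", function(object) {
    msg <- character()
    if (!is.numeric(object@matrix) || nrow(object@matrix) == 0L ||
        !identical(rownames(object@matrix), colnames(object@matrix)))
        msg <- c(msg, "substitution matrix must be square with identical row/column names")
    if (length(object@gapOpen) != 1L || length(object@gapExtend) != 1L ||
        !(object@gapOpen <= object@gapExtend) || !(object@gapExtend < 0))
        msg <- c(msg, "gap penalties must satisfy gapOpen <= gapExtend < 0")
    if (length(msg)) msg else TRUE
})

#' Global alignment result
#'
#' Optimal global alignment of two sequences.  Percent identity is
#' 100 * (identical columns) / (alignment length, gaps included); percent
#' similarity counts columns whose substitution score is positive, over the
#' same denominator.
#'
#' @slot score optimal alignment score in substitution-matrix units.
#' @slot alignedA,alignedB equal-length aligned strings ("-" = gap).
#' @slot identityPct,similarityPct percentages in [0, 100].
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(score = "numeric", alignedA = "character",
                   alignedB = "character", identityPct = "numeric",
                   similarityPct = "numeric"))

setValidity("AlignmentResult", function(object) {
    a <- object@alignedA; b <- object@alignedB
    msg <- character()
    if (nchar(a) != nchar(b))
        msg <- c(msg, "aligned strings must have equal length")
    if (grepl("-", a) || grepl("-", b)) {
        ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
        if (any(ca == "-" & cb == "-"))
            msg <- c(msg, "gap-gap column")
    }
    if (object@identityPct < 0 || object@identityPct > object@similarityPct ||
        object@similarityPct > 100)
        msg <- c(msg, "need 0 <= identityPct <= similarityPct <= 100")
    if (length(msg)) msg else TRUE
})

#' One species' protein set
#'
#' The proteins of one analysis species: an [Biostrings::AAStringSet] named
#' by accession, tagged with a species label.  Construct with
#' [SpeciesProteome()] or read from FASTA with [readProteome()].
#'
#' @slot speciesId short species label (e.g. "hsa").
#' @slot sequences [Biostrings::AAStringSet] named by accession; accessions
#'   unique; sequences over the 20 amino-acid letters plus X/B/Z/U.
#' @exportClass SpeciesProteome
setClass("SpeciesProteome",
    representation(speciesId = "character", sequences = "AAStringSet"))

setValidity("SpeciesProteome", function(object) {
    msg <- character()
    if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
        msg <- c(msg, "speciesId must be a single non-empty string")
    if (length(object@sequences) < 1L)
        msg <- c(msg, "proteome must contain at least one sequence")
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        msg <- c(msg, "accessions must be non-empty and unique within a species")
    seqs <- as.character(object@sequences)
    bad <- !grepl(AA_REGEX, seqs)
    if (any(bad))
        msg <- c(msg, paste0("invalid residue characters in: ",
                             paste(nm[bad], collapse = ", "),
                             " (allowed: ", paste(AA_ALLOWED, collapse = ""), ")"))
    if (length(msg)) msg else TRUE
})

#' Pairwise orthology map
#'
#' Reciprocal best hits between one species pair, together with the
#' per-direction best-hit tables and the similarity cutoff applied.
#'
#' @slot speciesA,speciesB species labels.
#' @slot cutoff percent similarity cutoff (inclusive) applied to RBH pairs.
#' @slot mode "identity" or "similarity" (which percentage was used).
#' @slot pairs data.frame with columns accessionA, accessionB, similarity;
#'   each accession occurs at most once.
#' @slot bestHitsAB,bestHitsBA data.frames with columns query, subject,
#'   similarity, tie.
#' @exportClass OrthologyMap
setClass("OrthologyMap",
    representation(speciesA = "character", speciesB = "character",
                   cutoff = "numeric", mode = "character",
                   pairs = "data.frame", bestHitsAB = "data.frame",
                   bestHitsBA = "data.frame"))

setValidity("OrthologyMap", function(object) {
    msg <- character()
    p <- object@pairs
    if (!all(c("accessionA", "accessionB", "similarity") %in% names(p)))
        msg <- c(msg, "pairs needs columns accessionA, accessionB, similarity")
    else {
        if (anyDuplicated(p$accessionA) || anyDuplicated(p$accessionB))
            msg <- c(msg, "an accession may appear in at most one RBH pair")
        if (nrow(p) && any(p$similarity < object@cutoff))
            msg <- c(msg, "all RBH pairs must meet the similarity cutoff")
    }
    if (identical(object@speciesA, object@speciesB))
        msg <- c(msg, "orthology is defined between two distinct species")
    if (length(msg)) msg else TRUE
})

#' Orthologous protein sets (IPN nodes)
#'
#' The nodes of an interolog network: each OPS holds exactly one protein per
#' analysis species, all pairwise reciprocal best hits.  Built with
#' [buildOPS()].
#'
#' @slot species ordered character vector of species labels (2--4).
#' @slot members data.frame with column `ops_id` plus one accession column
#'   per species; no accession occurs in two OPS.
#' @exportClass OPSSet
setClass("OPSSet",
    representation(species = "character", members = "data.frame"))

setValidity("OPSSet", function(object) {
    msg <- character()
    k <- length(object@species)
    if (k < 2L || k > 4L)
        msg <- c(msg, "an analysis spans 2 to 4 species")
    m <- object@members
    if (!identical(names(m), c("ops_id", object@species)))
        msg <- c(msg, "members must have columns ops_id then one per species")
    else {
        if (anyDuplicated(m$ops_id))
            msg <- c(msg, "ops_id must be unique")
        for (s in object@species)
            if (anyDuplicated(m[[s]]))
                msg <- c(msg, paste0("OPS are disjoint: duplicated accession in ", s))
    }
    if (length(msg)) msg else TRUE
})

#' One species' interaction network
#'
#' Undirected weighted network over protein accessions, STRING-style: each
#' edge carries an integer combined confidence score in [0, 1000].  Edges
#' are stored with lexicographically ordered endpoints; no self-loops, no
#' duplicates.
#'
#' @slot speciesId species label.
#' @slot edges data.frame with columns from, to, score.
#' @slot scoreCutoff the confidence cutoff already applied (0 = none).
#' @exportClass SpeciesNetwork
setClass("SpeciesNetwork",
    representation(speciesId = "character", edges = "data.frame",
                   scoreCutoff = "integer"))

setValidity("SpeciesNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "score") %in% names(e)))
        msg <- c(msg, "edges needs columns from, to, score")
    else if (nrow(e)) {
        if (any(e$from >= e$to))
            msg <- c(msg, "edge endpoints must be lexicographically ordered (no self-loops)")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicate edges")
        if (any(e$score < 0 | e$score > 1000 | e$score != floor(e$score)))
            msg <- c(msg, "scores must be integers in [0, 1000]")
        if (any(e$score < object@scoreCutoff))
            msg <- c(msg, "edges below the applied score cutoff")
    }
    if (length(msg)) msg else TRUE
})

#' Interolog protein network
#'
#' Simple undirected graph over OPS nodes.  Each edge records its coverage
#' (number of species whose networks contain the member-protein pair) and
#' the supporting species.  Built with [buildIPN()].
#'
#' @slot nodes an [OPSSet-class].
#' @slot edges data.frame with columns ops_i, ops_j, coverage,
#'   supporting_species (comma-joined species labels).
#' @slot parameters named list of the cutoffs and alignment parameters used.
#' @exportClass IPN
setClass("IPN",
    representation(nodes = "OPSSet", edges = "data.frame",
                   parameters = "list"))

setValidity("IPN", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("ops_i", "ops_j", "coverage", "supporting_species")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges needs columns ops_i, ops_j, coverage, supporting_species")
    else if (nrow(e)) {
        ids <- object@nodes@members$ops_id
        if (!all(e$ops_i %in% ids) || !all(e$ops_j %in% ids))
            msg <- c(msg, "every edge endpoint must be an IPN node")
        if (any(e$ops_i == e$ops_j))
            msg <- c(msg, "self-loops are not allowed")
        if (anyDuplicated(paste(pmin(e$ops_i, e$ops_j), pmax(e$ops_i, e$ops_j))))
            msg <- c(msg, "duplicate edges")
        k <- length(object@nodes@species)
        nsup <- lengths(strsplit(e$supporting_species, ",", fixed = TRUE))
        if (any(e$coverage != nsup) || any(e$coverage < 1L) || any(e$coverage > k))
            msg <- c(msg, "coverage must equal |supporting species| and lie in [1, k]")
    }
    if (length(msg)) msg else TRUE
})
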