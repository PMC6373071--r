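#' @include AllClasses.R
NULL

#' Accessors for interolog classes
#'
#' Small accessor generics: `speciesId()` returns the species label of a
#' [SpeciesProteome-class] or [SpeciesNetwork-class]; `accessions()` the
#' accession names of a proteome; `sequences()` its
#' [Biostrings::AAStringSet]; `edges()` the edge table of a
#' [SpeciesNetwork-class] or [IPN-class]; `scoreCutoff()` the confidence
#' cutoff already applied to a network; `opsMembers()` the node table of an
#' [OPSSet-class] or [IPN-class]; `opsIds()` its node identifiers;
#' `analysisSpecies()` the ordered species labels; `rbhPairs()` the
#' reciprocal-best-hit table of an [OrthologyMap-class]; `ipnParameters()`
#' the parameter record of an [IPN-class].
#'
#' @param x an interolog object.
#' @return see details above; tables are plain data.frames.
#' @name accessors
#' @aliases speciesId accessions sequences edges scoreCutoff opsMembers
#'   opsIds analysisSpecies rbhPairs ipnParameters
NULL

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("scoreCutoff", function(x) standardGeneric("scoreCutoff"))
#' @rdname accessors
#' @export
setGeneric("opsMembers", function(x) standardGeneric("opsMembers"))
#' @rdname accessors
#' @export
setGeneric("opsIds", function(x) standardGeneric("opsIds"))
#' @rdname accessors
#' @export
setGeneric("analysisSpecies", function(x) standardGeneric("analysisSpecies"))
#' @rdname accessors
#' @export
setGeneric("rbhPairs", function(x) standardGeneric("rbhPairs"))
#' @rdname accessors
#' @export
setGeneric("ipnParameters", function(x) standardGeneric("ipnParameters"))

#' @rdname accessors
setMethod("speciesId", "SpeciesProteome", function(x) x@speciesId)
#' @rdname accessors
setMethod("speciesId", "SpeciesNetwork", function(x) x@speciesId)
#' @rdname accessors
setMethod("accessions", "SpeciesProteome", function(x) names(x@sequences))
#' @rdname accessors
setMethod("sequences", "SpeciesProteome", function(x) x@sequences)
#' @rdname accessors
setMethod("edges", "SpeciesNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("edges", "IPN", function(x) x@edges)
#' @rdname accessors
setMethod("scoreCutoff", "SpeciesNetwork", function(x) x@scoreCutoff)
#' @rdname accessors
setMethod("opsMembers", "OPSSet", function(x) x@members)
#' @rdname accessors
setMethod("opsMembers", "IPN", function(x) x@nodes@members)
#' @rdname accessors
setMethod("opsIds", "OPSSet", function(x) x@members$ops_id)
#' @rdname accessors
setMethod("opsIds", "IPN", function(x) x@nodes@members$ops_id)
#' @rdname accessors
setMethod("analysisSpecies", "OPSSet", function(x) x@species)
#' @rdname accessors
setMethod("analysisSpecies", "IPN", function(x) x@nodes@species)
#' @rdname accessors
setMethod("rbhPairs", "OrthologyMap", function(x) x@pairs)
#' @rdname accessors
setMethod("ipnParameters", "IPN", function(x) x@parameters)

#' @describeIn accessors number of proteins in a proteome.
setMethod("length", "SpeciesProteome", function(x) length(x@sequences))

setMethod("show", "SpeciesProteome", function(object) {
    cat("SpeciesProteome '", object@speciesId, "': ",
        length(object@sequences), " proteins\n", sep = "")
})

setMethod("show", "AlignmentParams", function(object) {
    cat("AlignmentParams: ", object@matrixName,
        ", gapOpen=", object@gapOpen,
        ", gapExtend=", object@gapExtend, "\n", sep = "")
})

setMethod("show", "AlignmentResult", function(object) {
    cat("AlignmentResult: score=", object@score,
        ", length=", nchar(object@alignedA),
        ", identity=", round(object@identityPct, 1),
        "%, similarity=", round(object@similarityPct, 1), "%\n", sep = "")
})

setMethod("show", "OrthologyMap", function(object) {
    cat("OrthologyMap ", object@speciesA, " ~ ", object@speciesB, ": ",
        nrow(object@pairs), " RBH pairs (", object@mode,
        " >= ", object@cutoff, "%)\n", sep = "")
})

setMethod("show", "OPSSet", function(object) {
    cat("OPSSet: ", nrow(object@members), " orthologous protein sets over ",
        length(object@species), " species (",
        paste(object@species, collapse = ", "), ")\n", sep = "")
})

setMethod("show", "SpeciesNetwork", function(object) {
    cat("SpeciesNetwork '", object@speciesId, "': ", nrow(object@edges),
        " edges (score cutoff ", object@scoreCutoff, ")\n", sep = "")
})

setMethod("show", "IPN", function(object) {
    cat("IPN: ", nrow(object@nodes@members), " OPS nodes, ",
        nrow(object@edges), " edges over ",
        length(object@nodes@species), " species\n", sep = "")
})
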