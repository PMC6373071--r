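#' @include AllGenerics.R
NULL

#' Read a plain-text accession list
#'
#' One accession per line; blank lines and lines starting with `#` are
#' ignored.  Duplicates are dropped (first occurrence kept) with a warning.
#'
#' @param path path to the list file.
#' @return character vector of accessions in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("P12345", "", "# comment", "P12345", "Q67890"), f)
#' readAccessionList(f)
#' @export
readAccessionList <- function(path) {
    stopifnot(file.exists(path))
    x <- trimws(readLines(path, warn = FALSE))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    if (!length(x))
        stop("empty accession list: ", path)
    dup <- duplicated(x)
    if (any(dup))
        warning("duplicate accessions dropped: ",
                paste(unique(x[dup]), collapse = ", "))
    x[!dup]
}

#' Construct a SpeciesProteome
#'
#' @param speciesId short species label.
#' @param sequences named [Biostrings::AAStringSet] or named character
#'   vector of amino-acid sequences (names are accessions).
#' @return a [SpeciesProteome-class].
#' @examples
#' SpeciesProteome("sp1", c(P1 = "MKV", P2 = "MKLL"))
#' @export
SpeciesProteome <- function(speciesId, sequences) {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    new("SpeciesProteome", speciesId = as.character(speciesId),
        sequences = sequences)
}

# accession from a FASTA header token: the whole first word, and the second
# pipe-delimited field for UniProt-style "sp|P12345|NAME" headers
.headerAccessions <- function(headers) {
    tok <- sub("\\s.*$", "", headers)
    parts <- strsplit(tok, "|", fixed = TRUE)
    second <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                     character(1))
    list(token = tok, pipe = second)
}

#' Read requested proteins from a FASTA file
#'
#' Headers may carry the accession as the whole first word or as the second
#' pipe field of a UniProt-style header (`sp|P12345|NAME`).  Sequences are
#' uppercased and a trailing `*` is stripped.  Accessions not found in the
#' FASTA are dropped with a warning (or an error when `strict = TRUE`).
#'
#' @param fastaPath path to an amino-acid FASTA file.
#' @param accessions character vector of accessions to load.
#' @param speciesId species label; defaults to the FASTA file stem.
#' @param strict error (rather than warn) on missing accessions.
#' @return a [SpeciesProteome-class] with one record per accession found,
#'   in the order requested.
#' @export
readProteome <- function(fastaPath, accessions, speciesId = NULL,
                         strict = FALSE) {
    stopifnot(file.exists(fastaPath), length(accessions) >= 1L)
    if (is.null(speciesId))
        speciesId <- sub("\\.[^.]*$", "", basename(fastaPath))
    aa <- Biostrings::readAAStringSet(fastaPath)
    hdr <- .headerAccessions(names(aa))
    seqs <- toupper(sub("\\*$", "", as.character(aa)))
    found <- character(0)
    out <- character(0)
    for (acc in accessions) {
        hit <- which(hdr$token == acc | (!is.na(hdr$pipe) & hdr$pipe == acc))
        if (length(hit) > 1L)
            stop("ambiguous sequence: accession ", acc,
                 " matches ", length(hit), " FASTA entries")
        if (length(hit) == 1L) {
            out <- c(out, seqs[hit])
            found <- c(found, acc)
        }
    }
    missing <- setdiff(accessions, found)
    if (length(found) == 0L)
        stop("no requested accession found in ", fastaPath)
    if (length(missing)) {
        msg <- paste0("accessions not found in ", basename(fastaPath), ": ",
                      paste(missing, collapse = ", "))
        if (strict) stop(msg) else warning(msg)
    }
    names(out) <- found
    SpeciesProteome(speciesId, out)
}

#' Write a proteome to FASTA
#'
#' Plain `>accession` headers; round-trips through [readProteome()].
#'
#' @param proteome a [SpeciesProteome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path) {
    stopifnot(is(proteome, "SpeciesProteome"))
    Biostrings::writeXStringSet(sequences(proteome), path, width = 80L)
    invisible(path)
}
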