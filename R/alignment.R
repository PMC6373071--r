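#' @include AllGenerics.R
NULL

.STANDARD_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                        "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                        "PAM250")

#' Load a substitution matrix
#'
#' Standard amino-acid matrices (BLOSUM45/50/62/80/100, PAM30/40/70/120/250)
#' are taken from Biostrings; any other value is treated as the path of an
#' NCBI-format matrix file and parsed with [readScoreMatrix()].
#'
#' @param name matrix name or file path.
#' @return numeric substitution matrix with residue dimnames.
#' @examples
#' m <- loadSubstitutionMatrix("BLOSUM62")
#' m["M", "K"]
#' @export
loadSubstitutionMatrix <- function(name) {
    if (name %in% .STANDARD_MATRICES) {
        env <- new.env()
        data(list = name, package = "Biostrings", envir = env)
        return(get(name, envir = env))
    }
    if (file.exists(name))
        return(readScoreMatrix(name))
    stop("unknown substitution matrix '", name, "' (not a standard name, ",
         "not a file); standard names: ",
         paste(.STANDARD_MATRICES, collapse = ", "))
}

#' Parse an NCBI-format substitution matrix file
#'
#' The plain-text format used by NCBI toolkits: `#` comment lines, a header
#' row of single-letter column labels, then one row per residue starting
#' with its letter.
#'
#' @param path matrix file path.
#' @return numeric matrix with residue dimnames.
#' @export
readScoreMatrix <- function(path) {
    stopifnot(file.exists(path))
    ln <- readLines(path, warn = FALSE)
    ln <- trimws(ln)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (length(ln) < 2L)
        stop("malformed matrix file: ", path)
    cols <- strsplit(ln[1L], "\\s+")[[1L]]
    rows <- strsplit(ln[-1L], "\\s+")
    rn <- vapply(rows, `[`, character(1), 1L)
    vals <- lapply(rows, function(r) as.numeric(r[-1L]))
    if (any(vapply(vals, length, integer(1)) != length(cols)) ||
        anyNA(unlist(vals)))
        stop("malformed matrix file: ", path)
    m <- do.call(rbind, vals)
    dimnames(m) <- list(rn, cols)
    m
}

#' Construct alignment parameters
#'
#' @param matrix substitution matrix name or file path (see
#'   [loadSubstitutionMatrix()]), or a numeric matrix with residue dimnames.
#' @param gapOpen penalty for the first residue of a gap run (negative;
#'   default -10).
#' @param gapExtend penalty for each further gap residue (negative, with
#'   `gapOpen <= gapExtend`; default -1).  A gap run of length L costs
#'   `gapOpen + (L - 1) * gapExtend`.
#' @return an [AlignmentParams-class].
#' @examples
#' alignmentParams()                       # BLOSUM62, -10/-1
#' alignmentParams("PAM250", -12, -2)
#' @export
alignmentParams <- function(matrix = "BLOSUM62", gapOpen = -10,
                            gapExtend = -1) {
    if (is.character(matrix)) {
        nm <- matrix
        matrix <- loadSubstitutionMatrix(matrix)
    } else {
        nm <- "custom"
    }
    new("AlignmentParams", matrixName = nm, matrix = matrix,
        gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

# map residues to 0-based matrix indices; error names the offending character
.encodeSeq <- function(seq, residues, what) {
    ch <- strsplit(seq, "")[[1L]]
    idx <- match(ch, residues)
    if (anyNA(idx))
        stop("character '", ch[which(is.na(idx))[1L]], "' in ", what,
             " is not in the substitution matrix")
    idx - 1L
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' True global alignment (terminal gaps penalized) under the Gotoh
#' three-state recurrence.  The traceback is deterministic: score ties are
#' resolved preferring diagonal over up (gap in `seqB`) over left (gap in
#' `seqA`), applied from the start of the alignment, so aligned strings are
#' reproducible bit-for-bit.  The score is tie-invariant.
#'
#' @param seqA,seqB non-empty amino-acid sequences (character strings), all
#'   residues present in the substitution matrix.
#' @param params an [AlignmentParams-class]; default BLOSUM62 with gap
#'   penalties -10/-1.
#' @return an [AlignmentResult-class].
#' @examples
#' globalAlign("MKVL", "MKIL")
#' @export
globalAlign <- function(seqA, seqB, params = alignmentParams()) {
    stopifnot(is(params, "AlignmentParams"),
              is.character(seqA), is.character(seqB),
              length(seqA) == 1L, length(seqB) == 1L)
    if (!nzchar(seqA) || !nzchar(seqB))
        stop("sequences must be non-empty")
    sub <- params@matrix
    res <- rownames(sub)
    ai <- .encodeSeq(seqA, res, "seqA")
    bi <- .encodeSeq(seqB, res, "seqB")
    r <- gotoh_align_cpp(ai, bi, sub, params@gapOpen, params@gapExtend)
    ca <- strsplit(seqA, "")[[1L]]
    cb <- strsplit(seqB, "")[[1L]]
    alnA <- ifelse(r$a_idx == 0L, "-", ca[pmax(r$a_idx, 1L)])
    alnB <- ifelse(r$b_idx == 0L, "-", cb[pmax(r$b_idx, 1L)])
    len <- length(alnA)
    ident <- sum(alnA == alnB & alnA != "-")
    both <- alnA != "-" & alnB != "-"
    possub <- sum(sub[cbind(alnA[both], alnB[both])] > 0)
    new("AlignmentResult", score = r$score,
        alignedA = paste(alnA, collapse = ""),
        alignedB = paste(alnB, collapse = ""),
        identityPct = 100 * ident / len,
        similarityPct = 100 * possub / len)
}

#' Percent similarity between two sequences
#'
#' Percent identity (identical aligned columns) or percent similarity
#' (positive-scoring columns) of the optimal global alignment, over the
#' full gapped alignment length.  Symmetric in its two arguments: the pair
#' is put in a canonical order before aligning, so tie-broken tracebacks
#' cannot make `seqSimilarity(a, b)` differ from `seqSimilarity(b, a)`.
#'
#' @inheritParams globalAlign
#' @param mode "identity" (default) or "similarity".
#' @return percentage in [0, 100].
#' @examples
#' seqSimilarity("MKVL", "MKIL")                     # 75
#' seqSimilarity("MKVL", "MKIL", mode = "similarity")
#' @export
seqSimilarity <- function(seqA, seqB, params = alignmentParams(),
                          mode = c("identity", "similarity")) {
    mode <- match.arg(mode)
    if (seqB < seqA) { tmp <- seqA; seqA <- seqB; seqB <- tmp }
    r <- globalAlign(seqA, seqB, params)
    if (mode == "identity") r@identityPct else r@similarityPct
}
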