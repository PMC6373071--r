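#' @include writers.R fixtures.R
NULL

#' Assemble a run configuration
#'
#' @param species list of per-species entries, each a list with `id`,
#'   `accessions` (path), `fasta` (path), `edges` (path) and optional
#'   `mapping` (path of a network-ID to accession table).
#' @param outDir output directory.
#' @param matrix substitution matrix name/path (default "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (defaults -10, -1).
#' @param similarityCutoff percent similarity cutoff for RBH orthology
#'   (default 30).
#' @param similarityMode "identity" (default) or "similarity".
#' @param scoreCutoff STRING combined-score cutoff (default 400, medium
#'   confidence).
#' @param coverageCutoff minimum number of species supporting an IPN edge;
#'   default the number of species (fully conserved).
#' @param strict error (rather than warn) on accessions missing from FASTA.
#' @param dropIsolated drop isolated OPS from graph exports.
#' @param coverageSweep additionally write one edge table per coverage
#'   cutoff value 1..k (`edges_cov<c>.tsv`).
#' @return validated `RunConfig` list.
#' @export
runConfig <- function(species, outDir, matrix = "BLOSUM62", gapOpen = -10,
                      gapExtend = -1, similarityCutoff = 30,
                      similarityMode = c("identity", "similarity"),
                      scoreCutoff = 400L, coverageCutoff = NULL,
                      strict = FALSE, dropIsolated = FALSE,
                      coverageSweep = FALSE) {
    similarityMode <- match.arg(similarityMode)
    k <- length(species)
    if (k < 2L || k > 4L)
        stop("an analysis needs 2 to 4 species (got ", k, ")")
    ids <- vapply(species, function(s) as.character(s$id), character(1))
    if (anyDuplicated(ids)) stop("duplicated species ids")
    for (s in species)
        for (f in c("accessions", "fasta", "edges"))
            if (is.null(s[[f]]) || !file.exists(s[[f]]))
                stop("species '", s$id, "': missing ", f, " file")
    if (is.null(coverageCutoff)) coverageCutoff <- k
    stopifnot(similarityCutoff >= 0, similarityCutoff <= 100,
              scoreCutoff >= 0, scoreCutoff <= 1000,
              coverageCutoff >= 1, coverageCutoff <= k)
    cfg <- list(species = species, outDir = outDir, matrix = matrix,
                gapOpen = gapOpen, gapExtend = gapExtend,
                similarityCutoff = similarityCutoff,
                similarityMode = similarityMode,
                scoreCutoff = as.integer(scoreCutoff),
                coverageCutoff = as.integer(coverageCutoff),
                strict = isTRUE(strict), dropIsolated = isTRUE(dropIsolated),
                coverageSweep = isTRUE(coverageSweep))
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Read a run configuration from YAML
#'
#' The file holds the same fields as [runConfig()]; relative paths are
#' resolved against the config file's directory.
#'
#' @param path YAML config path.
#' @return validated `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    stopifnot(file.exists(path))
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    rel <- function(p) if (is.null(p) || grepl("^/", p)) p
                       else file.path(base, p)
    sp <- lapply(y$species, function(s) {
        s$accessions <- rel(s$accessions)
        s$fasta <- rel(s$fasta)
        s$edges <- rel(s$edges)
        s$mapping <- rel(s$mapping)
        s
    })
    args <- y[setdiff(names(y), c("species", "outDir"))]
    do.call(runConfig, c(list(species = sp,
                              outDir = rel(y$outDir)), args))
}

#' Run the full interolog pipeline
#'
#' Executes the five stages in order: load accession lists and sequences;
#' all-vs-all alignment and reciprocal-best-hit orthology per species pair;
#' OPS assembly; per-species network loading, confidence filtering and OPS
#' restriction; IPN edge extraction under the coverage cutoff.  Writes
#' `nodes.tsv`, `edges.tsv`, `ipn.graphml`, `ipn.dot`, per-pair best-hit
#' and RBH tables, and `manifest.yaml` to `config$outDir`.  Deterministic:
#' identical configs give byte-identical outputs.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @param quiet suppress stage messages.
#' @return the [IPN-class], invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    say <- function(...) if (!quiet) message(...)
    stage <- "config"
    run <- function(what, expr) {
        stage <<- what
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    ids <- vapply(config$species, function(s) s$id, character(1))
    k <- length(ids)
    params <- run("alignment-params",
                  alignmentParams(config$matrix, config$gapOpen,
                                  config$gapExtend))
    counts <- list()

    say("== stage 1: sequences ==")
    proteomes <- run("sequences", lapply(config$species, function(s) {
        acc <- readAccessionList(s$accessions)
        readProteome(s$fasta, acc, s$id, strict = config$strict)
    }))
    names(proteomes) <- ids
    for (p in proteomes) say("  ", speciesId(p), ": ", length(p), " proteins")
    counts$proteins <- lapply(proteomes, length)

    say("== stage 2: orthology (RBH) ==")
    pairIdx <- utils::combn(k, 2L, simplify = FALSE)
    maps <- run("orthology", lapply(pairIdx, function(ij) {
        orthologyMap(proteomes[[ij[1L]]], proteomes[[ij[2L]]], params,
                     config$similarityCutoff, config$similarityMode)
    }))
    nAln <- 0L
    for (m in maps) {
        nAln <- nAln + nrow(m@bestHitsAB) * nrow(m@bestHitsBA)
        say("  ", m@speciesA, " ~ ", m@speciesB, ": ", nrow(rbhPairs(m)),
            " RBH pairs")
        writeRBH(m, file.path(config$outDir,
                              paste0("rbh_", m@speciesA, "_", m@speciesB,
                                     ".tsv")))
        writeBestHits(m, file.path(config$outDir,
                                   paste0("besthits_", m@speciesA, "_",
                                          m@speciesB, ".tsv")), "ab")
        writeBestHits(m, file.path(config$outDir,
                                   paste0("besthits_", m@speciesB, "_",
                                          m@speciesA, ".tsv")), "ba")
    }
    counts$alignments <- nAln
    counts$rbh_pairs <- lapply(maps, function(m) nrow(rbhPairs(m)))
    names(counts$rbh_pairs) <- vapply(maps, function(m)
        paste(m@speciesA, m@speciesB, sep = "-"), character(1))

    say("== stage 3: OPS nodes ==")
    ops <- run("ops", buildOPS(maps, ids))
    say("  ", nrow(opsMembers(ops)), " orthologous protein sets")
    counts$ops <- nrow(opsMembers(ops))

    say("== stage 4: species networks ==")
    networks <- run("networks", lapply(config$species, function(s) {
        mapping <- if (!is.null(s$mapping)) readIdMapping(s$mapping)
        net <- readEdgeList(s$edges, s$id, mapping)
        restrictToOPS(filterByScore(net, config$scoreCutoff), ops)
    }))
    names(networks) <- ids
    for (n in networks) say("  ", speciesId(n), ": ", nrow(edges(n)),
                            " edges after filtering/restriction")
    counts$network_edges <- lapply(networks, function(n) nrow(edges(n)))

    say("== stage 5: IPN edges ==")
    paramRecord <- list(matrix = config$matrix, gap_open = config$gapOpen,
                        gap_extend = config$gapExtend,
                        similarity_cutoff = config$similarityCutoff,
                        similarity_mode = config$similarityMode,
                        score_cutoff = config$scoreCutoff)
    ipn <- run("ipn", buildIPN(ops, networks, config$coverageCutoff,
                               paramRecord))
    say("  ", nrow(edges(ipn)), " IPN edges at coverage cutoff ",
        config$coverageCutoff)
    counts$ipn_edges <- nrow(edges(ipn))

    run("write", writeIPN(ipn, config$outDir, config$dropIsolated))
    if (config$coverageSweep) {
        for (cc in seq_len(k)) {
            sweep <- run("ipn", buildIPN(ops, networks, cc, paramRecord))
            write.table(.ipnEdgeTable(sweep),
                        file.path(config$outDir,
                                  sprintf("edges_cov%d.tsv", cc)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            say("  coverage ", cc, ": ", nrow(edges(sweep)), " edges")
        }
    }
    inputs <- unlist(lapply(config$species, function(s)
        c(s$accessions, s$fasta, s$edges, s$mapping)))
    run("manifest", writeRunManifest(
        file.path(config$outDir, "manifest.yaml"),
        parameters = c(paramRecord,
                       list(coverage_cutoff = config$coverageCutoff,
                            species = ids)),
        inputs = inputs, counts = counts))
    invisible(ipn)
}
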