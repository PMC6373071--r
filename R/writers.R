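#' @include ipn.R
NULL

.ipnEdgeTable <- function(ipn) {
    e <- edges(ipn)
    m <- opsMembers(ipn)
    sp <- analysisSpecies(ipn)
    # per-species member-pair columns "<sp>_pair" = "accI|accJ"
    for (s in sp) {
        memb <- structure(m[[s]], names = m$ops_id)
        e[[paste0(s, "_pair")]] <- if (nrow(e))
            paste(memb[e$ops_i], memb[e$ops_j], sep = "|") else character(0)
    }
    if (nrow(e)) {
        e <- e[order(e$ops_i, e$ops_j), , drop = FALSE]
        rownames(e) <- NULL
    }
    e
}

.quoteDot <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

#' Convert an IPN to an igraph graph
#'
#' Undirected graph over `ops_id`s; vertices carry one attribute per
#' species (the member accession), edges carry `coverage` and
#' `supporting_species`.
#'
#' @param ipn an [IPN-class].
#' @return an [igraph::igraph] object.
#' @export
ipnToIgraph <- function(ipn) {
    m <- opsMembers(ipn)
    e <- edges(ipn)
    igraph::graph_from_data_frame(
        e[, c("ops_i", "ops_j", "coverage", "supporting_species"),
          drop = FALSE],
        directed = FALSE, vertices = m)
}

#' Write an IPN to disk
#'
#' Writes four files with fixed column orders and rows sorted by `ops_id`,
#' so outputs are diffable: `nodes.tsv` (ops_id + one accession column per
#' species), `edges.tsv` (ops_i, ops_j, coverage, supporting_species, one
#' member-pair column per species), `ipn.graphml` and `ipn.dot`.
#'
#' @param ipn an [IPN-class].
#' @param outDir output directory (created if needed).
#' @param dropIsolated drop OPS without any IPN edge from the graph
#'   exports (node/edge TSVs always keep all nodes).
#' @return named character vector of the paths written, invisibly.
#' @export
writeIPN <- function(ipn, outDir, dropIsolated = FALSE) {
    stopifnot(is(ipn, "IPN"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    m <- opsMembers(ipn)
    m <- m[order(m$ops_id), , drop = FALSE]
    nodesPath <- file.path(outDir, "nodes.tsv")
    write.table(m, nodesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    e <- .ipnEdgeTable(ipn)
    edgesPath <- file.path(outDir, "edges.tsv")
    write.table(e, edgesPath, sep = "\t", quote = FALSE, row.names = FALSE)

    g <- ipnToIgraph(ipn)
    if (dropIsolated)
        g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    gmlPath <- file.path(outDir, "ipn.graphml")
    igraph::write_graph(g, gmlPath, format = "graphml")

    # DOT written directly for stable quoting and attribute layout
    dotPath <- file.path(outDir, "ipn.dot")
    keepIds <- igraph::V(g)$name
    lines <- c("graph IPN {", "  node [shape=ellipse];")
    for (i in seq_len(nrow(m)))
        if (m$ops_id[i] %in% keepIds)
            lines <- c(lines, paste0("  ", .quoteDot(m$ops_id[i]),
                                     " [label=", .quoteDot(m$ops_id[i]),
                                     "];"))
    if (nrow(e))
        lines <- c(lines, paste0("  ", .quoteDot(e$ops_i), " -- ",
                                 .quoteDot(e$ops_j), " [label=",
                                 .quoteDot(as.character(e$coverage)), "];"))
    lines <- c(lines, "}")
    writeLines(lines, dotPath)

    invisible(c(nodes = nodesPath, edges = edgesPath, graphml = gmlPath,
                dot = dotPath))
}

#' Read an IPN back from its TSV exports
#'
#' Lossless counterpart of [writeIPN()] for nodes, edges, coverage and
#' supporting species (parameter records live in the run manifest).
#'
#' @param dir directory holding `nodes.tsv` and `edges.tsv`.
#' @param parameters optional parameter list to attach.
#' @return an [IPN-class].
#' @export
readIPN <- function(dir, parameters = list()) {
    m <- read.delim(file.path(dir, "nodes.tsv"), stringsAsFactors = FALSE)
    e <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE,
                    colClasses = "character")
    species <- setdiff(names(m), "ops_id")
    e <- e[, c("ops_i", "ops_j", "coverage", "supporting_species"),
           drop = FALSE]
    e$coverage <- as.integer(e$coverage)
    ops <- new("OPSSet", species = species, members = m)
    new("IPN", nodes = ops, edges = e, parameters = parameters)
}

#' Write best-hit / RBH tables
#'
#' `writeBestHits()` writes one direction's best hits; `writeRBH()` writes
#' the reciprocal pairs with columns species_a, accession_a, species_b,
#' accession_b, similarity.
#'
#' @param map an [OrthologyMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRBH <- function(map, path) {
    p <- rbhPairs(map)
    out <- data.frame(species_a = map@speciesA, accession_a = p$accessionA,
                      species_b = map@speciesB, accession_b = p$accessionB,
                      similarity = p$similarity, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRBH
#' @param direction "ab" or "ba".
#' @export
writeBestHits <- function(map, path, direction = c("ab", "ba")) {
    direction <- match.arg(direction)
    h <- if (direction == "ab") map@bestHitsAB else map@bestHitsBA
    sA <- if (direction == "ab") map@speciesA else map@speciesB
    sB <- if (direction == "ab") map@speciesB else map@speciesA
    out <- data.frame(species_a = sA, accession_a = h$query,
                      species_b = sB, accession_b = h$subject,
                      similarity = h$similarity, tie = h$tie,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a run manifest
#'
#' YAML record of the tool version, every parameter, input-file MD5
#' checksums and per-stage counts; enough to reproduce the run.  Contains
#' no timestamps, so identical runs give identical manifests.
#'
#' @param path output path.
#' @param parameters named list of parameters.
#' @param inputs character vector of input file paths.
#' @param counts named list of per-stage counts.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, parameters, inputs, counts) {
    checks <- as.list(tools::md5sum(inputs))
    names(checks) <- basename(names(checks))
    manifest <- list(tool = "interolog",
                     version = as.character(packageVersion("interolog")),
                     parameters = parameters, input_md5 = checks,
                     counts = counts)
    yaml::write_yaml(manifest, path)
    invisible(path)
}
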