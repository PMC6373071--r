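#' @include seqio.R ppin.R
NULL

#' Specification for a synthetic benchmark data set
#'
#' Describes an ancestral proteome and interaction network and how each of
#' k descendant species diverges from it: orthologs evolve by independent
#' per-site substitution, each species keeps each ancestral interaction
#' with probability `retentionP` and gains species-private spurious edges;
#' unrelated decoy proteins are added per species.  Ground truth (ortholog
#' groups and the edge set conserved in all k species) is known by
#' construction.
#'
#' @param nAncestral number of ancestral proteins (>= 1).
#' @param k number of descendant species (2--4).
#' @param subRate per-site substitution probability per species, in
#'   [0, 0.5]; a substituted site receives a uniformly drawn *different*
#'   residue.
#' @param decoysPerSpecies unrelated random proteins added per species.
#' @param ancestralEdgeP probability that an ancestral protein pair
#'   interacts (default 0.3).
#' @param retentionP per-species probability an ancestral edge is retained
#'   (default 1).
#' @param spuriousEdgesPerSpecies species-private random non-ancestral
#'   edges added per species (default 0).
#' @param scoreFloor lower bound of the uniform integer score assigned to
#'   emitted edges (default 700; scores lie in [scoreFloor, 1000]).
#' @param seed integer RNG seed; identical seeds give byte-identical files.
#' @return a validated `FixtureSpec` list.
#' @export
fixtureSpec <- function(nAncestral = 20L, k = 4L, subRate = 0.05,
                        decoysPerSpecies = 5L, ancestralEdgeP = 0.3,
                        retentionP = 1, spuriousEdgesPerSpecies = 10L,
                        scoreFloor = 700L, seed = 1L) {
    spec <- list(nAncestral = as.integer(nAncestral), k = as.integer(k),
                 subRate = subRate, decoysPerSpecies = as.integer(decoysPerSpecies),
                 ancestralEdgeP = ancestralEdgeP, retentionP = retentionP,
                 spuriousEdgesPerSpecies = as.integer(spuriousEdgesPerSpecies),
                 scoreFloor = as.integer(scoreFloor), seed = as.integer(seed))
    stopifnot(spec$nAncestral >= 1L, spec$k >= 2L, spec$k <= 4L,
              spec$subRate >= 0, spec$subRate <= 0.5,
              spec$decoysPerSpecies >= 0L,
              spec$ancestralEdgeP >= 0, spec$ancestralEdgeP <= 1,
              spec$retentionP >= 0, spec$retentionP <= 1,
              spec$spuriousEdgesPerSpecies >= 0L,
              spec$scoreFloor >= 0L, spec$scoreFloor <= 1000L)
    class(spec) <- c("FixtureSpec", "list")
    spec
}

.randomSeq <- function(len) paste(sample(AA_STANDARD, len, replace = TRUE),
                                  collapse = "")

.mutateSeq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    ch <- strsplit(seq, "")[[1L]]
    hit <- runif(length(ch)) < rate
    if (any(hit))
        ch[hit] <- vapply(ch[hit], function(orig)
            sample(setdiff(AA_STANDARD, orig), 1L), character(1))
    paste(ch, collapse = "")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Generate a synthetic benchmark data set with known truth
#'
#' Writes, per species `sp1` ... `spk`: a FASTA file (`<sp>.fasta`), an
#' accession list (`<sp>_accessions.txt`) and a STRING-style edge list
#' (`<sp>_edges.tsv`), plus two truth tables: `truth_orthologs.tsv`
#' (ancestral protein to per-species accession) and
#' `truth_conserved_edges.tsv` (ancestral pairs retained in all k species).
#' Ancestral sequences are i.i.d. uniform over the 20 residues, lengths
#' 60--120; decoys are fresh random sequences length-matched to the
#' ancestral length range.  Deterministic: the same spec (same seed) gives
#' byte-identical files.
#'
#' @param spec a [fixtureSpec()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a `FixtureTruth` list: `species`, `orthologs`
#'   (data.frame), `conservedEdges` (data.frame ancestral_a, ancestral_b),
#'   and `files` (named paths).
#' @export
generateFixture <- function(spec, outDir) {
    stopifnot(inherits(spec, "FixtureSpec"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .withSeed(spec$seed, {
        n <- spec$nAncestral
        k <- spec$k
        speciesIds <- paste0("sp", seq_len(k))
        ancIds <- sprintf("ANC%03d", seq_len(n))
        ancLens <- sample(60:120, n, replace = TRUE)
        ancSeqs <- vapply(ancLens, .randomSeq, character(1))

        # ancestral interactions
        ancPairs <- if (n >= 2L) utils::combn(n, 2L) else
            matrix(integer(0), nrow = 2L)
        isEdge <- if (ncol(ancPairs)) runif(ncol(ancPairs)) < spec$ancestralEdgeP
                  else logical(0)
        ancEdges <- ancPairs[, isEdge, drop = FALSE]

        orth <- data.frame(ancestral_id = ancIds, stringsAsFactors = FALSE)
        files <- character(0)
        retained <- vector("list", k)
        netEdges <- vector("list", k)
        proteomes <- vector("list", k)

        for (s in seq_len(k)) {
            sp <- speciesIds[s]
            orthAcc <- sprintf("%sP%03d", toupper(sp), seq_len(n))
            decoyAcc <- if (spec$decoysPerSpecies)
                sprintf("%sD%03d", toupper(sp), seq_len(spec$decoysPerSpecies))
                else character(0)
            orth[[sp]] <- orthAcc
            seqs <- vapply(ancSeqs, .mutateSeq, character(1),
                           rate = spec$subRate)
            decoySeqs <- vapply(sample(60:120, spec$decoysPerSpecies,
                                       replace = TRUE),
                                .randomSeq, character(1))
            allSeqs <- c(seqs, decoySeqs)
            names(allSeqs) <- c(orthAcc, decoyAcc)
            proteomes[[s]] <- allSeqs

            # retained ancestral edges
            keepEdge <- if (ncol(ancEdges))
                runif(ncol(ancEdges)) < spec$retentionP else logical(0)
            retained[[s]] <- keepEdge
            ef <- orthAcc[ancEdges[1L, keepEdge]]
            et <- orthAcc[ancEdges[2L, keepEdge]]

            # species-private spurious edges among all of this species'
            # proteins, avoiding retained ancestral pairs
            allAcc <- c(orthAcc, decoyAcc)
            if (spec$spuriousEdgesPerSpecies > 0L) {
                allPairs <- utils::combn(allAcc, 2L)
                pkey <- paste(pmin(allPairs[1L, ], allPairs[2L, ]),
                              pmax(allPairs[1L, ], allPairs[2L, ]), sep = "\r")
                used <- paste(pmin(ef, et), pmax(ef, et), sep = "\r")
                free <- which(!(pkey %in% used))
                if (length(free) < spec$spuriousEdgesPerSpecies)
                    stop("impossible spec: more spurious edges requested (",
                         spec$spuriousEdgesPerSpecies,
                         ") than available non-edges (", length(free), ")")
                pick <- sort(sample(free, spec$spuriousEdgesPerSpecies))
                ef <- c(ef, allPairs[1L, pick])
                et <- c(et, allPairs[2L, pick])
            }
            sc <- sample(spec$scoreFloor:1000L, length(ef), replace = TRUE)
            netEdges[[s]] <- data.frame(from = ef, to = et, score = sc,
                                        stringsAsFactors = FALSE)
        }

        # truth is read off the emitted networks themselves: an ancestral
        # pair is conserved iff its mapped pair is an edge in every species
        # (this also catches a spurious edge landing on an ancestral pair)
        orthoKeySets <- lapply(seq_len(k), function(s) {
            orthAcc <- orth[[speciesIds[s]]]
            e <- netEdges[[s]]
            ia <- match(e$from, orthAcc)
            ib <- match(e$to, orthAcc)
            both <- !is.na(ia) & !is.na(ib)
            paste(pmin(ia[both], ib[both]), pmax(ia[both], ib[both]))
        })
        consKeys <- Reduce(intersect, orthoKeySets)
        conserved <- if (length(consKeys)) {
            ij <- do.call(rbind, lapply(strsplit(consKeys, " "), as.integer))
            ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
            data.frame(ancestral_a = ancIds[ij[, 1L]],
                       ancestral_b = ancIds[ij[, 2L]],
                       stringsAsFactors = FALSE)
        } else data.frame(ancestral_a = character(0),
                          ancestral_b = character(0),
                          stringsAsFactors = FALSE)

        for (s in seq_len(k)) {
            sp <- speciesIds[s]
            fa <- file.path(outDir, paste0(sp, ".fasta"))
            writeProteome(SpeciesProteome(sp, proteomes[[s]]), fa)
            acc <- file.path(outDir, paste0(sp, "_accessions.txt"))
            writeLines(names(proteomes[[s]]), acc)
            ed <- file.path(outDir, paste0(sp, "_edges.tsv"))
            df <- netEdges[[s]]
            df <- df[order(df$from, df$to), , drop = FALSE]
            writeLines(c("protein1\tprotein2\tcombined_score",
                         sprintf("%s\t%s\t%d", df$from, df$to, df$score)), ed)
            files[paste0(sp, "_fasta")] <- fa
            files[paste0(sp, "_accessions")] <- acc
            files[paste0(sp, "_edges")] <- ed
        }
        orthPath <- file.path(outDir, "truth_orthologs.tsv")
        write.table(orth, orthPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        consPath <- file.path(outDir, "truth_conserved_edges.tsv")
        write.table(conserved, consPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files["truth_orthologs"] <- orthPath
        files["truth_conserved_edges"] <- consPath

        invisible(list(species = speciesIds, orthologs = orth,
                       conservedEdges = conserved, files = files))
    })
}

#' Read back fixture ground truth
#'
#' @param dir directory written by [generateFixture()].
#' @return list with `orthologs` and `conservedEdges` data.frames.
#' @export
readFixtureTruth <- function(dir) {
    list(orthologs = read.delim(file.path(dir, "truth_orthologs.tsv"),
                                stringsAsFactors = FALSE),
         conservedEdges = read.delim(file.path(dir,
                                               "truth_conserved_edges.tsv"),
                                     stringsAsFactors = FALSE))
}
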