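ops2 <- function(n, species) {
    cols <- c(list(ops_id = paste0("OPS", seq_len(n))),
              setNames(lapply(species, function(s)
                  paste0(s, "_p", seq_len(n))), species))
    new("OPSSet", species = species,
        members = as.data.frame(cols, stringsAsFactors = FALSE))
}

net_from_pairs <- function(sp, ij_pairs, members) {
    # ij_pairs: list of c(i, j) OPS index pairs to connect in this species
    if (length(ij_pairs)) {
        from <- vapply(ij_pairs, function(p) members[[sp]][p[1L]], character(1))
        to <- vapply(ij_pairs, function(p) members[[sp]][p[2L]], character(1))
        SpeciesNetwork(sp, data.frame(from = from, to = to, score = 900L,
                                      stringsAsFactors = FALSE))
    } else {
        SpeciesNetwork(sp, data.frame(from = character(0), to = character(0),
                                      score = integer(0)))
    }
}

test_that("edge coverage counts exactly the supporting species", {
    species <- c("s1", "s2", "s3")
    ops <- ops2(2, species)
    m <- opsMembers(ops)
    nets <- list(s1 = net_from_pairs("s1", list(c(1, 2)), m),
                 s2 = net_from_pairs("s2", list(c(1, 2)), m),
                 s3 = net_from_pairs("s3", list(), m))
    cov <- edgeCoverage(ops, "OPS1", "OPS2", nets)
    expect_equal(cov$coverage, 2L)
    expect_equal(cov$species, c("s1", "s2"))

    nets0 <- list(s1 = net_from_pairs("s1", list(), m),
                  s2 = net_from_pairs("s2", list(), m),
                  s3 = net_from_pairs("s3", list(), m))
    expect_equal(edgeCoverage(ops, "OPS1", "OPS2", nets0)$coverage, 0L)

    netsAll <- lapply(setNames(species, species), net_from_pairs,
                      ij_pairs = list(c(1, 2)), members = m)
    expect_equal(edgeCoverage(ops, "OPS1", "OPS2", netsAll)$coverage, 3L)

    expect_error(edgeCoverage(ops, "OPS1", "OPS2", nets[1:2]), "no network")
})

test_that("the coverage cutoff is inclusive and validated", {
    species <- c("s1", "s2", "s3")
    ops <- ops2(2, species)
    m <- opsMembers(ops)
    nets <- list(s1 = net_from_pairs("s1", list(c(1, 2)), m),
                 s2 = net_from_pairs("s2", list(c(1, 2)), m),
                 s3 = net_from_pairs("s3", list(), m))
    expect_equal(nrow(edges(buildIPN(ops, nets, 2))), 1L)
    expect_equal(nrow(edges(buildIPN(ops, nets, 3))), 0L)
    expect_error(buildIPN(ops, nets, 0), "coverage cutoff")
    expect_error(buildIPN(ops, nets, 4), "coverage cutoff")
    # isolated OPS stay in the node list
    expect_equal(opsIds(buildIPN(ops, nets, 3)), c("OPS1", "OPS2"))
})

test_that("IPN equals the exhaustive double-loop oracle on random instances", {
    set.seed(41)
    for (rep in 1:20) {
        k <- sample(2:4, 1)
        species <- paste0("s", seq_len(k))
        n <- sample(3:7, 1)
        ops <- ops2(n, species)
        m <- opsMembers(ops)
        allPairs <- combn(n, 2L, simplify = FALSE)
        nets <- lapply(setNames(species, species), function(sp) {
            take <- allPairs[runif(length(allPairs)) < 0.4]
            net_from_pairs(sp, take, m)
        })
        edge_sets <- lapply(nets, function(nt) {
            e <- edges(nt)
            paste(e$from, e$to, sep = "|")
        })
        for (cc in seq_len(k)) {
            got <- ipn_edge_keys(buildIPN(ops, nets, cc))
            want <- brute_ipn_edges(m, species, edge_sets, cc)
            expect_equal(got, want)
        }
    }
})

test_that("edge count is non-increasing in all three cutoffs", {
    # full pipeline on one fixture, swept over a cutoff grid
    spec <- fixtureSpec(nAncestral = 8, k = 3, subRate = 0.08,
                        decoysPerSpecies = 3, ancestralEdgeP = 0.4,
                        retentionP = 0.8, spuriousEdgesPerSpecies = 5,
                        scoreFloor = 0L, seed = 13)
    d <- withr::local_tempdir()
    generateFixture(spec, d)
    proteomes <- lapply(paste0("sp", 1:3), function(s)
        readProteome(file.path(d, paste0(s, ".fasta")),
                     readAccessionList(file.path(d, paste0(s, "_accessions.txt"))),
                     s))
    params <- alignmentParams()
    sims <- lapply(combn(3L, 2L, simplify = FALSE), function(ij)
        allVsAll(proteomes[[ij[1L]]], proteomes[[ij[2L]]], params))
    rawNets <- lapply(paste0("sp", 1:3), function(s)
        readEdgeList(file.path(d, paste0(s, "_edges.tsv")), s))
    names(rawNets) <- paste0("sp", 1:3)

    count_edges <- function(simCut, scoreCut, covCut) {
        maps <- mapply(function(m, ij)
            reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), simCut,
                               paste0("sp", ij[1L]), paste0("sp", ij[2L])),
            sims, combn(3L, 2L, simplify = FALSE), SIMPLIFY = FALSE)
        ops <- buildOPS(maps, paste0("sp", 1:3))
        if (!nrow(opsMembers(ops))) return(0L)
        nets <- lapply(rawNets, function(nt)
            restrictToOPS(filterByScore(nt, scoreCut), ops))
        nrow(edges(buildIPN(ops, nets, covCut)))
    }
    for (simCut in c(20, 50)) {
        for (scoreCut in c(0, 500)) {
            covCounts <- vapply(1:3, function(cc)
                count_edges(simCut, scoreCut, cc), integer(1))
            expect_true(all(diff(covCounts) <= 0L))
        }
        # score cutoff monotonicity at fixed coverage
        expect_gte(count_edges(simCut, 0, 2), count_edges(simCut, 500, 2))
    }
    # similarity cutoff monotonicity
    expect_gte(count_edges(20, 0, 2), count_edges(50, 0, 2))
})

test_that("at full coverage the IPN cannot outnumber the sparsest PPIN", {
    set.seed(59)
    for (rep in 1:10) {
        k <- sample(2:4, 1)
        species <- paste0("s", seq_len(k))
        n <- sample(3:6, 1)
        ops <- ops2(n, species)
        m <- opsMembers(ops)
        allPairs <- combn(n, 2L, simplify = FALSE)
        nets <- lapply(setNames(species, species), function(sp)
            net_from_pairs(sp, allPairs[runif(length(allPairs)) < 0.5], m))
        ipn <- buildIPN(ops, nets, k)
        minPPIN <- min(vapply(nets, function(nt)
            nrow(edges(restrictToOPS(nt, ops))), integer(1)))
        expect_lte(nrow(edges(ipn)), minPPIN)
    }
})

test_that("two identical species at full coverage reproduce the input network", {
    # degenerate identity limit: sp1 == sp2, cutoff 2
    species <- c("s1", "s2")
    n <- 5L
    ops <- ops2(n, species)
    m <- opsMembers(ops)
    pairs <- list(c(1, 2), c(2, 3), c(1, 4), c(4, 5))
    nets <- list(s1 = net_from_pairs("s1", pairs, m),
                 s2 = net_from_pairs("s2", pairs, m))
    ipn <- buildIPN(ops, nets, 2)
    expect_equal(ipn_edge_keys(ipn),
                 sort(vapply(pairs, function(p)
                     paste0("OPS", min(p), "|OPS", max(p)), character(1))))
})

test_that("ancestral edges retained everywhere are recovered exactly at full coverage", {
    spec <- fixtureSpec(nAncestral = 10, k = 3, subRate = 0.05,
                        decoysPerSpecies = 3, ancestralEdgeP = 0.35,
                        retentionP = 1, spuriousEdgesPerSpecies = 6,
                        seed = 21)
    d <- withr::local_tempdir()
    truth <- generateFixture(spec, d)
    cfg <- runConfig(fixture_species_config(d, truth$species),
                     file.path(d, "out"))
    ipn <- suppressWarnings(runPipeline(cfg, quiet = TRUE))
    expect_equal(nrow(opsMembers(ipn)), 10L)
    expect_equal(ipn_edges_as_ancestral(ipn, truth), truth_edge_keys(truth))
})
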