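make_map <- function(sA, sB, a, b, sim = 90) {
    pairs <- data.frame(accessionA = a, accessionB = b,
                        similarity = rep_len(sim, length(a)),
                        stringsAsFactors = FALSE)
    empty <- data.frame(query = character(0), subject = character(0),
                        similarity = numeric(0), tie = logical(0),
                        stringsAsFactors = FALSE)
    new("OrthologyMap", speciesA = sA, speciesB = sB, cutoff = 30,
        mode = "identity", pairs = pairs, bestHitsAB = empty,
        bestHitsBA = empty)
}

# random partial matching between two accession sets (valid RBH structure:
# each protein has at most one partner)
random_matching <- function(accA, accB, p = 0.6) {
    n <- min(length(accA), length(accB))
    take <- which(runif(n) < p)
    list(a = sample(accA, n)[take], b = sample(accB, n)[take])
}

test_that("with two species every RBH pair becomes one OPS", {
    m <- make_map("s1", "s2", c("a1", "a2"), c("b1", "b2"))
    ops <- buildOPS(list(m), c("s1", "s2"))
    expect_equal(opsMembers(ops)$s1, c("a1", "a2"))
    expect_equal(opsMembers(ops)$s2, c("b1", "b2"))
    expect_equal(opsIds(ops), c("OPS1", "OPS2"))
})

test_that("three species require a closed triangle", {
    maps <- list(make_map("s1", "s2", c("a1", "a2"), c("b1", "b2")),
                 make_map("s2", "s3", "b1", "c1"),
                 make_map("s1", "s3", "a1", "c1"))
    ops <- buildOPS(maps, c("s1", "s2", "s3"))
    m <- opsMembers(ops)
    expect_equal(nrow(m), 1L)
    expect_equal(unlist(m[1L, c("s1", "s2", "s3")], use.names = FALSE),
                 c("a1", "b1", "c1"))

    # open triangle: a1-b1, b1-c1 present but s1-s3 links a1 to c2
    maps2 <- list(make_map("s1", "s2", "a1", "b1"),
                  make_map("s2", "s3", "b1", "c1"),
                  make_map("s1", "s3", "a1", "c2"))
    expect_equal(nrow(opsMembers(buildOPS(maps2, c("s1", "s2", "s3")))), 0L)
})

test_that("missing species-pair map and bad species counts error", {
    m <- make_map("s1", "s2", "a1", "b1")
    expect_error(buildOPS(list(m), c("s1", "s2", "s3")), "no orthology map")
    expect_error(buildOPS(list(m), "s1"), "2 to 4")
    expect_error(buildOPS(list(m), c("s1", "s1")), "duplicated")
})

test_that("OPS equal brute-force one-per-species k-clique enumeration", {
    set.seed(17)
    for (rep in 1:25) {
        k <- sample(2:4, 1)
        species <- paste0("s", seq_len(k))
        proteins <- lapply(species, function(s)
            paste0(s, "_p", seq_len(sample(2:8, 1))))
        names(proteins) <- species
        maps <- list(); pair_sets <- list()
        for (ij in combn(k, 2L, simplify = FALSE)) {
            sA <- species[ij[1L]]; sB <- species[ij[2L]]
            mt <- random_matching(proteins[[sA]], proteins[[sB]])
            maps[[length(maps) + 1L]] <- make_map(sA, sB, mt$a, mt$b)
            pair_sets[[paste(sA, sB, sep = "|")]] <-
                data.frame(accessionA = mt$a, accessionB = mt$b,
                           stringsAsFactors = FALSE)
        }
        got <- opsMembers(buildOPS(maps, species))[, species, drop = FALSE]
        want <- brute_ops(pair_sets, species, proteins)
        rownames(got) <- NULL
        expect_equal(got, want, info = paste("rep", rep))
        # node-count bound: no more OPS than the smallest RBH pair set
        expect_lte(nrow(got),
                   min(vapply(pair_sets, nrow, integer(1))))
    }
})

test_that("requiring conservation in more species cannot enlarge the node set", {
    set.seed(29)
    for (rep in 1:10) {
        species <- paste0("s", 1:4)
        proteins <- lapply(species, function(s) paste0(s, "_p", 1:6))
        names(proteins) <- species
        maps <- list()
        for (ij in combn(4L, 2L, simplify = FALSE)) {
            sA <- species[ij[1L]]; sB <- species[ij[2L]]
            mt <- random_matching(proteins[[sA]], proteins[[sB]], p = 0.8)
            maps[[length(maps) + 1L]] <- make_map(sA, sB, mt$a, mt$b)
        }
        counts <- vapply(2:4, function(kk)
            nrow(opsMembers(buildOPS(maps, species[seq_len(kk)]))),
            integer(1))
        expect_true(all(diff(counts) <= 0L))
    }
})

test_that("ops ids are deterministic and OPS are disjoint", {
    m12 <- make_map("s1", "s2", c("a3", "a1"), c("b3", "b1"))
    ops <- buildOPS(list(m12), c("s1", "s2"))
    expect_equal(opsMembers(ops)$s1, c("a1", "a3"))  # sorted on species 1
    expect_equal(opsIds(ops), c("OPS1", "OPS2"))
    expect_false(anyDuplicated(unlist(opsMembers(ops)[, -1L])) > 0)
})
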