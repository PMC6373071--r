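make_sim <- function(vals, qnames, snames) {
    matrix(vals, nrow = length(qnames), byrow = TRUE,
           dimnames = list(qnames, snames))
}

test_that("all-vs-all has one entry per cross pair and is shared by both directions", {
    pa <- SpeciesProteome("a", c(a1 = "MKVL", a2 = "ACDE", a3 = "WWYF"))
    pb <- SpeciesProteome("b", c(b1 = "MKIL", b2 = "ACDD", b3 = "WYYF",
                                 b4 = "PPPP"))
    m <- allVsAll(pa, pb)
    expect_equal(dim(m), c(3L, 4L))
    expect_false(anyNA(m))
    # transposed view is literally the same storage
    expect_equal(t(m)["b1", "a1"], m["a1", "b1"])
    expect_equal(m["a1", "b1"], seqSimilarity("MKVL", "MKIL"))
})

test_that("best hits take the row argmax with lexicographic tie-breaking", {
    m <- make_sim(c(90, 40), "p1", c("q1", "q2"))
    h <- bestHits(m, "ab")
    expect_identical(h$subject, "q1")
    expect_false(h$tie)

    m <- make_sim(c(50, 50), "p1", c("q2", "q1"))  # tie, q1 listed second
    h <- bestHits(m, "ab")
    expect_identical(h$subject, "q1")
    expect_true(h$tie)
})

test_that("best hits equal a brute-force argmax on random matrices", {
    set.seed(11)
    for (i in 1:30) {
        nr <- sample(2:10, 1); nc <- sample(2:10, 1)
        m <- matrix(sample(0:100, nr * nc, replace = TRUE), nr,
                    dimnames = list(paste0("p", seq_len(nr)),
                                    paste0("q", seq_len(nc))))
        h <- bestHits(m, "ab")
        for (r in seq_len(nr)) {
            expect_equal(h$similarity[r], max(m[r, ]))
            expect_identical(h$subject[r],
                             sort(colnames(m)[m[r, ] == max(m[r, ])])[1L])
        }
        hb <- bestHits(m, "ba")
        expect_identical(hb$query, colnames(m))
    }
})

test_that("reciprocal best hits keep mutual pairs above the cutoff", {
    m <- make_sim(c(80, 10, 20, 70), c("p1", "p2"), c("q1", "q2"))
    om <- reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), 30)
    expect_equal(rbhPairs(om)$accessionA, c("p1", "p2"))
    expect_equal(rbhPairs(om)$accessionB, c("q1", "q2"))

    # non-reciprocal: p1 -> q1 but q1 -> p2
    m <- make_sim(c(50, 10, 60, 40), c("p1", "p2"), c("q1", "q2"))
    om <- reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), 30)
    expect_false("p1" %in% rbhPairs(om)$accessionA)

    # below cutoff
    m <- make_sim(c(25, 10, 5, 20), c("p1", "p2"), c("q1", "q2"))
    om <- reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), 30)
    expect_equal(nrow(rbhPairs(om)), 0L)
})

test_that("RBH equals brute-force mutual argmax on random matrices", {
    set.seed(23)
    for (i in 1:40) {
        nr <- sample(2:10, 1); nc <- sample(2:10, 1)
        m <- matrix(sample(0:100, nr * nc, replace = TRUE), nr,
                    dimnames = list(paste0("p", seq_len(nr)),
                                    paste0("q", seq_len(nc))))
        cutoff <- sample(0:80, 1)
        om <- reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"),
                                 cutoff)
        expect_equal(rbhPairs(om), brute_rbh(m, cutoff))
    }
})

test_that("raising the cutoff never adds an RBH pair", {
    set.seed(31)
    m <- matrix(sample(0:100, 64, replace = TRUE), 8,
                dimnames = list(paste0("p", 1:8), paste0("q", 1:8)))
    hab <- bestHits(m, "ab"); hba <- bestHits(m, "ba")
    prev <- NULL
    for (cutoff in seq(0, 100, by = 10)) {
        cur <- rbhPairs(reciprocalBestHits(hab, hba, cutoff))
        key <- paste(cur$accessionA, cur$accessionB)
        if (!is.null(prev)) expect_true(all(key %in% prev))
        prev <- key
    }
})

test_that("RBH set is invariant to record load order", {
    seqs <- c(a1 = "MKVLWA", a2 = "ACDEFG", a3 = "WWYFHH")
    seqs_b <- c(b1 = "MKILWA", b2 = "ACDDFG", b3 = "WYYFHH")
    om1 <- orthologyMap(SpeciesProteome("a", seqs),
                        SpeciesProteome("b", seqs_b), cutoff = 30)
    om2 <- orthologyMap(SpeciesProteome("a", rev(seqs)),
                        SpeciesProteome("b", rev(seqs_b)), cutoff = 30)
    expect_equal(rbhPairs(om1), rbhPairs(om2))
})

test_that("planted orthologs are recovered as RBH pairs on divergent proteomes", {
    spec <- fixtureSpec(nAncestral = 8, k = 2, subRate = 0.1,
                        decoysPerSpecies = 4, spuriousEdgesPerSpecies = 0,
                        seed = 5)
    d <- withr::local_tempdir()
    truth <- generateFixture(spec, d)
    p1 <- readProteome(file.path(d, "sp1.fasta"),
                       readAccessionList(file.path(d, "sp1_accessions.txt")),
                       "sp1")
    p2 <- readProteome(file.path(d, "sp2.fasta"),
                       readAccessionList(file.path(d, "sp2_accessions.txt")),
                       "sp2")
    m <- allVsAll(p1, p2)
    # each planted ortholog pair attains its row maximum (brute-force max)
    for (r in seq_len(nrow(truth$orthologs))) {
        a <- truth$orthologs$sp1[r]; b <- truth$orthologs$sp2[r]
        expect_equal(m[a, b], max(m[a, ]))
    }
    om <- reciprocalBestHits(bestHits(m, "ab"), bestHits(m, "ba"), 30,
                             "sp1", "sp2")
    got <- rbhPairs(om)
    expect_equal(got$accessionA, sort(truth$orthologs$sp1))
    expect_equal(got$accessionB,
                 truth$orthologs$sp2[match(got$accessionA,
                                           truth$orthologs$sp1)])
})
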