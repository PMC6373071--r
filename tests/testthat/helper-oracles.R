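# Independent oracles, deliberately written with different algorithms and
# conventions than the package code they check.

# number of monotone lattice paths (= global alignments) of an m x n pair;
# used to keep the exponential enumeration oracle tractable
delannoy <- function(m, n) {
    d <- matrix(1, m + 1L, n + 1L)
    for (i in seq_len(m)) for (j in seq_len(n))
        d[i + 1L, j + 1L] <- d[i, j + 1L] + d[i + 1L, j] + d[i, j]
    d[m + 1L, n + 1L]
}

# brute force: recursively enumerate every global alignment (affine gap
# pricing carried through the open/extend state) and return the maximum score
enum_align_score <- function(a, b, sub, gap_open, gap_extend) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    m <- length(av); n <- length(bv)
    rec <- function(i, j, prev) {
        if (i > m && j > n) return(0)
        best <- -Inf
        if (i <= m && j <= n)
            best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
        if (i <= m)
            best <- max(best, (if (prev == "X") gap_extend else gap_open) +
                        rec(i + 1L, j, "X"))
        if (j <= n)
            best <- max(best, (if (prev == "Y") gap_extend else gap_open) +
                        rec(i, j + 1L, "Y"))
        best
    }
    rec(1L, 1L, "M")
}

# classical single-matrix Needleman-Wunsch with a linear gap penalty
linear_nw_score <- function(a, b, sub, gap) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    m <- length(av); n <- length(bv)
    f <- matrix(0, m + 1L, n + 1L)
    f[, 1L] <- gap * (0:m)
    f[1L, ] <- gap * (0:n)
    for (i in seq_len(m)) for (j in seq_len(n))
        f[i + 1L, j + 1L] <- max(f[i, j] + sub[av[i], bv[j]],
                                 f[i, j + 1L] + gap,
                                 f[i + 1L, j] + gap)
    f[m + 1L, n + 1L]
}

random_aa_seq <- function(len, alphabet = c("A","C","D","E","F","G","H","I",
                                            "K","L","M","N","P","Q","R","S",
                                            "T","V","W","Y")) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random symmetric integer substitution matrix over a small alphabet;
# positive diagonal, as in every real substitution matrix
random_sub_matrix <- function(alphabet, lo = -4L, hi = 5L) {
    k <- length(alphabet)
    m <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
    for (i in seq_len(k)) for (j in i:k)
        m[i, j] <- m[j, i] <- if (i == j) sample(1:hi, 1L)
                              else sample(lo:hi, 1L)
    m
}

# brute force mutual-argmax RBH over a similarity matrix (ties resolved
# to the lexicographically smallest partner, mirroring the documented rule)
brute_rbh <- function(sim, cutoff) {
    out <- list()
    for (p in rownames(sim)) {
        best_q <- sort(colnames(sim)[sim[p, ] == max(sim[p, ])])[1L]
        back <- sort(rownames(sim)[sim[, best_q] == max(sim[, best_q])])[1L]
        if (back == p && sim[p, best_q] >= cutoff)
            out[[length(out) + 1L]] <- data.frame(
                accessionA = p, accessionB = best_q,
                similarity = sim[p, best_q], stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(accessionA = character(0),
                          accessionB = character(0),
                          similarity = numeric(0), stringsAsFactors = FALSE))
    r <- do.call(rbind, out)
    r <- r[order(r$accessionA), , drop = FALSE]
    rownames(r) <- NULL
    r
}

# brute force one-per-species k-clique enumeration over pairwise RBH pair
# sets; `pair_sets` is a list keyed "s|t" of data.frames (accessionA from s,
# accessionB from t); `proteins` a named list species -> accessions
brute_ops <- function(pair_sets, species, proteins) {
    k <- length(species)
    has_pair <- function(s, t, a, b) {
        key <- paste(s, t, sep = "|")
        if (!is.null(pair_sets[[key]]))
            return(any(pair_sets[[key]]$accessionA == a &
                       pair_sets[[key]]$accessionB == b))
        key <- paste(t, s, sep = "|")
        any(pair_sets[[key]]$accessionA == b & pair_sets[[key]]$accessionB == a)
    }
    grids <- expand.grid(lapply(species, function(s) proteins[[s]]),
                         stringsAsFactors = FALSE)
    names(grids) <- species
    attr(grids, "out.attrs") <- NULL
    keep <- logical(nrow(grids))
    for (r in seq_len(nrow(grids))) {
        ok <- TRUE
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
            if (!has_pair(species[i], species[j],
                          grids[r, i], grids[r, j])) { ok <- FALSE; break }
        keep[r] <- ok
    }
    res <- grids[keep, , drop = FALSE]
    res <- res[order(res[[1L]]), , drop = FALSE]
    rownames(res) <- NULL
    res
}

# exhaustive double loop over OPS pairs and species; edge sets as
# "from|to" keys with sorted endpoints
brute_ipn_edges <- function(members, species, edge_sets, cutoff) {
    n <- nrow(members)
    out <- character(0)
    if (n < 2L) return(out)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        cov <- 0L
        for (s in species) {
            a <- members[[s]][i]; b <- members[[s]][j]
            key <- paste(min(a, b), max(a, b), sep = "|")
            if (key %in% edge_sets[[s]]) cov <- cov + 1L
        }
        if (cov >= cutoff)
            out <- c(out, paste(members$ops_id[i], members$ops_id[j],
                                sep = "|"))
    }
    sort(out)
}

ipn_edge_keys <- function(ipn) {
    e <- edges(ipn)
    if (!nrow(e)) return(character(0))
    sort(paste(pmin(e$ops_i, e$ops_j), pmax(e$ops_i, e$ops_j), sep = "|"))
}

# minimal structural check of a DOT file: graph header, balanced braces,
# undirected edge operators, properly quoted identifiers on edge lines
expect_valid_dot <- function(path) {
    stopifnot(file.exists(path))
    ln <- readLines(path)
    expect_match(ln[1L], "^graph\\s+\\w+\\s*\\{\\s*$")
    open <- sum(lengths(regmatches(ln, gregexpr("\\{", ln))))
    close <- sum(lengths(regmatches(ln, gregexpr("\\}", ln))))
    expect_equal(open, close)
    body <- ln[-c(1L, length(ln))]
    edge_lines <- grep(" -- ", body, value = TRUE)
    for (el in edge_lines)
        expect_match(el, "^\\s*\"[^\"]+\" -- \"[^\"]+\"( \\[.*\\])?;\\s*$")
    invisible(TRUE)
}

# build species file-list entries for a generateFixture() output directory
fixture_species_config <- function(dir, species) {
    lapply(species, function(s) list(
        id = s,
        accessions = file.path(dir, paste0(s, "_accessions.txt")),
        fasta = file.path(dir, paste0(s, ".fasta")),
        edges = file.path(dir, paste0(s, "_edges.tsv"))))
}

# map IPN edges back to ancestral pair keys via the truth ortholog table
ipn_edges_as_ancestral <- function(ipn, truth) {
    m <- opsMembers(ipn)
    sp1 <- analysisSpecies(ipn)[1L]
    acc2anc <- structure(truth$orthologs$ancestral_id,
                         names = truth$orthologs[[sp1]])
    e <- edges(ipn)
    if (!nrow(e)) return(character(0))
    memb <- structure(m[[sp1]], names = m$ops_id)
    a <- acc2anc[memb[e$ops_i]]
    b <- acc2anc[memb[e$ops_j]]
    sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

truth_edge_keys <- function(truth) {
    ce <- truth$conservedEdges
    if (!nrow(ce)) return(character(0))
    sort(paste(pmin(ce$ancestral_a, ce$ancestral_b),
               pmax(ce$ancestral_a, ce$ancestral_b), sep = "|"))
}
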