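---
title: "Reconstructing conserved interolog protein networks"
author: "interolog package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing conserved interolog protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interolog)
```

## The problem and the model

Experimentally and computationally derived protein--protein interaction
networks (PPINs) carry substantial false-positive and false-negative rates,
and different sources disagree enough that there is no standard reference
network to benchmark against. An evolutionary argument offers a way out: an
interaction observed between *orthologous* protein pairs in several species
(an **interolog**) is far more likely to be real, because it has been
independently observed in independently evolving systems. The network of
such conserved interactions — the **interolog protein network (IPN)** — is
a small but high-confidence core that can serve as a gold standard for
clustering, centrality and function-prediction studies.

This package reconstructs the IPN shared by two to four species in five
stages:

1. **Sequences.** Each species contributes a list of protein accessions and
   an amino-acid FASTA file. Accessions absent from the FASTA are dropped
   with a warning (an error under `strict = TRUE`): sequence databases are
   never perfectly in sync with interaction databases, and a run should
   degrade gracefully rather than die on the first stale accession.
2. **Orthology.** Every cross-species protein pair is globally aligned
   (Needleman--Wunsch with affine gaps, below) and a percent similarity is
   computed. Orthologs are called as **reciprocal best hits (RBH)**: p and
   q are orthologs when q is p's highest-similarity match, p is q's, and
   their similarity reaches the cutoff (inclusive). RBH is strict
   one-to-one orthology — no paralog expansion, no many-to-many groups.
3. **Nodes.** An IPN node is an **orthologous protein set (OPS)**: exactly
   one protein per analysis species, with *every* pairwise relation an RBH
   — a one-per-species k-clique of the k-partite RBH graph. We
   deliberately require the full clique over all k species rather than a
   connected-component or star relaxation: the IPN is meant as a conserved
   gold standard, and the strict reading keeps node semantics unambiguous.
   Because RBH gives each protein at most one partner per other species,
   OPS are automatically disjoint.
4. **Networks.** Each species' PPIN is read from a STRING-style weighted
   edge list (`id1 id2 combined_score`, score an integer in 0--1000),
   optionally translated through a network-ID-to-accession mapping table,
   filtered at a minimum combined score, and restricted to OPS member
   proteins.
5. **Edges.** For each OPS pair (i, j), count the species in which member
   proteins interact: the edge's **coverage**. An IPN edge is drawn when
   coverage reaches the **coverage cutoff**. At cutoff k only fully
   conserved interactions survive; lower cutoffs trade conservation
   stringency for network size.

## Alignment details

Global alignment uses the Gotoh three-state recurrence with affine gap
penalties: a gap run of length L costs `gapOpen + (L-1) * gapExtend`
(defaults -10 and -1, BLOSUM62). Terminal gaps are penalized — this is
true global alignment, which is the right choice when comparing putative
full-length orthologs rather than locating domains. The recurrences are
implemented in C++; scores are exact maxima over all global alignments.

Two conventions deserve explicit statement because "percent similarity" is
not standardized:

* **identity mode** (default): 100 × (identical aligned columns) /
  (alignment length, gaps included in the denominator);
* **similarity mode**: the same denominator, counting columns whose
  substitution score is positive.

Identity over the full gapped length is the most conservative and most
reproducible convention, which is why it is the default; both are exposed
via `mode =`.

Traceback ties are resolved deterministically — diagonal over up (gap in
the second sequence) over left — applied from the start of the alignment,
so aligned strings are bit-for-bit reproducible. The optimal *score* is
tie-invariant; only the reported alignment strings depend on this rule.
`seqSimilarity()` additionally canonicalizes the argument order so that
the percentage is exactly symmetric even in tie cases.

Residues are scored by the substitution matrix's own rows: the ambiguity
codes X/B/Z are scorable under the shipped BLOSUM/PAM matrices, while a
residue the matrix lacks (e.g. selenocysteine U under BLOSUM62) is a hard
error naming the character — silently mis-scoring it could corrupt the
orthology calls. Custom matrices in NCBI text format can be supplied in
place of a matrix name.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `matrix` | BLOSUM62 | substitution matrix (name or NCBI-format file) |
| `gapOpen`, `gapExtend` | -10, -1 | affine gap penalties, matrix units |
| `similarityCutoff` | 30 (%) | minimum percent identity/similarity for an RBH pair (inclusive) |
| `similarityMode` | identity | which percentage the cutoff applies to |
| `scoreCutoff` | 400 | minimum STRING combined score (medium confidence) |
| `coverageCutoff` | k | species that must support an IPN edge (inclusive) |

All cutoffs are inclusive (≥): that matches what users expect from a
"cutoff", and for the coverage cutoff specifically, an exclusive reading
would make the maximum-conservation setting (cutoff k) unsatisfiable even
for interactions present in every species. 30% identity is the customary
twilight-zone boundary for safe homology inference; 400 is STRING's
conventional medium-confidence threshold. Both defaults are package
choices and should be tuned to the species set at hand.

## Monotonicity and size bounds

Raising any of the three cutoffs can only shrink the result: the RBH set
is anti-monotone in the similarity cutoff, the per-species edge sets in
the score cutoff, and the IPN edge set in the coverage cutoff. The test
suite asserts all three on randomized instances.

At full coverage (cutoff = k) every IPN edge corresponds to a distinct
edge in *every* species' restricted network, so the IPN can never have
more edges than the sparsest restricted input PPIN; `buildIPN()` asserts
this bound on every full-coverage run. Below full coverage the IPN is a
union of partially-supported edges across species and no such bound holds
in general (two species each contributing one private edge at cutoff 1
already exceed the sparser network), so the bound is asserted only where
it is a theorem.

## The synthetic benchmark generator

`generateFixture()` produces a complete, deterministic test bed with known
truth: an ancestral proteome (i.i.d. uniform sequences, lengths 60--120
residues — short enough to keep all-vs-all alignment fast, long enough
that unrelated sequences cannot reach high identity by chance) evolves
into k species by independent per-site substitution at `subRate`; each
species keeps each ancestral interaction with probability `retentionP`,
gains `spuriousEdgesPerSpecies` private edges, and receives
`decoysPerSpecies` unrelated, length-matched proteins. Decoys are
length-matched deliberately so that similarity cutoffs, not length
artifacts, drive their rejection. Edge scores are drawn uniformly from
[`scoreFloor`, 1000] with `scoreFloor` = 700, above the default confidence
cutoff, so score filtering and coverage filtering can be studied
independently. Ancestral interaction density defaults to
`ancestralEdgeP = 0.3`, giving a 20-protein ancestor a realistic ~60-edge
network. The conserved-edge truth is read off the *emitted* networks (a
spurious edge that happens to land on an ancestral pair in every species
counts as conserved), so truth and files can never disagree.

The substitution model is uniform random replacement without indels,
duplications or rate heterogeneity. That is enough to separate orthologs
from decoys and keeps the ground truth exact, but it means passing
recovery tests demonstrate correctness of the *pipeline logic*, not
robustness to realistic evolutionary complications (domain shuffling,
lineage-specific duplications, alignment ambiguity at high divergence).
At the benchmark settings (5% per-site divergence, orthologs at ~90%
identity, decoys near 0--10%), exact recovery of all planted ortholog
groups and conserved edges is the expected outcome and is what the
acceptance checks require.

## Numerical and design choices

* Duplicate edges in an input list (STRING exports often list both
  orientations) collapse to the **maximum** score; self-loops are dropped.
* Scores outside the integer 0--1000 convention are an error, not
  rescaled: a file of probabilities in [0, 1] almost certainly means the
  wrong export was supplied.
* `ops_id`s are assigned after sorting cliques on the first species'
  accession; all output tables are written in sorted order, and the run
  manifest contains no timestamps — two runs of one config are
  byte-identical.
* Test problem sizes: oracle comparisons use proteomes of ≤ 8 proteins
  per species and sequence lengths ≤ 30 where exhaustive enumeration is
  the oracle; the end-to-end benchmark uses 20 ancestral proteins across
  4 species (25 proteins/species). The brute-force alignment-enumeration
  oracle explores every global alignment, whose count grows as the
  Delannoy numbers (~2.7e9 at 12×12), so enumeration-checked pairs are
  sampled with a bounded path count while a polynomial dynamic-programming
  oracle covers the full length range.

## Limitations

* Strict RBH misses many-to-many orthology; recently duplicated genes can
  displace the true ortholog as best hit.
* An OPS must span every analysis species, so proteins lost in one lineage
  remove otherwise-conserved nodes; this is by design (conservation is
  intersective) but makes node counts fall as species are added.
* Interaction evidence is treated as binary above the score cutoff; the
  per-species confidence scores are not aggregated into an edge weight.
* No live sequence/interaction retrieval: inputs are local files, which
  keeps runs reproducible and offline.

## A minimal run

```{r example, eval = FALSE}
spec <- fixtureSpec(nAncestral = 8, k = 3, subRate = 0.05,
                    decoysPerSpecies = 3, spuriousEdgesPerSpecies = 5,
                    seed = 33)
dir <- tempfile()
truth <- generateFixture(spec, dir)
cfg <- runConfig(
    species = lapply(truth$species, function(s) list(
        id = s,
        accessions = file.path(dir, paste0(s, "_accessions.txt")),
        fasta = file.path(dir, paste0(s, ".fasta")),
        edges = file.path(dir, paste0(s, "_edges.tsv")))),
    outDir = file.path(dir, "out"))
ipn <- runPipeline(cfg)
ipn
head(edges(ipn))
```
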