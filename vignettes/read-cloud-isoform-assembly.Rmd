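---
title: "Assembling full-length isoforms from barcoded read clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling full-length isoforms from barcoded read clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Barcoded bulk RNA sequencing (SPIso-seq, Loop-Seq, Tell-Seq and similar
linked-read protocols) attaches a barcode to every read pair derived from the
same mRNA molecule. The set of reads sharing a barcode — a *read cloud* —
therefore samples one molecule (occasionally a few, almost always from
distinct genes), but often at very low coverage, down to about 1x. A cloud on
its own is usually too sparse to assemble, yet the pooled data is deep.
`isocloud` exploits both facts: all reads are co-assembled into **one**
global compacted de Bruijn graph, and each cloud is then reduced to a small
subgraph of that graph, within which its transcript is reconstructed as a
path. The key assumption is that two different isoforms of one gene
essentially never share a barcode, so whatever one cloud covers is a single
splicing structure.

```{r, eval = FALSE}
library(isocloud)
gene <- make_gene("demo", n_exons = 8, n_isoforms = 4, seed = 1)
sim  <- simulate_clouds(gene, n_barcodes = 12,
                        cloud_size_model = list(model = "passes", passes = 2),
                        error_rate = 0, seed = 2)
res  <- assemble_clouds(sim$clouds, k = 21)
filter_clusters(res$store, min_length = 300)
```

## The pipeline, pass by pass

**Global graph.** `build_graph()` builds the de Bruijn graph over all reads
(vertices are (k-1)-mers, edges maximal unbranched sequences; coverage is the
mean multiplicity of an edge's k-mers). The graph is double-stranded: every
edge has a reverse-complement twin and the twin map is an involution. The
default k is 55 for production-scale reads, while the package's own
experiments use k = 21, which suits 100 bp reads over gene-sized loci.

**Global pruning.** `prune_low_coverage()` removes only obvious
sequencing-error structures, because an edge that is noise for one barcode
can carry another barcode's isoform. Three removal rules, iterated with
re-compaction to a fixpoint:

* *tips* — dead-ended edges shorter than `2k` with coverage below the
  absolute cutoff (default 2.0);
* *bulges* — paths of sub-`bulge_cutoff` edges parallel to a similar-length
  alternative path carrying at least five times their coverage (`bulge_frac
  = 0.2`). Both sides may span several edges: at realistic depth,
  overlapping error bubbles interrupt each other, so single-edge parallelism
  is the exception rather than the rule;
* *dominated edges* — edges holding less than 5% (sub-cutoff edges) or 2%
  (short edges at any coverage) of the maximal depth in their immediate
  neighborhood. The rationale is empirical and mechanistic: an error path
  sits next to its own much deeper true alternative, so its share of the
  neighborhood's depth is tiny, while a genuine junction private to one
  isoform among n expressed isoforms still holds roughly a 1/n share —
  above 6% even for a 16-isoform gene. A relative rule is also the only one
  that survives depth changes: recurrent errors (the same miscalled base in
  two or more reads) outgrow any fixed absolute cutoff once per-base depth
  reaches a few hundred.

No edge at or above the absolute cutoff is removed by the cutoff-gated
rules, and `cutoff = 0` disables pruning entirely.

**Per-cloud subgraph.** Reads of one cloud are aligned back to the graph by
exact k-mer seeding and substitution-only extension that walks across edges
(`align_read()`); the aligner prefers the longest aligned span and breaks
ties by mismatches, and a read aligning equally well to several loci
contributes to all of them. The *cloud subgraph* (`derive_subgraph()`) is the
set of edges touched by at least one alignment, with barcode-specific
coverage (aligned bases / edge length) and the leftmost/rightmost alignment
position per edge — those extremes later become the transcript's endpoints.
The global graph is never modified.

**Subgraph correction.** Three passes, in order, iterated to a fixpoint
(`simplify_subgraph()`), all operating on *sequences of edges* because a tip
of the subgraph can be a chain of global edges:

* `clip_tips()` removes chains hanging off a branching vertex when they are
  short (`max_tip_len = 100` bp) or carry less than half the coverage of the
  through-going chain (`rel_cov = 0.5`);
* `remove_bulges()` removes, of two parallel chains of similar length
  (within `max(50 bp, 10%)`), the one with lower barcode-specific coverage,
  with a deterministic tie-break;
* `close_gaps()` re-inserts short global edges that merge two simple paths
  into one. The pipeline bounds insertable edges by the estimated fragment
  length (insert mean + 3 SD) rather than a fixed constant: a coverage hole
  in a cloud is a missing sequencing fragment, so the edges that need
  re-inserting are up to about one fragment long. Walks may use up to six
  edges — splice hubs in high-isoform genes chain several connector edges of
  length close to k, so an edge-count cap of two or three would reject
  exactly the gaps the pass exists for; the per-edge length bound and a BFS
  frontier cap bound the cost instead.

**Path extraction.** `extract_paths()` seeds one path per maximal simple
chain, longest first, and extends across branch vertices using read-pair
linkage: a candidate wins if at least `min_support = 2` pairs bridge the
junction and it leads the runner-up at least twofold (`support_ratio = 2`);
otherwise extension stops — fragmentation is preferred over chimerism. Pairs
whose two mates sit on one edge carry no junction information and are
ignored; a single alignment spanning from the path tail into the candidate
counts as support. Paths are edge-disjoint except where pair links demand a
short-repeat revisit (at most twice per edge). Endpoint offsets come from
the extreme alignment positions of the terminal edges.

**Clustering and abundance.** `insert_path()` groups paths across barcodes
by their exact edge chain; within a chain, a new path joins the first
cluster whose leftmost and rightmost endpoints both differ by strictly less
than 30 bp, else founds a new cluster. Reading the endpoint rule as
*both endpoints, each under the window* is the stricter and symmetric of the
two possible readings, and it is what separates isoforms that differ only in
their first or last exons. Orientation is canonicalised at the chain level
(the lexicographically smaller of the chain and its reverse-complement twin
chain), so the choice cannot depend on endpoint offsets. The representative
sequence is the founding path's — no consensus is computed, since the graph
already denoised the sequence. A cluster's abundance is its number of
distinct barcodes. `filter_clusters()` keeps clusters strictly longer than
300 bp with at least a minimum number of barcodes.

## The simulator

`make_gene()` draws a random exon/intron layout and distinct exon chains
that always contain the first and last exon — exon-skipping isoforms, the
dominant form of splicing complexity. Defaults (exons 120-240 bp, 200-600 bp
introns, transcripts at least 350 bp) give human-like gene-scale loci that
still assemble in seconds at k = 21.

`simulate_clouds()` models the library as follows. Each barcode captures one
molecule (optionally a few, from distinct genes; isoforms are drawn
uniformly, by weights, or round-robin with `balance_isoforms`). The default
fragmentation is a *partition*: random cut points tile the whole molecule,
as fragmentation of a physical molecule does, so molecule ends are
sequencable and a cloud that samples only part of the tiling has
fragment-sized interior holes — precisely the coverage-gap structure the
gap-closing pass addresses. (A `"uniform"` mode with independent fragment
positions is available for comparison.) Cloud sizes follow a configurable
model; the default negative binomial with mean 8 pairs and dispersion 2
yields many 1-3-pair clouds, i.e. per-molecule coverage around and below 1x.
Sizes are clamped to at least one pair, since a barcode with no reads is not
a read cloud. Errors are uniform substitutions; quality scores are constant.
One caution from this package's own development: fragment-length spread
matters. With a nearly constant fragment size the cut points of every tiling
pass fall on the same lattice, and sequence windows near lattice points are
never spanned by any read, silently deleting k-mers from the graph. Real
libraries have broad fragment distributions; simulations here use a
coefficient of variation of roughly 0.1-0.25.

What the simulator does **not** model: PCR duplicates, barcode errors or
collisions, position-dependent error profiles, 3' coverage bias, intron
retention and alternative donor/acceptor sites, and expression-level
differences between isoforms of one gene. Passing tests on this generator
therefore demonstrates the graph algorithms and the barcode logic, not
robustness to every artifact of real libraries.

## Evaluation

`assign_contig()` is a deliberately small stand-in for annotation-based
isoform assignment: the contig (either strand) is matched to reference
transcripts (exact containment first, then free-end-gap alignment accepted
up to 2% edit distance), its splice-junction chain is read off the gene
model, and the category follows from the chain and the endpoints — `unique`
(chain and endpoints within 30 bp match exactly one isoform), `unique_minor`
(endpoint slack up to 100 bp), `ambiguous` (chain is a contiguous subchain
of two or more isoforms), `inconsistent` (overlaps a gene but cannot be
certified), `non_informative` (span under 300 bp, or junction-free in a
multi-isoform gene), `intergenic` (no acceptable alignment).

`score_assembly()` reports precision (correct fraction of unique/minor
assignments), recall (fraction of truth barcodes whose isoform was correctly
recovered; the denominator is all truth barcodes by default, with a
min-reads mode available because published per-gene tables also report the
at-least-5-reads subset), and *fixed recall*: `fixed_filter()` first removes
the contigs of barcodes that received more than one assignment (barcode
mode) or whose (barcode, gene) pair recurs (gene mode) — such clouds were
either split by coverage gaps or contained two molecules — and the filtered
barcodes leave both numerator and denominator. Removing them from the
denominator is the only reading under which fixing can raise recall, which
is exactly the behavior the filter exists to produce.

## Problem sizes and what the package's own checks compute

The bundled experiments (also run by `scripts/acceptance.R`) use sizes that
complete on one CPU in a few minutes:

* `perfect_recovery_experiment()`: 50 random genes with 4-16 isoforms,
  three noiseless clouds per isoform, each molecule tiled three times
  (about 4x per molecule). Expected outcome: every barcode yields exactly
  one contig identical to its truth transcript.
* `robustness_experiment()`: one 12-exon, 16-isoform gene, 1000 clouds,
  negative-binomial cloud sizes with mean 8 pairs, 0.5% substitution
  errors. About a quarter of the clouds cover less than half of their
  molecule and are unrecoverable in principle, so recall lands around
  0.6 while precision stays near 1 and fixed recall is at or above recall —
  the qualitative signature of barcode-based assembly at about 1x.

## Numerical and degenerate-input notes

* Ties are broken deterministically everywhere (lexicographic edge ids or
  canonical chain keys), so identical inputs give identical outputs; the
  cluster partition does depend on insertion order, which is fixed by the
  pipeline.
* Reads shorter than k are skipped with a warning; k-mers containing N are
  skipped; an input whose every read is shorter than k is an error.
* Empty clouds produce empty subgraphs and are skipped and reported, not
  errors; an empty read set produces an empty graph.
* Spelling a zero-length path (equal offsets on one edge) is an error.
* Cycles in the graph are compacted starting from their smallest k-mer;
  twin pairing for cycle edges is resolved up to rotation.

## Known limitations

* Rare isoforms: the relative domination rule protects junctions holding at
  least a few percent of their neighborhood's depth; an isoform far below
  that share in a deeply covered gene can lose its private junctions to
  pruning.
* Two isoforms of one gene in a single cloud are resolved as one or two
  paths only insofar as pair links separate them; the design assumption is
  that this event is rare.
* Gap closing chooses the shortest bridging walk without consulting pair
  links, so a hole spanning an alternative-splicing region can occasionally
  be bridged through the wrong variant; downstream this surfaces as an
  inconsistent or wrongly-assigned contig and is the main precision cost at
  low coverage.
* The aligner is substitution-only by design (the graph is built from the
  same reads); indel-heavy data would need a different extension model.
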