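---
title: "Methods: how prophinder detects prophages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how prophinder detects prophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the detection model, its
parameters, the design decisions that were genuinely open, and what the
synthetic test bed does and does not demonstrate.

## The detection model

A prophage is an integrated phage genome: a contiguous stretch of the
bacterial chromosome, typically tens of kilobases, populated by genes whose
proteins are homologous to viral proteins and whose annotations carry phage
vocabulary (integrase, terminase, capsid, tail, holin, ...). `prophinder`
exploits both signals with two detectors whose minimal clusters are merged:

* **Density arm.** Phage-like genes — those with a homology hit to a viral
  protein database at e-value strictly below `evalue_max` — are chained
  along each contig whenever the inter-gene gap
  `max(0, start[i+1] − end[i])` is at most `protein_density_bp`; chains
  with at least `min_protein_num` members are minimal clusters. This is a
  deliberate reduction of DBSCAN: in one dimension with a gap metric,
  density-reachability chaining and single-linkage connected components
  coincide, so the reduction is implemented directly and the equivalence is
  *tested* (the suite compares it against an independent graph-components
  oracle on a thousand random layouts) rather than assumed. A classic
  DBSCAN on gene start coordinates (eps = `protein_density_bp`, minPts =
  `min_protein_num`) is available as `dbscan_mode = "strict"` for
  comparison; the two differ only through border-point semantics and the
  fact that start-coordinate distances ignore gene lengths, which is why
  chain mode — whose threshold is a property of the intergenic spacing, not
  of gene length — is the default.
* **Window arm.** A window of `window_size` consecutive annotated genes
  slides with step 1 over each contig. Windows with at least
  `min_keyword_hits` keyword-positive CDS products emit the minimal
  sub-region from their first to their last keyword-positive gene. Step 1
  is the only step that cannot skip over a qualifying stretch, which is why
  it is not configurable. Both CDS and tRNA features count toward the
  window size (the window measures annotated-gene context), but only CDS
  products are keyword-eligible — tRNA products carry no phage vocabulary.

Merging is transitive over envelope intersection, where intersection means
at least one shared base: half-open intervals that merely touch
(`end == start`) do **not** merge, because zero shared bases is not an
intersection.

## Coordinates and ordering

Internally every interval is 0-based half-open, which makes lengths and
gaps plain subtractions; every user-facing writer (summary TSV, GFF3,
FASTA headers) converts to 1-based inclusive, the convention of GenBank
and GFF3. Genes on a contig are ordered by start, ties by end, then `+`
before `-`; the ordinal index this induces is what window and flank logic
operate on. Compound (`join(...)`) GenBank locations are collapsed to
their outer envelope, and features spanning a circular origin are skipped
with a warning — the clustering and window logic operates on simple
intervals, and an origin-spanning feature has no single envelope.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `evalue_max` | 1e-7 | — | strict ceiling for phage-like calls |
| `min_protein_num` | 6 | genes | minimal cluster size, density arm |
| `protein_density_bp` | 3000 | bp | maximal neighbour gap, density arm |
| `window_size` | 60 | genes | sliding-window width |
| `min_keyword_hits` | 6 | genes | keyword threshold per window |
| `flank_genes` | 10 | genes | flank width around the integrase anchor |
| `att_min_len` | 12 | bp | minimal att repeat length |

The clustering defaults (6 proteins, 3,000 bp) are the calibrated values
for prophage detection in bacterial genomes; `tune_parameters()` re-derives
them for a user's own curated regions over the standard grid of sizes
6–10 (step 1) × densities 3,000–10,000 bp (step 1,000), i.e. 40 cells.
The e-value ceiling is *strict* (`< 1e-7`): a hit at exactly 1e-7 does not
qualify, and the boundary is pinned by tests on both sides.

The keyword list ships as a plain-text config file
(`inst/extdata/phage_keywords.txt`, one phrase per line, `-` prefix for
excludes), not as code. Only two keywords are canonical in the literature
("protease", "integrase"); the shipped list extends them with common phage
structural, lysis and integration vocabulary, and `crispr` is excluded
because CRISPR-associated proteases are host defence, not prophage,
machinery. Matching is case-insensitive substring matching on the product
field only.

## Per-gene best hits and taxonomy

When a gene has several qualifying hits, exactly one votes: minimum
e-value, ties by maximum bit score, then lexicographic subject id. The
order is total, so calls are invariant to hit-table row order — a property
the suite checks by permutation. Taxonomy labels are extracted from the
subject title (UniProt `OS=...` convention, falling back to a terminal
NCBI-style `[organism]` bracket, then `"unknown"`); a region's taxonomy is
the modal label over its phage-like genes, excluding `"unknown"`, ties
resolved to the lexicographically smallest label and flagged. One best hit
per gene casts one vote; letting every qualifying hit vote would weight
genes by database redundancy rather than by biology.

## att sites

Integrases determine integration-site specificity, so att search is
anchored on them: for every gene in a region whose product mentions
"integrase", the spans of the 10 genes upstream and downstream of *the
anchor itself* are extracted and aligned. Anchoring at the integrase
rather than at the region boundary is the configured default because the
integrase typically sits adjacent to one att site; the alternative reading
(flanks around the region) would be a one-line change in `detect_att()`
callers. Only forward-orientation (direct) repeats are eligible —
integrase-mediated recombination between attP and attB produces direct
repeats — while reverse-complement matches can be surfaced by the aligner
(`revcomp = TRUE`) for diagnostics but are never selected.

The default aligner is a built-in exact maximal-repeat finder
(seed-and-extend over a 12-mer index, score = 2 × length, mimicking the
match reward of short-query nucleotide alignment); it is compared
match-for-match against a longest-common-substring dynamic program in the
tests. An adapter to `blastn -task blastn-short -evalue 1000` is shipped
and exercised in one test; it can recover degenerate (mismatch-containing)
repeats the exact finder cannot, at the cost of an external dependency.
The best pair is the highest score, ties by longer match, then leftmost
attL, then leftmost attR — again a total order for reproducibility. Found
att pairs extend the reported region to `[attL_start, attR_end)`; if an
extension creates an overlap between regions, a second merge pass restores
disjointness (the pipeline asserts final disjointness).

## Degenerate inputs and edge semantics

* Contigs with zero genes are retained with a warning; contigs without
  sequence skip att detection with a warning rather than failing.
* Hit-table rows with unparseable numerics are skipped and counted; more
  than 50% skipped rows is treated as a wrong-dialect error.
* Pseudogenes (CDS without translation) keep their place in the gene map —
  they count toward window size — but can never be phage-like (no protein
  to hit).
* A run with no hit table at all warns and runs the window arm only. The
  command-line `detect` front end still *requires* `--hits`, because a
  silent single-arm run is rarely what a pipeline user intends; the
  library permits it explicitly for arm-independence analyses.
* Zero detected regions is a valid outcome: writers emit headers only and
  the run exits cleanly.

One algebraic subtlety found by property testing deserves a note: the
cluster *count* is not monotone in `protein_density_bp`. Widening the gap
threshold only ever merges runs, but two sub-threshold runs can merge into
one run that now passes `min_protein_num`, so the count of reported
clusters can increase. Total membership, by contrast, is monotone, and the
component count is monotone when `min_protein_num = 1`; those are the
properties the suite asserts.

## The synthetic test bed

`generate_genome()` emulates exactly the features the detector keys on: an
ordered gene map with product strings, a dense cassette (12 genes, 100 bp
spacing) of which 70% carry keyword products, one mid-cassette integrase,
matching hits at log-uniform e-values in [1e-50, 1e-10] carrying
`OS=<taxon>` titles, 5% background decoy hits at e-values ≥ 1e-5, and an
identical pair of 15 bp repeats planted in the intergenic gaps flanking
the cassette, inside the integrase's 10-gene flanks. Background genes have
intergenic gaps uniform in 200–800 bp. Everything derives from one integer
seed; regeneration is byte-identical.

Two layout rules are part of the emulated study conditions. Cassettes are
separated by more than 3,000 bp so default clustering can never chain
them; and by at least 61 background genes — more than one window — because
two cassettes closer than a window legitimately *should* be bridged by the
window arm (a single 60-gene window then contains ≥ 6 keyword genes from
the pair), and real prophages in multi-megabase genomes are typically
hundreds of genes apart. The integrase sits mid-cassette so both planted
repeats fall inside its flanks, which bounds cassettes at 19 genes.

What the generator does **not** emulate: realistic nucleotide composition
(background is i.i.d. uniform), codon structure, degenerate or partial att
repeats, fragmented assemblies that split a prophage across contigs,
overlapping or nested prophages, and hit-table noise beyond clean decoys.
Passing the end-to-end recovery tests therefore demonstrates that the
machinery implements its contracts exactly — not that the default
parameters achieve any particular recall on real genomes, which depends on
annotation quality and database coverage. Two further caveats follow: on
i.i.d. uniform flanks of ~11 kb, a chance exact repeat longer than a
planted 15-mer occurs in a few percent of instances, so end-to-end tests
assert that *an* att pair of qualifying length is found, and exact
planted-repeat identity is asserted on short constructed flanks; and the
region-level matching criterion (reciprocal overlap ≥ 50%) is itself a
convention, chosen because no standard definition of "correctly predicted
prophage" exists.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
20 end-to-end genomes of 112–186 genes (1–3 implants each), 1,000 random
clustering instances (3–20 genes), 500 window-scan instances (10–200
genes), 200 flank pairs of 100–200 bp with plants of 10–40 bp, and 500
random cluster sets for the merge algebra. These sizes were chosen so each
oracle comparison is exhaustive at small n — where brute force is
feasible and trustworthy — while the end-to-end genomes are large enough
that both arms, att search and taxonomy voting all engage.

## Similarity annotation

Region-vs-phage annotation scores each candidate phage with three
features: the fraction of region proteins with a qualifying protein hit
(e-value < 1e-7), the fraction of region bases covered by the union of
qualifying nucleotide alignments (e-value < 1e-3), and the mean identity
of per-protein best hits. These operational definitions are this package's
own interpretation of similarity-feature annotation; they are proportions,
invariant to duplicated hit rows, and ranked lexicographically with ties
on phage id. No phage database ships with the package — any multi-FASTA
of candidate phages plus externally computed hit tables works.

## Known limitations

* Exact-repeat att search cannot find degenerate repeats; use the blastn
  backend where sensitivity matters.
* Prophages split across contig boundaries are reported per contig; no
  stitching is attempted.
* Keyword matching is substring-based; products in languages other than
  standard English annotation vocabulary, or unusual abbreviations, are
  missed unless added to the keywords file.
* Taxonomy is only as good as the subject titles in the hit table;
  `"unknown"`-dominated regions are reported as `"unassigned"`.
* The package does not score prophage activity (intact vs cryptic).
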