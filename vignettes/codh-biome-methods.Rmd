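---
title: "Methods: biome distribution analysis of Ni-CODH protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biome distribution analysis of Ni-CODH protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, the algorithmic contracts, the synthetic
data generator and the numerical choices behind `codhbiome`. Everything here
describes what the package computes; no empirical claims are made beyond what
the package itself can recompute.

## 1. Model and analysis chain

The object of study is a protein family — nickel-containing carbon monoxide
dehydrogenase (Ni-CODH) — whose members fall into phylogenetic clades with
distinct accessory-gene repertoires and distinct biome distributions. The
analysis chain is:

sequences → motif QC → tiered greedy clustering → clade assignment on a
reference tree → biome/taxonomy/neighbourhood annotation → co-occurrence and
diversity statistics.

### 1.1 Motif QC

A *motif profile* records, on a reference sequence, the positions of the
D-cluster, the four B-cluster cysteines, catalytic-site residues and a
C-terminal block whose last three cysteines belong to the C-cluster
(1-based coordinates). A candidate is aligned globally to the reference
(BLOSUM62, gap open 11, gap extension 1) and fails if any profile position is
deleted, or if any of the seven essential cysteines is substituted (the
ambiguity code `X` counts as a substitution; substitutions at non-cysteine
profile positions are tolerated). `qc_tiers()` combines the motif verdict
with length rules into three exhaustive buckets:

* **representative** — ≥ 400 aa and motif PASS (tiers `REFSEQ_REP`,
  `MGNIFY_REP`);
* **salvage** — MGnify-only sequences of 100–399 aa or motif failures
  ≥ 100 aa (`MGNIFY_SALVAGE`); salvage sequences may join clusters but never
  found them;
* **rejected** — everything shorter than 100 aa, and RefSeq sequences that
  fail the representative rules.

### 1.2 Clustering

`cluster_greedy()` implements a UCLUST-style single-pass scan at a fixed
identity threshold (default 0.90). Input must be sorted by
`sort_for_clustering()`: tier (`REFSEQ_REP` < `MGNIFY_REP` <
`MGNIFY_SALVAGE`), then descending length, then lexicographic id — making
the scan fully deterministic. Each sequence is compared against existing
centroids *in centroid-creation order* and joins the **first** centroid
reaching the threshold; otherwise it founds a new cluster (representatives)
or is set aside (salvage). Identity uses ends-free (semi-global) alignment —
terminal gaps are free, so fragments can match their full-length centroid —
and is defined as identical columns over alignment columns of the trimmed
overlap, with `X` never matching.

### 1.3 Clade assignment

`assign_clades()` reads an unrooted tree with support values and a reference
table mapping ≥ 2 leaves per clade. Every internal edge induces a
bipartition; for a query leaf the candidate sides are scanned from smallest
to largest, keeping only sides whose support passes the gate (default 0.95;
supports > 1 are auto-scaled from percentages). The query takes the clade of
the first side in which all references agree; conflicted sides are skipped
(allowing paraphyletic reference placement), and a query with no unanimous
side is `UNASSIGNED`. Because bipartitions are properties of the unrooted
topology, the result is invariant under re-rooting; the two root-child sides
of a rooted binary tree describe the same edge and are deduplicated, merging
their supports by maximum. Queries whose supporting references all carry the
mini-CooS flag inherit it.

### 1.4 Annotation

Biome lineages (colon-delimited, e.g.
`root:Host-associated:Human:Digestive system:Large intestine`) collapse by
longest-prefix match — on token boundaries only — to three major categories
and fifteen subcategories; unmatched lineages become `OTHER`. Subcategories
with fewer than `min_sequences = 2` sequences are suppressed (kept at major
level by default). The rule table ships as
`inst/extdata/biome_mapping.tsv` and can be edited as database spellings
drift. Gene neighbourhoods are windows of ±15 coding sequences by gene order
on the contig; functional flags fire from COG rules, where *any*-rules need
one listed COG in the window and *all*-rules need every listed COG (possibly
on different neighbours). `join_annotations()` aggregates everything to one
row per cluster with list-columns that are always character vectors
(empty sets, never `NULL`).

### 1.5 Statistics

* **Dice coefficient** between biome labels $a,b$ over cluster presence
  sets: $2|A\cap B| / (|A|+|B|)$; two empty sets give 0 with a warning.
* **Shannon diversity** of within-biome phylum counts, natural log, via
  `vegan::diversity`.
* **PCA** of composition profiles: rows are groups, columns are relative
  abundances; `stats::prcomp`, centred but not scaled — columns share the
  unit simplex scale, and scaling would inflate rare labels.
* **Welch's t** via `stats::t.test` (unequal variances).
* **Grubbs' test** (one-sided, maximum): $G = (\max x - \bar x)/s$ with
  $p = n\,P\!\left(T_{n-2} > \sqrt{\tfrac{n(n-2)G^2}{(n-1)^2 - nG^2}}\right)$,
  capped at 1.
* **Density normalisation**: counts per Mbp of assembly.

## 2. Synthetic data generator

The generator plants ground truth at every level so each stage can be
validated exactly. All defaults in `sim_config()` are the study conditions.

### 2.1 Sequence hierarchy

A reference sequence (default 630 aa) carries the motif profile; positions
listed in the profile are frozen. Each clade draws an ancestor at half the
between-clade divergence (default 0.40), each cluster an ancestor at half the
between-cluster divergence (default 0.20), and each member mutates the
cluster ancestor at the within-cluster rate (default 0.05). Mutation applies
an **exact count** of substitutions, `round(rate × free_sites)`, each drawn
from the 19 non-identical residues at non-profile sites. Sampling only
non-identical residues is deliberate: it makes the planted divergence the
realised divergence, so threshold-recovery tests have exact margins instead
of stochastic ones.

### 2.2 Corruptions and metadata

With configurable fractions, members become *fragments* (100–399 aa windows
always covering the B-cluster, so the motif check still sees its positions),
*too-short* records (< 100 aa, rejected) or *motif-broken* (a B-cluster
cysteine → alanine, or a 4-residue D-cluster deletion). Expected verdicts
are recorded alongside.

Roughly 30% of members are labelled RefSeq (genomes with taxonomy and a
31-CDS contig whose focal gene sits mid-contig, with planted rule COGs and
random background COGs); the rest are MGnify samples with biome lineages and
assembly sizes. Lineages are drawn per clade from a three-way bias over the
major biomes: clades B, C and E are host-restricted
(engineered 0.10 / aquatic 0.00 / host 0.90), all other clades environmental
(0.40 / 0.55 / 0.05). These defaults were fixed a priori to encode the
qualitative design — host-restricted clades shared mostly with engineered
systems (which are seeded by host-derived microbes), not open water — and
they generate the expected orderings: the host-vs-aquatic Dice is the
smallest pair and host-associated Shannon phylum diversity the lowest.
Taxonomy assigns one phylum per clade and one genus per planted cluster, so
cluster genus purity has ground truth 1.

`sim_tree()` emits a caterpillar reference phylogeny with two reference
leaves per clade (support 0.99), and `write_sim_dataset()` writes a complete
file set (FASTA, profile JSON, metadata/biome/taxonomy/feature TSVs, truth
JSON) consumable by `run_pipeline()`. Determinism: every generator stage
seeds from `config$seed` plus a fixed offset, so identical configs give
byte-identical datasets.

## 3. Numerical choices

* **Alignment engine**: `Biostrings::pairwiseAlignment` with BLOSUM62, gap
  opening 11, extension 1 (a gap of length $L$ costs $11 + L$); `overlap`
  type for identity computations, `global` for motif mapping. The scores are
  validated in the test suite against an independently written affine-gap
  (Gotoh) recurrence, itself validated against exhaustive enumeration of all
  alignment paths on short pairs.
* **Identity denominator**: alignment columns of the trimmed overlap, not
  the shorter sequence length — fragments are neither penalised for missing
  termini nor rewarded for tiny overlaps at clustering time, because
  salvage-tier fragments cannot found clusters.
* **First-hit greedy rule**: joining the first (not best) acceptable
  centroid follows the UCLUST contract and keeps the scan order-deterministic
  and O(centroids) per query.
* **Support deduplication by maximum** when the same unrooted bipartition
  appears twice in a rooted representation.
* **Exact-count mutation** (above) rather than per-site Bernoulli.
* **1-based profile coordinates** throughout the R interfaces.

## 4. Problem sizes and limitations

The validation suite runs at desk scale: alignment oracles on pairs ≤ 12 aa,
clustering oracles on instances ≤ 50 sequences, planted-recovery runs of
200–256 sequences (8 clades), end-to-end runs in minutes on one CPU. Known
limitations:

* The greedy scan recomputes alignments against all centroids per query
  (no k-mer prefilter); hundreds of sequences are comfortable, hundreds of
  thousands are not.
* Clade assignment requires the provided tree to contain the centroid ids as
  leaves; it classifies relative to reference leaves and does not infer
  trees.
* The biome mapping is a fixed prefix table; lineages outside it collapse to
  `OTHER` rather than erroring.
* The simulator mutates sites independently and uniformly; it does not model
  rate heterogeneity, indels outside the planted corruptions, or homologous
  recombination, because the planted truths it must guarantee are set
  membership, motif state and biome bias — not realistic evolution.
* Statistical helpers are small-n tools mirroring the analysis chain; they
  are not a general hypothesis-testing framework (e.g. no multiple-testing
  correction is applied).
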