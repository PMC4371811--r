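---
title: "Methods: fungal LSU amplicon community analysis with LSUpipe"
author: "LSUpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fungal LSU amplicon community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`LSUpipe` implements a complete amplicon metabarcoding analysis for the
fungal large-subunit (28S) rDNA barcode, of the kind used to ask whether
the fungal community inside a mycoheterotrophic orchid tuber differs
from the community in its surrounding soil. The pipeline takes Illumina
paired-end reads of a primer-delimited LSU fragment (expected
167--218 bp including the 18 nt forward primer `AACACGGACCAAGGAGTC` and
the 20 nt reverse primer `CAGGCATAGTTCACCATCTT`), and proceeds through
five stages:

1. **Read QC** — primer qualification and trimming, quality-aware
   overlap merging, sliding-window quality filtering, orientation.
2. **Reference curation** — keyword selection of LSU records from raw
   (id, sequence, description) triples and attachment of seven-rank
   lineages (domain, phylum, class, order, family, genus, species;
   missing ranks are the distinguished label `unclassified`).
3. **Taxonomy classification** — nearest-neighbor search with
   lineage-consensus resolution, then a split of reads by domain
   (Fungi / Viridiplantae / Metazoa / unclassified).
4. **OTU construction** (fungal reads only, per sample) —
   dereplication, singleton removal, greedy clustering at 97% identity,
   reference-based two-parent chimera filtering, re-assignment of all
   unique reads at the 97% cutoff.
5. **Community comparison** — rarefaction, a neighbor-joining tree over
   the pooled OTU representatives, weighted and unweighted UniFrac,
   principal coordinates analysis, and per-rank composition summaries.

A synthetic-data module generates reference databases and tuber-/
soil-like communities so that every stage can be exercised and
validated without any external download.

# Read QC

A mate is *qualified* when exactly one whole primer (forward or
reverse) matches its plus strand, ungapped, with at most 2
substitutions; a pair is qualified when the two mates carry different
primers. Bases 5&prime; of the primer are trimmed (the primer itself is
kept); if a read runs through to the opposite primer site, bases
3&prime; of that site are trimmed too, and the partner read must show
both sites whenever it is long enough to span the implied amplicon.

Merging reverse-complements mate 2 and scans all overlaps of at least
`minOverlap = 10` bp, keeping the overlap with the most matching bases
subject to a mismatch fraction of at most 0.25 (the conventional
default of overlap-based mergers); ties prefer the longer overlap,
which avoids spuriously long amplicons. Disagreeing overlap bases take
the higher-quality call (mate 1 on a quality tie) and the overlap
quality is the per-base maximum — the merger the pipeline models does
not document its consensus rule, so this package fixes one and states
it. Two consequences used as analytic checks: the maximal merged length
is `len1 + len2 - 10` (190 bp for 100+100 mates, 260 bp for 145+125
mates), and merged reads shorter than 100 bp are discarded.

The quality filter slides a 5 bp window (step 1) along the merged read
and requires every window mean to be at least Phred 30; a read shorter
than the window is one window of its full length, and the exact
boundary (mean = 30) passes. Finally every amplicon is oriented so the
forward primer motif is at its 5&prime; end.

# Reference curation

Raw records are kept when the description contains `large`/`Large` as a
substring, or a delimited `LSU` token, or a delimited `2xS` token with
x in 3..8 (`23S`...`28S`; delimiters are whitespace, `( ) [ ] , / -` or
the string boundary), *and* shows ribosomal-RNA evidence (`rDNA`,
`rRNA`, or `ribosomal` together with `DNA`/`RNA`); records mentioning
`mRNA` or `spacer` are then excluded. The published description-matching
rule this reproduces is garbled in typesetting; the reading above is
fixed, documented, and unit-tested exhaustively. Lineages come from two
plain-text maps (record id &rarr; taxon id &rarr; seven rank labels);
records without a mapping are retained with an all-unclassified lineage
so that selection never silently drops sequences.

# Taxonomy classification

For each query (identical sequences are dereplicated internally) the
classifier reports **all** references tied at the best local-alignment
score. Scoring is fixed — match +1, mismatch &minus;2, gap open
&minus;2, gap extend &minus;1 on a seed-and-extend search (12-mer
candidate pre-screen, default 32 candidates) — because an E-value
ordering is aligner-specific and not reproducible; a fixed score keeps
the same "best set, ties kept" semantics deterministically. A hit is
reported only when it covers at least 50% of the query at 50% identity
or better; queries with no reported hit are unclassified.

The tied lineages are resolved by three rules applied in order:
placeholder lineages (any label containing `uncultured` or `fungal_sp`,
case-insensitive substrings) are demoted to all-unclassified and
dropped when a classified lineage co-occurs; only lineages of maximal
completeness (number of classified ranks) survive; each rank keeps its
label only when the survivors agree unanimously, otherwise it becomes
unclassified. Finally rank consistency is enforced — below the first
unclassified rank, everything is unclassified — so a read tied between
thirteen *Mycena* species and seven other Agaricales resolves to the
order Agaricales with family and below unclassified.

# OTU construction

Within each sample, fungal amplicons are dereplicated exactly
(counts conserved; ordering by count descending with a lexicographic
tie-break so the pipeline is deterministic), singletons are removed as
probable errors, and the remaining uniques are clustered greedily in
abundance order: a sequence joins the first centroid at &ge; 97% global
identity, else founds a new centroid. Identity is matches / alignment
columns of an end-to-end alignment with terminal gaps penalized
(amplicons share primer-delimited boundaries, so end gaps are real
differences), under match +1, mismatch &minus;2, gap &minus;2 per
column. Ties among equal-scoring alignments resolve to the path with
more matches, then more aligned pairs, which fixes the identity value
deterministically.

Chimeric centroids are removed with a reference-based two-parent model:
a centroid is chimeric when some 5&prime; segment of reference A joined
at a single breakpoint to the 3&prime; segment of reference B explains
it at &ge; 99% identity, beats the best single reference by &ge; 2
identity points, and gives each parent &ge; 30% of the centroid.
These three thresholds are this package's own surrogates for the
referenced tool's undocumented score and are labelled as such. Finally
*all* uniques — singletons included — are re-assigned to the surviving
centroids at the 97% cutoff (best centroid; ties to the more abundant
one); the published procedure is ambiguous about whether singletons
re-enter here, so the package re-assigns them and reports both totals
in the per-sample tally.

# Community comparison

OTU representatives of all samples are pooled. Pairwise p-distances
(1 &minus; global identity, gaps counted as differences) feed a
neighbor-joining reconstruction; negative NJ branch lengths are clamped
to zero and the tree is midpoint-rooted. This distance-based tree
replaces a progressive multiple alignment + relaxed NJ: both are
distance methods, the UniFrac oracle tests are tree-agnostic, and the
pairwise route removes a heavyweight dependency. In-silico PCR
(both primer sites, &le; 2 substitutions each, amplicon window
1--300 bp, primers included in the extracted segment) provides
reference segments that can be anchored into the tree when desired.

UniFrac distances are computed in both modes. Unweighted: shared vs
unique branch length over leaves present in either sample. Weighted:
the **normalized** variant,
d(A,B) = &Sigma;<sub>b</sub> l<sub>b</sub>|p<sub>Ab</sub> &minus;
p<sub>Bb</sub>| / &Sigma;<sub>b</sub> l<sub>b</sub>(p<sub>Ab</sub> +
p<sub>Bb</sub>), with p<sub>Xb</sub> the fraction of sample X's reads
under branch b. Normalization keeps both modes on a common [0, 1]
scale and makes the weighted distance invariant to sequencing depth
(the source method leaves its variant unstated; the normalized form is
chosen and documented). Ordination is classical metric PCoA
(double-centered &minus;D&sup2;/2, eigendecomposition); negative
eigenvalues are reported but excluded from the variance denominator.
"Principal component analysis of a distance matrix" is operationally
PCoA, which is what the package provides.

Rarefaction subsamples reads without replacement, 100 times per depth
by default with one documented seed (default 1), reporting mean
&plusmn; sd richness. Composition summaries list the top-15 taxa
(top 5 at phylum level) by mean fraction across samples, lump the rest
into "others", and leave the remainder to 100% as the unclassified
fraction at that level.

# Synthetic data: what it emulates, and what it does not

`generateReferenceDb()` builds references sharing a conserved
primer-binding scaffold — random flank, forward primer site, a
taxon-specific random insert of 129--180 bp, the reverse binding site,
random flank — so primer-included amplicons span exactly 167--218 bp.
It adds "uncultured" placeholder near-duplicates, partial lineages
(unclassified below a random rank), non-fungal (plant, metazoan)
reference taxa, and optional non-LSU decoy records (mRNA, spacer,
small-subunit) that exercise keyword selection.

`communitySpec()`/`generateSample()` emulate the two community styles
of a tuber/soil study. Tuber-like: ~30 fungal taxa, one dominant at
0.90 of the fungal fraction (within the 85--97% dominance such studies
report) plus a large plant fraction (0.35) — and, importantly, the
dominant mycobiont is a property of the study system (the first fungal
reference by default), so replicates generated with different seeds
share it, as tubers of one host population do, while minor taxa vary.
Soil-like: up to 1,000 fungal taxa with per-taxon abundances drawn from
the logarithmic (Fisher log-series) distribution with x = 0.9; this x
was chosen so that a 10&#8308;-read sample expresses most of the 10&sup3;
taxa, mirroring near-saturating soil rarefaction. Reads are drawn
multinomially; a configurable fraction are single-breakpoint chimeras
(each parent &ge; 30%); pair orientation is random; per-cycle quality
decays linearly from Q38 to a tail mean of Q31 — just above the Q30
window threshold so the quality filter is exercised in both regimes —
and substitution errors are placed with per-base probability
proportional to the quality-implied error rate, scaled to a mean of
0.5% per base. Each sample carries a truth table (template, domain,
chimera flag per read).

The generator does **not** model indels, quality correlation along
reads, PCR amplification bias, or phylogenetically structured sequence
similarity between taxa (inserts are random, so distinct taxa are
mutually ~25% identical). Passing tests therefore demonstrate that the
pipeline recovers what the generative model puts in — dominance,
richness contrast, community clustering — not that it is robust to
every artifact of real sequencers.

# Numerical choices and degenerate inputs

* Alignment tie-breaks are fixed as described above; all stochastic
  steps take explicit integer seeds and the same seed reproduces a
  sample byte for byte.
* Dereplication ties (equal counts) order lexicographically.
* Re-assignment identity ties go to the more abundant centroid.
* Fewer than three tree leaves yield a star (or single-leaf) tree with
  zero branch lengths; empty samples are an error for UniFrac;
  rarefaction depths above the read total are clamped with a warning.
* A read shorter than the quality window is one window; the exact
  window mean of 30 passes.
* The two-parent chimera search shortlists 8 parent candidates per
  centroid by shared 12-mers; the greedy clusterer prunes candidate
  centroids with a conservative shared-8-mer bound that can never
  reject a true &ge; 97% match.

# Problem sizes used for validation

The packaged validation runs a complete synthetic study of two
tuber-like replicates and one soil-like sample at 10,000 read pairs
each against an 1,100-taxon reference set — sizes chosen so the whole
study, including the pooled ~650-leaf tree and all-pairs alignments,
completes in a few minutes on one core while still exhibiting the
qualitative structure of interest (dominance recovery within
&plusmn;2 points, a &ge; 5&times; soil/tuber richness ratio, and tuber
replicates mutually closer than any tuber--soil pair under weighted
UniFrac). Oracle checks run 1,000 random UniFrac cases on trees of up
to six leaves against a brute-force branch enumeration, and compare the
greedy clusterer against an exhaustive pairwise-identity oracle built
on an independent aligner.

# Known limitations

* Identity between highly divergent sequences (tree p-distances near
  saturation) depends on the fixed scoring scheme; topologies deep in
  the tree are correspondingly approximate, which UniFrac tolerates
  but a phylogeneticist should not over-interpret.
* The nearest-neighbor candidate pre-screen can, in principle, miss a
  tied best hit that shares no 12-mer with the query; at the &ge; 97%
  identities that matter for classification this does not occur.
* The chimera model only detects two-parent, single-breakpoint
  chimeras against the provided references, by design.
* `fungal_sp` placeholder matching is substring-based, as the exact
  token convention in reference descriptions varies.
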