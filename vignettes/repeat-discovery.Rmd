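---
title: "Ab initio discovery of low-divergence repeat families with carpr"
author: "carpr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ab initio discovery of low-divergence repeat families with carpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transposable elements (TEs) make up large fractions of vertebrate genomes,
but the recently active families — the ones that still shape genome
evolution — are exactly the ones most likely to be missing from curated
reference libraries, especially for newly sequenced, non-model species.
`carpr` discovers them directly from an assembly, without prior knowledge,
by exploiting the one property recent families necessarily have: multiple
near-identical dispersed copies. As a by-product, the same signal exposes
segmental duplications (SDs): long, low-copy, high-identity duplicated
regions that masking-oriented repeat finders typically ignore.

The design follows the CARP family of pipelines (PALS/PILER lineage,
reimplemented as the krishna/igor/seqer tools), whose distinguishing choice
is to keep the full audit trail: every consensus sequence is traceable back
to the genomic intervals of the copies that produced it, so downstream
evolutionary analyses (dating, per-family phylogenies) remain possible.

# The method, stage by stage

## Self-alignment (the `-dpid` / `-dplen` gates)

`selfAlign()` performs an all-vs-all local self-comparison of the assembly:

1. every exact k-mer (default `seed_k = 12`) shared by two positions, on
   either strand, is a seed (k-mers containing N are skipped, and runs of N
   split the alignable space);
2. seeds are grouped by (orientation, diagonal bucket of width
   `band_width`) and split where the along-diagonal gap exceeds `max_gap`;
3. surviving chains are extended by banded affine-gap Smith–Waterman
   (scores +1/−2, gap −4 to open, −1 to extend), with the band following
   the diagonal range the chain's own seeds traced out;
4. an alignment is reported iff its identity is at least `min_identity`
   (default **0.94**) and *both* images are at least `min_length`
   (default **250 bp**) long.

Identity is defined as matches over *all* alignment columns, gap columns
included — the strictest common convention, which keeps the 94% gate
conservative. Alignment ends are wherever the dynamic programme maximises
score; no trimming heuristics are applied. Alignments whose two images
overlap each other are discarded: the model is *dispersed* repeat families,
and tandem self-overlap is not membership evidence. Duplicate alignments of
the same locus pair (e.g. from a chain split across a bucket boundary) are
collapsed to the highest-scoring one.

Two engineering gates keep the stage tractable without changing what is
found. First, a chain is extended only if it carries at least
`chain_density_frac × min_identity^k × (min_length − k + 1)` seeds
(default ≈ 29): a genuine alignment passing both reporting gates produces
several-fold more seeds than this with overwhelming probability, while
pairs of anciently diverged copies (say 75% identity) essentially never
reach it. Because the bound scales with `min_identity` and `min_length`,
relaxing either threshold can only add alignments (monotonicity).
Second, each seed position pairs with at most `max_occ_pairs` (default 100)
following occurrences of its k-mer. For a family with thousands of copies
this prunes far-apart pairs, but single-linkage clustering only needs a
connected path through the family — near neighbours in genome order remain
paired — so family recovery is unaffected.

## Piles and single-linkage families

Alignment images are merged into *element instances* ("piles") when they
overlap by at least `pile_min_overlap = 0.5` of the shorter image,
transitively; an instance's interval is the union span of its images. The
0.5 default tolerates boundary jitter between alignments of the same
element while not chaining adjacent distinct elements that merely touch;
any-overlap merging (fraction 0) reproduces classic pile behaviour and is a
single parameter away. Nested insertions that exceed the overlap fraction
merge into one instance — that is inherent to single linkage and is
documented rather than "fixed".

Families are the connected components of the graph whose nodes are
instances and whose edges are alignments linking two distinct instances;
singleton components are dropped. The edge list (instance, instance,
alignment) is retained per family — this, together with the member
manifest, is the audit trail.

A family needs one consistent strand before consensus building. A single
alignment only constrains the *relative* orientation of its two instances,
so a per-image majority vote is not well defined; instead strands are
propagated breadth-first along the alignment graph from the lowest-id
instance (arbitrarily '+'), flipping across opposite-orientation edges.
Conflicts (odd cycles, possible for palindromic or inverted-repeat
structures) resolve first-visit-wins, deterministically.

## Consensus building

Per family, members within **95%** of the longest member's length are
eligible (mixing heavily 5'-truncated copies into the alignment would smear
it), at most **100** are sampled uniformly without replacement under an
explicit seed, and the longest member is always kept since it defines the
constraint. The sample is aligned by centre-star progressive alignment with
the longest member as centre — adequate because members sit near the
identity gate by construction — and collapsed by per-column majority vote:

* columns where the *internal* gap is the strict majority are dropped,
  which is what prevents indel-driven consensus expansion (enforced by a
  hard 1.05× cap on consensus length relative to the longest sampled
  member);
* terminal gaps are treated as missing data, not as gap votes: a
  5'-truncated member simply does not cover those columns. Without this
  distinction the consensus of a truncated LINE family would be clipped to
  roughly the sample's median truncation point;
* base ties break in the fixed order A < C < G < T, and N is emitted only
  where every covering row is N.

An external multiple aligner can be substituted behind the same contract
(rows that de-gap to their inputs); the built-in star alignment removes the
runtime dependency.

## Cleaning and classification

Initial clusters can contain things that are not mobile elements. Two
filters run on the consensus set:

* **SSR filter** — consensus sequences covered ≥ 80% by short tandem runs
  (unit ≤ 6 bp, ≥ 4 copies, ≥ 12 bp) are removed as simple sequence
  repeats.
* **Host-gene filter** — each consensus is six-frame translated and
  locally aligned (BLOSUM62, gap open 11 / extend 1) against a host
  protein database and against a retroviral/reverse-transcriptase
  database. Significance uses the ungapped Karlin–Altschul approximation
  (λ = 0.318, K = 0.13, search space = query length × total database
  length) — deterministic and dependency-free. A consensus hitting the
  host database at E ≤ 1e−5 with *no* RT-database hit is removed as a gene
  family paralog; hitting both databases keeps it (retroelement proteins
  legitimately appear in curated host databases).

Survivors are classified against a nucleotide TE library
(Repbase-dialect `name#class/subclass` headers): *well annotated* when
hits to one reference family jointly cover ≥ 80% of the consensus
("almost full length" made operational — the threshold is exposed as
configuration), *partially annotated* when some hit reaches 50 bp but
coverage stays below that, *unannotated* otherwise. Partial ∪ unannotated
form the **unclassified** set.

## Genome annotation and repeat content

The kept consensus set plus the reference library are aligned back to the
genome at a relaxed identity floor of **0.80** (seed k = 8, milder
mismatch penalty): the whole point of the re-annotation pass is to catch
copies *below* the discovery threshold — the older members of a family
whose young core the self-alignment found. Overlapping hits are resolved
best-hit-first: the higher-scoring hit wins, the loser is trimmed to its
largest non-overlapping piece and discarded under 30 bp. After resolution
no genome position belongs to two hits, so per-class coverage percentages
(SINE/LINE/LTR/DNA/Other/Unclassified) add up without double counting.

## Segmental duplications vs novel TEs

Unclassified consensus sequences are triaged by copy number, counted over
resolved genome hits: SDs are intrinsically low copy, so records at or
below **2,000** copies (strict inequality sends a record to review) are SD
candidates, while high-copy records are novel or partial TE candidates.
For the latter, a per-position coverage profile over the consensus is
computed; peaks are maximal runs with depth ≥ 0.5 of the maximum and ≥ 30
bp wide (both invented, exposed defaults — the source material shows plots
only). A single peak spanning the whole consensus is the "uniform high
coverage" signature of a genuine novel TE; a localised peak indicates a
high-copy fragment inside a lower-copy consensus. A log–log OLS regression
of copy number on length (zero-copy records excluded, reported separately)
summarises the copy-number/length relationship; slope and standard errors
come from the standard normal equations via `lm()`.

## Potentially active elements

An element is *potentially active* when it carries an intact ORF2:
a contiguous ATG→stop open reading frame of ≥ **1,500 nt** (all frames,
both strands) whose protein contains a reverse-transcriptase domain
envelope of ≥ **200 aa** at E ≤ 1e−5 against user-supplied RT reference
proteins — regardless of the state of ORF1. "No inactivating mutations" is
operationalised exactly as ORF contiguity: a premature stop or a frameshift
drops the longest clean frame below the 1,500 nt floor. The domain search
is local protein alignment rather than a profile-HMM scan; an HMMER
backend can be plugged in behind the same envelope contract, which removes
any Pfam download dependency. The E ≤ 1e−5 default is a stand-in for an
unpublished threshold and is exposed as configuration.

# The synthetic evaluation genome

Everything above is testable without external data because the package
ships its own generator, `simulateGenome()` + `plantSpec()`. The defaults
encode the standard evaluation conditions used by the test suite and the
acceptance script:

* 1 Mb i.i.d. background at GC 0.42 (a Markov background is unnecessary:
  at k = 12, spurious seed sharing is already negligible at this scale);
* five dispersed TE families of 30–150 copies with within-family pairwise
  identities spanning ~95–99% (per-copy substitution rates 0.005–0.02,
  light indels), one of them a 2.4 kb LINE with exponential 5' truncation
  (mean fraction 0.15) and an intact ORF2 embedding a 300 aa RT protein;
* one high-copy novel TE: 40 recent copies plus ~2,460 ancient copies at
  ~85% identity to the ancestor. Old copies are invisible to the 94%
  self-alignment gate but annotate at the 0.80 floor, producing the
  \>2,000-copy signature with a small discovered family — the structure an
  old but recently re-active family leaves in a real genome;
* three SDs (5/8/15 kb, 2–3 copies, ~98% internal identity), one host gene
  paralog family (400 aa protein, 8 copies), and dispersed (AC)n tracts;
* copies are placed uniformly at random on random strands, never
  overlapping and separated by ≥ 150 bp of background, so that abutting
  copies cannot masquerade as tandem doubles;
* identical seeds give bit-identical genomes and truth tables.

What the generator deliberately does **not** emulate: nested insertions,
CpG-aware or lineage-heterogeneous mutation, tandem arrays beyond simple
SSRs, assembly gaps/errors, and genome-scale repeat densities. Passing
tests therefore demonstrate the machinery is correct under the stated
model, not that recovery rates transfer verbatim to real assemblies —
on real data the thresholds are the user's scientific choice, and results
should be read through the audit trail.

Within-family identity, not copy-to-ancestor identity, is the quantity the
94% gate acts on: two copies each 5% diverged from their ancestor are ~10%
diverged from each other and invisible to the default gates. The generator
is parameterised accordingly, matching the stated scope of the method —
recently active, low-divergence families.

# Numerical and design choices

* Coordinates are GRanges-convention 1-based closed everywhere in R;
  the C++ core uses 0-based offsets internally, converted at the boundary.
  GFF3 output is 1-based closed as the format requires.
* Alignment scores (+1/−2/−4/−1) are chosen so that a 94%-identity
  alignment scores clearly positive (expected ≈ +0.76/column); the
  annotation pass uses a milder −1 mismatch so 80%-identity alignments
  remain positive.
* Degenerate inputs: empty genomes and empty libraries error early with
  the stage named; an all-N genome aligns to nothing; consensus sets may
  legitimately be empty (a genome without recent repeats).
* Ties: consensus base ties break A < C < G < T; equal-scoring overlap
  conflicts resolve by genome position; family and instance ids are
  assigned in genomic order, so runs are deterministic end to end given
  the member-sampling seed.
* Problem sizes in the shipped tests: unit tests run on 10–100 kb
  genomes; the acceptance suite and `scripts/acceptance.R` use the
  ~2.3 Mb default evaluation genome, chosen so a complete run finishes in
  a few minutes on one CPU.

# Known limitations

* Single-linkage clustering chains families through shared segments: two
  elements sharing a long internal region can merge. The paper trail
  (edge list) makes such merges inspectable, but no sub-family splitting
  is attempted.
* The centre-star aligner assumes members are alignable to the longest
  member end-to-end; families with large internal rearrangements would be
  better served by an external MSA backend.
* The Karlin–Altschul E-values use ungapped constants for gapped scores —
  a standard, slightly conservative approximation.
* Copy numbers are counted after overlap trimming; a consensus whose hits
  are systematically trimmed by a higher-scoring overlapping library entry
  will be undercounted. Whether to count pre-resolution hits instead is a
  judgement call; the resolved count is what the repeat-content table uses,
  so the two outputs stay consistent.
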