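---
title: "Methods: R-gene identification and evolutionary dynamics"
author: "rgevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: R-gene identification and evolutionary dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rgevo` re-implements, as a reusable and fully testable pipeline, the
classic comparative-genomics workflow for plant disease-resistance
(R-) genes: identify NBS-LRR-type candidates by iterative homology
search, classify their CC/TIR/NBS/LRR domain architectures, map their
tandem clusters and syntenic context, classify their gene structures
(including pseudogenes), and quantify their evolutionary dynamics —
divergence rates from four-fold degenerate (4D) sites, family
birth–death events on the species tree, and Ka/Ks selection signals.
Because the real inputs of such studies are multi-gigabase genome
downloads, the package ships a synthetic-genome generator with complete
ground truth; every stage is validated by round trips against that
truth.

# The identification pipeline

Annotated proteins are screened by two routes:

* **NBS (NB-ARC) scanner.** A hit requires a P-loop motif
  (`[GA]x4GK[ST]`) plus at least one of kinase-2
  (`[LIVMF]{2}x{0,2}DD`) or `GLPL` downstream. A single motif is never
  sufficient. This motif triad stands in for a profile-HMM match of the
  NB-ARC domain; the three motifs are its diagnostic anchors. Scanner
  positives are additionally validated by lenient support in the seed
  database (E < `1e-5`): a bare motif coincidence in a random protein
  finds no such support, which keeps the background false-positive
  rate near zero.
* **Seed-database alignment.** Local alignment (BLOSUM62, affine gaps
  11/1) against a growing seed set of known R proteins; candidates pass
  at an E-value proxy below `1e-10`. The proxy is Karlin–Altschul
  shaped, \(E = K m n e^{-\lambda S}\) with \(K = 0.041\),
  \(\lambda = 0.267\) (ungapped BLOSUM62 constants); thresholds are
  configurable because the proxy is calibrated differently from any
  particular search engine.

Validated candidates join the seed set; the seeds are then searched
six-frame against the *unannotated* genome space (intergenic segments;
annotated gene spans are masked) at E-value `1e-5` to recover loci
missing from the annotation. The loop repeats until an iteration adds
nothing; the iteration at which each gene was found is recorded. The
candidate set grows monotonically, so the fixpoint exists; a
non-convergent run (cap 10 iterations) is an error that reports the
per-iteration growth.

All-vs-all and seed-vs-proteome comparisons are prefiltered by shared
6-mer counts (at least 3 shared words, top candidates aligned). Three
shared words is far below what any true homolog pair shares here
(tens to hundreds) and far above the chance expectation for unrelated
~400-aa proteins, so the filter changes nothing observable while
keeping the comparison count linear.

## Domain scanners and architecture labels

* **LRR**: runs of `LxxLxLxx` (L ∈ {L,I,V,F}); at least 3 repeats, each
  starting within 30 aa of the previous repeat's end; the longest run is
  reported.
* **TIR**: local alignment against a bundled consensus block; a hit
  needs a score of at least 0.4 of the consensus self-alignment. The
  consensus is the package's own synthetic TIR block, matched to the
  simulator's template; for real proteomes a user-supplied consensus is
  expected.
* **CC**: a 28-residue sliding window; for each of the 7 heptad
  registers the mean log-propensity is computed (hydrophobics favoured
  at heptad positions a/d: +2, else −1; E/K/Q/R favoured at e/g: +1),
  and the best register score is mapped through a logistic
  `plogis(10 s − 6)`; windows at probability ≥ 0.5 are hits (the
  conventional "probability 50" call). The calibration places a clean
  heptad array (score ≈ 0.86) at p ≈ 0.93 and random sequence
  (score ≈ 0) at p ≈ 0.002. The reported span is the contiguous run of
  qualifying windows containing the peak.
* **Overlap resolution**: CC and LRR are short periodic patterns that
  can fire inside globular domains (and on each other's repeats). A
  CC/LRR hit overlapping a TIR/NBS hit by ≥ half its length is
  suppressed, and on heavy CC–LRR mutual overlap the shorter hit is
  dropped — the same role clan competition plays in profile-based
  annotation.

Architecture labels compose presence and N-to-C order: CC/TIR before
the NBS, LRR after it, giving the ten named categories (CC, TIR, NBS,
LRR, CC-NBS, TIR-NBS, NBS-LRR, CC-NBS-LRR, TIR-NBS-LRR, CC-TIR-NBS).
Any order violation, or all four domains together, falls into
**Others**; no hits is **Un-annotated**. The treatment of non-canonical
combinations as Others (rather than Un-annotated) is the package's
convention for the residual class.

# Genomic context

Gene order is represented by 0-based ranks per chromosome (ties on
start broken by gene id). Two R-genes chain into one tandem cluster
when at most **8** genes lie between them (single linkage); size-1
"clusters" are singletons and excluded from the clustered fraction.
Orthologs are retained at **CIP > 60%** (cumulative identity
percentage: identities over aligned length, summed across retained
non-overlapping segments) and E-value < `1e-10`, with reciprocal best
hits flagged (ties broken by score, then E-value, then id). Chromosomes
anchor to the out-group chromosome contributing the plurality of
ortholog partners (ties by summed score). An R-locus maps onto the
out-group when at least **3** ortholog pairs within ±25 gene ranks
support one out-group chromosome ("synteny value" = that count; the
window is the package's choice where the original procedure leaves it
unstated).

# Gene structures

A CDS classifies as **Pseudo** when its reading frame is broken (length
≢ 0 mod 3, or a frame change in the locus chain) or it contains an
internal stop; otherwise **LackStart** / **LackStop** / **LackBoth** by
the terminal codons; otherwise **InDel** when the alignment to the
family seed has an internal gap of ≥ 3 codons; otherwise **Complete**.
Precedence is Pseudo > LackBoth > LackStart/LackStop > InDel >
Complete. For genomic loci, a frame-aware re-annotator chains the best
local alignments of the seed across the three forward frames (chains
must be colinear in query and subject; a frame change between adjacent
chained segments is a frameshift event). This intronless chaining
replaces splice-aware re-annotation and is adequate for the intronless
synthetic genes; applying it to spliced real genes would require a
splice-aware engine and is a documented limitation.

# Phylogenetics

Families come from Markov clustering (MCL) of the protein similarity
graph (edges at E < `1e-10`, symmetrised normalised scores; expansion
2, inflation 1.5, pruning `1e-5`, convergence `1e-8`; self-loops at the
maximum incident edge weight so that loops do not dominate normalised
weights). Strictly single-copy families are aligned by center-star
protein alignment (the center maximises summed pairwise scores;
"once a gap, always a gap" merging) and back-translated codon-atomically,
so the codon alignment is exact by construction. Center-star is a
deliberate simplification of progressive MSA; for the closely related
sequences used here its accuracy is indistinguishable, and its
determinism is what the tests need.

A codon column yields 4D sites when it is gap-free, all species share
the first two codon positions, and that prefix is four-fold degenerate
({TC, CT, CC, CG, AC, GT, GC, GG}). Requiring prefix conservation
across *all* taxa is the strictest reading and makes the extraction
order-independent. Distances are Kimura 2-parameter,
\(d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)\), with pairwise
deletion of gaps/ambiguities and a saturation flag when a log argument
is non-positive. Trees are neighbor joining (Saitou–Nei); a negative
branch at a join is clamped to zero with the deficit moved to its
sister so their sum is preserved (the terminal three-branch resolution
clamps without redistribution). Bootstrap resamples columns with
replacement; all replicate indices are drawn up front from one master
seed, so supports are reproducible regardless of evaluation order.
Support is counted on canonical unrooted bipartitions. Divergence-rate
comparisons report the ratio of total tree lengths (and per-leaf
root-to-tip ratios, since the literature is ambiguous about which is
meant by "average divergence rate").

# Family birth–death

Ancestral family copy numbers minimise the summed absolute change over
branches (Sankoff dynamic programme over counts 0..max, linear cost);
ties resolve toward the *smallest* ancestral count, which makes the
reconstruction deterministic and biases ambiguous cases toward gains —
the convention is pinned by tests against exhaustive enumeration. This
linear-cost parsimony deliberately replaces a stochastic birth–death
likelihood: it is deterministic, desk-scale, and sufficient for
per-branch expansion/contraction summaries; it produces no per-family
p-values.

# Selection

Ka/Ks uses the Nei–Gojobori (1986) method with Jukes–Cantor correction:
potential synonymous sites are the per-position fractions of
single-base changes that are synonymous (averaged over the two
sequences; changes to stop codons count as non-synonymous, so
S + N = 3L exactly); observed differences average over all mutational
pathways between codon pairs, excluding pathways through stop codons;
\(d = -\tfrac34\ln(1-\tfrac43 p)\) corrects both proportions. Ratios
bin as: < 0.25 purifying; [0.25, 0.8) intermediate; [0.8, 1.0]
candidate; > 1 positive; boundary values at 0.25 fall in
intermediate (the source rules are strict inequalities on both sides
and silent at the boundary). Undefined ratios (dS = 0 or saturation)
are reported separately, never binned. Dxy is the JC-corrected mean
raw difference proportion across ortholog alignments.

# The synthetic-data generator

The generator emulates the statistical structure of a legume-scale
R-gene study; its defaults are the package's study conditions:

* 8 species on a fixed rooted tree (two sister "soybean-like" taxa at
  0.01 substitutions/site, a distant out-group at 0.16; branch lengths
  are 4D-site substitutions per site chosen to span the
  shallow-to-deep range such studies cover).
* 20 R-gene families (root copy numbers drawn from {1,1,2,2,3}; gains
  and losses Poisson(0.05) per branch) over 320 single-copy background
  families — ~350 genes per species, a desk-scale stand-in for
  30–50k-gene genomes.
* R-genes evolve at **2×** the background substitution rate with
  dN/dS 0.2 (purifying); non-motif domain codons at dN/dS 0.05; the
  scanner-diagnostic motif codons (P-loop, kinase-2, GLPL, the LRR
  L-positions, the CC a/d/e/g positions) accept only synonymous
  changes, mirroring the near-invariance of these anchors in real R
  proteins. Codon evolution is acceptance–rejection (synonymous
  changes accepted; non-synonymous at probability ω;
  stop-creating changes rejected), with the substitution count drawn
  as Poisson(branch length × sites) — an approximation that honours
  the dN/dS contract without a rate-matrix exponential.
* Emitted R proteins average ≈ 500 aa under the default architecture
  mix (weighted toward NBS-containing categories).
* Multi-copy families within a species are laid out as tandem clusters
  with 0–8 intervening background genes (small gaps favoured, as for
  real tandem duplicates); distinct R loci are separated by > 8 genes,
  so cluster recovery is exactly decidable.
* 23% of R-gene copies carry planted structural defects
  (10% pseudogenizing frameshifts/premature stops — inside the 7–30%
  band such studies report — plus rarer InDel and terminal defects).
  Point defects are placed in the C-terminal tail downstream of the
  last domain: these model *recently* disabled copies, keep the planted
  architecture well-defined, and make structure truth recoverable from
  the CDS alone.
* 2 intact cluster members per species are hidden from the annotation
  (present only in the genome sequence) to exercise the genome-search
  stage.
* Byte-identical output under a fixed seed.

In the controlled-truth validation mode (`one_event_per_family`),
exactly one gain or loss is planted per family on a uniformly chosen
branch, excluding the two basal branches: an event on either side of
the root cannot be polarized by any reconstruction without a further
out-group, so those branches are outside what the experiment can test.

**What the generator does not emulate** — introns and splice variants,
transposable elements, whole-genome duplications, assembly
fragmentation, annotation noise beyond the planted defect classes, and
domain gains/losses along branches. Passing round trips therefore
demonstrate the internal consistency and correctness of each stage's
logic at realistic divergences, not performance on real genome
assemblies.

# Numerical behaviour worth knowing

* **NG86 under the simulator's mutation model.** The simulator rejects
  stop-creating mutations, while NG86 counts stop-bound changes as
  non-synonymous opportunity (S + N = 3L). Estimated dN/dS is
  therefore biased low by about 5% of ω at ω = 1 (≈ 0.94 recovered);
  the recovery experiments average four replicate descendants of a
  10,000-codon ancestor at 0.2 substitutions/site to keep sampling
  noise (≈ 0.02) well below the tolerance. The bias is a property of
  the estimator's mutation-opportunity assumption, which the original
  method shares.
* **Rate-ratio recovery** uses 140 single-copy families of 900 codons
  per cohort (≈ 10k 4D sites in the fast cohort); K2P de-saturates the
  deep comparisons, and the recovered total-tree-length ratio is
  2.0 ± 0.1 in practice.
* **Problem sizes.** The default round trip is 8 species × ~350 genes
  (~0.45 Mb per genome); these sizes were chosen as the smallest at
  which every phenomenon of interest (clusters, hidden loci, all
  defect classes, deep-vs-shallow divergences) occurs with comfortable
  multiplicity.
* **Determinism.** All tie-breaks are pinned (lexicographic ids,
  smallest ancestral counts, first minimal Q-matrix entry), all
  randomness flows from the caller's seed, and the serialisation is
  byte-stable.

# Known limitations

The E-value proxy is a calibration device, not a BLAST E-value; real
PFAM/HMM scanners, splice-aware re-annotation, stochastic birth–death
likelihoods (and their per-family significance tests), and YN00-style
codon models are all out of scope by design. The bundled TIR consensus
is synthetic. Applying the pipeline to real genomes would substitute
the scanners' inputs (a real consensus, a real seed database) and a
splice-aware structural engine, while the downstream statistics carry
over unchanged.
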