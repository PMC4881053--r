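# rgevo — evolutionary dynamics of plant disease-resistance genes

Plant disease-resistance (R-) genes — mostly intracellular immune
receptors built from CC/TIR, NBS (NB-ARC) and LRR domains — evolve by
rapid birth-and-death: tandem duplication, pseudogenization, and fast
sequence divergence under predominantly purifying selection. `rgevo`
implements the comparative-genomics workflow used to study this process
across a set of related genomes (the motivating setting is seven legume
genomes plus grape as out-group), end to end:

1. **Identification** — iterative seed-and-validate homology search:
   NBS-motif scanning (P-loop `[GA]x4GK[ST]` + kinase-2/GLPL) OR
   alignment to a growing seed database (BLOSUM62, affine 11/1,
   Karlin–Altschul-style E-value proxy < 1e-10), plus six-frame search
   of the unannotated genome space (E < 1e-5), iterated to a fixpoint.
2. **Architecture classification** — CC/TIR/NBS/LRR scanners composed
   into the ten named categories plus Others / Un-annotated.
3. **Genomic context** — tandem clusters (two R-genes no more than 8
   genes apart), CIP > 60% orthologs with reciprocal best hits,
   chromosome anchoring to the out-group, and a synteny-supported
   R-locus map (mapped iff synteny value ≥ 3).
4. **Gene structures** — Complete / InDel / LackStart / LackStop /
   LackBoth / Pseudo with precedence, from the CDS or from a
   frame-aware chaining re-annotation of the locus.
5. **Phylogenetics** — single-copy families, center-star codon
   alignments, four-fold-degenerate-site supergenes, Kimura
   2-parameter distances
   d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),
   neighbor-joining trees with column bootstrap, and cohort
   divergence-rate ratios.
6. **Evolutionary dynamics** — gene families by Markov clustering,
   per-branch family gains/losses by linear-cost (Sankoff) parsimony,
   and selection scans with the Nei–Gojobori method under Jukes–Cantor
   correction (dS = −¾ ln(1 − 4/3 pS), dN likewise; Ka/Ks bins
   < 0.25 purifying, 0.8–1.0 candidate, > 1 positive).

Real genome downloads are deliberately not required: a synthetic-genome
generator (`simulate_dataset()`) produces multi-species datasets with
planted architectures, clusters, family gains/losses, structural
defects and unannotated loci — with full ground truth, so every stage
is validated by round trips.

## Worked example

The analysis is organised as numbered scripts over the package
functions; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 42
Rscript analysis/02_identify.R
Rscript analysis/03_genome_context.R
Rscript analysis/04_structure.R
Rscript analysis/05_phylo.R
Rscript analysis/06_selection.R
```

With seed 42 this prints, step by step:

```
species: 8; genes/species: 352 (258 R-genes total, 16 hidden)
mean R protein length: 501 aa; pseudogene fraction: 0.12
recall 1.000 (258/258 truth R-genes; 16/16 hidden loci); FPR 0.0000; architecture accuracy 0.988
published census: 4217 R-genes across seven legumes; wild - cultivated soybean = 208
clustered fraction per species: Carietinum 0.71, Ccajan 0.57, Gmax 0.63, ...
Gmax vs Vvinifera: 357 ortholog pairs (321 RBH)
R-locus map: 27/27 mapped (synteny value >= 3)
structure-class accuracy vs truth: 1.000 (n = 242)
background supergene: 7128 4D sites; bootstrap supports: 100 100 100 100 100
purifying fraction 1.00; candidates (0.8-1.0): 0; positive (>1): 0
Dxy over ortholog alignments: 0.0936
```

Reading this: every planted R-gene was recovered (including the 16 loci
hidden from the annotation and found by six-frame genome search), no
background gene was falsely called, and 98.8% of recovered genes
received their planted architecture label. Tandem clustering, the
grape-anchored synteny map, the structure classes, the fully supported
background species tree, and the strongly purifying Ka/Ks distribution
all match what was simulated — and mirror the qualitative picture
reported for real legume R-genes (12–76% clustered, 7–30%
pseudogenized, purifying selection dominant).

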