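---
title: "Mining plant genomes for metabolic gene clusters from co-expression and chromatin signatures"
author: "mgcMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining plant genomes for metabolic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgcMiner)
```

## The mining model

Plant metabolic gene clusters are operon-like regions of 3–10+ physically
adjacent, largely non-homologous genes encoding the successive enzymes of a
specialized-metabolite pathway. Two genomic signatures distinguish them from
the surrounding sequence: their genes are tightly co-expressed (the pathway
is switched on and off as a unit, typically in narrow cell types or
conditions), and the region is covered by contiguous H3K27me3 marks, the
Polycomb modification associated with tight, tissue-restricted repression.
`mgcMiner` operationalizes both signatures and takes their intersection.

The pipeline's coordinate system is the **gene rank**: within each
chromosome, genes are numbered 0..n−1 by ascending start coordinate (ties
broken by gene ID for determinism). All adjacency notions — "within *g*
genes", "contiguous" — are defined on ranks, never on base pairs, and never
across chromosome boundaries. Organellar genomes are excluded. Genes without
expression data still occupy ranks: the physical window is genomic, while
only probe-covered genes can form graph edges (microarray designs cover
only ~80% of genes in a typical plant genome, so this distinction matters;
a flag on `bandedPCC()` restricts the window to the covered subset for
sensitivity analyses). Strand is recorded but ignored — clustered pathways
freely mix gene orientations.

### The banded co-expression graph

From a genes × samples log2 expression matrix, the Pearson correlation is
computed for exactly the same-chromosome pairs separated by 1..*g* ranks —
an off-diagonal band of the full correlation matrix, whose diagonal
(self-pairs) is excluded. Pairs with PCC ≥ *c* (inclusive: *c* is a minimum
attained value) become edges of an undirected, unweighted graph. Edges
between duplicate genes — the loose similarity tier, standing in for BLASTn
e < 0.2 — are removed, because homologs co-express trivially and would
inflate any clustering signal.

Probe-level matrices are first collapsed to one row per gene, keeping the
probe with the largest interquartile range (ties broken by probe ID). The
loader asserts the input is already log2 scale; array normalization (RMA
etc.) is deliberately out of scope.

Window and cutoff default to *g* = 10 and *c* = 0.65 and can be re-derived
with `optimizeParameters()`, which maximizes the **average clustering
coefficient** (ACC) — the mean over nodes of (triangles through the node) /
(pairs of its neighbours) — over a grid. Two choices here were genuinely
open and are worth recording. First, ACC averages over *non-isolated* nodes
only (degree-1 nodes contribute 0): averaging over all ~27k genes, nearly
all of them isolated at any stringent cutoff, would divide the signal by a
large constant and flatten the surface without changing the argmax ordering
in any useful way; a flag restores all-node averaging. Second, ACC ties are
broken toward the smallest *g*, then the largest *c* — the most local, most
stringent graph — so the search is deterministic. The grids themselves are
user-set; defaults span g = 1..15 and c = 0.50..0.90.

Degenerate inputs are handled conservatively: zero-variance rows are
excluded from the correlation map (correlation is undefined, not zero), and
with missing values a pairwise-complete correlation is used with a minimum
of 3 shared samples per pair.

### Cluster calling and the gene-order null

Two callers operate on the graph. The stringent method enumerates maximal
cliques of ≥ 3 nodes (Bron–Kerbosch with pivoting, via igraph) and merges
cliques sharing any node into one cluster by transitive closure. The
relaxed "subgraph" method takes connected components of ≥ 3 nodes. Clusters
are node sets, not intervals: members need not be rank-contiguous (the
graph only bounds pairwise separation by *g*), and the reported span is the
enclosing half-open rank interval. Every merged-clique cluster is contained
in exactly one component cluster — a property the test suite checks on
1,000 random graphs.

Significance is assessed by shuffling the gene order independently within
each chromosome (Fisher–Yates), rebuilding the banded graph from the same
correlation values re-indexed by the new ranks — each gene keeps its
expression profile and duplicate relations, so only physical adjacency is
randomized — and recalling clusters. (*g*, *c*) stay fixed at the
observed-data optimum across replicates. The summary reports the null mean
and sample standard deviation (denominator n−1), a one-sided upper-tail
normal p, and an empirical p of (#replicates ≥ observed + 1)/(n + 1) as a
distribution-free companion.

### Chromatin-mark runs and the mark-shuffle null

Mark calls are consumed as a binary per-gene track. `findMarkRuns()`
reports maximal runs of ≥ 4 contiguous marked genes (≥ 3 supported as the
documented relaxation), never crossing chromosome boundaries. The null
shuffles the genome-wide mark vector (preserving the marked count) and
recounts; a per-chromosome stratified mode is provided and agrees with the
genome-wide mode to within Monte-Carlo error at realistic scales, since a
plant genome contributes only a handful of boundaries. The replicate draws
the k marked positions as a uniformly random k-subset — exactly the
distribution a Fisher–Yates shuffle of the vector induces, at a fraction of
the cost.

The null has a closed-form check: the expected number of maximal runs of
length ≥ r among all C(n, k) equally likely placements is

E = [C(n−r, k−r) + (n−r)·C(n−r−1, k−r)] / C(n, k),

the two terms counting runs starting at position 1 and runs preceded by an
unmarked position. Computed with log-binomials this is exact at any n;
`expectedRunsExact()` matches brute-force enumeration to 1e-12 for every
n ≤ 15 and anchors the genome-scale simulation (at n = 27,206 genes with
k = 4,629 marked — the 17% genome-wide H3K27me3 fraction — and r = 4 it
gives 18.902, with the 10,000-shuffle simulation scattering around it with
sd ≈ 4.2). A note on p-values at this scale: the observed run counts sit so
far above the null that normal-approximation p-values underflow any
printable range; the empirical p is the honest companion statistic.

### Intersection, tandem filter, mis-regulation scan

A co-expressed cluster survives intersection when its rank span contains at
least 4 contiguous marked genes — a marked segment of length ≥ 4 lying
wholly within the span, evaluated against maximal runs of any length so a
long run overlapping the span edge counts by its contained portion — and at
least 3 of the cluster's members are themselves marked. "Contained in the
span" rather than "members marked in a row" is the closest literal reading
of a region-based criterion given that clique members need not be
contiguous.

Candidates are then grouped into gene families by transitive closure of the
strict duplicate tier (e < 0.01 stand-in) restricted to members; candidates
with fewer than 3 families — pure tandem arrays of one or two gene types,
which co-express and share chromatin state for uninteresting reasons — are
eliminated. Transitive closure makes "gene type" well defined even when
pairwise similarity is not transitive.

Finally, the mutant scan takes a wild-type + mutants RPKM table and computes
log2((mutant + ε)/(wild type + ε)) with a pseudocount ε = 1 guarding
division by zero (configurable; it compresses fold changes of weakly
expressed genes toward zero, a deliberate conservatism). A gene qualifies
in a direction when it changes ≥ 2-fold that way in ≥ 3 mutant genotypes;
maximal rank-contiguous stretches of ≥ 3 qualifying genes sharing one
direction are reported. The shared-direction rule is the default reading of
"similar mis-regulation" — clustered pathways respond coherently — with a
flag (`sharedDirection = FALSE`) to allow mixed-direction stretches.

## What the synthetic generator emulates — and what it does not

The generator stands in for the study-scale inputs the method was designed
for: a ~1,200-array expression compendium, genome-wide H3K27me3 calls,
BLASTn duplicate pairs, and RNA-seq RPKM for a wild type plus four
H2A.Z-pathway mutants (*arp6*, *pie1*, *swc6*, *hta9 hta11*).

- **Expression**: planted blocks share a latent factor — member gene j in
  sample s takes √ρ·z&#8347; + √(1−ρ)·ε — giving expected pairwise
  correlation exactly ρ in O(n) sampling time, with iid normal background.
- **Marks**: Bernoulli background at rate 0.17 (the genome-wide marked
  fraction, 4,629/27,206) with planted fully marked runs.
- **Duplicates**: tandem arrays partitioned round-robin into families; all
  within-family pairs emitted at the strict tier (hence also loose), with
  optional extra loose-only pairs.
- **RPKM**: log-normal wild type (meanlog = log 100, sdlog = 0.75 — typical
  moderately expressed genes, chosen so the ε pseudocount rarely pushes a
  true 4-fold change under the 2-fold threshold), mutants multiplied by
  2^(effect + N(0, 0.25)) with a −2 log2 effect in 3 of the 4 mutants for
  planted cluster genes.

Defaults describe the validation genome: 2 chromosomes × 1,000 genes, 200
samples, 20 planted 5-gene clusters at ρ = 0.9 under matching 5-gene mark
runs with ≥ 3 families each, one decoy 2-family tandem array per chromosome
(co-expressed *and* marked, so it probes the homology filters) and one
decoy mark-only run per chromosome. 200 samples is the package's desk-scale
stand-in for a thousand-array compendium; at that size background
correlations scatter with sd ≈ 0.07, so c = 0.65 separates planted from
background essentially without error. All generators are deterministic
under the config seed (sub-streams are derived per generator).

What passing these tests does **not** show about real data: the generator's
background is exchangeable — no expression gradients along chromosomes, no
chromatin domain structure beyond planted runs, no correlation between mark
status and expression level, no shared-sample batch structure, and complete
within-family duplicate detection. Real compendia violate all of these to
some degree; recovery rates on the synthetic genome are therefore an upper
bound, and the permutation nulls — which condition only on exchangeability
of order — are the component expected to transfer most directly. One
consequence of the complete-family simulation is worth noting: a 2-family
tandem array cannot form a triangle once loose-duplicate edges are removed,
so simulated decoy arrays die at the clique stage; the tandem-family filter
itself is exercised in unit tests with non-transitive family structures,
where it is the deciding step.

## Numerical and scale choices

Banded correlations are computed from row-standardized matrices as inner
products, checked against the dense correlation matrix to 1e-10 on 200-gene
instances. The permutation nulls at reference scale (27,206 genes, 10,000
shuffles) run in seconds via the k-subset sampling form. Test problem sizes
were chosen as the smallest instances that leave no ambiguity about the
property under test: 1,000 random graphs for the containment property,
exhaustive enumeration to n = 15 for the run-expectation oracle, the
2 × 1,000-gene genome for end-to-end recovery. Outputs carry no timestamps,
so identical configs and seeds reproduce byte-identical files; the manifest
records parameters, input MD5 checksums and per-stage counts instead.

## Known limitations

- PCC is the only similarity measure (no Spearman or mutual rank), by
  design: the method is defined on the correlation band.
- Cluster spans may include non-member genes; the intersection criteria are
  span-based, so a marked run between two member genes counts even if no
  member falls inside it. This is intended but worth knowing when reading
  candidate tables.
- The normal-approximation p is reported for continuity with common
  practice, but at genome scale the observed statistic is so extreme that
  only the empirical p is meaningful.
- The mis-regulation scan implements the fold-change stretch rule only;
  differential-expression significance calls (e.g. FDR-controlled Cuffdiff
  output) are upstream concerns and not re-implemented.
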