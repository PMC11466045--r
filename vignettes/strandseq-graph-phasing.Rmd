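---
title: "Phasing assembly graphs with Strand-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing assembly graphs with Strand-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitigphaser)
```

## The phasing problem

A diploid genome assembler produces a graph whose nodes (unitigs) each come
from one parental haplotype or from sequence where the two haplotypes
collapse. To emit two complete haplotypes, every unitig must be labeled
haplotype A, haplotype B, or homozygous. Strand-seq makes this possible from
a single sample: each single-cell library retains only one template strand
(Watson or Crick) per chromosome homolog, chosen independently with
probability 1/2. Reads from a library therefore align to a unitig in an
orientation determined by which strand its homolog retained in that cell,
and that inheritance pattern across many libraries is a chromosome- and
haplotype-specific fingerprint.

`unitigphaser` turns per-library Watson/Crick alignment counts on unitigs
into such fingerprints and resolves them in four stages: chromosome
clustering, misorientation correction, phase-geometry inference, and
haplotype-marker pooling. Two evidence channels are used throughout:

* **all-reads** counts (typically from a paired-end aligner), which carry
  chromosome and orientation signal but no haplotype signal, because the
  two near-identical homologs attract reads equally; and
* **phase-informative** counts from reads that align to exactly one place
  in the graph (one super-maximal exact match with a single hit), which
  come predominantly from the unitig's own homolog.

## Strand-state frequencies

For a unitig and library with `w` Watson and `c` Crick reads, the
strand-state frequency is `SSF = (w - c) / (w + c)`. A *matched* strand
state (both homologs retained the same strand, WW or CC) gives SSF near
±1; an *unmatched* state (WC/CW) gives SSF near 0 in the all-reads channel.
The vector of SSF values over libraries is the clustering feature. Cells
with `w + c = 0` are defined to have SSF 0 with weight 0: zero is the unique
value that contributes nothing to a cosine similarity, so "no signal" and
"no information" coincide.

Two properties make the *absolute cosine similarity* `|cos(a, b)|` the right
metric on these vectors. First, a misoriented unitig (assembled in reverse
complement) has its whole vector negated; the absolute value clusters by
parallelism and is blind to that. Second, degenerate sequence attracts reads
from all chromosomes and inflates both `w` and `c` uniformly, shrinking all
components of the vector by a common factor — which a normalized cosine
cannot see. The test suite checks this invariance exactly: adding equal
Watson and Crick background to every library leaves the unit-normalized
vector unchanged to 1e-12. The implicit assumption is that a unitig cannot
inherit an unmatched state in *every* library; with 96 libraries the
probability of that under fair strand inheritance is 2^-96 per chromosome,
so an all-unmatched pattern is read as degeneracy, not inheritance.

## Quality control

Before clustering, libraries and unitigs are screened on the all-reads
channel, once; the phase channel inherits the surviving sets. Each unitig is
expected to show matched and unmatched states in roughly a 50/50 ratio
across libraries, so a library calling unmatched nearly everywhere indicates
failed strand-removal chemistry. Defaults (all configurable, and chosen as
this package's own defaults — the upstream QC conventions they mirror do
not publish fixed values):

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.5 | `|SSF| >= tau` is a matched call |
| `min_cell_count` | 5 reads | below this a cell is `no_call` |
| `max_unmatched_frac` | 0.8 | drop a library above this unmatched fraction |
| `min_unitigs_per_lib` | 20 | drop a library covering fewer unitigs |
| `min_unitig_count` | 10 reads | drop a unitig with fewer total reads |

## Chromosome clustering

Unitigs are ranked by all-reads coverage (counts per bp) and admitted in
quantile batches of `batch_size = 1000` (or five equal quantiles when fewer
than five batches would result), highest-coverage first, so clustering is
seeded by high-signal unitigs. Within each admission the engine repeats
three operations to a fixed point:

1. **Grow** — attach the unclustered unitig with the highest mean pairwise
   absolute-cosine similarity to an existing cluster, while that maximum
   exceeds `sim_threshold_grow`.
2. **Create** — seed a new two-unitig cluster from the best unclustered
   pair above `sim_threshold_create`, then return to growing.
3. **Merge** — merge the best cluster pair above `sim_threshold_merge`,
   first restricted to pairs sharing a connected component (unitigs on one
   component are more likely to share a chromosome), then globally.

All three thresholds default to 0.6. On ideal geometry, same-chromosome
similarity is 1, while for two independent chromosomes the inner product
sums about `L/4` random ±1 terms over the co-matched libraries against
norms of about `sqrt(L/2)`, concentrating the cross-chromosome similarity
near 0.5 with spread shrinking as the library count `L` grows; 0.6 splits
the two regimes with margin from about 48 libraries up. Ties in every argmax
are broken lexicographically by (unitig id, cluster id), and batch quantiles
by unitig id, so the whole procedure is deterministic; an operation history
log is kept.

Refinement then runs twice around one re-clustering round: clusters smaller
than `min_cluster_size = 3` are dissolved; per connected component, cluster
labels covering less than `component_frac = 2%` of the component's bp are
dropped; components left with exactly one cluster absorb their unclustered
unitigs; and the agglomeration engine is re-run over everything still
unclustered (existing clusters may grow or merge).

Connected components are computed after excising the rDNA tangle: within
the bp-largest component, the largest connected subgraph induced solely by
nodes shorter than 50 kbp (summed bp; ties by node count, then smallest
member id) is removed with its incident edges, separating the acrocentric
chromosomes that the ribosomal DNA array fuses. A "tangle" is any connected
short-node subgraph — no topological criterion beyond short-node composition
is imposed. Unitigs shorter than `min_unitig_length = 50 kbp` are filtered
out entirely (boundary inclusive: a unitig exactly at the threshold stays).

## Misorientation correction

Within a cluster, correctly and incorrectly oriented unitigs form two
antipodal bundles under the *signed* cosine. Each cluster's unit vectors are
augmented with their negated copies — guaranteeing both orientations exist
even when all unitigs already agree — and average-linkage hierarchical
clustering on distance `1 - cos` is cut at two clusters. Average linkage on
the unit sphere respects the antipodal structure and is robust to single
outliers; neither the linkage nor the distance is canonical, and this is a
design choice of the package. The side holding the un-flipped copy of the
smallest unitig id is the reference orientation (the global sign is
meaningless downstream; fixing it by rule gives determinism). A unitig
whose original and negated copies land on the same side has mixed signal;
it is left unflipped and flagged, as are zero-signal unitigs and
assignments whose within-side minus cross-side mean cosine falls below
`flag_margin = 0.1`. Whole unitigs are corrected; locating an internal
breakpoint of a chimeric unitig is out of scope.

## Haploid chromosomes, the chromosome plane, and the phase vector

With phase-informative reads, a diploid cluster's unitig vectors point along
three directions — haplotype A, haplotype B, and their balanced homozygous
mixture — spanning a 2-D *chromosome plane*. Haploid chromosomes (X and Y in
a male sample) have one homolog and stay on a single line. The package runs
an **uncentered** PCA (SVD of the raw unit-vector matrix) per cluster:
directions are measured from the origin, which is what the geometry reasons
about; mean-centering would erase the haploid single-ray signature (a
`centered_pca` flag exists for comparison). Clusters with PC1 explained
variance above 70% *and* PC2 below 20% are flagged haploid and merged into
one cluster, so shared diploid sequence such as the pseudoautosomal region
is phased jointly. Orientation correction is re-run on the merged cluster
because merging changes membership; within that merged cluster relative
signs are only defined per chromosome ray, which is harmless downstream.

For each cluster:

* `v_clust` is the normalized length-weighted mean of the
  orientation-corrected all-reads unit vectors (length weighting prevents a
  more fragmented haplotype from dominating);
* the plane is the span of the first two principal directions of the
  phase-channel unit vectors;
* `v_phase_raw` is `v_clust` projected into the plane and rotated 90°
  (counterclockwise in plane coordinates; the sign ambiguity merely swaps
  haplotype labels, which are anyway "haplotypes with parentage unknown");
  it is orthogonal to `v_clust` by construction and the code asserts this
  to 1e-8;
* `v_phase` discretizes each component to its sign when its magnitude is at
  least half the largest component's magnitude, else 0. The relative rule
  keeps the discretization invariant to overall scale; the 0.5 factor is
  configurable.

For the merged haploid cluster, the size-weighted `v_clust` is biased toward
the larger chromosome, so a balancing correction is applied: unitig vectors
are expressed in the (`v_clust`, `v_phase`) in-plane basis, the unitigs with
the largest and smallest coordinate product are taken as representatives of
the two rays, and the basis is rotated so `v_clust` bisects them (the
rotation angle is the mean of the two representatives' polar angles; the
two-ray geometry keeps both well inside a half-plane, so no wrap-around
handling is needed). If all products share one sign — one haploid ray only —
the correction warns and does nothing.

## Pooling and calling

The non-zero components of `v_phase` identify the unmatched-state libraries,
the only ones carrying phase information; opposite signs mean opposite
Watson/Crick-to-haplotype assignments. Pooling therefore swaps Watson and
Crick counts in the `v_phase = -1` libraries and takes the dot products of
the Watson and Crick count columns with `|v_phase|`, yielding per-unitig
(haplotype A, haplotype B) marker counts. When `v_phase` is exactly ±1 on
those libraries, marker totals equal the phase-channel read totals of those
libraries exactly — a conservation identity the tests verify. Discretized
weights are the default; `continuous_weights` pools with `|v_phase_raw|`
instead for comparison.

The marker table (`marker_counts.tsv`: node, hapA_markers, hapB_markers,
...) is the hand-off point for graph-threading scaffolders, which combine
the shading with graph topology. The package also includes a fallback
caller for self-contained use: a unitig with fewer than `min_markers = 10`
markers is `UNASSIGNED`; otherwise `HAP_A`/`HAP_B` when the corresponding
marker fraction reaches `purity = 0.8`, else `HOMOZYGOUS` (homozygous
unitigs attract both homologs' reads and show balanced, and roughly
double-sized, marker counts). Both thresholds are this package's choices,
exposed in the configuration.

## The synthetic generator

`simulate_strandseq()` emulates the generative model the method assumes:
per (chromosome, library), each homolog independently retains Watson or
Crick with probability 1/2; haplotype-specific unitigs draw phase-channel
reads Poisson(depth) from their own homolog only (an idealization of
perfect unique-alignment filtering — a `leakage_rate` parameter relaxes
it); homozygous unitigs draw Poisson(depth/2) from each homolog; the
all-reads channel splits `allreads_multiplier x depth` evenly between
homologs for diploid unitigs. Misoriented unitigs have Watson and Crick
swapped in both channels; background adds symmetric Poisson counts at
`background_rate` of the channel depth to every cell. The graph is one
chain-shaped component per chromosome (haplotype-A chain, homozygous
unitigs, haplotype-B chain); bubble topologies are not modelled because the
phasing math uses components only.

The generator's defaults are the conditions under which the acceptance
properties are stated: 22 autosomes plus X and Y, 96 libraries (one typical
preparation run), 5 unitigs per haplotype and chromosome, phase depth 20,
all-reads multiplier 2, background 0.05, misorientation rate 0.10. Values
the model itself does not pin down were fixed once at realistic levels:
20% homozygous unitigs per autosome, lognormal unitig lengths with median
1 Mbp (floored at 100 kbp), and a low-quality library class with 6x
background and half depth, mirroring the distinction between high-quality
and noisier libraries in real preparations. At these sizes (about 274
unitigs x 96 libraries) a full pipeline run takes a couple of seconds, and
the test suite's ten-seed parameter-recovery studies and the 14-run
library-quality titration complete in about a minute together.

What passing these tests does *not* show: the generator draws counts from
clean Poisson models with library-independent states, contains no mappability
structure, no chimeric or switch-error unitigs, no fragmented short-unitig
tail, and its graph has no bubbles or tangled repeat structure beyond the
synthetic rDNA-style fixtures in the unit tests. Results on real assemblies
depend on alignment quality and assembly correctness in ways the simulation
cannot certify; the degenerate-background invariance is exact, but real
degenerate sequence is not uniformly distributed over libraries.

## Numerical and degenerate-input choices

* Zero-signal (all-zero SSF) unitigs are excluded from clustering and
  orientation (cosines are undefined there), reported, and flagged.
* Similarities are clamped to [0, 1] and distances floored at 0 to absorb
  floating-point excursions.
* Clusters with fewer than two non-zero phase vectors, a singular second
  principal component outside the haploid path, or a cancelling
  size-weighted mean are unphasable: their unitigs are `UNASSIGNED` and the
  cluster is flagged rather than failing the run.
* All stochastic stages run under a single configured seed; identical
  inputs and configuration give byte-identical outputs, including the
  operation history.

## Known limitations

Diploid genomes only; extending to higher ploidy would change the plane
geometry fundamentally. Switch errors present in the input assembly
propagate to the haplotypes — detecting them is a natural extension the
strand-state signal supports but this package does not implement. Heavily
fragmented assemblies stress the similarity thresholds; the batching keeps
the cost quadratic in the batch, not the assembly. The internal caller is
deliberately simple; for production scaffolding the marker table should go
to a graph-threading tool that can exploit topology.
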