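# unitigphaser

Haplotype phasing of diploid assembly graphs from single-cell strand
sequencing (Strand-seq) evidence.

A diploid assembler leaves each graph node (unitig) unlabeled: haplotype A,
haplotype B, or collapsed homozygous sequence. Strand-seq resolves this from
a single sample, with no parental data and no reference genome: each
single-cell library retains one template strand (Watson, W, or Crick, C)
per chromosome homolog, chosen independently with probability 1/2, so the
orientation of a library's alignments on a unitig reveals which strand its
homolog retained in that cell. `unitigphaser` implements the complete
engine from per-library W/C alignment counts to per-unitig haplotype marker
counts ready for a graph-threading scaffolder — plus a synthetic Strand-seq
generator so every stage is testable at desk scale.

For a unitig with `w` Watson and `c` Crick reads in a library, the
strand-state frequency is

```
SSF = (w - c) / (w + c)
```

close to ±1 when the homolog pair inherited matched strands (WW/CC) and
close to 0 when unmatched (WC/CW). The vector of SSF values over libraries
is the fingerprint everything else operates on:

1. **Chromosome clustering** — batched agglomerative clustering under
   absolute cosine similarity `|cos(a,b)|` (insensitive to misorientation
   and to uniform degenerate-sequence background), with connected-component
   aware merging, rDNA-tangle excision, a 50 kbp length filter, and
   contiBAIT-style library/unitig QC.
2. **Orientation correction** — per cluster, two-way hierarchical
   clustering of the unitig vectors together with their negated copies
   under signed-cosine distance; the antipodal bisection identifies
   misassembled reverse-complement unitigs, whose W/C counts are swapped.
3. **Phase geometry** — per cluster, an uncentered PCA of the
   phase-informative SSF vectors spans the "chromosome plane"; the cluster
   direction `v_clust` (length-weighted mean vector) rotated 90° in the
   plane gives `v_phase`, whose non-zero entries mark the
   phase-informative libraries and whose signs align their W/C labels.
   Haploid chromosomes (X/Y) are detected by their one-dimensional ray
   signature (PC1 > 70%, PC2 < 20% explained variance), merged, and
   re-balanced so `v_clust` bisects the two chromosome rays.
4. **Marker pooling and calling** — W/C counts of `v_phase = -1` libraries
   are swapped, then dotted with `|v_phase|`, giving (hapA, hapB) marker
   counts per unitig; the marker table feeds graph-threading tools, and a
   built-in fallback caller labels unitigs
   `HAP_A`/`HAP_B`/`HOMOZYGOUS`/`UNASSIGNED`.

See `vignettes/strandseq-graph-phasing.Rmd` for the full model, parameter
meanings, and design rationale.

## Worked example

Simulate a small male genome (3 autosomes + XY, 48 libraries, planted
misorientations and background noise), run the pipeline, and inspect:

```r
library(unitigphaser)

sim <- simulate_strandseq(sim_config(
  n_autosomes = 3, n_libraries = 48, unitigs_per_haplotype = 4, seed = 11
))
run <- run_pipeline(sim$graph, sim$counts_all, sim$counts_phase)

glance(run)
#> # A tibble: 1 × 16
#>   n_unitigs_input n_unitigs_length_filtered n_libraries_retained
#>             <int>                     <int>                <int>
#> 1              38                         0                   48
#>   n_unitigs_qc_retained n_unitigs n_clusters n_unclustered n_zero_signal
#> 1                    38        38          4             0             0
#>   n_operations n_haploid n_unphasable n_hap_a n_hap_b n_homozygous n_unassigned
#> 1           34         1            0      16      16            6            0

head(tidy(run))
#> # A tibble: 6 × 8
#>   unitig   cluster flip  flagged hap_a hap_b call       component
#>   <chr>      <int> <lgl> <lgl>   <dbl> <dbl> <chr>          <int>
#> 1 utg_1_01       1 FALSE FALSE     414     7 HAP_A              1
#> 2 utg_1_02       1 FALSE FALSE     513    12 HAP_A              1
#> 3 utg_1_03       1 FALSE FALSE     491    13 HAP_A              1
#> 4 utg_1_04       1 FALSE FALSE     431    13 HAP_A              1
#> 5 utg_1_05       1 FALSE FALSE     233   231 HOMOZYGOUS         1
#> 6 utg_1_06       1 FALSE FALSE     242   242 HOMOZYGOUS         1
```

`n_clusters = 4` is the 3 autosomes plus the merged X+Y haploid cluster;
haplotype-A unitigs pool ~400–500 markers against single-digit
contamination, while homozygous unitigs show the expected balanced counts.
Comparing to the planted truth:

```r
clustering_recovery(run$clustering, sim$truth_unitigs)
#>     ari n_clusters n_unclustered
#> 1     1          5             0
call_accuracy(run$phasing$markers, sim$truth_unitigs)
#>   accuracy accuracy_n n_unassigned
#> 1        1          1            0
```

`autoplot(run)` draws the hapA-vs-hapB marker blob plot,
`autoplot(run$ssf_all)` the SSF heatmap, and `plot_phase_plane(run, 1)` a
cluster's chromosome plane. `write_phase_run(run, "out/")` writes every
stage table (`clusters.tsv`, `orientation.tsv`, `geometry.tsv`,
`marker_counts.tsv`, QC and SSF tables, `summary.json`); the
`marker_counts.tsv` columns `node`/`hapA_markers`/`hapB_markers` are the
hand-off to graph threading.

Real inputs enter the same way: `read_gfa()` for the assembly graph, count
TSVs or per-library SAM/BAM (`read_strandseq_alignments()` +
`filter_mem_alignments()`) and bwa-fastmap text (`read_fastmap()` +
`filter_single_smem()`) for the two evidence channels. A thin command-line
wrapper covers the same flow:

```sh
Rscript inst/cli/unitigphaser.R simulate --seed 1 --out simdir
Rscript inst/cli/unitigphaser.R run --gfa simdir/sim.gfa \
  --counts-all simdir/counts_all.tsv --counts-phase simdir/counts_phase.tsv \
  --out outdir
```

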