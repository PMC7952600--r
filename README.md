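# genotag

Joint single-cell DNA genotyping and antibody-tag (surface-protein)
profiling for droplet experiments.

Targeted single-cell DNA platforms can co-capture oligonucleotide-tagged
antibodies, so each droplet yields both a genotype over a panel of amplified
loci and an immunophenotype over a panel of surface markers. This matters in
leukemia, where malignant blasts are heterogeneous in both domains at once:
mutationally identical cells can span an immunophenotypic continuum, and
phenotypically identical blasts can carry different driver mutations.
`genotag` processes such experiments end to end and quantifies how well the
two domains correspond — per patient, per timepoint, per clone.

The pipeline, stage by stage:

1. **Read parsing** — combinatorial cell barcodes from Read 1 (fixed-layout
   schema, per-segment whitelist correction at Hamming distance ≤ 1,
   ambiguous matches discarded); 8 bp antibody tags + 10 bp UMIs from
   Read 2 (tags corrected at distance ≤ 1 against a panel with pairwise
   distance ≥ 3; UMI bases required to be Phred ≥ 20).
2. **UMI deduplication** — the adjacency network rule: UMI *b* merges into
   *a* when they differ by one substitution and
   count(*a*) ≥ 2·count(*b*) − 1; molecules are counted greedily by
   descending read count.
3. **Cell calling** — barcode-rank knee (max distance to chord in log–log
   space) AND ≥ 60% of amplicon intervals covered by ≥ 8 reads AND ≥ 100
   antibody UMIs with isotype-control count ≤ 5× the experiment median.
4. **Genotype condensation** — per-cell calls coded 0/1/2/3 (wild type,
   het, hom-alt, no call), with GQ < 30 or DP < 10 demoted to no-call;
   clone labels are combined variant calls over the relevant loci
   (het/hom-alt merged in patient mode to absorb allele dropout).
5. **Antibody correction** — for log(c+1) counts, OLS regression on the
   leading left-singular vectors of the z-scored log quality matrix
   *q* (total antibody reads, deduplicated totals, IgG1 count, amplicon
   reads); residuals **u**_j are the corrected signal.
6. **Embedding and clustering** — PCA → SNN graph → Leiden (modularity,
   resolution 1 or 0.1) and a UMAP layout (15 neighbors, 16 PCs,
   min_dist 0.2/0.1), all seeded and exactly reproducible.
7. **Concordance** — adjusted Rand index
   (Σ C(n_xy,2) − E) / (½[Σ C(a_x,2) + Σ C(b_y,2)] − E) and uncertainty
   coefficient U(X|Y) = I(X;Y)/H(X) between clone labels and phenotype
   clusters.
8. **Gradient analysis** — SVD of the blast-cluster rows of **u**, cells
   ordered by the second left-singular vector; moving-window (200-cell)
   profiles of markers and clone fractions, Pearson/Kendall trend
   statistics, and a cubic spline tracing the gradient in the embedding.

A first-class synthetic-data module (`simulate_truth()`,
`emit_antibody_reads()`, `emit_dna_fixtures()`, `scenario_bundled()`)
generates complete experiments — FASTQ pairs, depth tables, multi-sample
VCFs, and the ground truth behind them — so every stage is testable
offline.

## Worked example

Run the bundled three-population scenario (two mutually exclusive mutant
clones plus a wild-type blast-like population, ~1,000 cells) end to end:

```r
library(genotag)
run <- run_all(list(input = list(scenario = list(n_cells = 1000)),
                    outdir = "demo_run", seed = 1))
length(run$cells)
#> [1] 755
run$concordance
#>  n_cells       ari u_genotype_given_cluster u_cluster_given_genotype applicable
#>      693 0.9824816                0.9696099                0.9705585       TRUE
clone_fractions(run$clone_labels[!is.na(run$clone_labels)])[, c("clone", "n", "percent")]
#>   clone   n  percent
#>  mut:wt 279 40.25974
#>   wt:wt 216 31.16883
#>  wt:mut 198 28.57143
```

755 of 1,000 planted cells pass the knee/coverage/antibody filters (the
knee rule is deliberately conservative on dispersed depth distributions).
Among the 693 cells with confident calls at both loci, phenotype clusters
recover the planted clones almost perfectly: ARI 0.98 between clone labels
and Leiden clusters, and ~97% of the information in a cell's genotype is
predictable from its cluster (and vice versa). The clone table shows the
recovered mutant fractions; `mut:wt` is the clone mutated at the first
locus only.

`demo_run/` then contains the QC table, coded genotype matrix, corrected
antibody matrix, cluster/embedding coordinates, concordance report,
gradient profiles and a JSON manifest that fully specifies the run. The
same pipeline is scriptable from a shell via `inst/cli/genotag.R`
(`run` and `stage <name>` subcommands, YAML configuration).

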