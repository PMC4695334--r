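# smadcontext

Two cell populations carrying the same signalling machinery can respond to
the same cue with largely different transcriptional programs. `smadcontext`
implements an integrative two-condition analysis for dissecting one such
case: context-specific TGF-β/SMAD3 responses in breast-tumor-initiating
cell (BTIC) models, where the question is whether a gene's
condition-specific response is explained by differential SMAD3 binding,
by a permissive epigenetic configuration (open chromatin or promoter
hypo-methylation), by both, or by neither.

The package is aimed at computational epigenomics users who have called
peaks (e.g. MACS/SICER output), window-level read counts for chromatin
marks and DNA methylation, and a treated-vs-control expression time
course, for two conditions — and who want the full gene-level taxonomy
rather than a per-peak differential list. A fully seeded synthetic-data
generator with planted ground truth is included, so every stage is
validated end-to-end at known truth.

## The analysis

For each gene *g* with transcription start site TSS and body
[start, end), two windows are derived (all coordinates 0-based
half-open):

- **gene-proximal**: from 1,500 bp upstream of the TSS to the gene body
  end — the space in which a TF peak counts as belonging to the gene;
- **TSS-proximal**: TSS ± 1,500 bp — used only for DNA methylation.

The stages are:

1. **Responsive-gene calling.** Per condition and time point t ∈
   {1, 3, 6, 24} h, treated vs control log2 expression is tested
   (moderated t by default; Welch available), BH-adjusted; a gene is
   responsive at FDR < 0.1. At each time point the universe partitions
   into A-unique, B-unique, shared and independent sets; genes responsive
   in neither condition at any time form the TGF-β-independent
   background.
2. **Peak comparison.** Peaks of the two conditions are matched
   one-to-one: a pair is *shared* when the summit of either peak lies in
   the other peak's interval (greedy resolution by summit distance);
   the rest are condition-unique. Summit-centred 5-kb occupancy matrices
   support the usual occupancy heat maps.
3. **Binding modes.** Per gene, gene-proximal matches are counted by
   status (n<sub>unique A</sub>, n<sub>unique B</sub>, n<sub>shared</sub>)
   and the gene is placed in one of four modes — bound in A only (1),
   B only (2), both (3), neither (4) — with mode 3 refined into
   *identical*, *mixed* and *mutually-exclusive* occupancy categories.
   Mode enrichment of any gene set over the background is tested by 2×2
   chi-square (no continuity correction), BH across the four modes.
4. **Differential chromatin.** Per factor (SMAD3, H3K4me3, H3K27ac,
   Pol II, H3K27me3, DNA methylation) window counts are compared between
   conditions — edgeR's exact NB test with replicates, the classic
   two-library exact binomial test without — calling `higher_A` /
   `higher_B` at FDR < 0.05 and |log2FC| ≥ 1. From these calls come, per
   condition, the **SMAD3-high**, **open-chromatin-high** (union over
   H3K4me3/H3K27ac/Pol II) and **hypo-methylation** (lower TSS
   methylation) gene sets; set-vs-set over-representation uses the
   one-sided hypergeometric test.
5. **Context classification.** Every context-specific responsive gene is
   labeled: `epigenome_assisted` (SMAD3-high ∧ an epigenetic set),
   `epigenome_directed` (¬SMAD3-high ∧ an epigenetic set), `smad3_only`,
   or `unexplained`.

## Worked example

```r
library(smadcontext)

exp <- simulate_experiment(simulation_config(seed = 42))
res <- analyze_experiment(exp)

head(res$profiles[res$profiles$mode == 3, ], 3)
#>     gene_id n_unique_a n_unique_b n_shared mode  category
#> 2 gene_0002          0          0        2    3 identical
#> 3 gene_0003          0          3        2    3     mixed
#> 4 gene_0004          0          0        2    3 identical

classification_summary(res$classification)
#>   context              label  n
#> 1       a epigenome_assisted 61
#> 2       b epigenome_assisted 61
#> 3       a epigenome_directed 44
#> 4       b epigenome_directed 56
#> 5       a         smad3_only 12
#> 6       b         smad3_only 11
#> 7       a        unexplained 44
#> 8       b        unexplained 55

subset(res$mode_enrichment, set_label == "a_unique_t24")
#>       set_label mode  fold chisq        p      fdr
#> 13 a_unique_t24    1 2.915  63.3 1.77e-15 7.07e-15
#> 14 a_unique_t24    2 0.155  14.7 1.29e-04 1.72e-04
#> 15 a_unique_t24    3 1.445   7.3 6.91e-03 6.91e-03
#> 16 a_unique_t24    4 0.373  47.0 7.07e-12 1.41e-11
```

Reading the enrichment table: genes uniquely responsive in condition A at
24 h are ~2.9-fold enriched for A-only SMAD3 binding (mode 1) and
~1.4-fold for common binding (mode 3) over the TGF-β-independent
background, and depleted for B-only and unbound modes — the signature of
late responders driven partly by condition-unique binding and partly by
epigenetic differences at commonly bound genes.

Because the inputs are synthetic, recovery can be scored against truth:

```r
rep <- truth_vs_result_report(exp$truth, res)
rep$mode$accuracy            #> 1
rep$context_label$accuracy   #> 0.968
```

`run_pipeline(simulation_config(seed = 42), "out/")` runs the same
stages and writes the nine result tables plus a run manifest;
`inst/scripts/smadcontext-cli.R` wraps `simulate` and `run-all` for
shell use, with a YAML config.

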