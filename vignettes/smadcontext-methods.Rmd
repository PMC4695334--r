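---
title: "Methods: two-condition SMAD3 response analysis with epigenome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition SMAD3 response analysis with epigenome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smadcontext)
```

# The question and the model

Two conditions (think of two breast-tumor-initiating-cell models with
opposite TGF-β responses) share a signalling pathway whose effector,
SMAD3, binds chromatin after pathway activation. A gene that responds to
the cue in one condition but not the other could do so because SMAD3
binds it only there (*differential binding*), because the local
epigenome — open-chromatin marks, promoter DNA methylation — licenses
the response only there (*epigenome-directed*), or because both layers
differ (*epigenome-assisted*). `smadcontext` formalizes that taxonomy as
a deterministic rule over three differential gene sets and applies it to
every context-specific responsive gene.

The pipeline assumes:

* genes are single transcriptional units (multi-isoform annotations are
  collapsed to the union span before analysis; the collapsed TSS is the
  most-upstream one);
* TF regulation acts gene-proximally — a peak matters for a gene when it
  overlaps the window from 1,500 bp upstream of the TSS to the gene body
  end; DNA methylation matters only within TSS ± 1,500 bp;
* expression is measured as approximately Gaussian log2 intensities with
  at least two replicates per (condition, treatment, time) cell;
* window counts for chromatin factors are negative-binomial-like, with a
  genome-wide library size per sample.

# Coordinate conventions

All intervals are 0-based half-open (BED convention). The TSS of a `-`
strand gene is the base `end - 1`. The gene-proximal window is
`[start - 1500, end)` on `+` and `[start, end + 1500)` on `-`, clipped to
the chromosome. The TSS-proximal window is `[TSS - 1500, TSS + 1500)` on
`+` and `[TSS - 1499, TSS + 1501)` on `-`: the one-base shift keeps the
3,000-bp window symmetric about the TSS base on either strand. The same
formulas are used everywhere (window derivation, peak placement in the
generator, per-base membership tests), so strand reflection through the
chromosome midpoint maps windows onto each other exactly — a property the
test suite exercises directly.

# Peak sharedness

Published peak callers disagree on peak widths far more than on summit
placement, so "same binding site" is defined summit-first: peaks *a* and
*b* are candidate mates when the summit of either lies inside the other's
interval; candidates resolve to a one-to-one matching greedily by summit
distance, ties broken by input order, and unmatched peaks are
condition-unique. The criterion is symmetric in the two conditions and
robust to a narrow-vs-broad caller mismatch. A plain ≥ 1 bp
interval-overlap criterion is available (`criterion = "overlap"`) for
users who prefer the permissive classic rule. Peaks without a called
summit (BED6 input, or narrowPeak column 10 equal to −1) use the interval
midpoint.

Binding modes are then a function of per-gene counts of unique-A,
unique-B and shared matches: bound in A only (1), B only (2), both (3),
neither (4), where "bound in A" means at least one A-unique *or* shared
match. Mode 3 is refined by occupancy category: `identical` (shared
matches only), `mixed` (shared plus unique), `mutually_exclusive` (unique
on both sides, none shared). Note a gene with unique peaks on both sides
but no shared match is mode 3 — commonly bound, at different sites.

# Statistical choices

**Responsive genes.** Default: limma's moderated t on treated vs control
log2 values per (condition, time), BH across genes, responsive at
FDR < 0.1. A plain Welch t is available (`method = "welch"`). The
moderated default is a deliberate design choice: at realistic replicate
counts (n = 3) the Welch test's ~4 residual degrees of freedom put even
clean 4-fold effects at p ≈ 10⁻², which is not reliably below a BH
threshold when responders are a minority of the universe; variance
moderation recovers the lost power without inflating the null (the null
p values stay KS-uniform, which the acceptance suite checks).

**Differential chromatin.** With replicates, edgeR's exact
negative-binomial test with empirical dispersion estimation — the
standard differential-binding test for window counts; a Welch t on
log2(CPM + 0.5) is retained as an option. Without replicates, the classic
two-library exact binomial conditional test: countA vs countA + countB
with success probability libA/(libA + libB). The reported log2 fold
change is always `log2((mean CPM A + 0.5) / (mean CPM B + 0.5))`, so
swapping conditions negates it exactly. Direction calls require both
FDR < 0.05 and |log2FC| ≥ 1; the effect floor emulates calling only the
most pronounced signal differences and is configurable.

**Enrichment.** Binding-vs-response enrichment uses the 2×2 Pearson
chi-square without continuity correction against the
TGF-β-independent background (genes responsive in neither condition at
any time point — a conservative, global background definition), with a
`low_expected` flag when any expected cell drops below 5, and BH across
the four modes. Set-in-set over-representation uses the one-sided
hypergeometric tail, reported separately per direction so the two
conditions can be displayed on a bi-symmetrical axis. A degenerate 2×2
table with an empty margin is defined as "no evidence" (statistic 0,
p = 1) rather than NaN.

**Degenerate inputs.** Zero variance in both expression groups gives
p = 1 at zero mean difference and p = 0 otherwise (the noise-free limit);
the moderated path falls back to this rule when every residual variance
is zero, and the edgeR path falls back to a near-Poisson dispersion when
the empirical dispersion fit degenerates on constant replicates. These
limits make the zero-noise identity check exact.

# The synthetic-data generator

The generator emulates the *structure* of the real study: two conditions,
four expression time points (1, 3, 6, 24 h) with control and treated
arms, TF peak sets per condition, and window counts for six factors. Its
defaults are the package's study conditions and are deliberately fixed:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | genes on a 2-chromosome toy genome, one 20-kb slot each |
| `expr_log2fc`, `expr_sigma`, `expr_reps` | 2, 0.5, 3 | planted response size, Gaussian noise sd, replicates |
| `class_fractions` | 0.15/0.15/0.10/0.60 | A-unique/B-unique/shared/independent genes |
| `p_early` | 0.4 | responders with onset 6 h (rest 24 h) |
| `nb_mean_low`, `nb_mean_high`, `nb_size` | 50, 200, 20 | NB window-count means (a 4-fold state difference) and dispersion |
| `count_reps` | 3 | count replicates per condition |
| `jitter` | 50 | max shift (bp) of the B copy of a shared peak |
| `peak_fp_rate`, `peak_fn_rate` | 0, 0 | spurious/dropped peak rates |

Context genes carry a planted label with onset-specific fractions
(early: 20% assisted / 50% directed / 5% SMAD3-only / 25% unexplained;
late: 50/25/5/20) — so early responders are dominated by commonly bound,
epigenome-coupled genes and late responders by condition-unique binding,
the qualitative structure the mode-enrichment stage should report. The
label dictates the rest of the planting: assisted and SMAD3-only genes
get own-condition-unique peaks (mode 1/2) and a high SMAD3 count state in
their condition; directed genes get identical shared peaks and equal
SMAD3 states; the epigenetic difference routes through an open mark, TSS
methylation, or both (0.4/0.3/0.3). Count magnitudes (CPM ≈ 50–200 over
multi-kb windows at a 10⁶ library) were chosen once as realistic
window-count scales.

Each output family (structure/truth, peaks, counts, expression) draws
from its own RNG stream derived from the master seed (offsets 0–3 on R's
default Mersenne-Twister), so regenerating one family never perturbs the
others. Peak placement splits each gene-proximal window into equal bins,
one peak per bin with a margin wider than the jitter, which guarantees
that jittered shared copies still satisfy the summit criterion and that
mutually exclusive unique peaks never collide; a window too small for the
requested peaks is an error naming the gene.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level noise and peak-caller artefacts
(peaks appear as intervals, not as alignments), copy-number and
mappability biases in window counts, CpG-density-dependent methylation
signal, correlated marks at shared regulatory elements, isoform and
alternative-promoter structure, and any dependence between expression
noise and chromatin state. Recovery rates on synthetic data are
upper bounds, not field performance claims.

# Validation design and problem sizes

The acceptance suite runs, at fixed seeds: 100 random instances each of
peak matching and proximal assignment against O(n·m) brute-force scans
(≤ 200 peaks, ≤ 50 genes); the chi-square closed form on a fixed 2×2
table and the hypergeometric tail against exhaustive enumeration over
every universe ≤ 25; 1,000 null replicates of mode enrichment (600
genes, 150-gene sets) checking the empirical type-I error at 0.05, plus
a KS uniformity check of null differential-expression p values (2,000
genes); full recovery on the 1,000-gene default configuration; a planted
mode-by-onset enrichment structure (800 genes); hand-built archetype
genes (identical binding + methylation difference ⇒ directed;
unique binding + methylation difference ⇒ assisted); and the zero-noise
identity at 1,000 genes. Unit tests use 100–150-gene simulations. These
sizes keep the whole suite around a minute while leaving every statistic
in its well-calibrated regime.

# Known limitations

* The pipeline is strictly two-condition; multi-condition designs need
  pairwise runs.
* Distal (enhancer-space) TF binding is out of scope; only gene-proximal
  and TSS-proximal windows are analysed.
* The `unexplained` label is reported but not interpreted: it covers
  genes whose context-specificity is not captured by any of the three
  differential sets at the chosen thresholds, which includes
  false-negative differential calls.
* With a single count column per side, the exact binomial test assumes
  Poisson sampling; biological overdispersion will inflate its
  significance, which is why the effect-size floor is kept in place.
* The classification is associative, not causal: an epigenome-directed
  label identifies a coupled epigenetic difference, not a demonstrated
  mechanism.
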