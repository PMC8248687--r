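---
title: "Methods: mapping activity-induced DNA breaks against transcription"
author: "breakscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping activity-induced DNA breaks against transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

γH2AX — H2AX phosphorylated at Ser139 — spreads over kilobase-to-megabase
domains around DNA double-strand breaks, so γH2AX ChIP-seq signal over gene
bodies proxies where breaks occur. In brain tissue after a learning
stimulus, the genes with the most γH2AX are also the most transcribed, and
stimulus-induced genes are highly transcribed by definition. Any claim that
induced genes break *more than expected* therefore has to control for
expression. This package implements that control (an expression-matched
permutation test) together with the quantification, peak-calling,
annotation, grouping, enrichment and motif steps such a study needs.

## Coordinate and container conventions

All genomic data live in `GenomicRanges::GRanges` (1-based, closed — the
Bioconductor convention). BED and bedGraph are 0-based half-open and are
converted at the I/O boundary; GTF is 1-based inclusive and maps directly.
Interval lengths, overlap lengths and merge gaps are identical under either
convention, so no statistic depends on the choice. Overlap computations are
strand-blind throughout; strand is used only to locate TSSs. Chromosome
names are matched by exact string equality — no "chr" aliasing — so fixture
mistakes surface as missing-chromosome warnings instead of silent zeros.

## Signal quantification

`gene_body_signal` integrates track density over each gene body (introns
and exons): mass = Σ value×covered-bp, mean density = mass / length, and an
RPKM-equivalent using the total track mass as library size. `rpkm` is the
standard count / (kb × millions) form. The tissue-weighted expression scale
used for whole-tissue comparisons is 0.6·FPKM⁺ + 0.4·FPKM⁻ by default,
reflecting the approximate 60/40 neuronal/non-neuronal composition of the
bulk tissue the γH2AX ChIP was performed in; both weights are arguments.

`percentile_bins` ranks genes by expression into near-equal quantile bins
(ties broken by stable gene-id order; remainder genes go to the lowest
bins) and summarises a companion value per bin — the display behind
"break signal rises with expression percentile". `aggregate_profile`
averages signal in fixed-width bins around anchor midpoints (defaults
flank 2000 bp, bin 50 bp, deepTools-like; the upstream work does not state
its window, so both are exposed) and reports the apex bin, ties taking the
lower index. `marker_aggregate_score` summarises marker-set expression as a
geometric mean (pseudocount 0.01 FPKM, since a geometric mean is undefined
at zero) followed by a row Z-score with the population (n) standard
deviation; zero-variance rows are flagged rather than raised as errors,
matching heat-map semantics.

## Peaks

`call_broad_peaks` is a deliberately simple, fully documented surrogate for
a broad-peak caller: fixed windows (200 bp default), a Poisson upper-tail
p-value of each window's signal mass against the genome-wide mean rate, and
merging of significant windows within `max_gap` (1 kb default). It applies
the cutoff to the raw Poisson p rather than a q-value, because the
surrogate's calibration differs from a local-background caller anyway;
externally called peaks in BED form can be substituted at every point that
consumes peaks. The two-tier step — the procedure of interest — retains
relaxed-threshold peaks (cutoff 0.1) that overlap stringent ones (cutoff
1e-5), capturing broad domain extents with stringent confidence.

Peak-to-gene annotation uses "≥ 50% of the **peak** covered by the gene",
boundary inclusive, mirroring `bedtools intersect -f` semantics on the peak
file. Whether the 50% should be measured on the peak or the gene is
genuinely ambiguous in this analysis tradition, so both the fraction and
the direction are arguments. One peak may annotate to several genes.
`nearest_gene` assigns each site to the gene with the closest TSS on the
same chromosome (cross-chromosome distances are meaningless), with the
distance signed by gene strand (positive = downstream) and exact ties
broken by lexicographically smaller gene id for determinism.

`scan_pwm` scores every window on both strands as Σ log2(p_i(base)/bg(base))
in bits, skips windows containing non-ACGT characters, and refuses PWMs
with zero probabilities (regularise with a pseudocount; 0.01 is the default
in `pwm_from_consensus`). Uniform background is the default.

## Statistics

- `filter_expressed`: FPKM strictly > 0.2 in at least one time point — the
  strict inequality follows the wording of the filter it reproduces.
- `classify_differential_grouping`: "up in a fraction" means padj < 0.05
  and log2FC > 0 at any time point. Categories are neuron-only up, shared
  up, non-neuron-only up, down, ns. A gene significantly up in one fraction
  and down in the other is categorised by the up-call: the four-way scheme
  is mutually exclusive and an induction anywhere is the biologically
  salient event. `glia_only_fraction` computes the percentage of responsive
  genes regulated only in glial populations, rounded half-up.
- `hypergeometric_overlap` is the inclusive upper tail P(X ≥ k);
  `ora_gene_sets` applies it per gene set over an expressed background with
  BH correction across sets (default report cutoff q ≤ 0.01). BH itself is
  `stats::p.adjust(method = "BH")` behind a validating wrapper; the test
  suite checks it against an independently written step-up.

### The expression-matched permutation test

Bin edges are the n_bins-quantiles of the **target** expression (default
n_bins = 10; the binning scheme is not fully specified upstream, so it is
exposed), extended to ±∞ at the extremes so every universe gene belongs to
a bin. Each of n_perm iterations draws, per bin and without replacement
from that bin's universe stratum, exactly the bin's target count; the null
distribution is the mean signal of the pooled draws. The tail rule is
inclusive (≥) by default for conservatism, with strict (>) available; both
are recorded in the output. The fraction rule can return p = 0, so the
(k+1)/(n+1) estimator is always reported alongside. All draws come from a
single seeded generator consumed in sorted bin order, making results
reproducible to the byte. Preconditions are enforced with actionable
errors: targets ⊆ universe, n_bins ≤ |targets|, and every stratum at least
as large as its required draw (otherwise: use fewer bins).

Matching diagnostics report the per-bin counts and the null-vs-target mean
expression on two scales. The arithmetic mean FPKM is the conventional
diagnostic but is dominated by the few most-expressed genes when expression
spans several orders of magnitude: for ~100 targets drawn from a log-normal
universe its own sampling noise exceeds 5–30% even under *exact*
distributional matching, so run-to-run arithmetic differences of that size
are expected and not evidence of poor matching. The log-scale
(geometric-mean-like) difference is the informative diagnostic; on the
synthetic conditions used in the tests it stays below ~3% on every run.
This is a known limitation of mean-FPKM equivalence displays in general.

### What the calibration shows — and assumes

Binned matching is exact only within bins. If the break signal were a
near-deterministic function of expression *and* targets occupied a
different within-bin distribution than their strata (e.g. a hard
expression-threshold target set), the discretisation bias would make the
test anti-conservative; with 10 bins this is visible in simulation. Real
target sets arise from differential-expression detection, whose power is a
smooth, saturating function of expression, and real γH2AX signal has large
gene-level variability unexplained by expression — both of which the
generator emulates (see below). Under those conditions the test is
calibrated to a good approximation, but not exactly: because the selection
propensity increases with expression, targets sit slightly above their
stratum's average *within* every bin, so the observed mean is very mildly
favoured. Across independent 200-replicate null campaigns the fraction of
p < 0.05 ranges about 0.05–0.09 and the mean p about 0.42–0.47; a KS test
against uniformity detects the residual tilt in some campaigns and not in
others. This within-bin selection tilt is intrinsic to quantile-binned
matching — the real analyses it mirrors share it — and shrinks with more
bins at the cost of stratum depletion. For sharply selected target sets or
a tight signal–expression relation, increase `n_bins` and check the
matching diagnostics.

## The synthetic-data generator

`sim_config` defaults define the emulated study: 2000 genes of 1–10 kb on 4
chromosomes plus one gene-free background chromosome; baseline FPKM
log-normal (`rlnorm(meanlog = 1, sdlog = 1.5)` — median ≈ 2.7 FPKM and a
dynamic range of several orders of magnitude, giving the rank structure the
percentile analyses need); negative-binomial counts (dispersion 0.05, 4
replicates per fraction × condition, ~2M fragments); 100 induced genes with
mean log2FC 2 in the stimulated conditions of their designated fractions
(60% neuron-only / 10% shared / 30% non-neuron by default). Induced genes
are drawn with a logistic propensity in log expression
(`plogis((log FPKM − log 2)/0.7)`): upregulated-gene sets in practice come
from padj thresholds, and detection power rises smoothly and saturates with
expression — a hard eligibility cutoff would be both unrealistic and
distributionally pathological for matching. FPKM is computed with
median-of-ratios size factors, since raw-library normalisation lets a
handful of strongly induced genes deflate every other gene in stimulated
samples (the composition bias the standard DE tools correct). DE calls use
a limma-trend moderated t-test per fraction and time point; with 4
replicates an unmoderated test has far less power than the moderated
analyses these tables emulate.

The γH2AX track has gene-body density
`base_density × (1 + gamma_slope·log1p(weighted FPKM)) × gene-level
log-normal factor (sd 0.6) × excess_delta (induced genes)`, background 0.05
reads/bp elsewhere, emitted as 200-bp bins with Poisson counts. The
gene-level factor encodes that real break propensity varies with domain
size, topology and chromatin beyond expression; per-bin Poisson noise alone
would make signal an almost deterministic function of expression, which
real data are not. `excess_delta = 1` is the null. Binding-site simulation
plants a consensus motif in a stated fraction of uniform-base site
sequences near the TSSs of a designated (by default glia-induced) subset.

What the generator does **not** emulate: read-level artifacts (mappability,
GC, duplicates), fragment-size effects, batch effects, inter-gene
correlation of expression, and broad-domain spreading beyond gene bodies.
Passing tests therefore validate the statistical machinery and its
calibration under the stated generative model, not robustness to those
real-data phenomena.

## Pipeline, sizes and numerical choices

`run_pipeline` executes simulate (or load) → quantify → peaks → stats,
writes every intermediate, and emits `report.json`/`report.md` plus a
`MANIFEST` of completed stages; identical config + seed gives byte-identical
reports. Test and acceptance campaigns use 200 null replicates at 2000
genes / 100 targets / 500 permutations, 20 replicates per effect size at
5000 genes / 150 targets / 1000 permutations, and 20 peak-recovery datasets
at 300 genes — sizes chosen so each campaign gives stable estimates while a
full run stays within a few minutes on one CPU. Fractional window masses in
the Poisson caller are rounded up to the next count (conservative);
`-log10 p` scores are capped at 1000; degenerate inputs (empty tracks,
flat expression, zero-variance marker rows) return empty or flagged results
rather than errors where a downstream display would tolerate them, and
errors with instructions where they would not.
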