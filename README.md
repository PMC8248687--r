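# breakscan

Neuronal activity breaks DNA. Learning paradigms such as contextual fear
conditioning induce DNA double-strand breaks (DSBs) at rapidly transcribed
genes in the brain, and γH2AX ChIP-seq — the phosphorylated histone variant
deposited in broad domains around each break — is the standard genome-wide
readout. The statistical difficulty is a strong confound: γH2AX signal rises
with transcription, and stimulus-induced genes are by construction highly
transcribed. `breakscan` implements the computational pipeline for this kind
of study, for epigenomics analysts who have gene-level signal and expression
tables rather than raw reads:

- gene-body and peak **RPKM quantification** from bedGraph signal tracks
  (`gene_body_signal`, `rpkm`);
- a **two-tier broad-peak workflow**: peaks called at a stringent and a
  relaxed threshold, keeping relaxed extents supported by a stringent call
  (`call_broad_peaks`, a documented Poisson-window surrogate for a broad
  caller — externally called peaks in BED are accepted anywhere —
  and `two_tier_filter`), then annotated to genes by a ≥50% overlap rule
  (`annotate_peaks_to_genes`);
- **cross-fraction differential grouping** of responses in sorted neuronal
  (NeuN+) and non-neuronal (NeuN−) nuclei
  (`classify_differential_grouping`, `glia_only_fraction`);
- **gene-set statistics**: hypergeometric overlap tests and GMT-based
  over-representation with Benjamini–Hochberg correction
  (`hypergeometric_overlap`, `ora_gene_sets`, `bh_adjust`);
- **motif and site tools**: PWM log-odds scanning on both strands
  (`scan_pwm`), single-nearest-gene TSS annotation (`nearest_gene`) and
  anchored aggregate signal profiles with apex localisation
  (`aggregate_profile`);
- the headline statistic, an **expression-matched permutation test**
  (`expression_matched_permutation`).

## The permutation test

Let *T* be the target genes (e.g. genes upregulated after conditioning),
*U* the expressed universe, *e(g)* each gene's tissue-weighted expression
(0.6·FPKM⁺ + 0.4·FPKM⁻, reflecting neuronal/non-neuronal composition of bulk
tissue) and *s(g)* its gene-body γH2AX RPKM. Targets are split into
expression bins at the quantiles of *e(T)*; each of *n* permutations draws,
per bin and without replacement from that bin's universe stratum, as many
genes as there are targets in the bin. With null means
*m₁…mₙ* of the pooled pseudo-target sets and observed mean *s̄(T)*,

```
p = #{ m_i ≥ s̄(T) } / n
```

so a small *p* means the targets carry more break signal than
expression-matched random genes — transcription alone cannot explain it.
The result also reports the (k+1)/(n+1) estimator and matching diagnostics
(per-bin counts, null-vs-target mean FPKM on arithmetic and log scales).

A seeded synthetic-data generator (`sim_config`, `simulate_dataset`)
produces gene annotations, negative-binomial expression for the two
fractions across naive/10′/30′ conditions, a γH2AX track whose density
rises with expression and carries an injectable multiplicative excess at
induced genes, and motif-planted binding sites — so the whole pipeline is
testable hermetically.

## Worked example

```r
library(breakscan)
cfg <- validate_config(list(
  simulate = list(n_genes = 800, n_induced = 80, excess_delta = 1.5),
  stats    = list(n_perm = 1000),
  seed     = 11))
report <- run_pipeline(cfg, "demo")
```

`demo/report.md` from this run:

```
## Peaks
- stringent / relaxed / two-tier: 639 / 678 / 612
- genes with an annotated peak: 612

## Differential grouping
- neuron_only_up: 48
- shared_up: 8
- nonneuron_only_up: 24
- down: 8
- ns: 712

## Expression-matched permutation test
- t10: observed 393.727 vs expected 297.088 (ratio 1.32529), p < 1/1000 [0; (k+1)/(n+1) = 0.000999001]
- t30: observed 395.501 vs expected 298.489 (ratio 1.32501), p < 1/1000 [0; (k+1)/(n+1) = 0.000999001]
```

Reading it: 612 two-tier γH2AX peaks were annotated to genes; the grouping
recovers the 80 planted induced genes split across fractions; and induced
genes carry ~1.33× the γH2AX of expression-matched controls — no permutation
out of 1000 reached the observed mean, so p is reported as < 1/1000. With
`excess_delta = 1` the ratio sits near 1 and p is uniform. Runs with the
same seed are byte-identical (`report.json`).

A thin CLI wrapper is installed at `inst/scripts/breakscan.R`
(`Rscript breakscan.R run --config cfg.yaml --outdir out --seed 1`).

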