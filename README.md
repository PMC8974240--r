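# panelgwas

Mixed-model GWAS, rule-based QTL region calling, and causal trait-network
learning for structured inbred diversity panels — the analysis pattern used
to dissect arsenic-related traits (grain arsenic, hull silica, straighthead
severity, and companion elements) in rice diversity collections such as the
USDA rice minicore. It is written for quantitative geneticists who want the
whole chain — replicated phenotypes → BLUPs → per-panel mixed-linear-model
scans → named QTL intervals → co-location and allele pivots → candidate
genes → Bayesian trait network — as tested, scriptable R functions, with a
synthetic-panel generator so every stage runs and is verifiable without any
data download.

## The model in brief

* **Phenotypes.** Replicated records `y = mu + accession + environment + e`
  are fit by average-information REML; accession BLUPs
  `(sigma_a^2 / (sigma_a^2 + sigma_e^2/r)) * (ybar_i - ybar)` (balanced
  case) feed correlations, GWAS, and network learning. Skewed element
  concentrations are natural-log transformed first.
* **Association.** Per SNP, `y = mu + PCs·gamma + x·beta + u + e` with
  `u ~ N(0, sigma_g^2 K)`, `K` the centred-genotype kinship. One
  eigendecomposition of `K` per panel; the variance ratio is re-estimated
  for every marker by REML (grid + Brent); the marker F test gives
  `-log10(p)` and `beta` is reported per allele copy, oriented to the
  panel's most common allele.
* **QTL rules.** Significant SNPs (`-log10 p > 5`) chain within 200 kb;
  regions are spans ± 50 kb; single-SNP and all-rare (< 6 carriers)
  regions are flagged, not claimed; same-trait SNP strings merge across
  panels when gaps ≤ 800 kb and effect signs agree, and a sign flip inside
  a dense string splits it into two QTL; QTL of different traits co-locate
  when spans overlap or region ends are ≤ 500 kb apart; genes within 1 Mb
  are candidates.
* **Trait network.** HITON-PC screening (partial-correlation t-tests,
  alpha 0.1) restricts a BIC-maximising hill climb under growth-stage
  blacklists (flowering/height → elements → straighthead), validated by
  10-fold cross-validation with 17-accession validation sets.

## Worked example

Simulate a 167-accession minicore-like panel (five subpopulations plus
admixed, 12 chromosomes, 2,000 SNPs in tight linkage blocks, planted
pleiotropic QTL, a known trait graph), then run everything:

```r
library(panelgwas)
cfg <- pipeline_config(
  sim_config = panel_config(n_snps = 2000, ld_block_size = 8,
                            ld_switch_prob = 0.05, seed = 1),
  outdir = "demo_out", seed = 2026)
res <- run_pipeline(cfg)
```

Claimed QTL from `demo_out/qtl_report.tsv` (this exact run):

```
     qtl    trait chr   start     end size_mb peak_pos minus_log10_p effect_common pct_alt
    qSi6       Si   6 7994278 8173880   0.180  8067844        34.99        -0.536   29.94
    qAs8       As   8 5264217 5456237   0.192  5406237        10.71        -0.425   28.74
     qP8        P   8 5264217 5456237   0.192  5343736         8.26        -0.199   28.74
qStHDms8   StHDms   8 5264217 5456237   0.192  5343235         7.15        -0.725   27.54
```

Reading this: the simulator planted a Si QTL at chr6:8,067,844 and one
pleiotropic As/StHD QTL at chr8:5,314,217 — the scan's peak SNPs land on or
beside them, the three chr8 QTL co-locate (identical intervals), and a P
QTL appears there too because the planted truth routes As → P. Effects are
per copy of the most common allele on the (log) trait scale; `pct_alt` is
the alternate-allele carrier percentage. The learned network
(`demo_out/trait_dag.tsv`) recovered the planted arcs:

```
 from     to    coef strength
DHDnt  PHTnt  0.744      0.6
DHDnt     As  0.407      1.0
   As      P  0.391      1.0
DHDnt     Cu -0.473      1.0
   As StHDms  0.963      1.0
PHTnt StHDms  0.443      1.0
```

with zero stage-blacklist violations (e.g. no element → flowering arcs).

The same stages are callable piecewise — `simulate_genotypes()`,
`fit_two_level_reml()`, `mlm_scan()`, `call_qtl()`, `coloc()`,
`pivot_allele_effects()`, `genes_near()`, `cv_learn()` — and from the
subcommand CLI (`Rscript inst/cli.R all --config cfg.json --seed 1`).
Formats: HapMap and VCF genotypes, TSV phenotypes/reports, BED regions
(0-based half-open), GFF3/TSV annotations, DOT networks, JSON truth sets.

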