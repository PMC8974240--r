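---
title: "Methods: mixed-model GWAS, QTL region rules, and trait networks for inbred diversity panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model GWAS, QTL region rules, and trait networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panelgwas)
```

# Scope and scientific setting

`panelgwas` re-implements, as a tested and reusable pipeline, the analysis
pattern used to dissect arsenic-related traits in a structured rice
diversity collection: replicated field phenotypes are reduced to BLUPs,
per-marker mixed-linear-model (MLM) association scans are run across nested
population panels, significant SNPs are turned into named QTL intervals by
an explicit rule set, QTL for different traits are tested for co-location,
peak-SNP allele effects are cross-tabulated against other traits, candidate
genes are pulled from annotation within a window, and a Gaussian Bayesian
network with developmental-stage constraints is learned over the trait
matrix. Every stage can be exercised on a synthetic panel with planted
truth, so all behaviour is testable offline.

# The synthetic panel

`simulate_genotypes()` draws ancestral allele frequencies uniformly on a
configurable range (default 0.05–0.5) and per-subpopulation frequencies from
the Balding–Nichols model,
$f_k \sim \mathrm{Beta}\!\big(p\tfrac{1-F_{ST}}{F_{ST}},\,(1-p)\tfrac{1-F_{ST}}{F_{ST}}\big)$,
with $F_{ST}=0$ handled as the no-drift limit. Accessions are fully inbred:
a dosage is $2\cdot\mathrm{Bernoulli}(f)$, so heterozygotes never occur and
a locus with per-copy effect $a$ at frequency $p$ contributes genetic
variance $4p(1-p)a^2$. Admixed accessions use 50/50 mixtures of two parent
subpopulations' frequency vectors, which is how the emulated collection's
admixed members behave for panel-assignment purposes.

Defaults emulate the rice minicore: 167 accessions (30 aus, 54 indica, 29
temperate japonica, 28 tropical japonica, 6 aromatic, 20 admixed), 12
chromosomes with rice-like lengths, and a marker count scaled to desk size
(10,000 by default versus 3.2 M in the emulated data).

**Linkage blocks.** Real resequencing-density maps put many nearly
perfectly correlated SNPs inside every associated region; the region-calling
rules (two-SNP minimum, 200 kb chaining) were designed for such maps.
Independent markers cannot reproduce that, so the generator optionally
groups consecutive markers into physically tight blocks (~100 kb) that copy
a per-accession founder allele and are redrawn independently with a small
switch probability (default 0.1; the acceptance simulations use block size
10 with switch probability 0.05, i.e. $r \approx 0.9$ between neighbours,
a conservative stand-in for resequencing density). Coalescent haplotype
simulation, selection and epistasis are out of scope.

**Traits.** `simulate_traits()` builds each trait's accession value as
intercept + planted-QTL effects + arc contributions (path coefficient times
the centred parent value) + a polygenic normal term, then adds
per-environment effects and replicate noise per record. The default truth
(`default_truth()`) stages nine traits — flowering (DHDnt) and height
(PHTnt) upstream; hull-Si and grain As, P, S, Ca, Cu intermediate;
straighthead severity (StHDms) terminal — with |path coefficients| of
0.4–0.8. Element traits are exponentiated so raw records are right-skewed
and the natural-log transform recovers the latent scale; StHDms is a latent
continuous severity clamped to the 0–9 rating scale (not discretised by
default, because downstream analyses use continuous BLUPs). The emulated
study does not report trait heritabilities, so the default effect sizes are
package choices, stated here and in the configuration docs: planted QTL use
per-copy effects of 0.5–0.6 at frequency ≈ 0.3, i.e. roughly 15–50% of the
latent variance depending on the trait's polygenic spread.

What a green test on this world establishes: the estimators and rules do
what they claim under a linear, homoscedastic, structured-but-LD-simple
genetic architecture. It does not establish robustness to real LD decay
patterns, genotyping error, non-Gaussian trait scales beyond the built-in
log/clamp, or selection-induced frequency patterns.

# Phenotype statistics

`fit_two_level_reml()` fits a Gaussian mixed model with random accession,
optionally random environment and a random subpopulation block (the "nested
family structure" variant used before network learning). Variance components
are estimated by average-information (AI) REML: Newton steps on the
restricted likelihood using the average-information matrix, with EM fallback
steps whenever an AI step leaves the parameter space, and convergence
declared on the gradient. The gradient criterion is what lets balanced
one-way fits agree with the analytic shrinkage formula
$\mathrm{BLUP}_i = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_e/r}(\bar y_i - \bar y)$
to 1e-8 relative error — a derivative-free search over the nearly flat
profile likelihood typically leaves ~1e-4 parameter error and would miss
that tolerance. Degenerate inputs short-circuit: a zero-variance trait
returns all-zero BLUPs with a warning; identical replicates per accession
return $\sigma^2_e = 0$ and unshrunken deviations.

`lsmeans()` is the fixed-effects counterpart (accession + sum-contrast
environment, ordinary least squares); for balanced data it equals the
accession mean. An accession absent from an environment triggers an
estimability warning and falls back to its mean over available cells.
Element concentrations are natural-log transformed (the base is a package
choice — it only rescales effects — and is recorded in the trait-matrix
metadata). Correlations use the exact Student-t form
$t = r\sqrt{(n-2)/(1-r^2)}$.

# Mixed-model association scans

`centered_kinship()` uses the VanRaden-style centred cross-product
$K = CC^\top / \sum_j \mathrm{var}(c_j)$. The exact "centered IBS" algorithm
of the original software is unpublished detail; this matrix plays the same
role (it is the covariance kernel of the polygenic term) and satisfies the
same invariants (symmetry, zero row sums, positive semidefiniteness).

`mlm_scan()` fits $y = \mu + Q\gamma + x\beta + u + e$ per SNP with
$u \sim N(0, \sigma^2_g K)$, via the standard eigendecomposition trick: one
decomposition of $K$ per panel, then for every marker a 1-D REML
optimisation of $\lambda = \sigma^2_g/\sigma^2_e$ (64-point log-spaced grid,
vectorised across markers through the Schur-complement identity
$\det(W^\top DW) = \det(X^\top DX)\,\lVert r_x\rVert^2$, followed by Brent
refinement to 1e-8 on $\log\lambda$). This honours per-marker variance
components without compression. The marker test is the F statistic by
default (Wald available); effects are reported per allele copy and oriented
to the panel's most common allele. Missing dosages are mean-imputed within
panel; allele-count ties resolve to the lexicographically smaller base so
output is deterministic.

Per-panel principal components (default 3 for the full panel, 2 for the
indica subspecies, 1 for japonica and IND, 0 for the single subpopulations)
enter as fixed covariates, mirroring standard practice for these panels.

# QTL region rules

All coordinates are 1-based, inclusive on both ends, matching printed QTL
tables; only BED export converts (start−1, end). The rules, applied in
order:

1. **Significance**: −log10(p) > 5.
2. **Chaining**: significant SNPs on a chromosome chain while consecutive
   gaps ≤ 200 kb; each cluster's region is its SNP span ± 50 kb, clamped at
   position 1 (no chromosome-length clamp unless lengths are supplied).
3. **Stringency flags**: single-SNP clusters and clusters whose members all
   have rare alternate alleles (< 6 carriers) are flagged, not dropped —
   they are excluded from claims but kept for diagnostics, since stringency
   is applied "as needed" during interpretation.
4. **Cross-panel merge**: same-trait significant SNPs pooled over panels
   merge while span gaps ≤ 800 kb *and* effect signs agree; the 800 kb gap
   is measured between significant-SNP spans (the rule speaks of strings of
   SNPs), not between flanked regions. Before the sign test each SNP's
   effect is re-oriented to the allele most common in the full panel, which
   makes "the predominant allele" well defined across panels. A sign change
   inside a dense chain splits it at the boundary between the last SNP of
   one sign and the first of the other — the two resulting regions may
   overlap once flanks are re-applied, reproducing the published
   two-QTL-with-overlap pattern.
5. **Peak**: the member SNP with maximal −log10(p); ties break to the
   smaller position, then the lexicographic panel name.
6. **Names**: `q<Trait><chr>`, with `-k` ordinals by start position only on
   chromosomes carrying more than one claimed QTL for the trait.
7. **Co-location**: two QTL of different traits co-locate when their SNP
   spans overlap ("interspersed") or their region ends are ≤ 500 kb apart.
   Whether "interspersed" requires actual interleaving is ambiguous; span
   overlap is the default and a strict alternation mode is available.
8. **Candidate genes**: annotation records within 1 Mb interval distance of
   a QTL (0 for overlap), sorted by distance.

# Trait network learning

`hiton_pc()` screens each trait's parent/children candidates
(semi-interleaved HITON-PC): candidates ranked by unconditional association
enter in turn and are rejected permanently if any conditioning subset of the
current set (up to size 3) renders them independent of the target at
α = 0.1 by the partial-correlation t-test; admitted sets are re-checked
after each admission. The generous α keeps weakly associated traits in play
at screening time, as the emulated analysis intended.

`hill_climb()` then maximises the Gaussian BIC (larger is better; per-node
parameters counted as parents + intercept + variance) by greedy single-arc
addition/deletion/reversal, restricted to the screened skeleton and the
blacklist, maintaining acyclicity; every accepted move strictly increases
the score. The stage blacklist forbids arcs from later to strictly earlier
developmental stages; DHDnt and PHTnt are staged together so their
relationship can point either way, accommodating the bidirectional
flowering–height link.

`cv_learn()` runs 10-fold cross-validation with a random validation set of
17 accessions per fold (training ≈ 150 at the emulated panel size), records
held-out Gaussian log-likelihood, and defines arc strength as the fraction
of fold DAGs containing the arc. The emulated description does not say how
fold models were combined; this package recomputes each fold DAG's BIC on
the full data and selects the maximum (recorded in output metadata), with
majority-vote averaging exposed as a non-default option. The "significance
level p = 0.001" attached to the published network figure is treated as a
display threshold on arcs, not a learning parameter.

# Numerical choices and edge cases

- REML convergence: gradient below 1e-10 × |restricted log-likelihood|;
  variance floors at 1e-10 × trait variance; non-finite AI steps fall back
  to EM.
- Marker-scan grid spans λ ∈ [1e-5, 1e5]; refinement is plain Brent
  (`stats::optimize`) inside the winning grid bracket.
- p-values are floored at 1e-300 before −log10.
- Rounding for printed-table arithmetic uses round-half-away-from-zero
  (`round_half_up()`), because published tables round 0.1555 to 0.156 where
  banker's rounding would not.
- Stream seeds for pipeline stages are derived from the master seed and are
  kept below 2^31.
- Writers emit fixed-format numbers and a provenance comment header
  (version, seed, parameter hash, no timestamps) so identical seeds give
  byte-identical files.

# Known limitations

- The simulator's LD is block-wise and stationary; it does not emulate
  recombination-rate variation, LD decay with distance, or inversions.
- The MLM assumes a single polygenic variance component and homoscedastic
  residuals; no compression, GBLUP prediction, multi-trait models, or
  rare-variant tests.
- Region calling is purely positional; no LD-based refinement, conditional
  association, or fine-mapping posteriors.
- The network learner is linear-Gaussian; discrete/hybrid networks and
  bootstrap model averaging beyond CV strengths are out of scope, and arcs
  are dependence statements under the stage constraints, not causal claims.
- Published-table arithmetic checks exercise the data model against printed
  values; the full 195-QTL catalogue from 3.2 M real SNPs is not
  recomputable at desk scale and is not attempted.
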