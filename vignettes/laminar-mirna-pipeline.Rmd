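---
title: "Methods: laminar miRNA-mRNA co-expression and target integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar miRNA-mRNA co-expression and target integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamir)
```

# The analysis problem

During the first postnatal weeks the rat medial entorhinal cortex (MEC)
matures dramatically, and layer II (LII, rich in stellate neurons) diverges
from the deeper layers (LDeep, layers III-VI) in morphology, physiology and
gene expression. miRNAs are strong candidates for orchestrating this laminar
specialisation because a single miRNA can post-transcriptionally repress
many mRNAs, usually leaving an *anti-correlated* footprint between the
miRNA and its targets.

`lamir` implements the full computational chain such a study needs, on top
of a synthetic-data generator that reproduces the study design: paired
LII/LDeep samples from the same animal at postnatal days P2, P9, P23 and
P45, measured on arrays (miRNA), RNA-seq (mRNA) and qPCR (sorted stellate
cells vs the rest of the MEC).

The stages, each an exported function:

1. **Normalization** - presence filtering and quantile normalization for
   arrays; TMM scaling, log-CPM and voom-style precision weights for
   counts; delta-Ct for qPCR (`filter_features()`, `quantile_normalize()`,
   `tmm_factors()`, `log_cpm()`, `precision_weights()`,
   `delta_ct_normalize()`).
2. **Differential expression** - per-feature weighted least squares with
   empirical-Bayes moderated t statistics and Benjamini-Hochberg control
   (`fit_and_moderate()`, `bh_adjust()`, `call_de()`,
   `run_all_contrasts()`).
3. **Co-expression modules** - recursive gap-statistic thresholding (PART)
   of an average-linkage dendrogram under 1 - Pearson distance
   (`correlation_dendrogram()`, `part_partition()`, `module_profiles()`).
4. **Genomic miRNA clusters** - 10-kb chaining of loci and a pair-level
   association test between genomic clustering and module co-membership
   (`call_clusters()`, `co_membership_test()`).
5. **Target integration** - Spearman correlations of predicted/validated
   miRNA-mRNA pairs across platform-matched samples, the three-requirement
   negative-correlation filter, candidate ranking, and the
   correlation-skew Mann-Whitney analysis with stacked stringency filters
   (`pair_correlations()`, `three_requirement_filter()`,
   `rank_candidates()`, `correlation_skew_test()`).
6. **Enrichment** - local Fisher over-representation with odds ratios, BH
   control, term-size caps and a capped dot-matrix export
   (`select_query_genes()`, `fisher_enrichment()`, `export_dot_matrix()`).

`run_pipeline()` chains everything deterministically from one seed.

# Statistical models and their assumptions

## Moderated t

Per feature $g$ we fit $y_g = X\beta_g + \varepsilon_g$ by (optionally
weighted) least squares and test a contrast $c^\top \beta_g$. The residual
variances $s_g^2$ (on $d$ df) are shrunk toward a prior $s_0^2$ with prior
df $d_0$ estimated by the method of moments on $\log s_g^2$: with
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$,

$$\widehat{\mathrm{var}}(e) - \psi'(d/2) = \psi'(d_0/2), \qquad
\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2),$$

where the trigamma inversion uses Newton iteration (tolerance $10^{-8}$,
at most 50 steps). The moderated statistic
$\tilde t_g = c^\top\hat\beta_g / (\mathrm{se}_g\,\tilde s_g)$ has
$d + d_0$ df with $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$.
When the log-variance moment is non-positive (no excess dispersion:
variances exchangeable), $d_0 = \infty$ and $s_0^2$ is the arithmetic mean
of the variances, the convention of the standard empirical-Bayes
implementations. Zero-variance features are excluded from the moment
estimation and reinstated at $s_0^2$, so no division by zero can occur.
Forcing `prior = list(d0 = 0, ...)` recovers the ordinary t exactly, and
`d0 = Inf` pools every variance - both are tested identities.

**Design matrices.** Layer contrasts are paired within animal, so they use
a cell-means design (one column per age-by-layer cell) plus animal blocking
columns sum-coded *within each age* (animals are nested in age; global
animal coding would be collinear with the cells). Age contrasts compare
cell means only. Whether the original analysis shared one variance model
across per-age layer contrasts is unknowable from the publication; we fit
one blocked model and extract per-age contrasts from it.

## Benjamini-Hochberg

`bh_adjust()` is the textbook step-up rule
$\tilde p_{(k)} = \min_{j \ge k} p_{(j)} m / j$ capped at 1. A final
`pmax(adj, p)` guards the mathematically guaranteed invariant
$\tilde p \ge p$ against 1-ulp floating-point rounding.

## PART co-expression modules

Features are clustered under $d = 1 - r$ (Pearson across all samples),
average linkage. At each recursion node the number of clusters
$k \in \{1..K\}$ is chosen by the gap statistic: $B$ reference datasets are
drawn uniformly over the per-sample range of the node's features, clustered
the same way, and the first $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k{+}1) - s_{k+1}$ (one-standard-error
rule) wins. $k = 1$ emits the node as a module; otherwise the node is cut
into $k$ parts and each part of at least `min_size` features is recursed
into; smaller parts become outliers (label 0). Defaults: `min_size = 5`,
`max_k = 10`, `B = 50` - the method citation behind the original analysis
publishes no internals, so these are our choices, all configurable, and the
module *count* is always treated as an outcome, never a target. Features
entering clustering are the union of all DE calls (age, pooled layer, and
per-age layer contrasts). Within-cluster dispersion is floored at
$10^{-12}$ before taking logs so identical profiles cannot produce
$\log 0$.

## Genomic clusters

Loci keep 1-based inclusive coordinates throughout - the convention of the
GFF3 boundary and of GenomicRanges, which handles that boundary. The chain
rule is applied directly in those coordinates: per chromosome, sort by
start and chain while `next.start - prev.end` (floored at 0 for overlaps,
using the running maximum end so nested intervals cannot break a chain) is
at most 10,000 bp, *inclusive*; maximal chains of two or more loci are
clusters. Strand is ignored (co-transcription of clustered miRNAs does not
require the test to be strand-aware, and the measurement start-to-start vs
interval-gap is ambiguous in the source; interval gap is used and flagged
here). The association between genomic clustering and module co-membership
is tested over all unordered pairs of module-labelled miRNAs; because pairs
sharing a miRNA are dependent, the Fisher hypergeometric p is reported as
descriptive and a label-permutation p (default 1000 shuffles) as the
calibrated one. The permutation p is also provided in a smoothed,
randomized-tie-break form which is exactly uniform under the null; the
conservative `(1+k)/(B+1)` form is discrete and super-uniform, so
calibration diagnostics (e.g. a Kolmogorov-Smirnov check) should use the
smoothed value.

## Target integration

Spearman's rho (average ranks, then Pearson on the ranks) is computed over
samples matched between the miRNA and mRNA platforms by `(animal, layer)` -
the publication does not describe its matching, so the package logs the
matched sample count per run. The three-requirement filter keeps a pair
when (1) it is a conserved prediction (context score strictly below -0.1)
or a validated interaction, (2) both members are differentially expressed
between ages or both between layers, and (3) rho is strictly below -0.5.
"Significantly negatively correlated" is operationalised purely as the rho
threshold; no extra correlation p value is imposed. The "layer" DE set is
the union of the pooled and per-age layer calls, which is how a laminar
difference confined to one age still qualifies. Candidate ranking filters
on median normalized log2 expression >= 5 and (optionally) DE in both
contrasts, then orders by best context score, then most negative rho, ties
broken by gene id. The top-expression filter keeps the top-q fraction by
median with boundary ties included.

The skew analysis compares conserved-pair correlations against all
predicted pairs (including non-conserved - the control *contains* the
conserved set, matching the original control definition) with a one-sided
Mann-Whitney U: exact enumeration of all $\binom{n+m}{n}$ assignments when
both sides have at most 8 observations (valid under ties), otherwise the
tie-corrected normal approximation with continuity correction. The
direction (conserved more negative) is fixed a priori. Three optional
stringency filters apply to the conserved side only: stricter context
threshold, top-quartile miRNAs, and a minimum fraction of same-module
sites on the target gene.

## Enrichment

One-sided hypergeometric enrichment per term, after intersecting terms
with the universe and discarding terms covering more than 2,500 universe
genes; BH over the tested terms (the published analysis states FDR
adjustment, so the web service's bespoke multiple-testing scheme is
deliberately not reproduced); sample odds ratio ad/bc with the
Haldane-Anscombe 0.5 correction when a cell is zero. Query genes need
|LFC| strictly above 0.5 in the stated direction. The universe defaults to
all genes expressed after filtering; a whole-annotation universe is a
caller choice. Manual curation of redundant terms is out of algorithmic
scope; a term blocklist argument stands in for it. Display caps (odds
ratio 12, -log10 p 15) are applied only in the `*_capped` export columns.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions every
recovery statement in the test suite refers to.

* **Design**: `n_animals_per_age = 3` animals per age (configurable; the
  original per-age replicate counts are published only graphically, so no
  claim of matching them is made), each contributing one LII and one LDeep
  sample - pairing is always on.
* **Expression model**: log2-scale Gaussian. A miRNA in module $m$ has
  value `baseline + loading x effect_size x shape_m(age, layer) + noise`.
  The eight default shapes - age ramp up/down, constant laminar offset in
  both directions, age-by-layer interaction in both directions, and an
  early (P2/P9) laminar transient in both directions - are pairwise
  orthogonal or exact mirrors over the eight design cells, echo the module
  patterns described for the developing MEC (sharp changes between P9 and
  P23, laminar modules, laminar-at-P9 modules), and are each detectable by
  at least one fitted contrast. Defaults `effect_size = 2` log2 units and
  `noise_sd = 0.5`.
* **Mean-variance trend**: per-miRNA noise is scaled up to 2x for the
  lowest-baseline miRNAs (`expr_noise_slope = 1`). Low-abundance signals
  are noisier on every platform - the same phenomenon voom weights model -
  and this is what makes the top-expression skew filter informative.
* **Targets**: a fraction `frac_true_targets = 0.2` of genes follow
  `baseline + target_slope x (driver miRNA centered value) + noise` with
  `target_slope = -1`. Drivers are sampled with weight proportional to the
  baseline percentile to the 4th power: abundant miRNAs are more likely to
  exert measurable repression. True pairs receive conserved context scores
  in (-0.8, -0.2); false conserved pairs (3 per true pair; i.e. one in
  four conserved predictions is functional, mid-range of published
  estimates of how many conserved predictions show detectable repression)
  get weaker scores in (-0.5, -0.101); non-conserved controls sit above
  -0.1. True target genes also carry weak (non-conserved) sites from the
  driver's module with probability 0.9 - co-expressed miRNAs co-target -
  plus random background sites, which is what the same-module-fraction
  filter exploits. 25% of non-target genes get their own planted shapes so
  gene DE sets and enrichment have structure. Gene baselines span
  (6, 11) log2 units, i.e. moderately-to-highly expressed genes as after a
  typical expression filter.
* **Genomic loci**: per module, 75% of its miRNAs are chained on one
  chromosome with gaps uniform in (0.2, 0.8) x 10 kb; all remaining loci
  are at least 100 kb apart.
* **qPCR**: two groups x 5 replicates; 7 planted miRNAs have Ct lowered by
  3 cycles (higher expression) in the stellate group, noise 0.3 cycles; a
  configurable fraction of wells (default 5%) is flagged Undetermined at
  random. Note the strict reliability rule (a feature flagged in any
  sample is dropped) makes per-feature survival $(1-f)^{10}$, so recovery
  statements are made over surviving features.
* **Counts**: RNA-seq-like matrices are produced by exponentiating to a
  per-cell mean, scaling by a lognormal depth, and drawing
  negative-binomial counts (dispersion 0.1), so the TMM / log-CPM /
  precision-weight path runs on realistically overdispersed data.
* **Seeding**: one config seed; every stage draws from a fixed child seed
  (seed + a documented offset), so adding or rerunning one stage never
  perturbs another stage's stream and identical configs are byte-identical.

What the generator does **not** emulate: probe-level array artefacts,
GC/length biases and count outliers of real RNA-seq, structured (detection
driven) qPCR dropout, miRNA family cross-hybridisation, shared-seed
dependence between miRNA families, or biological covariance between
non-target genes. Passing recovery tests therefore demonstrates that the
algorithms do what they claim under the stated generative model - not that
the pipeline is robust to every artefact of real laminar expression data.

# Numerical choices and degenerate inputs

* Quantile normalization maps ties to the mean of their quantile values;
  it refuses missing values.
* TMM: reference sample by 75th-percentile count fraction closest to the
  mean; zero counts excluded pairwise; double trim (30% on M, 5% on A);
  inverse-asymptotic-variance weights; factors rescaled to geometric mean
  1 (to 1e-12, tested). Identical or purely depth-scaled libraries give
  unit factors.
* log-CPM: `log2((count + 0.5) / (library x factor + 1) x 1e6)`; the prior
  keeps zeros finite.
* Precision weights: lowess (span 0.5) of sqrt(residual sd) against mean
  log-CPM, weights = trend^-4 clipped to [1e-6, 1e6]; a single-feature
  input yields unit weights with a message. The exact smoother variant is
  a configuration knob, not a claim about the original analysis.
* Delta-Ct: the per-sample reference is the mean over features reliably
  detected in *all* samples (no named endogenous controls are assumed);
  output is negated centered Ct so positive fold changes mean
  up-regulation on every platform.
* Ties in ranking candidates break by gene id; modal-module ties break
  toward the smallest label - both deterministic.
* PART reference draws, permutation tests and the simulation consume
  explicit seeds; identical inputs and seeds give identical outputs
  (tested, including byte-identical pipeline reruns).

# Problem sizes

The shipped defaults - 160 miRNAs (8 modules of ~15 plus background), 400
genes, 24 paired samples, B = 50 gap references, 1000 permutations - run
the full pipeline in a couple of seconds and the entire test suite,
including 20-seed null calibrations and 100-instance oracle sweeps, in a
few minutes on one core. These sizes were chosen so the planted effects
sit at realistic detectability (not at asymptotic certainty) while keeping
iteration fast; all of them scale up through the configuration objects.

# Known limitations

* The pair-level co-membership Fisher p ignores pair dependence by
  construction; use the permutation p.
* The moderated-t model assumes exchangeable feature variances after the
  mean-variance trend is handled by weights; strong variance structure
  violating both will miscalibrate (as it would in any such framework).
* PART's gap statistic with correlation distance can merge modules whose
  centroid correlation is high; the planted shapes avoid this regime, real
  data need not.
* `read_mirbase_gff()` reads hairpin records by default (mature records
  are an option); which the original cluster analysis used is not
  recoverable from the publication.
* The enrichment stage consumes flat gene sets; no ontology-graph
  propagation.
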