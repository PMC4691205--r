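---
title: "Methods: miRNA profiling and multi-miRNA target prioritization in allergic airways disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA profiling and multi-miRNA target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmir)
```

## The design and the statistical model

`lungmir` analyses miRNA microarray intensities from a four-arm murine
model of allergic airways disease: PBS-sensitised/PBS-challenged controls
(PBS/PBS), challenge-only controls (PBS/OVA), ovalbumin-sensitised and
challenged allergic animals (OVA/OVA), and allergic animals treated with
the glucocorticoid dexamethasone (OVA/OVA DEX), with n = 6 animals per
group. The quantities of interest are, per miRNA and per pair of groups,
a **signed fold change** and a **two-sided Mann-Whitney p-value**, and the
derived classifications built on them.

Intensities are treated as log-normal: the working scale throughout is
log2, group summaries are geometric means (arithmetic means of log2
intensities), and the signed fold change of groups with geometric means
$m_1, m_2$ is

$$\mathrm{fc}(m_1, m_2) \;=\; \begin{cases} m_1/m_2 & m_1 \ge m_2 \\
 -\,m_2/m_1 & m_1 < m_2,\end{cases}$$

so every value satisfies $|\mathrm{fc}| \ge 1$ and a two-fold decrease
reads $-2$. The geometric-mean summary is the package's own choice — it is
the summary under which the log-scale normalization and the fold-change
ratio are mutually consistent; the original platform software does not
document its choice.

### Normalization

`percentile_normalize()` shifts every sample on the log2 scale so that its
75th percentile (computed over the sample's positive intensities) equals
the across-sample median of those percentiles. The shift is multiplicative
on the raw scale: within-sample ranks are untouched and zeros stay zero.
The operation is idempotent. Percentile-shift at the 75th percentile is
the conventional normalization for single-channel expression arrays; the
percentile is configurable (`normalization_percentile`).

### Detection

A probe is **detected** when, in at least one treatment group, at least a
fraction `detection_fraction` of the replicates exceed the intensity
`detection_floor` (strictly). The defaults are 0.6 — at the study's
n = 6 this demands at least 4 of 6 replicates, a strict majority — and a
floor of 4 intensity units, matching the synthetic generator's separation
between expressed and non-expressed probes. When the matrix carries
scanner-level detection flags those replace the floor comparison.
Detection is decided *per group* and a probe expressed in any single group
counts, because group-restricted expression (e.g. inflammation-driven
induction) is exactly what the experiment is looking for.

### Testing

`mann_whitney_exact()` computes the two-sided Mann-Whitney (Wilcoxon
rank-sum) p-value **exactly, by full enumeration** of all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled ranks, whenever the
pooled size is at most 20 — which covers the study's 6-vs-6 comparisons
($\binom{12}{6} = 924$ assignments). Ties receive mid-ranks and the
enumeration is carried out on the tied rank vector, so tied data are
handled exactly as well. The two-sided p-value is the null probability of
a rank-sum at least as far from its expectation as the observed one. For
pooled sizes above 20 the classical normal approximation with tie
correction (no continuity correction) is used.

Two numerical notes. First, enumerated null distributions for untied
samples are cached per $(n_1, n_2)$, which makes screening thousands of
probes cheap. Second, the exact test is *discrete*: at $n_1 = n_2 = 6$ the
attainable significance levels near 0.05 are 0.0411 and 0.0649, so a
caller thresholding at $p < 0.05$ has true size 0.0411, slightly
conservative. This is a property of the exact test itself, visible in the
type-I calibration checks.

Multiple-testing adjustment defaults to **none** — the published analysis
thresholds raw p-values at 0.05 — with Benjamini-Hochberg available via
`analysis_config(adjust_method = "BH")`.

### Calling and classification

A miRNA is called `up` in a contrast when $\mathrm{fc} \ge$
`fc_threshold` **and** $p < \alpha$ (the *dual criterion*; defaults 2 and
0.05), `down` symmetrically. The threshold is inclusive ($\ge$, not $>$):
printed fold changes of exactly 2.01–2.02 count as altered. When the
input is a bare fold-change table with no replicate data — as when
re-analysing the published printed table — classification runs in
**fold-change-only mode**, using $|\mathrm{fc}| \ge$ threshold alone.

From the per-contrast calls, `classify_mirnas()` derives:

* `de_any` — altered in at least one contrast. The published set of 29
  miRNAs satisfies the union-over-contrasts reading of the
  $|\mathrm{fc}| \ge 2$ rule, which is what is implemented (the printed
  table does not record per-contrast p-values, so a per-contrast joint
  rule cannot be reconstructed from it).
* `steroid_sensitive` — $|\mathrm{fc}(\text{OVA/OVA vs OVA/OVA DEX})| \ge$
  threshold: the allergic alteration moves when dexamethasone is given.
  The source describes steroid sensitivity qualitatively; this
  operationalization reproduces the published count of 26 of 29.
* `venn_region` — the membership pattern over the three headline
  comparisons (OVA/OVA vs PBS/PBS, OVA/OVA DEX vs PBS/PBS, OVA/OVA vs
  OVA/OVA DEX). Regions partition the `de_any` set; an altered miRNA
  outside all three (altered only vs PBS/OVA) is labelled `"none"`.

`summarize_calls()` reports two kinds of counts, deliberately distinct:
`n_up`/`n_down` record the *direction of change* of the `de_any` miRNAs
in a given contrast by fold-change sign (this is the published "22 of 29
upregulated vs 7 down" bookkeeping, which includes sub-threshold
directions), while `n_altered` counts miRNAs passing the full calling
criterion in that contrast.

## Clustering

Heatmap display values are per-miRNA z-scores using the population (1/n)
standard deviation; constant rows are zero-filled and flagged rather than
dropped. `hierarchical_cluster()` uses 1 − Pearson correlation distance
with average linkage by default (the conventional expression-heatmap
pairing; Euclidean and complete linkage are available). Input rows are
sorted by label before clustering, which makes tie-breaking deterministic
and the result invariant to input order. Both individual samples and
group centroids can be clustered; `group_similarity_order()` ranks group
pairs by cophenetic merge height, breaking exact ties lexicographically.
On data with effects planted only in the allergic group, the three
control-like groups merge first and OVA/OVA joins last — the qualitative
structure expected of the real experiment.

## Multi-miRNA target prioritization

Target predictions are consumed as a plain edge list (miRNA, gene,
optional support score) from any prediction source; the package does not
implement target prediction itself. A gene's **multiplicity** is the
number of *distinct* differentially expressed miRNAs predicted to target
it — multiple predicted sites for the same miRNA on one gene collapse to
a single edge, matching the published counting, which sums miRNAs rather
than sites. The count is decomposed by the direction of the targeting
miRNA (`n_up`, `n_down`, `diff = n_up − n_down`); direction is taken from
the OVA/OVA vs PBS/PBS contrast by default, the decomposition context of
the published table (a DE miRNA with fold change exactly 1 in that
contrast has no direction and raises an error rather than being silently
dropped).

`candidate_table()` keeps genes at multiplicity ≥ 6 (the published
filter), ordered by multiplicity descending with ties broken by gene id
— the published within-tier order is unexplained and is not reproduced.
`summarize_candidates()` reports column means and their nearest-integer
roundings, *half away from zero*, matching the printed "Average" row
(note the printed roundings (7, 6, 1, +4) are consistent: the exact means
are 6.89, 5.64, 1.25 and 4.39, so the rounded difference is 4 even though
6 − 1 = 5).

`multiplicity_enrichment_test()` is an **extension beyond the published
analysis**, off by default in the pipeline: it compares the observed
number of genes at or above a multiplicity threshold with the counts
obtained from random miRNA subsets of the same size, with
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm}+1)$. Under a
fully exchangeable null this p-value is uniform on its attainable grid;
the count statistic is discrete, so the package's uniformity check uses a
250-gene background network, large enough that tie-induced granularity is
small against the Dvoretzky–Kiefer–Wolfowitz band at 200 replicates.

## qPCR quantification and concordance

Relative expression is $2^{-\Delta C_t}$ with
$\Delta C_t = C_t^{\text{assay}} - C_t^{\text{reference}}$ against a
single housekeeping assay (sno202 for miRNA, HPRT for mRNA), no
calibrator sample, and amplification efficiency fixed at 2 — the study
plots group fold changes of reference-normalized expression, not
calibrated ratios, so the $2^{-\Delta\Delta C_t}$ form is not used. Group
fold changes are signed fold changes of geometric means of the relative
values, the same summary as the array side; concordance between
platforms is reported as the fraction of shared miRNAs with agreeing
direction plus the Spearman rank correlation of the signed fold changes.

## The synthetic-data generators

The generators exist so that every stage has inputs with known truth.

`simulate_expression()` draws intensities
$2^{\,b_i + \delta_{i,g} + \varepsilon}$,
$\varepsilon \sim N(0, \sigma)$, with per-probe baselines
$b_i \sim N(7, 1)$ on the log2 scale. Defaults mirror the study
conditions: 611 arrayed probes of which 228 are expressed, 29 planted
effects, magnitudes uniform on [2, 6] (the observed range) with
upregulation three times as likely as down (the observed 22:7
predominance), effects confined to the OVA/OVA group, n = 6 per group,
and $\sigma = 0.5$. The noise SD is a **stand-in**: the study reports no
replicate variance estimates, and 0.5 log2 units is a typical
between-animal spread for whole-tissue arrays. Non-expressed probes are
emitted *at or below* the detection floor (4 intensity units) rather than
as missing values, so detection calling is exercised rather than
bypassed. Dye bias, spatial artifacts and cross-hybridization are out of
scope; consequently, passing calibration here demonstrates correctness of
the statistics under the stated model, not robustness to platform
artifacts in real arrays.

`simulate_interactions()` plants hub genes wired to 6–12 distinct DE
miRNAs (the observed candidate multiplicity range) over an independent
Bernoulli background; with the background switched off, candidate
recovery is exact by construction, which is what makes it a useful test.
`simulate_ct()` builds Ct tables with
$C_t^{\text{target}} = C_t^{\text{ref}} - \log_2(\text{rel}) + \text{noise}$,
so planted relative expression is recovered exactly in the noiseless
limit.

All generators take a mandatory seed, use a private RNG stream, and
restore the caller's RNG state; identical seeds give bit-identical
output.

## Calibration results and problem sizes

The test-suite calibration checks run at the following sizes, chosen to
keep the whole suite fast while leaving the binomial/DKW error bands
meaningful: type-I error on 2,000 planted-null probe-tests at n = 6/group
(empirical false-positive rate within the binomial 95% band of
$\alpha = 0.05$; the exact test's true size at this n is 0.0411, inside
the band but near its lower edge); power ≥ 0.9 on 500 replicates of a
planted 4-fold change at $\sigma = 0.5$ (observed ≈ 1.0 — a 4-fold
change over this noise is a 4-SD separation); fold-change recovery within
±20% (median over 100 replicates) at n = 6; exact hub recovery over 20
background-free networks; and perfect 2-cluster recovery at a 6-SD group
separation. `scripts/acceptance.R` recomputes the same quantities from
scratch at an arbitrary seed.

## Known limitations

* The fold-change-only re-analysis of the published table can only apply
  the $|\mathrm{fc}| \ge 2$ rule; the underlying p-values of the original
  arrays are not printed and are not reconstructed.
* Database-dependent quantities (how many genes a prediction database
  assigns per miRNA, the shape of the multiplicity distribution over all
  computed targets) depend on the prediction snapshot used and are
  exercised qualitatively on synthetic networks, not reproduced
  numerically.
* The exact test's discreteness makes the caller conservative at small n;
  at n = 6/group the effective size at nominal 0.05 is 0.0411.
* The log-normal noise model is homoscedastic on the log scale;
  intensity-dependent variance of real scanners is not modelled.
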