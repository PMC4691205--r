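# lungmir

Differential miRNA expression and multi-miRNA target prioritization for a
steroid-sensitive mouse model of allergic airways disease (AAD).

## What this package is for

In the ovalbumin-driven AAD model, whole-lung miRNA microarrays are
collected across four arms — PBS/PBS and PBS/OVA controls, allergic
OVA/OVA animals, and OVA/OVA animals treated with dexamethasone
(OVA/OVA DEX), n = 6 per group. `lungmir` implements the complete
in-silico analysis of such an experiment for researchers profiling small
RNAs in airway disease models:

* **Normalization and detection** — 75th-percentile shift on the log2
  scale; a probe is detected when a within-group majority of replicates
  exceeds the detection floor in at least one group.
* **Differential expression** — signed fold changes of group geometric
  means, with the convention fc = m₁/m₂ if m₁ ≥ m₂ and −m₂/m₁ otherwise
  (so |fc| ≥ 1 always), paired with the **exact** two-sided Mann-Whitney
  test (full enumeration of all C(n₁+n₂, n₁) rank assignments for pooled
  n ≤ 20; mid-ranks for ties). A miRNA is called up in a contrast when
  fc ≥ 2 and p < 0.05 (dual criterion; thresholds configurable,
  Benjamini-Hochberg optional).
* **Classification** — alteration in any contrast, steroid sensitivity
  (|fc(OVA/OVA vs OVA/OVA DEX)| ≥ 2), and Venn membership over the three
  headline comparisons; hierarchical clustering (1 − Pearson r, average
  linkage) of samples, miRNAs and group centroids.
* **Multi-miRNA target prioritization** — consuming any miRNA→gene
  prediction table as data, per-gene *multiplicity* = number of distinct
  differentially expressed miRNAs targeting the gene, split into up- and
  downregulated contributors; genes at multiplicity ≥ 6 form the
  candidate table. A permutation enrichment test against random miRNA
  subsets is included as an optional extension.
* **qPCR** — 2^−ΔCt relative quantification against a housekeeping assay
  (sno202/HPRT) and array-vs-qPCR fold-change concordance.
* **Synthetic data** — seeded generators for expression matrices with
  planted fold changes, bipartite interaction networks with planted hub
  genes, and Ct tables, each emitting its ground truth, so the whole
  pipeline is testable without the original arrays.

The published 29-miRNA fold-change table and the 44-gene candidate table
ship as packaged fixtures (`load_table2_fixture()`,
`load_table3_fixture()`).

## Worked example

```r
library(lungmir)

# the published fold-change table: 29 miRNAs x 5 contrasts
t2  <- load_table2_fixture()
cls <- classify_mirnas(t2)          # fold-change-only mode, threshold 2
summarize_calls(cls, contrast("OVA/OVA", "PBS/PBS"))
#> $n_up
#> [1] 22        # miRNAs increased in allergic lungs (by fc sign)
#> $n_down
#> [1] 7
#> $n_unchanged
#> [1] 0
#> $n_altered
#> [1] 20        # passing |fc| >= 2 in this specific contrast
#> $n_steroid_sensitive
#> [1] 26        # reverted by dexamethasone
#> $n_de_any
#> [1] 29        # altered in at least one contrast

# the candidate genes targeted by >= 6 of the 29 DE miRNAs
summarize_candidates(candidate_table(load_table3_fixture(), 6))
#> 44 candidate genes; mean targeting miRNAs 6.89 (up 5.64, down 1.25,
#> diff +4.39); rounded (7, 6, 1, +4); max 12
```

A full synthetic study runs through the numbered drivers:

```sh
Rscript analysis/01_simulate.R                 # 611 probes, 228 expressed,
                                               # 29 planted effects, network
Rscript analysis/02_differential_expression.R  # normalize/detect/test/classify
Rscript analysis/03_clustering.R               # group similarity structure
Rscript analysis/04_target_multiplicity.R      # candidates + enrichment
Rscript analysis/05_qpcr_concordance.R         # 2^-dCt vs array fold changes
```

Each writes its tables under `results/`; `run_pipeline()` exposes the
same orchestration programmatically.

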