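# xbias

Tissue-bias scoring and X-chromosome representation analysis for
*Drosophila* expression data.

## The problem

Male-biased genes are scarce on the *Drosophila* X chromosome, and global
meiotic sex chromosome inactivation (MSCI) — silencing of the X in
primary spermatocytes — has long been invoked to explain it. Deciding
between MSCI and alternatives needs several analyses run together on the
same gene universe:

* a **tissue-bias statistic** per gene: the minimal target-to-panel
  signal ratio
  `r_min = min_i (s_target + eps) / (s_i + eps)`
  over a panel of non-target tissues, with bias categories at inclusive
  thresholds 2, 5 and 10;
* **chromosomal representation** of gene sets: the ratio
  `(|S on arm| / |S|) / (N_arm / N)` with hypergeometric tails, Fisher's
  exact test, chi-square category contrasts, and Bonferroni/BH control;
* a **testis-development time course**: log2 quantile normalization,
  moderated-t differential calls versus the earliest day (empirical-Bayes
  variance shrinkage with moment-matched prior `d0`, `s0^2`; q < 0.1
  threshold), and a per-timepoint Wilcoxon comparison of global X-linked
  versus autosomal expression;
* **chromatin association**: Pearson correlations between developmental
  up-regulation and the binding of silencing- versus activation-role
  chromatin proteins, plus thresholded bound-gene frequency enrichment
  split by X versus autosomes;
* a **synthetic-data generator** that plants every one of those effects
  (bias factors, X depletion of high-bias genes, monotone activation
  trajectories, signed binding correlations attenuated on the X) so each
  stage has a parameter-recovery test with known truth.

The package is aimed at genome biologists analysing tissue-specificity
and sex-chromosome gene content in flies or comparable systems, and at
anyone needing a fully tested reference implementation of these standard
operations.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
synthetic study at the default conditions (13,000 genes, X high-bias
depletion 0.5, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_bias_representation.R
Rscript analysis/03_timecourse.R
Rscript analysis/04_chromatin.R
Rscript analysis/05_report.R
```

which prints, stage by stage:

```
simulated 13000 genes at seed 1: 4225 planted tissue-biased (1708 high-bias), 1969 activated
union of >=10x tissue-biased sets: 1370 genes, X representation ratio 0.547 (p_under 2e-16)
up-regulated at q<0.1: 1989 genes (sensitivity 0.978, FDR 0.032 vs planted truth)
X vs autosomes: max |median difference| 0.079 log2 units; min Bonferroni p 1.000
=> no evidence of global X down-regulation at any timepoint
final-timepoint correlations: silencing mean r 0.334, activation mean r -0.329
inverse correlation pattern: TRUE
mean |relative frequency - 1| for up-regulated genes: X 0.563 vs autosomes 1.137
```

Reading those numbers: the genes measured as ≥10-fold tissue-biased sit
on the X at barely half the genome-average rate (representation ratio
0.547, hypergeometric under-representation p ≈ 2e-16) even though global
X expression tracks the autosomes at every developmental timepoint (all
Bonferroni-adjusted rank-sum p-values at 1) — the planted dissociation
between "no global X silencing" and "depletion of highly biased genes on
the X". Developmental up-regulation correlates positively with
silencing-protein binding and negatively with activation-protein binding
(the inverse pattern), and those deviations from genome-average binding
are markedly weaker on the X, as planted via the attenuation factor.

The same stages are available programmatically:

```r
library(xbias)
study <- simulate_study(sim_config(seed = 1))
bias  <- bias_table(study$atlas, "testis")       # min_ratio + category per gene
sets  <- biased_gene_set(study$atlas, "testis", 10)
representation_ratio(sets, study$catalog, "X")
fc    <- fold_change_vs_earliest(normalize_arrays(study$timecourse))
upregulated_set(fc)                              # q < 0.1, positive FC
x_vs_autosome_profile(normalize_arrays(study$timecourse), study$catalog)
```

User-supplied tables enter through `read_catalog()` and `read_matrix()`
(TSV, gzip accepted, sidecar JSON/YAML for sample metadata and binding
thresholds/roles); `collapse_by_gene()` reduces probe-level tables to
per-gene medians.

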