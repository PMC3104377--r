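---
title: "Methods: tissue-bias scoring, X-chromosome representation, and chromatin association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-bias scoring, X-chromosome representation, and chromatin association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Male-biased genes are scarce on the *Drosophila* X chromosome. One popular
explanation — meiotic sex chromosome inactivation (MSCI), a global
silencing of the X in primary spermatocytes — predicts that X-linked genes
should fail to activate during the meiotic stages of testis development.
`xbias` implements the analyses needed to interrogate that model with
expression data: a tissue-bias statistic, chromosomal representation
tests, a developmental time-course analysis, and a chromatin-binding
association analysis, together with a synthetic-data generator that plants
each effect so that every stage has a parameter-recovery test.

The package's combined picture, on data with the planted structure, is the
one the analyses are designed to resolve: X-linked and autosomal genes can
share identical developmental activation profiles (no global X
inactivation) while *highly* tissue-biased genes are nevertheless depleted
on the X — a deficit general to tissue-biased genes, not specific to the
germline.

# The tissue-bias statistic

For a gene with target-tissue signal $s_T$ and panel signals
$s_1,\dots,s_k$ (every other tissue in the atlas),

$$ r_{\min} = \min_{i \le k}\ \frac{s_T + \varepsilon}{s_i + \varepsilon}. $$

The *minimum* over the panel is deliberately conservative: a gene only
scores as biased if its target signal exceeds every panel tissue, so a
single somatic tissue with comparable expression vetoes the call. Bias
categories use inclusive lower edges at ratios 2, 5 and 10 ("<2",
"$\ge$2", "$\ge$5", "$\ge$10"), so a ratio of exactly 10 is highly biased.
Design points:

* **Panel.** All atlas tissues except the target, ovary included — no
  germline exclusion is applied when scoring testis bias. This mirrors the
  somatic-panel convention of atlas-style datasets and makes the statistic
  symmetric across target tissues.
* **Pseudocount.** Microarray intensities can be zero; $\varepsilon$
  defaults to half the smallest positive intensity in the atlas, which
  leaves well-measured ratios essentially untouched while bounding ratios
  involving zeros. With $\varepsilon = 0$ the statistic is exactly
  scale-invariant; with $\varepsilon > 0$ scale changes perturb it by at
  most the pseudocount terms.
* **Ties** need no special handling; the minimum is well defined.

# Chromosomal representation

For a gene set $S$ in a catalog of $N$ genes with $N_a$ on arm $a$, the
representation ratio is

$$ R_a = \frac{|S \cap a| / |S|}{N_a / N}, $$

1.0 being genome-average. Significance comes from the hypergeometric
distribution ($p_{\text{under}} = P(K \le k)$, $p_{\text{over}} = P(K \ge
k)$; both tails are always reported because claims of paucity are
directional but the consumer chooses the tail), Fisher's exact test
(two-sided, point-probability rule — the convention of R's
`fisher.test`), and Pearson's $\chi^2$ on category-count tables (both the
full 2$\times$C table and a collapsed 2$\times$2 are exposed, since either
contrast is defensible). "Autosomes" means 2L, 2R, 3L, 3R **and** 4; the
dot chromosome is never excluded. Multiple testing uses Bonferroni within
one analysis table as the family, or Benjamini–Hochberg q-values where an
FDR is wanted.

# Time-course analysis

Raw intensities are log2 transformed and quantile normalized
(`limma::normalizeQuantiles`) — a declared in-repo surrogate for the
external normalization protocols that usually accompany two-colour array
data; the downstream statistics are rank- and difference-based and robust
to this choice. The two-colour competitive design is abstracted to
per-sample intensity columns; dye effects are out of scope.

Differential expression versus the earliest timepoint uses a moderated
two-sample t: gene-wise pooled variances $s^2_g$ (residual df $d$) are
shrunk toward a prior,

$$ \tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, $$

with $(d_0, s_0^2)$ estimated from the marginal distribution of the
$s^2_g$ by moment matching: under the scaled-F marginal,
$\mathrm{Var}(s^2)/\mathrm{E}(s^2)^2 = 2(d + d_0 - 2)/(d (d_0 - 4))$,
solved for $d_0$ (set to $\infty$, i.e. full pooling, when the observed
spread does not exceed the pure-noise expectation), and $s_0^2 =
\bar{s^2}(d_0-2)/d_0$. P-values use $d_0 + d$ degrees of freedom (normal
when $d_0 = \infty$) and q-values are Benjamini–Hochberg within each
contrast. Moment matching was chosen over marginal-likelihood fitting for
transparency; the two agree in rank on simulated data, which the test
suite checks against limma as an independent implementation. Limits
behave as expected: $d_0 \to 0$ recovers the ordinary t, $d_0 \to \infty$
a z-like statistic with pooled variance. Degenerate genes (zero variance
everywhere) get $t = 0$, $p = 1$ when their fold change is zero.

"Up-regulated in testis development" is defined operationally as $q <
0.1$ with a positive log2 fold change at one or more later timepoints;
genes significant only with negative fold changes are excluded.

The global X-versus-autosome comparison reports, per timepoint, medians
and quartiles of the per-gene mean normalized signal for both groups, the
median difference, and a two-sided Wilcoxon rank-sum p-value with
Bonferroni adjustment across the timepoint series. Medians with quartiles
are reported (rather than means) for robustness to the heavy-tailed
intensity distribution. "Significant" for this comparison means adjusted
$p < 0.01$, the detection level the power analysis of this module is
calibrated to.

qPCR quantification is the standard $2^{-\Delta\Delta C_t}$: target minus
loading-control $C_t$, referenced to a designated sample whose relative
expression is 1 by construction.

# Chromatin association

Two separate treatments mirror the two kinds of published binding
summaries:

* **Continuous**: Pearson correlation (two-sided, t transform) between a
  protein's binding score and the log2 fold change at each timepoint over
  the genes shared by both tables — pairwise-complete per protein, because
  the source binding datasets assess different gene subsets and a global
  intersection would discard most genes. Log2 fold changes are used (a
  flag exposes linear). Bonferroni runs across the full
  protein-by-timepoint series as one family. Cells with fewer than three
  shared genes are omitted with a log entry.
* **Thresholded**: per-protein bound/non-bound calls at that protein's
  threshold (the published thresholds are arbitrary, so the generator and
  defaults use the 0.75 quantile of the score distribution), then
  bound-gene frequencies in the X-linked and autosomal members of a set,
  normalized to the bound frequency in the whole assessed genome. Empty
  compartments are flagged not-assessable instead of aborting a batch.

The "inverse pattern" flag summarizes the role structure: it is true when
significant correlations (adjusted $p < 0.05$) of silencing-role proteins
are predominantly positive *and* those of activation-role proteins
predominantly negative, each role contributing at least one significant
cell. Protein roles are input metadata, never inferred; defaults ship for
the classic panel (H1, H3K27me3, LamDm0, D1, Pc, esc, Sce as silencing;
H3.3A, H3K4me3, DJun, bcd as activation).

# The synthetic-data generator

The generator emulates the four data types with known planted structure.
Defaults describe a single fixed set of study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 13,000 | genome-scale array coverage |
| `arm_proportions` | X .17, 2L .185, 2R .21, 3L .195, 3R .22, 4 .02 | approximate real arm shares of the gene count |
| `baseline_log_mean`, `baseline_log_sd` | 5.5, 1.2 (natural log) | log-normal intensities: positive, right-skewed, ~3 decades of dynamic range |
| `bias_fraction_per_tissue` | 0.025 | ~2.5% of genes biased toward each of 13 tissues (~32% tissue-biased overall) |
| `bias_strata` | weights .35/.25/.40 over 2–5, 5–10, 10–50 | a substantial highly-biased tail, as testis-type tissues show |
| `x_highbias_depletion` | 0.5 | high-bias genes reach the X at half the genomic rate |
| `activation_fraction` | 0.15 | share of genes activated during testis development |
| `trajectory_slope_range` | 0.3–1.2 log2/day | 2- to 60-fold activation over the 6-day course |
| `noise_cv` | 0.2 | replicate-level multiplicative noise of averaged array signals |
| `n_replicates` | 3 | minimum replication the loader expects |
| `binding_rho_silencing` / `_activation` | +0.4 / −0.4 | moderate planted correlations of either sign |
| `x_attenuation` | 0.5 | planted binding correlation halved on the X |

Seed handling: one root seed; each table draws from a substream derived
deterministically from (seed, table name), so regenerating one table never
perturbs the others, and identical configurations are byte-identical.

Two generator semantics deserve explicit statement:

* **Depletion.** For a planted high-bias gene the X probability is set to
  `x_highbias_depletion` times the X share and the *autosomal*
  probabilities are rescaled to absorb the freed mass. Under this
  construction the expected X fraction of high-bias genes is exactly the
  depletion multiplier times the X share, so the measured representation
  ratio estimates the multiplier directly (up to dilution of the
  genome-average denominator by the depleted genes themselves, a factor
  $1/(1 - (1-d)h)$ for depletion $d$ and high-bias genome fraction $h$).
* **Independence.** Tissue bias, developmental activation and arm
  assignment are planted independently (except for the high-bias/X
  coupling); binding scores correlate with planted *up-regulation*. Real
  testis data couples bias and activation strongly; the generator does
  not, so analyses that live on that coupling (e.g. the bias-category
  composition of the up-regulated set) are structurally present but
  weaker in synthetic data than in the real system.

What the generator does **not** emulate: probe-level effects, dye/channel
artifacts, spatial array structure, correlated gene modules, or
multi-tissue bias. Passing recovery tests therefore demonstrates
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real array data.

# Numerical and calibration notes

* Hypergeometric tails come from `phyper` (log-space stable well beyond
  $2\times10^4$ genes) and are verified against exhaustive subset
  enumeration for all universes up to 15 genes.
* Hypergeometric p-values are discrete and conservative; the null
  calibration check therefore uses set and catalog sizes (2,000-gene sets
  in 10,000-gene catalogs) at which the lattice spacing is well inside
  the Kolmogorov–Smirnov band used.
* Quantile normalization assumes near-identical intensity distributions
  across samples. A strong planted global activation violates this and
  slightly compresses late-timepoint fold changes; correlation-recovery
  checks therefore run on the log2 course directly, which is exact for
  the generator (it plants no array-level technical effects). On real
  data the normalization step is the appropriate default.
* Problem sizes used by the test suite (100-seed panels at n = 13,000 for
  depletion recovery, 1,000 replicates for null calibration, 100 seeds at
  n = 2,000 for correlation recovery and the null X profile) keep the full
  suite under a minute while leaving comfortable power margins.
* The depletion-recovery band is the one place where those margins are
  structurally thin: with ~1,400 genes in the measured $\ge$10$\times$
  union, the X count is irreducibly binomial, so the per-seed
  representation-ratio standard deviation is ~0.05 while its mean sits at
  $0.5/(1-0.5h) \approx 0.55$; individual seeds therefore exceed 0.6 in
  roughly a tenth of replicates no matter how the prevalence is chosen.
  The test states the nominal band regardless and the shortfall is a
  documented property of the construction, not a defect of the estimator
  (which is unbiased for the planted multiplier before dilution).

# Known limitations

* Multi-probe tables must be collapsed to gene level; the provided helper
  takes per-gene medians (the source publications exclude ambiguous
  probes but do not state a collapse rule — the median is this package's
  choice).
* The atlas is assumed pre-normalized between arrays; the bias statistic
  is ratio-based and scale-invariant, but cross-tissue normalization
  errors translate directly into bias-ratio errors.
* Binding "bound/non-bound" thresholds are inherently arbitrary;
  conclusions should be checked across a threshold range (the quantile
  default makes that a one-parameter sweep).
* The pipeline provides correlation machinery for dosage-compensation
  (msl-2-type) columns but no spreading/domain analysis.
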