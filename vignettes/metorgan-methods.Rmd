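---
title: "Rank-based discovery of organ-specific metastasis signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based discovery of organ-specific metastasis signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tumours metastasize with strong organ preference, and part of that
preference is thought to be written in expression programs that let cancer
cells colonise one target organ regardless of where the primary tumour
arose. Finding such programs requires comparing metastases from *different*
primary origins against normal tissue of the *same* target organ, which in
practice means pooling many small public microarray datasets measured on
different platforms in different laboratories. Absolute intensities from
such collections are not comparable: each dataset carries its own
normalisation, scanner response, and batch offsets.

`metorgan` implements the full discovery chain for this setting:

1. **Integration** of gene-level log2 matrices on the genes detected on all
   platforms — and nothing else: no cross-dataset intensity normalisation.
2. **Rank-based differential expression** from within-sample relative
   expression orderings (REO), which additive or monotone per-sample
   distortions cannot change.
3. An **effect-size screen** on a heteroscedastic standardized mean
   difference.
4. The **organ signature** as the direction-consistent intersection of
   per-origin DEG lists, with hypergeometric overlap statistics.
5. **Pathway enrichment** stratified by direction.
6. **Survival validation** on an independent cohort via per-gene Cox
   screening, pathway risk indices, median-split log-rank tests, and
   hierarchical clustering.
7. A **synthetic-data generator** that reproduces the statistical structure
   the method assumes, so that every stage is testable without downloads.

# The rank-based DEG model

## Stable pairs

For genes $a, b$ and a sample $s$, the REO is the sign of
$x_a(s) - x_b(s)$. In control tissue these orderings are largely fixed:
`find_stable_pairs()` keeps the ordered pair $(a, b)$, meaning $a < b$, when
$x_a < x_b$ holds in at least a fraction $c$ of control samples (default
$c = 0.99$). Ties count against consistency, and a pair can enter in at
most one orientation. Because only within-sample comparisons are used, the
pair set is exactly invariant under any strictly increasing transform
applied per sample — the formal version of "robust to batch effects and
insensitive to normalisation", and a property the test suite asserts
bit-for-bit.

## Per-sample reversal test

For a disease sample and a gene $g$ with $U$ stable pairs on whose low side
it sits and $D$ on whose high side, let $u$ and $d$ be the counts of those
pairs whose ordering the sample reverses. A reversal of a low-side pair is
evidence that $g$ moved up; of a high-side pair, that it moved down.
`sample_reversal_test()` tests the null that up- and down-supporting
reversal rates are equal with a two-sided Fisher exact test on

$$\begin{pmatrix} u & U - u \\ d & D - d \end{pmatrix},$$

assigns the direction with the larger reversal rate, and flags significance
by Benjamini–Hochberg within the sample (default level 0.05). Genes with no
stable partner are reported untestable ($p = 1$). The Fisher $p$ is the sum
of hypergeometric probabilities over tables with the observed margins not
exceeding the observed table's probability, computed vectorised over all
genes of a sample; it agrees with `stats::fisher.test()` and with direct
enumeration to $10^{-10}$ in the tests.

## Subpopulation-level DEGs

Disease samples are heterogeneous, so a gene is called at the population
level when a non-random *fraction* of samples calls it individually:
`population_deg_test()` counts supporting samples $k$ per direction (ties
between directions excluded), computes the exact upper binomial tail
$P(X \ge k)$ under a null per-sample call rate (default 0.05, the rate
implied by the per-sample BH level), and applies BH across genes at a 5%
FDR.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_consistency` | 0.99 | stable-pair consistency across controls (fraction, in [0.5, 1]) |
| `sample_fdr` | 0.05 | within-sample BH level for per-sample calls |
| `null_rate` | 0.05 | binomial null per-sample call probability |
| `fdr` | 0.05 | BH threshold for the final DEG flag |
| `effect_threshold` | 0.5 | minimum Kulinskaya delta magnitude (dimensionless) |
| `effect_center` | `"median"` | per-sample centering before effect sizes |

The consistency default of 0.99 is deliberately strict; with $n$ controls
it admits only pairs consistent in at least $\lceil 0.99\,n \rceil$
samples, which for $n \le 100$ means at most one violation. Lowering it
grows the pair set (more power per sample, weaker background) and is the
first knob to consider for small control sets.

# The effect-size screen

Expression of a DEG in the two groups is modelled as normal with unequal
variances, $X_i \sim N(\mu_i, \sigma_i^2)$, $X_j \sim N(\mu_j,
\sigma_j^2)$. With $n = n_i + n_j$ and $q = n_j / n$ the standardized
effect is

$$\delta = \frac{\mu_i - \mu_j}{\sigma}, \qquad
  \sigma^2 = \frac{q\,\sigma_i^2 + (1-q)\,\sigma_j^2}{q\,(1-q)},$$

which satisfies $\sigma^2 / n = \sigma_i^2/n_i + \sigma_j^2/n_j$ and hence
$\sqrt{n}\,\hat\delta = t_{\text{welch}}$ exactly. Note the scale: for
equal group sizes and equal unit variances, a one-unit mean difference
gives $\delta = 0.5$, i.e. this $\delta$ is half the classic pooled-SD
standardized difference. The screen keeps DEGs with $|\delta| \ge 0.5$
(boundary inclusive) whose sign agrees with the rank-based direction;
sign conflicts are dropped and counted, never silently re-signed.
Variances use the unbiased $n-1$ estimator; groups pool samples across
datasets.

**Why per-sample median centering.** The screen compares group *means*,
which — unlike the rank stage — are exposed to per-dataset additive
offsets. In this study design cases and controls never share a dataset, so
a dataset offset is perfectly confounded with the group contrast and would
alias directly into $\hat\delta$ for every gene at once. Subtracting each
sample's median (default `effect_center = "median"`) removes any additive
per-sample component using only that sample's own values, leaves
within-sample structure untouched, and — because planted or real DEG sets
are a minority of genes in both directions — moves the median itself only
negligibly. Set `effect_center = "none"` to reproduce raw pooled means.

# Signature and overlap statistics

`intersect_deg_lists()` intersects the per-origin lists by direction:
`shared_up` is the intersection of up lists, `shared_down` of down lists,
and a gene differential everywhere but with conflicting directions is
excluded and reported as discordant. Overlap significance for a pair of
lists of sizes $m, n$ sharing $k$ genes in a universe of $N$ is the exact
upper hypergeometric tail $P(X \ge k)$; percentages are reported against
each list and against the shorter list. For overlaps as extreme as the
published brain-metastasis counts the tail underflows double precision, so
`overlap_significance(..., log10_p = TRUE)` also returns the exact
base-10 log of the tail.

# Pathway enrichment

`run_enrichment()` tests up- and down-regulated signature genes
separately: per pathway, $K$ members in the universe, $k$ in the stratum
of size $n$, $p = P(X \ge k)$ hypergeometric, BH across pathways at 5%
FDR. The default universe is the integrated genes annotated in at least
one supplied set — with small curated collections an all-genes universe
would make every pathway look depleted-then-enriched purely through
annotation coverage; `universe = "all"` is available when the collection
is genome-wide. Displayed FDRs below 0.001 render as "< 0.001", with full
precision kept in the machine-readable column.

# Survival validation

For each enriched pathway, the signature genes it contains are screened
with univariate Cox models (Efron ties; Wald $p$; constant genes skipped),
the per-patient risk index is the linear combination of expression
weighted by the fitted coefficients, and the cohort is split at the median
risk index — ties to the low-risk group, deterministically — and compared
with the two-group log-rank test. Both raw and BH-adjusted significant
fractions of the per-gene screen are reported, since published "percent
significant" figures rarely state which was used. Patients are clustered
on signature genes with $1 -$ Pearson correlation distance and average
linkage (defaults; both configurable), serialised to Newick, and flat
clusters are tested for enrichment of a patient label (e.g. brain
metastasis) with one-sided Fisher tests. Because the risk coefficients are
fitted and evaluated on the same cohort, decoy pathways also separate
risk groups to a degree; the validation mirrors the published design
rather than adding a train/test split. A Pearson chi-square
(`covariate_balance_chisq()`, no continuity correction, expected-count
warning below 5) checks clinical covariate balance between groups.

# The synthetic-data generator

`simulate_multibatch()` emulates the features of the real collection the
method must survive:

- per-gene baselines $N(7, 2^2)$ on the log2 scale (a broad, unimodal
  stand-in for normalised array intensities), unit-SD Gaussian sample
  noise;
- one dataset per origin plus control dataset(s), each missing a random
  10% of genes ("platforms"), each with an additive scalar batch shift
  $N(0, \texttt{batch\_shift\_sd}^2)$ — the additive half of the batch
  mechanisms REO methods claim to resist; `monotone_distort()` supplies
  the other half (random strictly increasing per-sample cubics);
- planted common DEGs (default 10% of genes, half up, half down, shifted
  by ±1 noise-SD in every origin's cases) and per-origin private DEGs
  (5% each), all disjoint.

Batch shifts are generated as unit draws scaled by `batch_shift_sd`, so
runs that differ only in batch severity share every other random choice —
which is what makes "calls identical at shift SD 0 and 5" a meaningful
paired test. `simulate_survival_cohort()` produces exponential event times
with log-hazard $\sum_g \beta_g x_g$ ($\lVert\beta\rVert$ = the `effect`
parameter), uniform censoring calibrated to a target fraction (default
0.5), and a concordantly signature-high patient subgroup (default 20%)
that mirrors the clinically observed cluster of metastasis-prone patients.

**What the generator does not emulate:** probe-level noise, per-gene
variance heterogeneity, correlated gene modules, intensity-dependent
variance, or subtype structure. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its own model assumptions, not
performance on real arrays.

**Power characteristics worth knowing.** Two consequences of the default
conditions are structural, not bugs, and the acceptance-style tests in
`tests/testthat/test-acceptance.R` measure them honestly rather than
papering over them. First, with 40 controls at consistency 0.99 a stable
pair must be consistent in all 40, which concentrates the pair set on
control margins of roughly three noise-SDs and larger; a one-SD planted
shift then reverses any given stable pair with probability below ~8%, so
per-sample reversal tests recover only a minority of planted genes, and
the end-to-end recovered signature is a small, essentially false-positive
free subset of the planted truth (the measured empirical FDR of the
recovered signature is ~0). Second, a one-noise-SD shift sits exactly at
the screen boundary on this $\delta$ scale (see above), so the screen
passes planted genes with probability near one half. Larger planted
effects, more controls, or a lower consistency threshold all raise
recovery; the defaults were kept at the stated study conditions rather
than tuned.

# Numerical and degenerate-input choices

- Exact tails throughout (`dhyper`/`phyper`/`pbinom`); p-values floored at
  the smallest positive double, never 0.
- Ties: within-sample expression ties break pair consistency and are not
  reversals; direction ties at the population level exclude the gene;
  median-risk ties go to the low-risk group.
- Duplicate gene symbols on input collapse by per-sample mean (configurable
  to median/max); symbols are upper-cased; integrated gene order is
  lexicographic.
- Both-variances-zero effect sizes return a flagged infinite sentinel;
  groups of size < 2 are errors.
- Constant genes are skipped (with a warning) by the Cox screen; constant
  patient profiles are an error for correlation-distance clustering.
- Test-suite problem sizes: unit tests run a 300-gene, 2x8-case,
  12-control configuration; the acceptance-style tests run the full
  2000-gene, 2x30-case, 40-control configuration over seeds 1-20, the
  survival checks 100 replicates at n = 300.

# Known limitations

- Per-sample Fisher calls on genes at the extremes of the baseline
  distribution are weak in one direction (a top-expressed gene has few
  stable partners above it to reverse), an intrinsic asymmetry of REO
  evidence.
- The binomial null rate is a parameter, not an estimate; if per-sample
  calls are correlated across samples (shared stable-pair background,
  genes partnered with true DEGs), the population test can flag genes that
  are only "contaminated" by partners — the effect-size screen is what
  removes these, which is why running the screen is not optional in this
  pipeline.
- The survival validation fits and evaluates risk indices on the same
  cohort, as in the published design; its log-rank p-values are
  optimistic and should be read as descriptive.
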