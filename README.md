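# metorgan

Discovery and validation of **organ-specific metastasis gene signatures**
from heterogeneous transcriptomic collections.

Metastases to one organ (say, brain) arise from different primary tumours
(breast, lung, ...), profiled in different laboratories on different
microarray platforms. Genes that let cancer cells colonise the *target
organ* — rather than genes peculiar to one primary tumour type — should be
differentially expressed against that organ's normal tissue in metastases
from *every* origin. `metorgan` implements that analysis for researchers
working with multi-dataset expression collections where absolute
intensities are not comparable across batches:

- **Integration** restricted to genes detected on all platforms, with no
  cross-dataset intensity normalisation (none is needed downstream).
- **Rank-based differential expression** from relative expression
  orderings (REO). A *stable pair* $(a, b)$ satisfies $x_a < x_b$ in at
  least a fraction $c$ (default 0.99) of control samples. In a disease
  sample, for a gene $g$ with $u$ of $U$ low-side and $d$ of $D$ high-side
  stable pairs reversed, a two-sided Fisher exact test on
  $[[u, U-u], [d, D-d]]$ calls per-sample dysregulation; an exact binomial
  test ($P(X \ge k)$ at null rate 0.05, BH at 5% FDR) promotes genes
  supported by a non-random fraction of disease samples. All calls are
  exactly invariant under any strictly increasing per-sample transform.
- **Effect-size screen**: the heteroscedastic standardized difference
  $\delta = (\mu_i - \mu_j)/\sigma$ with
  $\sigma^2 = \{q\sigma_i^2 + (1-q)\sigma_j^2\}/\{q(1-q)\}$, $q = n_j/n$
  (so $\sqrt{n}\,\delta$ is the Welch t); DEGs kept at $|\delta| \ge 0.5$.
- **Signature**: the direction-consistent intersection of per-origin DEG
  lists, with exact hypergeometric overlap significance and overlap
  percentages.
- **Pathway enrichment** (hypergeometric, up/down-stratified, BH).
- **Survival validation**: univariate Cox screening, pathway risk indices
  $\sum_g \beta_g x_g$, median-split log-rank tests, hierarchical
  clustering, covariate-balance chi-square.
- A **synthetic-data generator** (multi-platform, batch-shifted, planted
  ground truth) making the whole chain testable offline.

## Worked example

The four numbered drivers under `analysis/` run the whole study on
synthetic data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_detect_degs.R
Rscript analysis/03_build_signature.R
Rscript analysis/04_validate_survival.R
```

Stage 2 and 3 print, for the default simulated study (2 origins x 30
metastasis cases, 40 controls, 2000 genes on 3 platforms, planted common
and private DEGs at a 1-SD shift):

```
Integrated 3 datasets: 1452 genes x 100 samples
Stable pairs in 40 controls: 327589
breast   30 cases: 181 DEGs at 5% FDR, 47 pass |delta| >= 0.5
lung     30 cases: 178 DEGs at 5% FDR, 59 pass |delta| >= 0.5
organ_signature for brain: 6 up + 9 down shared genes across 2 origin(s); 0 discordant
overlap breast vs lung: 15 genes = 32% of the shorter list (p = 6.13e-11)
signature composition: 40% up, 60% down
reference counts: 1612/1857 = 87%, 1612/1979 = 81%, log10 p = -1181.9
```

Reading: ~180 genes per origin survive the rank-based subpopulation test,
the medium-effect screen keeps the strong minority, and 15 genes are
called in the same direction in both origins — the simulated
"brain-specific" signature, far more overlap than chance for these list
sizes (hypergeometric p ~ 1e-11). The last line re-expresses the published
study's printed brain-metastasis counts with the same functions: a
1612-gene overlap between lists of 1857 and 1979 in a 9797-gene universe
is 87% and 81% of the two lists, with an (underflowing) hypergeometric
tail of 1e-1182 — comfortably below the study's reported 1e-6 bound.
Stage 4 validates a planted 20-gene signature on an independent simulated
cohort of 300 patients (Cox screen: 100% of signature genes at p < 0.05;
best pathway log-rank p = 2.6e-33; all 56 metastasis-labelled patients in
one cluster).

The same chain is available programmatically:

```r
library(metorgan)
sim  <- simulate_multibatch(sim_config(seed = 1))
coll <- simulate_gene_sets(sim$truth,
                           Reduce(intersect, lapply(sim$matrices, genes)))
rep  <- run_organ_pipeline(sim$matrices, collection = coll)
print(rep)
```

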