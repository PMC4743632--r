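# emdde

Differential expression analysis for two-class genomics data with high
**within-class** heterogeneity, scored by the earth mover's distance.

## Why

Conventional differential-expression statistics (t-type scores, moderated
or not) detect separated class *means*. But a gene can be strongly
class-associated while its means coincide — e.g. one class unimodal, the
other an equal mixture of up- and down-shifted subpopulations, as happens
when a phenotype such as drug resistance arises through several distinct
molecular programs. Such genes have fold change ≈ 1 and t ≈ 0, yet their
expression *distributions* differ dramatically.

`emdde` scores each gene by the earth mover's distance (EMD) between the
two class-wise expression histograms. For unit-mass signatures
P = {(p_i, w_i)}, Q = {(q_j, v_j)} the score is the optimal transportation
cost

    EMD(P,Q) = min_F Σ_ij f_ij |p_i − q_j|   subject to the flow constraints,

which on a shared 1-D grid reduces to the Wasserstein-1 closed form
`binwidth · Σ_i |CumSum(P)_i − CumSum(Q)_i|`. Significance comes from label
permutations: the per-gene median m_k of permuted scores forms the null
vector, FDRs are evaluated on a threshold grid

    FDR(j, t) = #{m_k > t} / #{s_k > t}   for genes with s_j ≥ t,

and each gene's q-value is its minimum FDR over the grid. Baseline
two-sample statistics (Kolmogorov–Smirnov with BH-adjusted analytic
p-values; Cramér–von Mises and a SAM-style moderated t routed through the
same permutation machinery), a mixture-of-Gaussians simulator with ground
truth, and ROC/confusion evaluation are included, so the method and its
conventional competitors can be compared under controlled heterogeneity.

## Worked example

A mean-matched bimodal signal — invisible to fold change — detected

```r
library(emdde)
sim <- simulate_case(builtin_case(4, n_genes = 400, n_de = 40, seed = 42))
res <- run_emd_de(sim$expression, sim$labels, n_perm = 200, seed = 42)
head(res[order(res$q_value), ], 5)
#>     gene    score null_median q_value fold_change
#> 1 g00001 1.789333   0.5853333       0   1.4537199
#> 2 g00002 2.114667   0.6142222       0   0.7654402
#> 3 g00003 2.433333   0.6720000       0   1.0939114
#> 4 g00004 2.056889   0.6151111       0   0.4347249
#> 5 g00005 2.438222   0.6173333       0   0.7005757

roc_auc(res$q_value, sim$truth)
#> ROC over q-value sweep: 24 points, AUC = 1.0000
confusion_at_q(res$q_value, sim$truth, 0.05)
#> tpr fpr
#>   1   0
summary(res$fold_change[sim$truth])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.4347  0.6943  0.8569  0.9267  1.0748  1.9644
```

Every truly differential gene is recovered at q < 0.05 with no false
positives (`tpr = 1, fpr = 0`, AUC 1.0), even though the median fold change
of those genes is 0.86 — a mean-based method would rank most of them as
unremarkable. The `score` column is in expression units (here, ~2 log2
units of distribution distance); `null_median` is each gene's own permuted
null level.

The same pipeline from the shell:

```sh
emdde simulate --case 4 --seed 42 --ngenes 400 --nde 40 --out-prefix sim
emdde run --expression sim_expression.tsv --labels sim_labels.tsv \
          --method emd --nperm 200 --seed 42 --out results.tsv
emdde evaluate --results results.tsv --truth sim_truth.tsv --out metrics.tsv
```

(`emdde` is installed to `<library>/emdde/exec/emdde`; `run` also accepts
`--method cvm|ks|sam`, preprocessing switches `--filter/--log2/--quantile`,
and a `--config file.yaml` whose keys explicit flags override.)

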