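# scm6a

N6-methyladenosine (m6A) is the most prevalent internal mRNA modification,
and its levels differ strongly between cells — yet the standard assay,
antibody-based m6A-seq/MeRIP-seq, measures bulk populations. `scm6a`
implements a machine-learning route to **single-cell m6A quantification**:
since m6A deposition at a site is controlled by *trans* regulators
(writers, erasers, readers and their cofactors) and by *cis* sequence
elements (DRACH/GGACU-type motifs), per-site methylation levels can be
regressed on regulator expression, and the fitted models then applied to
scRNA-seq expression profiles to predict m6A levels cell by cell.

The package is aimed at epitranscriptomics groups who have (i) bulk m6A-seq
IP/input window counts for training/validation and (ii) single-cell or bulk
RNA-seq expression matrices for prediction — plus anyone who needs a clean,
tested implementation of winscore-based m6A-seq quantification.

## What it computes

**Winscore quantification** of m6A-seq. For window *w* on the sliding grid
(100 bp windows, 50 bp steps by default),

```
RPKM_w    = count_w / ((width_w/1000) · (library_size/10^6))
winscore_w = (RPKM_w^IP + 1) / (RPKM_w^input + 1)
```

Windows with winscore > 2 are significant; maximal runs of consecutive
significant windows within a gene are merged into peaks and peaks longer
than 5 windows (300 bp) are split greedily. Peak levels are the mean (or
max) of member-window winscores, giving a peaks × samples m6A matrix.

**Scm6A prediction.** For each m6A site *s*, a regressor
`y_s ≈ f_s(x)` is fitted, where `x` is the (log1p) expression vector of the
m6A trans-regulator panel (optionally joined with per-site cis features —
flattened position probability matrices or motif match scores). Five
families are available — random forest, linear regression, k-nearest
neighbours, linear SVR and polynomial SVR — with hyperparameters chosen by
grid search under 5-fold cross-validation on a random 70/30 train/test
split.

**Evaluation.** Per-site R², tolerance-label ROC/AUROC and balanced
accuracy (a prediction is "accurate" when |ŷ − y| ≤ 0.5), permutation
nulls with empirical p-values, matched-window correlation between
independently quantified m6A matrices, and 30-bin metagene peak profiles
(10 bins each in 5'UTR, CDS, 3'UTR). Metric distributions are summarized
by median and quartiles.

A seeded synthetic-data generator plants a sparse regulator→site network,
log-normal expression, Poisson IP/input window counts with configurable IP
enrichment, and motif PPMs, so the entire pipeline is testable end-to-end
without any external download.

## Worked example

```r
library(scm6a)
cfg <- sim_config(n_cells = 300, n_regulators = 30, n_sites = 10,
                  noise_sd = 0.1, seed = 3)
sim <- simulate_dataset(cfg, fold_from_levels = TRUE)

# 1. winscore quantification of the simulated IP/input pair
q <- quantify_m6a(sim$counts$ip, sim$counts$input)
q$peaks[1:3, c("peak_id", "n_windows", "start", "end")]
#>              peak_id n_windows start  end
#> 1   GENE0001:250-450         3   250  450
#> 2 GENE0002:1100-1350         4  1100 1350
#> 3  GENE0003:850-1100         4   850 1100

matched <- match_windows(sim$m6a, q$levels)
correlate(rowMeans(sim$m6a)[matched$id_a], q$levels[matched$id_b, 1])
#> $r [1] 0.6175892   $p [1] 0.0570944   $n [1] 10

# 2. Scm6A: per-site random forests on regulator expression
feats <- log1p(build_trans_features(t(sim$expr), colnames(sim$expr)))
fit  <- fit_scm6a(model_spec("rf", grid = list(num.trees = 300)),
                  feats, sim$m6a, train_config(seed = 3))
pred <- predict(fit, feats)
evaluate_predictions(sim$m6a[, fit$split$test],
                     pred[, fit$split$test], eval_config(seed = 3))
#> $summary
#>                        q25    median       q75
#> r2                0.764103 0.7791103 0.8029372
#> auroc             1.000000 1.0000000 1.0000000
#> balanced_accuracy 1.000000 1.0000000 1.0000000
```

Reading the output: all ten planted peaks are recovered by the winscore
method and matched 1:1 to the planted sites; winscore levels correlate
positively (r = 0.62 over 10 sites) with the planted truth; and the random
forests explain a median 78% of held-out per-cell variance in site
methylation. The AUROC/balanced-accuracy columns are computed on the
tolerance-labeled pool, where the label is a threshold of the error score —
they sit near 1 whenever predictions are mostly accurate and are meaningful
relative to their permutation null (~0.5), not in absolute terms (see the
methods vignette).

The same workflow runs from the shell via the thin CLI in
`inst/cli/scm6a`:

```sh
Rscript inst/cli/scm6a all --seed 3 --out my_run
```

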