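# methylnb

Weighted Bernoulli naive Bayes classification of tumor methylomes from
sparse, binary single-molecule CpG methylation calls.

## The problem

DNA methylation profiles assign tumors — CNS tumors in particular — to
molecularly defined classes, but array workflows take days. Real-time
nanopore sequencing produces per-molecule 5mC calls within minutes of
loading a library, covering only a tiny, essentially random subset of the
reference CpGs (well under 2% after 15 minutes), each as a single binary
observation. `methylnb` is for analysts who want to train on bulk
methylation-rate references (450k/EPIC-style beta matrices) once and then
classify such sparse binary observations live, while sequencing is still
running.

## The model

Training on a samples-by-probes rate matrix yields per class $C_j$ the
centroid $\mu_{i,j}$ (class mean rate of CpG $i$, used as the Bernoulli
success probability), the log prior (empirical class frequency), and
ReliefF feature weights $w_{i,j} = e^{-\omega_{i,j}}$, where
$\omega_{i,j}$ sums, over the class's samples, the mean per-feature
distance to the $k = 5$ nearest foreign-class centroids minus the mean
distance to same-class samples. A prediction-time observation is a set of
calls $(x_i, r_i, \eta_i)$ — binary state, read weight
$r_i = 1/(\text{model CpGs on the read})$ (reads with more than 10 are
dropped), and noise $\eta_i = \max(0.05, 0.5 - |m_i - 0.5|)$ — scored by

$$
L_j = \frac{300/\sum r_i}{W_j} \sum_i r_i\, w_{i,j}
  \left[x_i \log \mu'_{i,j} + (1 - x_i) \log(1 - \mu'_{i,j})\right],
\qquad \mu' = \mu(1 - 2\eta) + \eta,
$$

with unobserved CpGs simply omitted. Posteriors come from the log-sum-exp
normalized $L_j + \log P(C_j)$; the top class is reported as a
high-certainty call when its posterior reaches $\tau = 0.6$. See the
methods vignette (`vignettes/classifying-sparse-methylomes.Rmd`) for the
weight-transform sign convention and every numerical choice.

## Worked example

Train on a synthetic reference (10 samples for each of 6 classes, 5,000
CpGs, 5% class-informative features), then classify a fresh profile from
1,000 observed CpGs:

```r
library(methylnb)

fixture <- generate_reference_fixture(m = 6, p = 5000, n_per_class = 10,
                                      n_informative = 250, delta = 0.4,
                                      seed = 1)
model <- meth_nb(fixture, weighting = "none")
model
#> <meth_nb> 6 classes x 5000 probes (k = 5, weighting = none)

beta <- attr(fixture, "class_beta")["class_03", ]    # a new class-03 methylome
profile <- simulate_profile(beta, seed = 2)          # binary molecule-level draw
obs <- subsample_cpgs(profile, 1000, seed = 3)       # 1,000 observed CpGs
predict(model, obs, tau = 0.6)
#> # A tibble: 1 x 7
#>   top_class top_posterior high_certainty n_calls n_features effective_read_count
#>   <chr>             <dbl> <lgl>            <int>      <int>                <dbl>
#> 1 class_03          0.970 TRUE              1000       1000                 1000
```

The sample is assigned to its true class with posterior 0.97 — a
high-certainty call at the 0.6 threshold — from 20% of the reference CpGs
observed once each. The full ranked posterior sits in the `posterior`
list-column:

```r
head(predict(model, obs)$posterior[[1]], 3)
#>   class    log_posterior posterior
#> 1 class_03       -0.0305    0.970
#> 2 class_01       -4.23      0.0145
#> 3 class_05       -4.57      0.0104
```

For BAM input, `extract_calls()` decodes MM/ML tags against a probe
manifest, `binarize_calls()` + `filter_and_weight_reads()` prepare the
observation, and `run_offline()` / `run_live()` classify whole directories
(the live mode re-emits a posterior every `min_entries` new CpG calls
while files keep arriving). `score_predictions()`, `threshold_sweep()` and
`time_course()` evaluate predictions at the fine class, clinical-group and
class-family tiers.

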