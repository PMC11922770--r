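---
title: "Classifying tumor methylomes from sparse single-molecule CpG calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor methylomes from sparse single-molecule CpG calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylnb)
```

## The problem

Methylation profiling assigns tumors to molecularly defined classes with
high reliability, but array-based workflows take days. Real-time
single-molecule sequencing delivers CpG methylation calls within minutes of
loading a library — only very few of them. After 15 minutes a run typically
covers well under 2% of the CpG probes a reference cohort was profiled on,
each covered by a single molecule, so the observation is a sparse *binary*
vector rather than a methylation-rate profile. `methylnb` classifies such
observations against bulk reference cohorts.

## Model

A reference cohort is a samples-by-probes matrix of methylation rates
(beta values) with class labels. Training produces, per class $C_j$:

* **centroids** $\mu_{i,j}$ — the class mean methylation rate of probe $i$,
  used as the Bernoulli success probability $P(x_i = 1 \mid C_j)$;
* **log priors** $\log P(C_j)$ — empirical class frequencies by default;
* **feature weights** $w_{i,j}$ — ReliefF-derived likelihood exponents
  (below).

A prediction-time observation is a set of calls $(x_i, r_i, \eta_i)$: a
binary methylation state, a read weight, and a noise term. Under the naive
conditional-independence assumption the class log-likelihood uses only the
observed probes — missing features simply drop out of the product, which is
what makes the model natural for shallow sequencing:

$$
L_j = \frac{s}{W_j} \sum_i r_i\, w_{i,j}
  \left[ x_i \log \mu'_{i,j} + (1 - x_i) \log (1 - \mu'_{i,j}) \right],
$$

with three corrections:

* **Noise shrinkage.** Each call's uncertainty
  $\eta_i = \max(0.05,\ 0.5 - |m_i - 0.5|)$ (with $m_i$ the methylation
  probability) shrinks the centroid toward $1/2$:
  $\mu' = \mu (1 - 2\eta) + \eta$. With the 0.05 floor, $\mu'$ is confined
  to $[0.05, 0.95]$, so no log term can diverge even for degenerate
  centroids of 0 or 1.
* **Read weighting.** CpGs on the same molecule are strongly correlated.
  Reads covering more than 10 model CpGs are dropped entirely, and each
  remaining call is weighted by $r_i = 1/(\text{model CpGs on its read})$.
  The summed log-likelihood is rescaled by $s = 300 / \sum_i r_i$, a
  standardization to a base count of 300 reads that keeps posteriors on a
  comparable scale across sequencing depths (it never changes the argmax).
* **Class weight normalization** $W_j$: because weights are class-specific,
  classes would otherwise spend different total weight mass on the same
  observation. Each class's sum is divided by its mean observed weight
  ($W_j = \sum_{i \in \text{obs}} w_{i,j} / n_{\text{obs}}$), the simplest
  normalization that equalizes the spent mass; it is exposed as the
  `normalize` argument of `weighted_log_likelihood()`.

Posteriors are computed with the log-sum-exp trick and remain well-defined
for log-likelihoods down to $-10^6$. The argmax class is reported, flagged
high-certainty when its posterior reaches the threshold $\tau$ (default
0.6, the operating point that balances precision against call rate in a
threshold sweep); ties are broken lexicographically and logged.

## ReliefF feature weighting and its sign convention

Feature informativeness is scored per class by an adapted ReliefF: for each
training sample of class $C_j$, the mean per-feature distance to its $k$
(default 5) nearest foreign-class *centroids* (misses) minus the mean
distance to the remaining same-class samples (hits), summed over the
class's samples. Nearest centroids are identified by the whole-profile mean
absolute difference — the same per-feature distance the score itself uses;
the metric is a package choice, made configurable in spirit by operating on
any rate matrix. Hits are sample-to-sample, which is what makes training
quadratic in per-class sample counts (and linear in features and classes).
Informative features receive $\omega > 0$.

Scores become likelihood exponents through $w = e^{-\omega}$ (after
clipping $\omega$ to $\pm 50$; $e^{50}$ already dominates any sum). This is
the published convention, and the package implements it exactly as printed.
Note its direction: features with *large* $\omega$ — the discriminative
ones — receive exponents *below* one, i.e. their likelihood contribution is
flattened, and anti-informative features are amplified. On reference
cohorts whose classes are strongly correlated, $\omega$ stays near zero and
the transform is a mild regularizer. On a well-separated, conditionally
independent fixture it is not mild: the `parameter_recovery()` experiment
(reported by `scripts/acceptance.R` as `recovery_accuracy_relieff_expneg`
next to the unweighted `recovery_accuracy_1000cpg`) shows the printed
transform collapsing an otherwise essentially perfect recovery. Because the
intent behind the published sign cannot be inferred from its description,
the package does not silently "fix" it: `weight_transform = "exp_neg"` is
the default, `"exp_pos"` is available behind a flag, and
`weighting = "none"` disables weighting altogether.

Consequently the canonical parameter-recovery experiment runs the
**unweighted** Bernoulli core. Its fixture generates conditionally
independent features — exactly the regime in which unweighted naive Bayes
is the correct model and a correlation-compensating weighting scheme has
nothing to correct. Recovery there validates centroid estimation, the
noise-adjusted likelihood and the posterior machinery; it deliberately does
not validate the weighting scheme, whose effect on real, correlated
methylomes synthetic fixtures cannot capture either way.

## Out-of-sample recovery draws

`parameter_recovery()` classifies profiles Bernoulli-sampled from *freshly
jittered* class methylomes rather than from the training samples
themselves. Replicating a training sample feeds its own jitter back through
the class centroid and measurably inflates accuracy — on an uninformative
fixture (all class methylomes identical) replicate draws score far above
the $1/m$ chance level, while out-of-sample draws sit on it. The replicate
protocol (100 binary replicates per training sample) is still available as
`simulation_study()`, because it is the standard evaluation design for
cohort-scale references, where a single sample's leverage on its class
centroid is small.

## The synthetic-data generator

`generate_reference_fixture()` emulates an array-style reference: a
baseline beta vector shared across classes (Uniform(0.05, 0.95)), per class
a random subset of features shifted by $\pm\delta$ (clipped to
[0.02, 0.98]), and per-sample truncated-Gaussian jitter ($\sigma = 0.05$ by
default) providing the within-class variance without which ReliefF hit
terms degenerate. The canonical study conditions are 10 classes, 5,000
features, 20 samples per class, 5% informative features at $\delta = 0.4$,
and 1,000 observed CpGs per classified profile.

`generate_manifest()` plus `generate_synthetic_bam()` build a synthetic
chromosome with CpG sites at fixed spacing and write aligned reads whose
MM/ML tags encode a chosen binary profile (probabilities near 0/1, a
configurable fraction inside the discard band, forward- and reverse-strand
alignments, per-read timestamps). This exercises the full ingest path —
MM/ML decoding, CIGAR mapping, strand collapsing, binarization at the
0.2/0.8 (or 0.3/0.7 for R10-style calls) cutpoints, read filtering and
weighting — end to end against a known truth.

What the generator does **not** emulate: inter-feature correlation along
the genome, class-imbalanced cohorts, purity gradients, basecaller error
physics, and platform-specific probability distributions beyond the
discard-band knob. Passing synthetic tests therefore demonstrates
correctness of the machinery, not clinical performance.

All randomness descends from one master seed through a fixed splitting
scheme (a prime-stride sequence kept below $2^{31}$), so every experiment
regenerates identically.

## Numerical and design choices

* Binarization bounds are inclusive ($\le 0.2$ unmethylated, $\ge 0.8$
  methylated; 0.3/0.7 in R10 mode), and the per-read feature count for the
  \>10-CpG filter is taken *after* discard-band removal (configurable),
  since only retained calls enter the likelihood.
* Reverse-strand calls are collapsed onto the forward-strand probe
  coordinate; CpG methylation is strand-symmetric. A read yielding several
  calls at one probe keeps the first in file order.
* Duplicate coverage of a probe by different reads is retained: each
  molecule is an independent observation.
* ML probability bytes are decoded as $\mathrm{ml}/255$.
* Missing training rates are imputed by class-conditional means (the
  centroid is unchanged by construction); an all-missing class/feature cell
  falls back to the overall feature mean, with a message.
* Batch correction removes per-feature batch-group means (the closed form
  of a univariate fixed-effect fit), preserving the grand mean exactly and
  clipping rates back to [0, 1].
* The base-count scale $s$ is applied after the $W_j$ normalization; the
  order is irrelevant to the argmax but defines the calibrated scale
  against $\tau$.
* The exact signed-rank null for `compare_f1()` is enumerated for up to 12
  informative pairs (average ranks under ties, zeros dropped, $p = 1$ for
  all-zero differences); larger inputs fall back to the asymptotic test.
* Live mode is purely filesystem-driven (polling), emits a posterior per
  `min_entries` new CpG entries with carry-over (so one large batch can
  trigger several emissions), and flushes a final emission for any
  remainder — making the emission count for a finished run
  $\lceil \text{entries} / \text{min\_entries} \rceil$ and the final tables
  identical to an offline run over the same files.

## Problem sizes used in the checks

The test suite and acceptance script run the recovery experiment at the
canonical fixture scale (10 x 5,000 x 20, 1,000 draws), the replicate
protocol at smoke scale (5 replicates per sample on a 6-class, 5,000-probe
fixture), and ingest round trips on references of a few hundred CpG sites;
these sizes give binomial standard errors of about one percentage point on
the reported accuracies. Published-scale references (thousands of samples,
428,201 probes) are handled by the same code paths; the `reproduce/`
workflow documents that run, which requires downloading the public GEO
cohorts.

## Limitations

* The package consumes normalized beta matrices; raw IDAT processing
  (background/dye-bias correction, detection p-values) belongs to the
  array-processing toolchain upstream.
* No copy-number, purity, or hierarchy-aware decision modeling: the class
  hierarchy is an evaluation-time relabeling, not a model structure.
* The weighting scheme's behavior on real, correlated methylomes cannot be
  validated synthetically; the printed transform is preserved as published
  and its alternatives are exposed as options rather than silently chosen.
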