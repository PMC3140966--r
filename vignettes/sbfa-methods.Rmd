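---
title: "Sparse Bayesian factor analysis of spatial expression images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian factor analysis of spatial expression images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spexfa)
```

## The model

A corpus of registered, background-free grayscale embryo images is reduced
to an $N \times P$ matrix $X$: each image contributes one row of $P$
grid-patch mean intensities (row-major over the grid), centered to zero
mean. The generative model is

$$X = \Lambda F + E,$$

where the $K$ rows of $F$ ($K \times P$) are latent *spatial factors* —
image-shaped templates such as an anterior domain or a pair-rule stripe
pattern — and $\Lambda$ ($N \times K$) holds the *mixing weights* (factor
loadings) that say how strongly each image uses each template. $E$ is
Gaussian noise with per-feature precision $\psi_p$.

The biological prior is sparsity: an expression pattern is built from a
handful of spatial domains, so each row of $\Lambda$ should have few
appreciable entries. Each loading gets a normal prior with its own
precision, $\lambda_{nk} \sim \mathcal N(0, \alpha_{nk}^{-1})$ with
$\alpha_{nk} \sim \text{Gamma}(a, b)$ (shape–rate); marginalizing
$\alpha$ gives a Student-t prior that concentrates mass at zero while
keeping heavy tails for the loadings that matter. Factor entries have
standard normal priors; $\psi_p \sim \text{Gamma}(c, d)$.

## Gibbs sampling

All four conditionals are conjugate, and one sweep updates, in fixed
order,

1. **Factors.** Column $p$ of $F$ is Gaussian with covariance
   $\Sigma_p = (I_K + \psi_p \Lambda^\top\Lambda)^{-1}$ and mean
   $\psi_p \Sigma_p \Lambda^\top x_p$. All $P$ columns are drawn at once
   through an eigendecomposition of $\Lambda^\top\Lambda$ (the columns
   share it; only the scalar $\psi_p$ differs).
2. **Loadings.** Row $n$ of $\Lambda$ is Gaussian with covariance
   $(\mathrm{diag}(\alpha_n) + F \Psi F^\top)^{-1}$ and mean
   $\Sigma_n F \Psi x_n$; sampled via Cholesky factorization of the
   precision (jitter $10^{-10}$ is added only if factorization fails,
   with a message).
3. **Loading precisions.**
   $\alpha_{nk} \sim \text{Gamma}(a + \tfrac12,\; b + \lambda_{nk}^2/2)$.
4. **Noise precisions.**
   $\psi_p \sim \text{Gamma}(c + \tfrac N2,\; d + \tfrac12 \sum_n (x_{np} -
   \lambda_n^\top f_p)^2)$, per feature by default (`psi_mode = "scalar"`
   pools them).

The posterior summary is the plain arithmetic mean of the post-burn-in
sweeps (no thinning). Factor rows are reported with unit L2 norm, moving
the arbitrary scale split between $\Lambda$ and $F$ into the loadings;
`normalize_factors = FALSE` returns raw means. The per-sweep
reconstruction MSE is kept as a convergence trace (`plot_trace()`).

### Why the default prior is $a = 0.5$, $b = 10^{-10}$

The likelihood is invariant under invertible mixing of the factors; only
the sparsity prior can break that rotation. The Student-t marginal
discriminates a zero from a nonzero loading on the scale $\sqrt{2b}$: the
conditional log-density difference between $\lambda = 0$ and
$|\lambda| = s$ is about $(a + \tfrac12)\,\log(1 + s^2/2b)$. If
$\sqrt{2b}$ is comparable to a typical nonzero loading, the prior barely
distinguishes a sparse loading matrix from a rotated dense one, and the
sampler settles in a rotated mode: on the default synthetic corpus with a
broad prior ($a = b = 10^{-3}$) the estimated factors span the true
subspace almost perfectly (canonical correlations > 0.98) yet individual
factors stay mixed (mean $|r| \approx 0.74$). With $b = 10^{-10}$ and
$a = 0.5$ the discrimination is sharp, and the same chains recover the
planted templates with mean $|r| > 0.9$ across seeds. Both parameters
remain arguments of `sbfa()`; the noise prior stays broad
($c = d = 10^{-3}$).

Iteration defaults are `n_iter = 1000`, `burn_in = 300`. The package's
own tests and the acceptance script use 600–800 sweeps on the default
corpus (below), where the trace flattens within the first 100–200
sweeps; these problem sizes keep a full run in tens of seconds.

### Identification

Factor models are identified only up to row permutation and sign.
`align_factors()` greedily matches estimated to reference rows by largest
absolute Pearson correlation and fixes signs to make matched correlations
positive; it is used whenever estimates are compared to planted truth.

## The synthetic corpus

`simulate_corpus()` generates data with exactly the structure the model
assumes, so every downstream stage is testable without any external
image archive:

* **Templates.** Six stock kinds on an elliptical embryo mask: anterior
  and posterior half-domains, dorsal and ventral bands, periodic stripes
  along the A–P axis, and the embryo shape itself (mimicking the
  non-expression factors real corpora produce). Unit-norm, row-major.
  The *default* corpus uses anterior, posterior, both bands and two
  stripe factors of different period: anterior + posterior equals the
  shape template exactly, so including the shape factor would make the
  truth rank-deficient after centering and factor recovery ill-posed.
* **Loadings.** Entries are exactly zero with probability `sparsity`
  (default 0.8) and otherwise *half-normal*: staining accumulates, so an
  image uses a template additively or not at all. This also keeps
  annotation terms planted by a loading threshold one-sided, hence
  learnable by a linear classifier. A gene's replicate images (default
  2) share its loading row; `prop_noninformative` zeroes a random
  fraction of image rows to emulate failed stainings.
* **Noise.** Gaussian with a single precision chosen so that
  `var(centered signal) * psi = snr` (default 10), implying a
  reconstruction $R^2$ of $\mathrm{snr}/(1+\mathrm{snr}) \approx 0.91$.
* **Labels and gene sets.** `derive_labels()` assigns a term to every
  gene whose absolute loading on the term's factor exceeds a threshold;
  `plant_gene_sets()` builds, per factor, a set of its top-loading genes
  plus background, giving enrichment analyses a known answer.

Default scale: 100 genes × 2 images, $K = 6$, grid 20 × 40
($P = 800$), sparsity 0.8, SNR 10. This is desk-scale — a full Gibbs
run takes well under a minute — while leaving recovery nontrivial.

What the generator does *not* emulate: staining chemistry, focal blur,
tilt, registration error, multi-view mixtures, or the long-tailed image
counts per gene of real archives. Passing tests demonstrate correctness
of the inference and analysis machinery under the model's own
assumptions, not robustness to real-data pathologies.

## Downstream analyses

* **Clustering.** Each gene goes to the factor with its largest absolute
  pooled loading (`gene_loadings()` pools a gene's images, mean by
  default; ties to the lowest index; all-zero rows unassigned).
* **Informative entries and cluster links.** A loading is informative
  when within a fraction `tau` (default 0.1) of the row's absolute
  maximum; two clusters are linked by the genes informative for both.
* **Enrichment.** Hypergeometric upper-tail (exact) or Pearson
  chi-square (no continuity correction, flagged when an expected cell is
  zero), against the universe of analyzed genes, with joint BH (default)
  or Bonferroni adjustment across all set × cluster cells.
* **Filtering.** Images whose loading row has small Euclidean norm use no
  factor appreciably — failed stainings and ubiquitous expression.
  `valley_threshold()` picks the separating value as the density minimum
  between the two main modes of the *log* norm distribution (the two
  groups differ by orders of magnitude, so the valley is well defined on
  the log scale); rows exactly at the threshold are kept.
* **Annotation.** `train_smlr()` maximizes the exact L1-penalized
  logistic log-likelihood (MAP under a Laplacian prior; binary case of
  sparse multinomial logistic regression) by accelerated proximal
  gradient with monotone restarts, then plain proximal polishing so
  inactive weights are exactly zero; the intercept is unpenalized so
  sparsity is not coupled to class balance. Convergence is declared at
  an objective change below `tol`. `reg_lambda` defaults to 0.1 (total
  penalty, not per-sample). A polynomial-kernel SVM with unit cost is
  available through an adapter (`train_svm_poly()`), its decision values
  oriented so positive predicts the positive class.
* **Evaluation.** Gene-level leave-one-out CV (`gene_loocv()`) holds out
  all images of one gene per fold. Majority voting labels a gene 1 only
  with a strict majority of positive images (ties → negative,
  conservative); minority voting counts a gene correct if any image is
  right — which logically dominates majority accuracy. For ROC analysis
  a gene's score is the fraction of its images with positive decision
  value, so thresholding at 1/2 reproduces majority voting and at 0
  minority voting; the reducer is pluggable and recorded in reports.
  AUC is the rank-based Mann–Whitney statistic (ties half). Recognition
  rate (ARR) is reported at stated level (image or gene) because it is
  inflated on unbalanced data — a trivial larger-class predictor scores
  the base rate. `evaluation_report()` never leaves the voting rule,
  classifier, CV scheme or level implicit.

## Numerical choices and edge cases

* Grid features require image dimensions divisible by the grid; the
  bilinear rescale (align-corners convention, so constants and linear
  ramps are exact) guarantees divisibility rather than silently padding.
* Stacking order is row-major everywhere, so factor rows are
  reconstructable as images.
* Zero-variance rows in alignment match with correlation 0.
* Hypergeometric tails are exact sums, never normal approximations.
* SMLR's nonzero count along a regularization path is reported as is:
  the attained L1 norm is provably non-increasing in `reg_lambda`, but
  the active set itself can gain a coordinate locally, so the package
  does not "clean up" such solutions.
* All simulation and inference functions take explicit seeds and restore
  the caller's RNG state.

## Known limitations

* Inference is single-chain Gibbs; no automatic selection of $K$, no
  rotation-identified (orthogonalized) solutions, no variational
  alternative.
* Posterior means are reported without credible intervals.
* The classifier suite is binary per term; multi-label structure across
  terms is not modeled.
* Real-image preprocessing (segmentation, registration, stain
  separation) is out of scope; inputs are assumed registered and
  background-free.
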