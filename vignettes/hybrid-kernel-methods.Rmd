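---
title: "A hybrid linear-Gaussian-polynomial kernel SVM pipeline for imbalanced expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid linear-Gaussian-polynomial kernel SVM pipeline for imbalanced expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgpsvm)
```

## The problem

Microarray (and more generally bulk expression) classification sits in an
awkward statistical regime: tens to a few hundred samples, thousands to
tens of thousands of genes, and class frequencies that are often severely
imbalanced (a tumour subtype with 6 patients next to one with 139). A
support vector machine is a natural classifier here, but its behaviour is
governed entirely by three choices: the penalty `C`, the kernel family,
and the kernel's parameters. `lgpsvm` implements a complete pipeline that
makes those choices automatically:

1. min-max normalization of each gene to `[0, 1]`;
2. a train/test split, with 5-fold cross-validation inside the training
   set;
3. per-fold PCA feature extraction (components retained by a 95%
   cumulative-variance rule);
4. a multiclass soft-margin SVM on the PCA scores, driven by a hybrid
   **linear-Gaussian-polynomial (LGP)** kernel;
5. particle swarm optimization (PSO) of every free parameter against the
   cross-validated accuracy;
6. evaluation with imbalance-aware multiclass metrics (G-mean, macro
   F-score, prevalence-weighted accuracy).

## The LGP kernel

Single kernels trade off complementary strengths: the linear kernel is a
*global* similarity (distant samples still influence the decision
surface), the Gaussian kernel is *local* (dominated by near neighbours),
and the polynomial kernel interpolates with good extrapolation behaviour.
The hybrid kernel mixes all three:

$$K_{\mathrm{LGP}}(x, y) \;=\; \beta_1\,(x \cdot y) \;+\;
\beta_2\,\exp\!\left(-\,\frac{\beta_3\,\bigl(\eta\,(x \cdot y) + \delta\bigr)^{d}}{2\sigma^2}\right)$$

with mixing weights on the probability simplex
($\beta_1 + \beta_2 + \beta_3 = 1$, each $\beta_i \in [0,1]$): a weighted
linear kernel plus a Gaussian-type envelope of the polynomial kernel. With
$\beta = (1,0,0)$ it reduces exactly to the linear kernel; with
$\beta_3 = 0$ the exponential term degenerates to the constant 1.

```{r}
p <- kernel_params("lgp", beta = c(0.5, 0.3, 0.2),
                   eta = 1, delta = 0, degree = 2, sigma = 1)
lgp_kernel(c(1, 0), c(1, 0), p)   # 0.5 + 0.3 * exp(-0.1)
```

### Series oracle and its convergence region

Expanding the exponential term as a Taylor series in the polynomial
kernel,

$$K_{\mathrm{LGP}} = \beta_1 K_{\mathrm{lin}} + \beta_2 \sum_{i \ge 0}
\frac{(-\beta_3\gamma)^i}{i!}\,K_{\mathrm{poly}}^{\,i}, \qquad
\gamma = \frac{1}{2\sigma^2},$$

gives an independent route to the same value, used in the test suite as a
numerical oracle ([lgp_series_oracle()]). A truncated Taylor polynomial of
$e^{-z}$ only represents the function inside its convergence region: the
remainder after $n$ terms is bounded by the first omitted term
$|z|^{n+1}/(n+1)!$ once terms decrease ([lgp_series_bound()]). At the
extremes of the search ranges ($\gamma$ up to $2^3$, $\delta$ up to 5,
$d$ up to 5) the exponent argument can reach $\sim 10^6$, where the
30-term partial sum is pure floating-point cancellation — no
implementation could match it there, and the package's oracle tests are
therefore restricted to draws whose remainder bound is below $10^{-10}$.

### Mercer validity is checked, not assumed

The series has alternating signs, so positive semidefiniteness of the
hybrid kernel does **not** follow from closure of Mercer kernels under
sums and products for every admissible parameter set. The package treats
PSD as an empirical property: [check_psd()] examines the spectrum of any
Gram matrix, the pipeline warns (or errors, under `strict_psd = TRUE`)
when the final training Gram matrix is indefinite, and the test suite
carries a documented counterexample — $\beta = (0.05, 0.5, 0.45)$,
$\eta = 1$, $\delta = 0$, $d = 2$, $\sigma = 0.25$ on orthonormal inputs
yields a negative eigenvalue. The SMO solver tolerates mildly indefinite
kernels, which is why the default gate is a warning rather than an error.

A second sharp edge: with an odd degree and negative dot products
(routine on centered PCA scores) the exponent flips sign and the
Gaussian envelope is unbounded — `exp()` explodes toward overflow, and
the hybrid loses its local-similarity semantics. The package's
feasibility rule ([kernel_bounded()]) requires the envelope to stay in
$(0, 1]$ over the data at hand (polynomial base non-negative, or an even
degree); the cross-validated fitness scores an unbounded parameter set
as $-\infty$, so the swarm simply discards that region. The final refit
re-checks the rule on the full training scores and warns in the rare
case where a fold-feasible optimum is not train-feasible.

## Per-fold PCA without leakage

PCA is fitted **inside** each cross-validation fold: means and covariance
come from the four calibration folds only, and the held-out fold is
projected with that basis (subtract calibration means, multiply by
calibration loadings). The retained component count follows the smallest
$k$ whose cumulative proportion of variance reaches the threshold
(default 0.95) and may legitimately differ between folds and the final
model; the run report lists all of them rather than forcing agreement.
Because genes vastly outnumber samples, the eigenpairs are computed via
the SVD of the centered data matrix — mathematically identical to
diagonalizing the covariance with the $M-1$ denominator, at a fraction of
the cost. Eigenvector signs are arbitrary; the package fixes each loading
column so its largest-magnitude entry is positive.

The fold plan is fixed once per run, *before* the swarm search, so the
fitness function is deterministic in its parameters; the per-fold PCA
scores are likewise precomputed once ([cv_fold_scores()]) since they do
not depend on the SVM parameters. This makes an 80-particle, 50-iteration
search affordable on a laptop.

## The swarm

Each kernel model spans its own search space
(`D` = 1 linear, 2 Gaussian, 4 polynomial, 8 LGP), with
$-5 \le \log_2 C \le 15$, $-15 \le \log_2\gamma, \log_2\eta \le 3$,
$0 \le \delta \le 5$, $d \in \{2,\dots,5\}$, and the three $\beta$
dimensions decoded jointly onto the simplex (raw values in $[0,1]$
divided by their sum; a collapsed group below $10^{-6}$ total mass is
re-randomized). Swarm size defaults to $10 \times D$ — 80 particles for
the LGP model — with inertia $w = 1$, learning factors $c_1 = c_2 = 2$,
and 50 iterations.

Two numerical choices are the package's own. First, velocities are
clamped per dimension to half the bound width: with $w = 1$ and no clamp
the canonical swarm can diverge, and the clamp preserves the stated
inertia while keeping the search usable (the quadratic-recovery test in
the suite verifies ≥95/100 seeded successes). Second, positions are
clamped to the bounds with the corresponding velocity component zeroed,
and the integer degree dimension is searched continuously and rounded at
decode, which keeps the updater uniform across dimensions.

## Imbalance-aware metrics

All metrics derive from the confusion matrix (rows = true class,
columns = predicted). Writing $\mathrm{Acc}_i$ for class $i$'s *recall*
(diagonal over row sum):

- **G-mean** $= \left(\prod_i \mathrm{Acc}_i\right)^{1/C}$ — one fully
  missed class drives it to 0;
- **macro F-score** $=$ mean over classes of the per-class
  precision/recall harmonic mean;
- **weighted accuracy** $= \sum_i \mathrm{Acc}_i P_i$ with $P_i$ the
  class prevalence, which under the recall reading is identically
  `trace / total`.

The recall reading of per-class accuracy is the only one under which the
multiclass G-mean reduces to $\sqrt{\mathrm{TPR}\cdot\mathrm{TNR}}$ and
the weighted accuracy to the overall binary accuracy on two classes —
both identities are property-tested on random matrices. Zero-denominator
ratios are reported as 0 with an `undefined` flag instead of `NaN`, so
aggregates over degenerate folds stay computable.

## The synthetic generator

Real microarray benchmarks cannot ship with a package, so
[generate_dataset()] emulates their geometry: `M` samples split into
imbalanced classes, `N` genes of which only `n_informative` carry class
signal, the rest i.i.d. Gaussian noise, and the whole matrix shifted
affinely into a positive expression-like range (min-max normalization
later erases location and scale, so only geometry matters).
[paperlike()] reproduces the shapes of four classic benchmarks — 62×2000
with classes 40/22, 72×7129 with 47/25, 215×12558 with seven classes
9/18/42/14/28/52/52 (the last generated *diffuse*, i.e. without
informative structure, mirroring a catch-all diagnostic group), and
203×3312 with 139/21/20/6/17.

Class structure comes in two flavours. `linear` draws per-class mean
profiles on the informative genes with spread `effect_size` (in units of
`noise_sd`), giving linearly separable classes at `effect_size` ≥ 3.
`radial` places classes on concentric rings of a 2-D latent plane
embedded across the informative genes (radii $(1 + 2c)\,\cdot$
`effect_size` $\cdot$ `noise_sd`): class means are all zero, so no linear
separator works, while the low latent dimension keeps the shells
learnable from tens of samples — the test suite verifies the Gaussian
kernel's advantage over the linear one on this structure. `mixed` devotes
half the informative genes to each.

What the generator deliberately does **not** model: probe effects, batch
effects, heavy-tailed noise, gene-gene correlation outside the
informative block, or missing values. Passing tests on this generator
demonstrate the pipeline's mechanics (leakage-free CV, parameter
recovery, metric behaviour under imbalance), not performance on real
tissue data.

## Normalization timing

Min-max statistics can be fitted globally before splitting (the default,
matching the pipeline order in which normalization precedes the split) or
on the training set only (`normalization = "train_fitted"`), in which
case test values outside the training range are clipped to `[0, 1]`.
Constant genes map to 0. The global default is the more faithful
reproduction of the published procedure; the train-fitted mode is offered
because the global mode technically lets test extremes influence the
scaling.

## Problem sizes in the test and acceptance runs

The shipped tests and the acceptance script exercise the pipeline on
generated datasets of roughly 40–62 samples × 25–200 genes with swarms of
4–80 particles and 2–20 iterations, and the kernel/metric property suites
use 200–1000 random draws. These sizes were chosen so the whole suite
documents every contract at interactive speeds; all of them are
parameters, and a real analysis would simply use the defaults
(50 iterations, 10×D particles) on its own data.

## Known limitations

- The hybrid kernel's PSD property is parameter-dependent; the pipeline
  surfaces this rather than hiding it, but an indefinite Gram matrix
  means the dual is no longer a convex QP and the solver's solution is
  only a stationary point.
- One-vs-one voting ties are broken toward the lowest class index.
- Whether published test metrics for this family of pipelines come from
  one split or averaged repeats is generally unstated; `run_experiment`
  reports a single seeded split, and averaging over seeds is a loop the
  caller writes.
- The stochastic comparison "hybrid ≥ best single kernel on mixed-
  structure data" holds on average but not per seed; it is not asserted
  as a hard test.
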