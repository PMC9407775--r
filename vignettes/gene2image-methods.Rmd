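---
title: "From expression vectors to discriminative images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression vectors to discriminative images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk blood-transcriptome classification — for example separating Alzheimer's
disease (AD) patients, mild-cognitive-impairment (MCI) patients and healthy
controls (CTL) — is a high-dimension, low-sample-size problem: tens of
thousands of gene measurements against a few hundred samples. Convolutional
networks handle such regimes well *for images*, because locality and weight
sharing act as a strong structural prior. gene2image makes that prior
applicable to expression data by laying genes out in a plane so that genes
with similar discriminative power become spatial neighbours, then rendering
each sample as a grayscale image that a small CNN can classify.

## The transform, stage by stage

All stages are fitted on the training samples only; the fitted layout is a
frozen function from an expression vector to an image and is reused
unchanged for held-out or future samples.

**1. Min–max normalization.** Each gene is rescaled to $[0,1]$ across
samples: $v \mapsto (v - \min)/(\max - \min)$. A constant gene maps to all
zeros — it carries no class information, and zero is the image background
value. When several cohorts are merged, each is normalized, the matrices
are joined on the shared gene set (in the first cohort's gene order), and
the merged matrix is normalized once more, so every gene again spans
$[0,1]$ over the pooled samples.

**2. LASSO gene selection.** An L1-penalized least-squares regression of
the 0/1 class indicator on all genes,
$$\tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 +
\lambda\lVert\beta\rVert_1,$$
keeps the genes with non-zero coefficients. The default penalty is
$\lambda = 6\times10^{-3}$, the operating point established for the
blood-transcriptome setting this method was developed in. We use the
linear (not logistic) form deliberately: it is the plainer reading of
"LASSO regression" as a selector, and only the support of $\beta$ is used
downstream. With three or more classes the selection is one-vs-rest — one
fit per class, union of supports — since a single 0/1 target is no longer
defined. `choose_lambda()` implements the practical recipe of picking the
penalty by the gene count it yields: it returns the largest grid value
whose selection can fill every Fisher category with at least two genes
(the feasibility floor of stage 4).

**3. Fisher-distance categorization.** Each selected gene $g$ is scored by
$$d(g) = \frac{\lvert \mu_1 - \mu_2 \rvert}{\sigma_1^2 + \sigma_2^2},$$
with class means $\mu_j$ and *population* variances $\sigma_j^2$ (the
formula is stated with plain $\sigma^2$; the biased estimator is the
literal reading, and the choice is isolated in one function). With three
classes the score is the mean of the three pairwise distances. A
zero-variance denominator is floored at $10^{-12}$, so a constant gene
whose class means differ gets a huge but finite score rather than a
division error. Genes are then sorted by distance (ties broken by input
order, so the map is reproducible) and cut into $t$ consecutive,
equal-count categories; when $t$ does not divide the gene count the
remainder goes one-per-category to the *highest* categories. Category $t$
holds the most discriminative genes. The default $t = 13$ is the category
count that maximized held-out accuracy in the original tuning sweep over
$\{7, 9, 11, 13, 15, 17\}$; `sweep_categories()` reproduces that sweep on
any dataset, reusing one split across all $t$ for comparability.

**4. LDA embedding of genes.** The mapping to the plane treats *genes* as
observations: each gene's feature vector is its expression profile across
the training samples, and its class label is its Fisher category. Linear
discriminant axes are found from the generalized eigenproblem
$S_b\,a = \lambda\,S_w\,a$ (between- vs within-category scatter), solved
via Cholesky whitening of $S_w$, and every gene is projected onto the top
two axes. This is the one reading under which "category" can supervise the
embedding, and it is what makes same-category genes land in each other's
vicinity. Because the feature dimension (number of training samples) can
rival the genes-per-category count, $S_w$ is always shrunk towards a
trace-scaled identity, $S_w + \gamma\,\frac{\mathrm{tr}(S_w)}{p}I$ with
$\gamma = 10^{-3}$ — enough to keep the solve well-posed, small enough to
leave a well-conditioned problem essentially unchanged. Axis signs are
fixed so the top category's centroid has non-negative coordinates; without
this convention the layout would be reproducible only up to reflections.

**5. Minimum-area enclosing rectangle.** The convex hull of the gene
cloud is computed (`grDevices::chull`), and the minimum-area enclosing
rectangle is found by the rotating-calipers property: the optimum has one
side collinear with a hull edge, so it suffices to test each hull-edge
direction. The angle is reduced to $[0, \pi/2)$ (quarter-turn symmetry),
swapping width and height accordingly. Degenerate clouds are defined, not
rejected: one point gives a $0\times0$ rectangle, collinear points a
zero-height rectangle along their span. The cloud is then rigidly rotated
and translated so the rectangle sits axis-aligned with its lower-left
corner at the origin — this removes the sparse corners an axis-aligned
bounding box would create.

**6. Rasterization and rendering.** Coordinates are scaled to
$[0, W{-}1] \times [0, H{-}1]$ pixels and snapped with round-half-up
(`floor(x + 0.5)`; base R's round-half-even would make layouts depend on
parity). Row 0 is the top row. Genes sharing a pixel form a *collision
group*; a sample's image holds, at each occupied pixel, the mean
expression of that pixel's group, and exact zero everywhere else. The
resolution is a free parameter: coarser grids force more collisions
(averaging, denoising, information loss), finer grids spread genes out.
The package default is $64\times64$; the bundled tests and the acceptance
study use $16\times16$, which comfortably holds the few dozen genes
selected at desk scale while keeping CNN training on a single CPU fast.

## The classifier

The CNN is the fixed six-convolution architecture: 3×3 same-padding
convolutions with 32, 32, 64, 64, 128, 128 filters, ReLU activations, a
2×2 max pool after each pair (so three poolings; inputs must be at least
8×8), then two ReLU dense layers (defaults 64 and 32 units) each followed
by dropout 0.4, and a sigmoid unit (binary) or softmax (multi-class).
The dense weights carry L1 ($10^{-5}$) and L2 ($10^{-4}$) penalties.
Training minimizes cross-entropy with Adam at learning rate $10^{-4}$,
batch size 32, default 500 epochs. The six-convolution backbone has
exactly 286,432 parameters irrespective of resolution; the dense widths
are configuration-exposed because no published width total pins them
down. The engine is implemented in compiled code inside the package
(im2col convolutions as GEMMs); all stochastic elements — weight
initialization, epoch shuffling, dropout masks — draw from an internal
xorshift generator seeded from the configuration, so a run is bit-stable
for a fixed seed on a fixed BLAS.

Two classifier-level choices matter on short training schedules:

* **Zero-initialized head.** The output layer starts at zero, so the
  untrained decision is exactly $p = 0.5$ (uniform softmax). Gradients
  through it are immediately non-zero, and nothing about the converged
  model changes.
* **Mean-image centering.** `train_model()` subtracts the training-set
  mean image and stores it with the model; prediction applies the same
  offset. This classical preprocessing step removes the brightness
  common-mode that class-shifted genes induce. Without it, a short Adam
  schedule (each parameter moves at most `lr` per step) can rank samples
  perfectly yet leave every logit on one side of the threshold: the
  single output bias cannot absorb an $O(1)$ offset in a few hundred
  steps. Centering makes the logit distribution straddle zero from the
  start, so accuracy at the fixed 0.5 threshold reflects the ranking.

Evaluation reports accuracy at 0.5/arg-max, the ROC curve traced over all
score thresholds with trapezoidal AUC (it equals Mann–Whitney pair
counting, a property the tests enforce), and a confusion matrix
row-normalized by true class; a class absent from an evaluation set
yields an all-NA row rather than a silent 0/0.

## The synthetic generator

`simulate_expression()` produces the ground-truth-bearing data every
pipeline stage is tested on. Non-informative genes draw i.i.d. from
$N(0.5, \sigma^2)$ in all classes; informative genes add $+\delta$ in AD
and $+m\delta$ in MCI ($m$ = `mci_mixing`, the position of the
intermediate class on the control→disease axis); values are clipped to
$[0,1]$. Defaults: $\sigma = 0.1$ (clipping bias negligible at three
sigma from both bounds), $\delta = 0.15 = 1.5\sigma$, 40 informative genes
among 1000, 100 samples per class — a realistic DEG-minority regime in
which selection, categorization and classification all have genuine work
to do. The three-class study in `scripts/acceptance.R` uses class sizes
96/63/93 (AD/MCI/CTL, the cohort proportions of the motivating datasets
scaled to desk size), $m = 0.7$, and a weaker $\delta = 0.5\sigma$ so
task accuracies sit in a moderate regime where the pooled-task ordering —
(AD+MCI) vs CTL easier than AD vs (MCI+CTL), AD vs CTL easiest of the
pairwise tasks — is visible rather than saturated at 1.0; it trains for
150 epochs because the imbalanced pooled tasks need the longer schedule
to calibrate their decision threshold.

What the generator deliberately does **not** emulate: gene–gene
correlation structure, probe-level artifacts, batch effects between
cohorts, heavy-tailed noise. Passing tests on this generator therefore
demonstrate that the machinery recovers planted mean-shift structure —
not that the method's published real-data accuracies transfer, and not
that min–max scaling suffices as batch correction when real platforms are
merged.

## Numerical and protocol choices

* **Population variance** in the Fisher score; denominator floor
  $10^{-12}$.
* **Stratified split** with `round_half_up(fraction × class size)` (at
  least 1) test samples per class; the split seed is an explicit argument
  and the generator's RNG never leaks into the caller's session state.
* **Fit-on-train-only throughout.** Selection, scores, categories,
  embedding, rectangle and layout are all computed from the training
  partition; the acceptance tests byte-compare layout JSON with and
  without the test samples present to prove it.
* **Equal-count ties** broken by gene input order; remainder genes go to
  the top categories.
* **Canonical JSON layouts**: collision groups serialized in sorted key
  order so identical fits produce byte-identical files.
* **One shared split** across a category sweep, so sweep rows differ only
  in $t$.

## Limitations

* The LDA embedding needs $t \ge 3$ and at least two genes per category;
  with the default $t = 13$ a selection must contain at least 26 genes.
  `choose_lambda()` exists for exactly this applicability constraint.
* The CNN engine is single-image-at-a-time compiled code tuned for
  desk-scale images (tens of pixels squared); it is not a GPU framework
  and 500-epoch runs at 64×64 are minutes-to-hours, not seconds.
* Binary AUC only; multi-class reports accuracy and the confusion matrix.
* Min–max merging of cohorts performs no batch-effect correction.
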