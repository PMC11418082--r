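---
title: "Regularized latent search for microscopy super-resolution: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized latent search for microscopy super-resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latsr)
```

## The estimation problem

A low-resolution (LR) fluorescence image $y$ is related to an unknown
high-resolution (HR) image $x$ by a known, non-invertible downscaling
operator $D$ and independent noise, $y = D(x) + \eta$. At the upscaling
factors this package targets (8x--32x), infinitely many HR images downscale
to the same $y$, so maximum-fidelity reconstruction alone is ill-posed. The
package constrains the problem with a generative image prior: the
reconstruction is required to lie in the range of a style-based generator
$G$ pretrained (or, at desk scale, fixed) on the image domain, and the
search is carried out over the generator's extended latent space $W^+$ — one
$d$-dimensional style vector per synthesis layer, $w^+ = (w_1, \dots, w_L)$.

The MAP estimate minimizes

$$
E(w^+) \;=\; \frac{1}{m}\bigl\lVert D(G(w^+)) - y \bigr\rVert_1
\;+\; \lambda_1\, P_1(w^+) \;+\; \lambda_2\, P_2(w^+),
$$

with three terms:

* **Data fidelity.** The noise is modeled as Laplace, whose log-likelihood
  is the $\ell_1$ distance between $D(G(w^+))$ and $y$; the Laplace scale is
  absorbed into $\lambda_1, \lambda_2$ (only the ratios matter). $\ell_1$
  is preferred over $\ell_2$ for its robustness to outliers — salt-and-pepper
  corruption, for instance, perturbs few pixels by large amounts and is
  discounted by the median-like behavior of the $\ell_1$ fit. The term is a
  *mean* over the $m$ LR pixels rather than a sum, so the default lambdas
  transfer across resolutions. An $\ell_2$ variant is kept for oracle tests.
* **Flow-density prior** $P_1$: the average negative log-density of the $L$
  style copies under a normalizing flow fitted to the style distribution
  (below). It keeps the search in the high-density region of the style
  space, i.e. among latents that decode to domain-typical images.
* **Pairwise-consistency prior** $P_2$: the mean squared Euclidean distance
  over all unordered pairs of style copies. A single style vector repeated
  across layers is what the generator saw during its own training;
  penalizing the spread of the copies keeps $w^+$ near that manifold while
  still allowing per-layer freedom. Squared distances are used for smooth
  gradients; an unsquared variant is available as a config switch.

Defaults follow the reference settings: $\lambda_1 = 5\times10^{-5}$,
$\lambda_2 = 0.01$, Adam with learning rate 0.5 for 200 iterations,
initialized with all copies at the mean of 10{,}000 mapped random latents.
Performance is insensitive across $\lambda_1 \in [10^{-6}, 5\times10^{-4}]$
and $\lambda_2 \in [0.005, 0.05]$; `rls_config()` warns (not errors) outside
these bands. Adam moment parameters are the conventional (0.9, 0.999).
`superresolve()` returns the best-total iterate rather than the last: at
learning rate 0.5 the trace oscillates late in the run, and the running
minimum is the meaningful estimate.

## The flow prior

The style distribution — the image of a standard normal under the mapping
network $F$ — is not Gaussian, so neither a hypersphere heuristic nor a
fixed whitening transform describes it well. The package Gaussianizes it
with a masked autoregressive flow: blocks of the form
$u_i = (x_i - \mu_i(x_{<i}))\,e^{-\alpha_i(x_{<i})}$ with a fixed reversal
permutation between blocks, MADE-style masked two-hidden-layer conditioners
(tanh activations, sequential degree assignment), and exact log-density via
the change-of-variables formula. Per-dimension log-scales are soft-capped at
$\pm 3$ for stability. Conditioner output layers start at zero, so an
untrained flow is exactly the composition of its permutations — this
stabilizes early training and gives closed-form unit tests (for example,
the log-density of the zero vector in two dimensions is $-\log 2\pi$).

The density is defined on $W$ (dimension $d$), not on the $L \times d$
stack; $P_1$ averages the per-copy values, which keeps $\lambda_1$
meaningful independent of $L$. The flow enters only through its density
(and gradient); the search itself stays in $W^+$. A reparameterized search
in the flow's base space would be an alternative, but optimizing the
objective directly in $W^+$ keeps the data term's geometry untouched.

Flow fit quality is judged by the squared-norm diagnostic: if $f(w)$ is
standard normal, $\lVert f(w)\rVert^2 \sim \chi^2_d$ with mean $d$ and
variance $2d$. `gaussianization_report()` compares the transformed and
untransformed squared-norm moments against these references. At the paper
scale the flow uses 5 blocks of hidden width 1024 trained on 100{,}000
mapped samples; the desk scale in this package uses $d = 16$, 2 blocks of
width 64, 20{,}000 samples, 20 epochs of Adam at $2\times10^{-3}$ with a 0.9
per-epoch decay. The decay matters: the flow slightly overfits its finite
sample when trained flat, and fresh-sample tails (which the squared-norm
variance is sensitive to) degrade.

## Desk-scale generators

Full generator training is out of scope: the contribution under study is
the search, not the weights. Two fixed generators stand in:

* **`style_mini`** — a 3-layer mapping MLP and a modulated-convolution
  synthesis stack (constant $4\times4$ input, nearest upsampling, $3\times3$
  convolutions whose input channels are scaled by per-layer affine styles,
  leaky-ReLU, tanh-bounded RGB head; $64\times64$ output, $L = 8$). Weights
  are drawn once from a seed and frozen. The mapping layers are orthogonal
  matrices (gain-corrected for the activation) with leaky-ReLU slope 0.3:
  a raw He-initialized random MLP produces a pathologically heavy-tailed,
  anisotropic style distribution that no affine-autoregressive flow can
  bring near chi-squared — an artifact of random folding that a *trained*
  mapping does not exhibit. The orthogonal construction emulates the
  benign-but-non-Gaussian distribution the method actually encounters
  (squared-norm variance still $\sim 3.5\times$ the Gaussian reference, so
  the Gaussianization comparison remains meaningful). The path-length
  penalty of full-scale style generators concerns their training and is not
  modeled; its consequence (treating the synthesis Jacobian determinant as
  constant in the prior) is assumed directly.
* **`linear_oracle`** — $G(w) = \mathrm{reshape}(Aw) + \mathrm{offset}$ with
  full-column-rank $A$. With the $\ell_2$ data term and an identity flow
  (quadratic prior), the MAP problem is ridge regression with the
  closed-form solution `closed_form_linear_map()`; the iterative optimizer
  is required to match it to $10^{-3}$ relative error, which pins down the
  correctness of the whole gradient chain. `fit_pca_generator()` builds the
  same structure from the principal components of an image collection, so
  the generator range contains realistic reconstructions of that
  collection — the desk-scale stand-in for "a generator trained on the
  domain" in the workflow experiments.

Gradients are analytic throughout (im2col-based convolution backprop,
masked-MLP backprop, and the transpose of the separable downscale for the
data term) and are verified against central finite differences at relative
error $10^{-3}$ in the tests.

## Degradation operators

The downscale is Keys bicubic ($a = -0.5$) with the kernel support
stretched by the factor (antialiasing) and reflect boundaries, applied
separably as explicit row/column matrices — which makes it exactly linear,
cheaply transposable, and bit-reproducible. Only power-of-2 factors are
supported, matching the 16x/32x regime of interest. Robustness corruptions
(Gaussian noise, salt-and-pepper, Gaussian blur with radius
$\lceil 3\sigma \rceil$) follow the downscale, each with its own seed;
noisy outputs are clipped to the valid range by default (a documented
knob). The clean downscale is what the optimizer differentiates through;
corruption steps model the observation only.

## Uncertainty

The SR problem remains ill-posed after regularization, so the package
reports a set of plausible solutions rather than only the MAP point:
latents are drawn from $\mathcal{N}(w_{\mathrm{MAP}}, \sigma^2 I)$ per
copy, with $\sigma^2 \sim \mathrm{InvGamma}(\alpha, \beta)$ and
$\hat\sigma$ estimated by maximizing the Laplace log-likelihood of the MAP
residual plus the inverse-gamma log prior (1-D bounded search; the prior
already penalizes large $\sigma$, so no extra penalty term is added — a
deliberate interpretation, exposed through `alpha`/`beta`). With a zero
residual the likelihood is flat and the prior mode $\beta/(\alpha+1)$ is
returned. Each sample is refined for 20 objective steps at step size 0.1 —
much smaller than the global search step. The step size is load-bearing:
adaptive-moment steps move every coordinate by roughly the learning rate
regardless of gradient magnitude, so refining at the global step size
traverses the posterior and collapses the samples onto the MAP solution,
while no refinement leaves samples data-inconsistent. At 0.1 the samples
stay within twice the MAP data term while the per-pixel standard deviation
still grows monotonically with $\sigma$. Samples violating the
data-consistency tolerance are flagged, never dropped.

## Synthetic microscopy

The simulator emulates 3-channel cell-painting-style single-cell crops
(DNA / reporter / cell body) with two parameterized phenotypes: nuclear
translocation of the reporter (fraction $t$ of reporter intensity in the
nucleus; the negative and positive control presets are $t = 0.1$ and
$t = 0.9$) and Golgi scattering ($n$ perinuclear discs of radius $r$;
presets one disc of radius 5 vs eight discs of radius 1.5). Geometry is a
jittered soft-edged nuclear ellipse inside a soft cell disc; spot centers
are drawn in the perinuclear ring with a minimum separation and bounded
retries. Noise follows the standard fluorescence camera model
$\mathrm{Poisson}(s \cdot \mathrm{signal})/s + \mathcal{N}(0, r^2)$ with
photon scale 200 and read noise 0.01 by default. The default canvas is
$64\times64$.

What the simulator does *not* emulate: real texture (actin filaments,
tubulin networks), multi-cell fields, illumination gradients, dose-response
continua, and the full variability of real cell-painting data. Tests
passing on these synthetics therefore demonstrate the correctness and the
qualitative behavior of the machinery — not performance on real microscopy.

## The two-step workflow at desk scale

The headline use case splits analysis of an LR image into deep-learning SR
followed by handcrafted, interpretable quantification: the
nucleocytoplasmic reporter ratio (Otsu-segmented nucleus from the smoothed
DNA channel, largest 8-connected component, holes filled; cytoplasmic ring
by 4-pixel dilation) and the mean reporter spot area (Otsu threshold within
the cell mask, 8-connected components, minimum area 2 px). Both recipes are
config-exposed since no canonical parameterization exists. A
midpoint-of-medians threshold rule with balanced accuracy stands in for a
learned two-condition classifier, keeping the decision interpretable.

The desk-scale experiment uses `fit_pca_generator()` on simulated cell
populations (32 components on 200 cells for translocation; 96 components on
400 cells for Golgi — scattered small spots need a higher-rank basis to
reconstruct), in-range HR targets (PCA projections of held-out renders),
bicubic downscaling, and RLS at 60 iterations. Downscale factors differ by
assay: 8x for translocation, whose signal is low-frequency, and 4x for the
Golgi assay, whose spot-scale features on a 64-pixel canvas would otherwise
be proportionally more destroyed than at the reference experiments' image
sizes. Classification accuracy from both HR and SR features exceeds 0.9
for both assays in the acceptance suite.

## Numerical choices and degenerate inputs

* Internal image range is $[-1, 1]$ (generator convention); file I/O uses
  $[0, 1]$. `to_internal()` / `to_file_range()` convert, the latter with
  clipping.
* All randomness runs through per-call seeds with local RNG state, so no
  package call disturbs the caller's random stream and every result is
  reproducible from its configuration.
* Flow inversion is sequential over dimensions (exact to machine precision
  for the affine blocks); the round-trip tolerance is $10^{-4}$.
* The optimizer aborts with the iteration index and term values on a
  non-finite loss; flow training aborts on a non-finite transform.
* `mean_spot_area` returns value 0 with zero objects for a blank reporter
  (not an error); `translocation_ratio` errors with "no nucleus detected"
  when the DNA channel is empty, and `extract_features` maps per-image
  failures to `NA`.
* MS-SSIM uses the standard 5-scale weights with an $11\times11$ Gaussian
  window ($\sigma = 1.5$); scales are auto-reduced (weights renormalized)
  for small images, and signs are preserved when weighting the per-scale
  terms.
* Problem sizes in the tests and the acceptance script — $d = 16$ at
  $64\times64$ with a 2-block flow, 10--20 targets per experiment, 100
  images per condition — are the package's desk-scale study conditions;
  the full-scale reference settings remain the documented defaults.

## Known limitations

* Corruption robustness at desk scale is partial: the $\ell_1$ data term
  absorbs Gaussian and salt-and-pepper noise (clean-downscale anchoring
  within $3\times$ the uncorrupted residual), but blur robustness depends
  on the generator manifold rejecting blurred images, which a frozen
  random miniature generator — whose $W^+$ tangent space absorbs a
  substantial fraction of any LR-space perturbation — does not provide.
  With a trained domain generator the mechanism is expected to behave as
  at full scale; the acceptance suite documents the desk-scale blur ratio
  honestly rather than relaxing the check.
* The flow prior is fitted to a frozen style distribution; nothing adapts
  it to a user-supplied generator beyond retraining via `train_flow()`.
* The uncertainty model is a deliberately simple local Gaussian with a
  shared scalar scale — not a posterior in the Bayesian sense; its
  calibration is out of scope.
* Feature extractors assume a single dominant cell per crop.
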