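# latsr — regularized latent search super-resolution for microscopy

Single-image super-resolution at extreme upscaling factors (8x–32x) is
ill-posed: infinitely many high-resolution (HR) images downscale to the same
low-resolution (LR) observation. `latsr` makes the problem well-posed with a
generative prior: the reconstruction is constrained to the output manifold of
a style-based generator `G`, and recovered by **regularized latent search
(RLS)** — MAP optimization over the generator's extended latent space W⁺
(one style vector per synthesis layer):

```
E(w⁺) = ‖D(G(w⁺)) − y‖₁ / m  +  λ₁ P₁(w⁺)  +  λ₂ P₂(w⁺)
```

* the L1 data term is the log-likelihood of a Laplace noise model through
  the known downscaling operator `D` (antialiased Keys bicubic);
* `P₁` is the average negative log-density of the style copies under a
  **masked autoregressive flow** fitted to the style distribution — an exact
  density via the change-of-variables formula — keeping the search in
  regions that decode to domain-typical images;
* `P₂` is the mean squared pairwise distance between the W⁺ copies, keeping
  the search near the single-style manifold.

Defaults are λ₁ = 5e-5, λ₂ = 0.01, Adam for 200 iterations at learning rate
0.5, initialized at the mean of 10,000 mapped random latents. Around the
optimizer the package provides: flow training and the chi-squared
squared-norm Gaussianization diagnostic; differentiable degradation
operators (bicubic downscale, Gaussian noise, salt-and-pepper, blur);
ablation variants (without P₁, P₂, or both); posterior sampling of plausible
reconstructions with an inverse-gamma scale prior; a synthetic
cell-painting-style microscopy simulator (nuclear-translocation and
Golgi-scattering phenotypes with Poisson–Gaussian noise); and interpretable
feature quantification — nucleocytoplasmic ratio, mean Golgi spot area,
PSNR/MS-SSIM, and a threshold classifier — implementing the two-step
workflow: deep-learning SR first, handcrafted interpretable measurement
second. It is aimed at computational microscopists studying generative-prior
restoration and assay designers who need quantification to survive SR.

All gradients (synthesis network, flow density, degradation) are analytic,
hand-derived, and verified against finite differences in the test suite; no
deep-learning framework is required.

## Worked example

Build the desk-scale study generator (d = 16, 64×64, L = 8 style inputs),
fit the flow prior on 20,000 mapped style vectors, then super-resolve an
8x-downscaled in-range target:

```r
library(latsr)

gen  <- make_style_mini(d = 16, size = 64, seed = 11)
Z    <- local({ set.seed(5); matrix(rnorm(20000 * 16), 20000, 16) })
W    <- t(apply(Z, 1, map_latent, gen = gen))
flow <- train_flow(W, flow_config(n_blocks = 2, hidden = 64,
                                  n_samples = 20000, epochs = 20,
                                  learning_rate = 2e-3, lr_decay = 0.9,
                                  seed = 4))
gaussianization_report(flow, gen, n = 5000, seed = 9)
#> <gaussianization report n=5000>
#>   transformed |u|^2: mean 15.913 (ref 16), var 37.299 (ref 32)
#>   untransformed |w|^2: mean 15.094, var 117.280

z  <- local({ set.seed(421); rnorm(16) })
hr <- synthesize(matrix(rep(map_latent(z, gen), each = gen$L), gen$L, 16), gen)
op <- forward_operator(op_step("bicubic_downscale", factor = 8))
lr <- apply_operator(op, hr)

res <- superresolve(lr, gen, op, flow, rls_config(seed = 7))
res
#> <latsr_rls_result iters=200 best_iter=133 total=0.020439 data=0.018658
#>  flow=10.995 pairwise=0.12315>

psnr(to_file_range(res$sr_image), to_file_range(hr))            # 32.6 dB
psnr(to_file_range(bicubic_upscale(lr, 8)), to_file_range(hr))  # 16.6 dB
ms_ssim(to_file_range(res$sr_image), to_file_range(hr))         # 0.993
```

Reading the numbers: the flow has Gaussianized the style distribution — the
squared norms of transformed vectors match the chi-squared reference
moments (mean 15.9 vs 16, variance 37.3 vs 32) where the raw style vectors
do not (variance 117) — and the regularized search recovers the 64×64 truth
from an 8×8 observation 16 dB above the bicubic baseline, with a final L1
data fit of 0.019 on the [-1, 1] scale.

The same machinery is scriptable from a shell through the thin entry point
`inst/cli/latsr.R` (subcommands `simulate`, `train-flow`, `diagnose`, `sr`,
`ablate`, `sample`, `quantify`, `e2e`), e.g.

```sh
Rscript inst/cli/latsr.R sr --input lr.tif --generator g.ckpt --flow f.ckpt \
        --factor 16 --iters 200 --seed 1 --out sr.tif --trace trace.csv
```

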