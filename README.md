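# fuzzyseg

Spatially constrained kernel fuzzy C-means segmentation for brain MRI,
with Perona–Malik anisotropic diffusion preprocessing and a full
synthetic-phantom evaluation workbench.

## The problem

Brain MR images carry noise, weak tissue boundaries, and smooth intensity
inhomogeneity, which defeat plain intensity clustering: classical fuzzy
C-means (FCM) assigns each pixel independently, so impulse noise survives
segmentation as scattered mislabeled pixels. `fuzzyseg` implements a
classical pipeline that addresses this with three ingredients:

1. **Edge-preserving denoising.** Perona–Malik (PM) anisotropic diffusion
   evolves the image by `∂I/∂t = div(c(|∇I|) ∇I)` with a diffusion
   coefficient that decays with the local gradient — either
   `c₁(g) = exp(−(g/λ)²)` or `c₂(g) = 1/(1 + (g/λ)^(1+α))` — so noise
   inside homogeneous tissue is smoothed while edges above the gradient
   threshold λ are preserved (the flux `φ(g) = c(g)·g` peaks at `λ/√2`
   for c₁ and at `λ` for c₂ with α = 1).

2. **Fuzzy clustering.** Classical FCM minimizes
   `J = Σᵢ Σⱼ uᵢⱼᵐ ‖xⱼ − vᵢ‖²` subject to unit column sums of the
   membership matrix U; closed-form alternating updates follow from the
   Lagrangian. Two robust variants are provided: FCM_S, which augments
   the distance with a neighborhood term
   `(α/N_R) Σ_{r∈Nⱼ} ‖x_r − vᵢ‖²`, and the kernel method (SIPMFCM),
   which replaces squared distance with the Gaussian-kernel-induced
   distance `1 − K(x, v)`, adds a membership penalty
   `ρ Σ u(1 − u)` rewarding crisp assignments, and a term on the
   median- (or mean-) filtered image injecting local spatial information.

3. **Spatial membership fusion.** After convergence the membership of
   each pixel is re-weighted by the membership mass its neighborhood
   lends each cluster: `u′ᵢⱼ = uᵢⱼᵖ sᵢⱼ^q / Σ_k u_kⱼᵖ s_kⱼ^q`, then
   defuzzified by per-pixel argmax.

Evaluation uses Dice (`2|T∧P|/(|T|+|P|)`), Jaccard (`|T∧P|/|T∨P|`), the
partition coefficient `V_pc = (1/n)ΣΣu²` and partition entropy
`V_pe = −(1/n)ΣΣ u ln u`, PSNR, and optimal cluster-to-truth label
matching. A seeded phantom generator (piecewise-constant tissue maps,
Gaussian / salt-and-pepper noise, multiplicative bias fields) makes every
stage testable with no clinical data.

## Worked example

```r
library(fuzzyseg)

ph    <- make_phantom(phantom_spec(seed = 1))                     # 160x160, tissues 0.2/0.5/0.8
noisy <- add_noise(ph$image, noise_spec("salt_pepper", 0.2, seed = 1))
den   <- pm_denoise(noisy, diffusion_config())                    # c1, auto lambda, 15 iters
fit   <- sipmfcm_fit(den, fcm_config(n_clusters = 3, seed = 1))
fit
#> <fcm_state: sipmfcm, c = 3, 10 iterations, converged>
#>   centers: 0.2667, 0.4975, 0.7376
#>   final objective: 1885.65

U   <- fuse_spatial_membership(fit$memberships,
                               spatial_function(fit$memberships, dim(den), 1))
lab <- defuzzify(U, dim(den))
validity_report(U = U, pred = lab, truth = ph$labels,
                clean = ph$image, test = den)
#> <validity_report>
#>   V_pc = 0.9719, V_pe = 0.0510
#>   DSC per class:     0.9870 0.9693 0.9880
#>   Jaccard per class: 0.9743 0.9405 0.9763
#>   PSNR = 22.83 dB (max 1)
```

The centers sit near the true tissue means (0.2/0.5/0.8; the residual
pull toward 0.5 reflects partially smoothed impulses), the high `V_pc` /
low `V_pe` indicate a crisp partition, and per-class Dice above 0.96 at
20% impulse noise is the robustness the spatial and kernel terms buy —
plain `fcm_fit` on the same noisy image reaches a mean Dice of about
0.87.

The same pipeline is scriptable:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","fuzzyseg.R",package="fuzzyseg"))') \
  segment --method sipmfcm --clusters 3 --denoise c1:auto:15 --seed 7 \
  in.png --labels out.png --memberships u.csv --report report.json
```

Subcommands `phantom`, `denoise`, `segment`, `evaluate`, and `pipeline`
compose; `run_pipeline()` drives noise-level × seed sweeps and writes
per-run JSON plus an aggregate CSV.

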