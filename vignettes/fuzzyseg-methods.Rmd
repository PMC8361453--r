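---
title: "Methods: spatially constrained kernel fuzzy clustering for MRI segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially constrained kernel fuzzy clustering for MRI segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyseg)
```

## Overview

`fuzzyseg` segments 2-D grayscale brain images by intensity clustering
made robust to noise in three stages: Perona–Malik (PM) anisotropic
diffusion, a kernel fuzzy C-means with membership penalty and
neighborhood term (SIPMFCM), and spatial membership fusion. This
vignette records the models, their assumptions, the tunable parameters,
the numerical choices, and what the synthetic experiments do and do not
demonstrate.

All images are represented internally as unit-range float matrices;
8-bit conversion happens only at file I/O, so the mathematics is
independent of file dialects. The coordinate convention everywhere is
(row, col), 0-based labels, origin top-left.

## Fuzzy C-means and its fixed-point updates

Classical FCM minimizes
$$J(U, V) = \sum_{i=1}^{c} \sum_{j=1}^{n} u_{ij}^m \, d_{ij}^2, \qquad
\sum_{i=1}^c u_{ij} = 1 \;\forall j,$$
with $d_{ij} = \lVert x_j - v_i \rVert$. Eliminating the per-pixel
Lagrange multipliers gives the familiar alternating updates
$$u_{ij} = \Big(\sum_k (d_{ij}/d_{kj})^{2/(m-1)}\Big)^{-1}, \qquad
v_i = \frac{\sum_j u_{ij}^m x_j}{\sum_j u_{ij}^m}.$$
When a column contains zero distances, the entire membership mass is
split uniformly over the zero-distance clusters. Both steps are exact
minimizers of their subproblem, so the recorded objective history is
non-increasing — the test suite asserts this on every fitter, and
additionally checks the FCM fixed point against a generic
simplex-constrained numeric minimizer (BFGS over softmax-parameterized
memberships plus free centers).

The fuzzifier defaults to $m = 2$. The kernel fitter requires $m = 2$
because that is the case with closed-form membership updates; FCM and
FCM_S accept any $m > 1$.

**Initialization.** Memberships start from a seeded flat Dirichlet per
pixel. For the kernel fitter this is not sufficient: the
membership-weighted mean of a flat random simplex puts every prototype
at the grand intensity mean, a symmetric configuration whose basin is a
collapsed local minimum (all centers in the largest tissue class; its
objective is two orders of magnitude worse than the good optimum). The
kernel fitter therefore spreads its initial prototypes over seeded,
jittered intensity quantiles at probabilities $(2k-1)/2c$. Independent
restarts (`restarts`) keep the lowest-objective run; because the
collapsed minimum is so much worse, a single restart suffices in
practice and is the default.

**Convergence** is declared when $\max_{ij} |\Delta u_{ij)}| <$ `tol`
(default $10^{-5}$) or after `max_iter` (default 100) iterations.

## The spatially constrained variant (FCM_S)

FCM_S augments each squared distance with the neighborhood average
$$D_{ij} = \lVert x_j - v_i\rVert^2 +
\frac{\alpha}{N_R} \sum_{r \in N_j} \lVert x_r - v_i \rVert^2,$$
where $N_j$ is the square window of radius 1 around pixel $j$ (the
8-neighborhood, $N_R = 8$, reflected at borders). Centers become
$v_i = \sum_j u_{ij}^m (x_j + \tfrac{\alpha}{N_R}\sum_r x_r) /
((1+\alpha)\sum_j u_{ij}^m)$. The neighborhood sums are expanded through
the window statistics $\sum_r x_r$ and $\sum_r x_r^2$, so the code path
is identical to plain FCM with those arrays zeroed; with $\alpha = 0$
the two fitters are bit-identical by construction, which the tests
assert literally.

## The kernel fitter (SIPMFCM)

For $m = 2$ the kernel objective is
$$J = 2\sum_{i,j} u_{ij}^2 \, (1 - K(x_j, v_i))
  + \rho \sum_{i,j} u_{ij}(1 - u_{ij})
  + 2\rho \sum_{i,j} w_{ij} (1 - K(\bar{x}_j, v_i)),$$
with $K(x,v) = \exp(-(x-v)^2/\sigma^2)$, $\bar{x}$ the 3×3 median- (or
mean-) filtered image, and the kernel-induced distance $1-K$ bounded in
$[0,1)$ — which is what buys robustness to outlying intensities. The
membership penalty ($u(1-u)$, zero at 0 and 1) rewards crisp
assignments; the $\bar x$ term injects local spatial information.

Two choices here were genuinely open and are worth recording:

* **Weighting of the smoothed-image term.** Written without membership
  weighting ($w_{ij} = 1$, mode `"literal"`), the term is constant in
  $U$ and moves only the centers — the memberships would never see the
  spatial information that the model's purpose demands. The default
  mode `"membership_weighted"` sets $w_{ij} = u_{ij}^2$, the standard
  kernel-spatial convention, so the term informs both updates. Both
  modes are implemented and tested.
* **One weight or two.** The penalty and the smoothed-image term share
  the single scalar $\rho$ (default 0.1), as the objective is printed;
  no per-cluster $\rho_i$ differentiation is supported because nothing
  defines it.

**Membership update.** Per pixel the subproblem is minimizing
$\sum_i a_i u_i^2$ on the probability simplex with
$a_i = 2(1-K_{ij}) - \rho + 2\rho\, w(1-\bar K_{ij})$ (the linear
$\rho \sum_i u_i$ part is constant on the simplex). When all $a_i > 0$
the Lagrange closed form $u_i \propto 1/a_i$ is interior and exact.
When some $a_i \le 0$ — a pixel essentially on top of a prototype, with
the penalty dominating — the closed form leaves the simplex; the exact
constrained minimizer is the vertex (or tie-face) at the most negative
coefficient, which is also where Euclidean projection of the diverging
closed form lands, and that is what the code returns (uniform over
ties, mirroring the zero-distance rule). Iterations where this engages
are flagged in `projection_active`; monotonicity of the objective is
asserted in tests including such iterations. Only if *every* pixel
lacks a positive coefficient is the configuration hopeless, and the
fitter raises a diagnostic error asking for a smaller $\rho$.

**Center update.** Stationarity gives the kernel-weighted mean
$v_i = (\sum_j w_{ij} K_{ij} x_j + \rho \sum_j \bar w_{ij} \bar K_{ij} \bar x_j) /
(\sum_j w_{ij} K_{ij} + \rho \sum_j \bar w_{ij}\bar K_{ij})$, which is a
fixed-point equation because $K$ depends on $v$; it is solved by damped
fixed-point iteration (damping 0.5, inner tolerance $10^{-12}$, at most
60 inner steps). Tests verify that at convergence re-applying either
update moves the state by less than $10^{-6}$ and that a BFGS minimizer
started at the returned state cannot improve the objective by more than
$10^{-6}$.

$\sigma$ defaults to `"auto"`: the sample standard deviation of the
image intensities, a scale that keeps typical within-class distances
well inside the kernel's sensitive range.

## Spatial fusion and defuzzification

After convergence, $s_{ij}$ sums the memberships of cluster $i$ over
the radius-1 window around $j$, and
$u'_{ij} = u_{ij}^p s_{ij}^q / \sum_k u_{kj}^p s_{kj}^q$ (defaults
$p = q = 1$). Fusion is applied once, post-convergence: it is a
relabeling-stage cleanup, and applying it inside the loop would destroy
the objective's monotonicity guarantee; the pipeline treats it as the
final membership estimate before per-pixel argmax (ties to the lowest
cluster index).

## Perona–Malik diffusion

The continuous model $\partial I/\partial t = \mathrm{div}(c(|\nabla I|)\nabla I)$
is discretized with the classic explicit 4-neighbor scheme,
$I \leftarrow I + \Delta t \sum_{d \in \{N,S,E,W\}} c(\nabla_d I)\,\nabla_d I$,
with one-sided differences, no gradient pre-smoothing, and half-sample
reflected borders. The reflection makes the boundary flux exactly zero
and the pairwise fluxes antisymmetric, so the mean intensity is
conserved to machine precision; $\Delta t \le 1/4$ (default 0.2) keeps
each update a convex combination of neighbors, giving the maximum
principle. Both are asserted per iteration in tests.

$\lambda$ separates "noise" gradients (diffused) from "edge" gradients
(preserved): the flux $c(g)g$ peaks at $\lambda/\sqrt 2$ for $c_1$ and
at $\lambda$ for $c_2$ with $\alpha = 1$. The default is `"auto"`: the
90th percentile of all one-sided gradient magnitudes, computed once on
the input and then held fixed (floored at $10^{-6}$ on constant
images). On an impulse-corrupted image this percentile is dominated by
the corruption, so diffusion is aggressive exactly when the image is
badly corrupted; 15 iterations (the default) raise PSNR by roughly
10 dB at 10–40% impulse density on the default phantom.

The $c_2$ exponent is implemented as $(1+\alpha)$ with $\alpha = 1$ by
default, which reproduces the classic quadratic form.

## The phantom generator

The generator emulates the relevant features of an axial brain slice at
desk scale: a 160×160 grid, three tissue classes at intensities
0.2/0.5/0.8 (CSF-, gray-, white-matter-like), nested-ellipse geometry
with seeded jitter of center and axes (or seeded Voronoi cells as an
alternative), additive Gaussian noise, salt-and-pepper corruption at a
given density (each corrupted pixel set to 0 or 1 with equal
probability — "X% noise" is read as corruption density, the standard
convention), and a multiplicative bias field built from
Gaussian-filtered white noise, centered to grid mean exactly 1 and
scaled to a chosen maximum modulation. Every operation draws from a
counter-based seeded substream, so adding one operation never perturbs
another's draws and all outputs are bit-reproducible.

What the phantom does **not** emulate: real anatomy (no atlas
deformation), MRI physics (no Rician noise, no partial-volume mixing),
3-D structure. Consequently, passing the synthetic experiments
demonstrates the algorithmic contracts — noise robustness, spatial
regularization, metric correctness — not clinical segmentation
accuracy. On clean phantoms classes are exactly separable, which is why
near-perfect Dice there is a sanity check rather than a result.

## Experiment sizes and defaults

The packaged experiments use 160×160 phantoms: five replicates for the
Gaussian-noise (σ = 0.05) parameter-recovery study, twenty (tests) or
ten (acceptance script) replicates for the 20% impulse-noise comparison
against plain FCM, and one seeded phantom per density for the 10–40%
PSNR sweep. Smaller 16×16–32×32 phantoms back the per-operation unit
tests. These sizes make every property deterministic to assert while
each full pipeline run stays in the low seconds on one core.

## Known limitations

* Grayscale intensity is the only feature; multi-channel MRI is out of
  scope.
* The cluster count is user-supplied; no model selection.
* The kernel fitter is restricted to $m = 2$.
* PM diffusion is the unregularized original; for extremely heavy
  impulse noise a median prefilter (the `smoother` already computes
  one) is the practical complement.
* PSNR reports which peak value was used (1.0 for unit-range floats,
  255 for 8-bit I/O); partition entropy is the standard signed
  $-\frac1n\sum u\ln u$ form, with the unsigned squared-membership
  variant available as `v_pe(U, literal = TRUE)` for comparison.
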