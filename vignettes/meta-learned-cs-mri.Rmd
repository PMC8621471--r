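---
title: "Meta-learned convergent optimization for compressed-sensing MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learned convergent optimization for compressed-sensing MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaloa)
```

## The reconstruction problem

Compressed-sensing MRI measures a subset of k-space: `y = P F x + n`, where
`x` is the complex image, `F` the 2D discrete Fourier transform, `P` a binary
sampling pattern, and `n` complex acquisition noise. `metaloa` uses the
centered, orthonormal DFT convention (`dft2()`), which makes `F` unitary,
gives the data-fidelity term `f(x) = 0.5 ||P F x - y||^2` a 1-Lipschitz
gradient on a full mask, and makes a single unit-step gradient iteration
recover the fully sampled solution exactly. The measurement model never
states a scaling, and all operators in the package inherit this choice.

Reconstruction minimizes a variational objective

    f(x) + kappa * r(x; theta),

where the regularizer `r` is the l2,1 norm of features from a small complex
convolutional network `g` (default: 3 layers, 4 channels, 3x3 complex
kernels, no bias), and `kappa = sigmoid(omega)` is a scalar weight in (0, 1)
specific to each acquisition task (mask family and sampling ratio). The
l2,1 groups are the `d`-channel complex feature vectors at each spatial
location — the standard joint-sparsity reading — so `r` measures spatial
sparsity of learned features. The nonsmooth norm is smoothed per location as
`sqrt(||g_j||^2 + eps^2) - eps`; per term this is sandwiched between the
exact norm and the norm minus `eps`, so over `m` locations the exact l2,1
norm is matched to within `m * eps` (the provable summed bound, which is the
one the tests assert).

The activation is a C1 piecewise-quadratic smoothing of the ReLU with
half-width `delta = 0.001`, applied separately to real and imaginary
channels; it deviates from the ReLU by at most `delta / 4`. `delta` is kept
fixed (not trained). Complex convolutions act by true complex
multiplication with zero padding, stride 1, and same-size output.

All gradients treat the real and imaginary parts of `x` as independent real
coordinates (equivalently, twice the conjugate Wirtinger derivative), so
every gradient of a real-valued objective is itself a complex image and
gradient-descent steps are well defined.

## The convergent iteration

Each iteration first tries the inexpensive candidate step

    z = x - alpha * grad f(x)
    u = z - tau * kappa * grad r_eps(z)

and accepts `u` only if `||grad phi_eps(x)|| <= a ||u - x||` and
`phi_eps(u) - phi_eps(x) <= -(1/a) ||u - x||^2` (`phi_eps = f + kappa *
r_eps`). If the test fails, a safeguard step `v = x - alpha * grad
phi_eps(x)` is taken, with `alpha` shrunk by `rho = 0.9` until the same
sufficient-descent inequality holds; this preserves convergence while the
candidate branch keeps the common path cheap. When the gradient norm falls
below `sigma * gamma * eps`, the smoothing level shrinks (`eps <- gamma *
eps`, `gamma = 0.9`), driving the smoothed problem toward the nonsmooth one;
the run terminates once `sigma * eps < eps_tol`. Defaults follow the
reference configuration: `a = 1e5`, `sigma = 1e3`, `rho = gamma = 0.9`,
`alpha0 = tau0 = 0.01`, `eps0 = 0.001`, `eps_tol = 1e-3`.

Two numerical guards matter in practice. First, when the predicted descent
`alpha * ||grad||^2` falls below the floating-point resolution of the
objective, the safeguard returns the iterate unchanged (a zero step
satisfies the descent inequality trivially); without this, backtracking near
machine-precision stationarity cannot certify any step. Second, during
training only, if exploratory parameter values push the local curvature
beyond what the line-search trial budget can match, the unrolled forward
pass likewise takes a zero step rather than aborting; `run_loa()` (the
inference path) keeps the hard error.

The surrogate derivation combines two step sizes harmonically
(`tau = alpha * beta / (alpha + beta)`); since `beta` never appears
independently afterwards and `tau` is initialized directly, the package
parameterizes `tau` as a free positive learnable scalar (the harmonic
relation is kept as a unit test). After a line-search shrink the reduced
`alpha` persists as the next iteration's starting value — the algorithm
text updates the state variable and never resets it. The gradient norm at
each new iterate is computed once and cached: it serves both the smoothing
test at the end of one iteration and the acceptance test at the start of
the next, as long as `eps` is unchanged.

## The unrolled network and its gradients

`unrolled_forward()` runs exactly this control flow for a fixed number of
phases `T`, with per-phase learnable step sizes `(alpha_t, tau_t)` and the
shared extractor weights; `eps0` is learnable through a softplus
reparameterization so it stays positive. Branch decisions, line-search
shrinks, and smoothing-schedule triggers are non-differentiable control
flow: gradients flow through the arithmetic of the branch actually taken
(for a shrunk step, through the chain `alpha_used = rho^s * alpha_t`).

R has no automatic differentiation, so `unrolled_grad()` is a hand-coded
reverse sweep. First-order pieces — the conv-stack backward passes for
`grad r_eps` with respect to both the image and the kernels — are exact and
analytic (C++ core, validated against central finite differences to 1e-9
relative in the unit tests). The reverse sweep through the phases needs
curvature terms: the Hessian-vector product `H_r(z) lambda` and the mixed
kernel derivative of `lambda' grad r_eps(z; w)`. Both are computed as
central finite differences of the analytic first-order gradient along the
adjoint direction (step 1e-6 on unit directions), which costs two gradient
evaluations per phase and never materializes a matrix. The same pattern
computes the penalty terms of the bilevel objective below. Finite
differences of an exact gradient lose little accuracy here: the full
network gradient agrees with finite differences of the loss to about 1e-5
relative on test instances.

## Bilevel meta-training

Training data are partitioned into tasks (one sampling mask each), each with
disjoint train/validation/test splits. The task-invariant parameters
`theta` (kernels, step sizes, `eps0`) should minimize the summed training
loss; the task-specific weights `omega_i` are chosen so that the resulting
`theta` performs well on validation data. The lower-level optimality
constraint is relaxed to a penalty:

    L(theta, omega; val) + (lambda/2) * ||grad_theta L(theta, omega; tr)||^2

and minimized by an alternating scheme: sample a cross-task mini-batch
(per task, `J_tr` training and `J_val` validation pairs; the batch is the
union over tasks), take `K` optimizer steps on `theta`, then one on
`omega`, repeating while the squared gradient norm exceeds `delta`; then
`delta` shrinks by `nu_delta = 0.95` and `lambda` grows by `nu_lambda =
1.001` (defaults: `delta0 = 1e-3`, `delta_tol = 4.35e-6`, `lambda0 =
1e-5`). One "epoch" maps to one outer iteration (batch draw plus inner
loop); `lambda` and `delta` update once per outer iteration. `K` is not
pinned by the reference description; the package default is `K = 5`, and a
hard cap on inner iterations (default 200) guards against non-termination
at small `delta`. Adam (lr 1e-3) is the default optimizer for both
parameter groups, with plain SGD available. `omega` starts at 0
(`kappa = 0.5`, symmetric and unbiased); step sizes are kept in
`[1e-8, 2]` by projection after each update — the upper bound keeps the
line-search trial budget sufficient for the curvature the safeguard can
encounter.

Stair training grows the network: train with one phase, append a phase
(new step sizes at their defaults, shared weights kept) when the stage
ends, and stop when the stage-end validation loss fails to decrease or the
phase cap is reached. Adaptation to an unseen task freezes `theta`
bit-identically and fits only the scalar `omega` by Adam on the new task's
training pairs.

## Synthetic data

`make_phantom()` generates piecewise-smooth complex phantoms: randomly
placed rotated ellipses with piecewise-constant magnitude increments over a
mild smooth background, multiplied by a unit-modulus smooth phase field,
normalized to maximum modulus 1. This emulates the structure of intensity-
normalized brain slices — piecewise-smooth anatomy with slowly varying
receive phase — while remaining a pure, seeded function of its parameters.
It does not emulate realistic MR contrast physics, partial-volume texture,
or coil sensitivities, so passing tests demonstrate correctness of the
method and its training dynamics, not clinical image quality.

Masks: radial spokes through the k-space center (spoke count chosen by
bisection to land within one percentage point of the requested ratio, with
a pixelwise center-out top-up when whole spokes are too coarse at small
grids); random Cartesian phase-encode rows with an always-on 4% center
band; and variable-density Poisson sampling (density decaying with
k-space radius, exact sample count drawn without replacement). Noise is
circular complex Gaussian added at sampled locations only. Task suites
share one image population across tasks — only the undersampling differs —
mirroring the multi-task design where the same volumes are undersampled at
different ratios.

Default sizes are 32x32 for tests and demonstrations (the reference
experiments used 160x180 slices; desk scale demands smaller). The default
k-space noise level is 0.01 (1% of the normalized intensity scale), a mild
but nonzero acquisition noise.

## Problem sizes and what the scaled-down experiments show

The end-to-end experiments in the test suite and `scripts/acceptance.R`
train on two radial tasks (20% and 40% sampling, 32x32, 50/20/20 images per
split), stair-growing to at most 3 of the allowed 5 phases, with `K = 2`,
one inner iteration per outer loop, batch `J_tr = J_val = 2` per task, Adam
with lr 1e-2 for `theta` and 1e-3 for `omega`, and a few tens of outer
iterations per stage. These sizes were chosen so a full five-seed study
runs in minutes on one CPU core.

Scale changes what is reachable. At 32x32, a radial mask's spokes cover a
proportionally large fraction of k-space, so the zero-filled baseline is
comparatively strong, and a safeguarded scheme truncated at five phases can
apply only a bounded amount of feature shrinkage per phase. A reference
experiment with an ideal hand-built edge-sparsity (TV-like) regularizer —
the configuration the learned extractor would ideally discover — gains
about 1 dB mean over zero-filling at 5 phases on this suite, and over 3 dB
mean when allowed 30 phases. The learned model is therefore evaluated
against trends (training reduces loss; lower sampling ratios fit larger
task weights; the per-phase objective decreases while PSNR rises), and the
absolute PSNR margin over zero-filling at truncated depth is reported as
measured; reproducing the multi-dB margins of the full-scale reference
setting would require the original data scale and training budget.

## Known limitations

- Single-coil, Cartesian-grid k-space only; no NUFFT trajectories or 3D.
- The curvature terms of the training gradient are finite differences of
  analytic gradients; step sizes are fixed (1e-6 directional, 1e-5 for the
  penalty), adequate for the tested scales but not adaptive.
- The serialization helpers use R's native RDS format rather than a
  language-neutral container.
- Training at desk scale is sensitive to learning rates: the bilevel
  objective has a trivial basin where the regularizer is switched off
  (`tau -> 0`); small `omega` steps and moderate `theta` steps reduce the
  pull of that basin but do not remove it.
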