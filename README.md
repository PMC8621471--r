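# metaloa

Meta-learned convergent optimization for compressed-sensing MRI
reconstruction.

## The problem

Accelerated MRI measures only a fraction of k-space: `y = P F x + n`, with
`x` the complex image, `F` the (centered, orthonormal) 2D DFT, `P` a binary
sampling pattern, and `n` complex noise. Reconstruction solves the
variational problem

    min_x  1/2 ||P F x - y||^2  +  sigma(omega) * r(x; theta)

where the regularizer `r` is the smoothed l2,1 norm of features from a
small complex-convolution network (joint sparsity of learned features), and
`sigma(omega) in (0, 1)` weights it per *task* — one acquisition setting
(mask family and sampling ratio) per task. The solver is a learnable
optimization algorithm with a convergence guarantee: each iteration tries a
cheap two-step candidate (gradient step on the fidelity, then on the
smoothed regularizer) and falls back to a safeguarded line-search step only
when a sufficient-descent test fails, while the smoothing parameter `eps`
is driven to zero on a geometric schedule. Unrolling `T` iterations of this
scheme — with per-phase learnable step sizes and shared learnable filters —
gives the reconstruction network.

Training is a bilevel problem: task-invariant parameters `theta` (filters,
step sizes, initial smoothing) should minimize the training loss, while the
task-specific weights `omega_i` are tuned so the result also performs well
on validation data. The package trains the penalty relaxation
`L_val + (lambda/2) ||grad_theta L_tr||^2` by a stochastic alternating
scheme on cross-task mini-batches, grows the network one phase at a time
(stair training), and adapts to an unseen sampling pattern by re-fitting
only the scalar `omega` with everything else frozen.

The package is for method developers and students of unrolled optimization:
it includes seeded generators for piecewise-smooth complex phantoms and
radial / Cartesian / variable-density Poisson masks, so everything runs
from synthetic data with no downloads.

## Worked example

Reconstruct a 64x64 phantom from a 30% radial mask with an edge-sparsity
regularizer (two complex finite-difference kernels, task weight
`sigma(3) = 0.95`):

```r
library(metaloa)

x_star <- make_phantom(64, 64, n_ellipses = 6, seed = 42)
mask   <- make_radial_mask(64, 64, target_ratio = 0.3, seed = 7)
y      <- add_noise(forward_op(x_star, mask), std = 0.01, seed = 1)
mask
#> <sampling_mask> radial 64x64, ratio 0.3074

k <- array(0 + 0i, c(3, 3, 1, 2))
k[2, 2, 1, 1] <- 0.01; k[2, 3, 1, 1] <- -0.01   # horizontal difference
k[2, 2, 1, 2] <- 0.01; k[3, 2, 1, 2] <- -0.01   # vertical difference
fe <- feature_extractor(weights = list(k))

rec <- run_loa(y, fe, task_weight(3),
               loa_config(alpha0 = 1, tau0 = 1, eps_tol = 0, max_phases = 30))

x0 <- zero_fill(y)
cat(sprintf("zero-filled : PSNR %.2f dB  SSIM %.3f  NMSE %.4f\n",
            psnr(x0, x_star), ssim(x0, x_star), nmse(x0, x_star)))
cat(sprintf("reconstructed: PSNR %.2f dB  SSIM %.3f  NMSE %.4f\n",
            psnr(rec$x, x_star), ssim(rec$x, x_star), nmse(rec$x, x_star)))
#> zero-filled : PSNR 22.19 dB  SSIM 0.412  NMSE 0.0815
#> reconstructed: PSNR 24.90 dB  SSIM 0.545  NMSE 0.0433
```

The +2.7 dB over zero-filling comes from 30 safeguarded phases of feature
shrinkage interleaved with data-consistency gradient steps; `rec$trace`
records the objective value, gradient norm, branch taken (`u` = candidate,
`v` = safeguard), line-search trials, and smoothing level per phase.

Training and adaptation use the same building blocks:

```r
tasks <- build_task_suite(ratios = c(0.2, 0.4), families = "radial",
                          n_train = 50, n_val = 20, n_test = 20, seed = 1)
fit <- stair_train(tasks, feature_extractor(seed = 1),
                   stair_schedule(epochs_per_stage = 25, max_phases = 3),
                   bilevel_config(K = 2, max_inner = 1, lr_theta = 1e-2),
                   loa_config(eps_tol = 0), seed = 1)
tw <- adapt_unseen_task(fit$pp, build_task_suite(0.3, seed = 99)[[1]])
```

A thin command-line interface (`inst/cli/metaloa`) wraps simulation,
reconstruction and evaluation:

```sh
Rscript inst/cli/metaloa simulate --height 64 --width 64 --ratio 0.3 \
    --mask radial --seed 7 --out sample.rds
Rscript inst/cli/metaloa reconstruct --suite suite.rds --task 1 --index 1 \
    --phases 10 --out recon.png --trace trace.csv
```

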