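#' Piecewise-smooth complex brain-like phantom
#'
#' Superposition of randomly placed, rotated ellipses with piecewise-constant
#' magnitudes over a mild smooth background, multiplied by a unit-modulus
#' smooth spatial phase field, and normalized to maximum modulus 1.
#' Deterministic per seed: the generator is a pure function of its spec.
#'
#' @param height,width grid dimensions (>= 8).
#' @param n_ellipses number of ellipse inserts (default 6).
#' @param intensity_range range of ellipse magnitude increments.
#' @param phase_smoothness correlation length (pixels) of the smooth phase
#'   map; larger is smoother.
#' @param phase_amplitude peak-to-peak amplitude (radians) of the phase map.
#' @param seed integer seed.
#' @return complex `height x width` matrix with `max(Mod(.)) == 1`.
#' @export
make_phantom <- function(height = 32L, width = 32L, n_ellipses = 6L,
                         intensity_range = c(0.2, 1), phase_smoothness = 8,
                         phase_amplitude = pi / 2, seed = 1) {
  stopifnot(height >= 8, width >= 8, n_ellipses >= 0)
  with_seed(seed, {
    ii <- matrix(seq_len(height), height, width)
    jj <- matrix(seq_len(width), height, width, byrow = TRUE)
    # Mild smooth background so the image is never identically flat.
    bg <- 0.15 + 0.1 * sin(2 * pi * ii / height + stats::runif(1, 0, 2 * pi)) *
      cos(2 * pi * jj / width + stats::runif(1, 0, 2 * pi))
    mag <- bg
    for (e in seq_len(n_ellipses)) {
      ci <- stats::runif(1, 0.2 * height, 0.8 * height)
      cj <- stats::runif(1, 0.2 * width, 0.8 * width)
      ai <- stats::runif(1, 0.08, 0.3) * height
      aj <- stats::runif(1, 0.08, 0.3) * width
      th <- stats::runif(1, 0, pi)
      amp <- sample(c(-1, 1), 1) *
        stats::runif(1, intensity_range[1], intensity_range[2])
      di <- ii - ci; dj <- jj - cj
      u <- cos(th) * di + sin(th) * dj
      v <- -sin(th) * di + cos(th) * dj
      mag <- mag + amp * ((u / ai)^2 + (v / aj)^2 <= 1)
    }
    mag <- pmax(mag, 0)
    ph <- smooth_field(height, width, phase_smoothness)
    ph <- phase_amplitude * ph / max(abs(range(ph)), 1e-12)
    img <- mag * exp(1i * ph)
    img / max(Mod(img))
  })
}

# Smooth zero-mean random field: low-pass filtered white noise in k-space.
smooth_field <- function(h, w, corr_len) {
  noise <- matrix(stats::rnorm(h * w), h, w)
  ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  ctr <- kspace_center(h, w)
  r2 <- (ii - ctr[1])^2 + (jj - ctr[2])^2
  lp <- exp(-r2 * (corr_len / max(h, w))^2)
  f <- Re(idft2(dft2(noise) * lp))
  f - mean(f)
}

#' Specification and generation of a multi-task reconstruction suite
#'
#' Generates a shared population of phantom images, splits it into disjoint
#' train/validation/test sets, and produces one [task_bundle()] per
#' `(mask family, ratio)` pair: the task's mask is applied to every image
#' (plus optional k-space noise) to form `(y, x_star)` pairs. All tasks
#' share the same underlying images — only the undersampling differs.
#'
#' @param ratios numeric vector of sampling ratios, one per task.
#' @param families mask family per task (recycled; default `"radial"`).
#' @param n_train,n_val,n_test images per split.
#' @param height,width image size (default 32).
#' @param noise_std k-space noise level (default 0.01).
#' @param seed integer seed; all masks, images and noise derive from it.
#' @param n_ellipses passed to [make_phantom()].
#' @return list of [task_bundle()]s.
#' @export
build_task_suite <- function(ratios, families = "radial", n_train = 10L,
                             n_val = 5L, n_test = 5L, height = 32L,
                             width = 32L, noise_std = 0.01, seed = 1,
                             n_ellipses = 6L) {
  stopifnot(length(ratios) >= 1)
  families <- rep_len(families, length(ratios))
  n_total <- n_train + n_val + n_test
  images <- lapply(seq_len(n_total), function(i) {
    make_phantom(height, width, n_ellipses = n_ellipses,
                 seed = seed * 10000L + i)
  })
  splits <- list(train = seq_len(n_train),
                 val = n_train + seq_len(n_val),
                 test = n_train + n_val + seq_len(n_test))
  lapply(seq_along(ratios), function(ti) {
    mask <- make_mask(families[ti], height, width, ratios[ti],
                      seed = seed * 100L + ti)
    make_split <- function(idx) {
      lapply(seq_along(idx), function(k) {
        i <- idx[k]
        y <- forward_op(images[[i]], mask)
        if (noise_std > 0) {
          y <- add_noise(y, noise_std, seed = seed * 1000000L + ti * 10000L + i)
        }
        list(y = y, x_star = images[[i]])
      })
    }
    task_bundle(task_id = sprintf("%s_%02d", families[ti],
                                  round(100 * ratios[ti])),
                mask = mask,
                train_pairs = make_split(splits$train),
                val_pairs = make_split(splits$val),
                test_pairs = make_split(splits$test),
                omega = 0)
  })
}

#' Evaluate reconstructions on a task's test pairs
#'
#' Runs the unrolled network (or the zero-filled baseline) on every test
#' pair and reports image-quality metrics.
#'
#' @param task a [task_bundle()].
#' @param pp a [phase_params()], or `NULL` for the zero-filled baseline.
#' @param omega task-specific scalar (ignored for the baseline).
#' @param cfg a [loa_config()].
#' @param split which split to evaluate (default `"test"`).
#' @return a [metric_report()].
#' @export
evaluate_task <- function(task, pp = NULL, omega = 0, cfg = loa_config(),
                          split = c("test", "val", "train")) {
  split <- match.arg(split)
  pairs <- task[[paste0(split, "_pairs")]]
  preds <- lapply(pairs, function(p) {
    if (is.null(pp)) zero_fill(p$y) else unrolled_forward(p$y, pp, omega, cfg)$x
  })
  truths <- lapply(pairs, `[[`, "x_star")
  metric_report(preds, truths)
}
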