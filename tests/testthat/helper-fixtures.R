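# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (explicit loops, direct formula evaluation) and
# independent of the implementation paths they check.

rand_image <- function(h, w, seed = 1, scale = 1) {
  metaloa:::with_seed(seed, {
    matrix(complex(real = stats::rnorm(h * w, sd = scale),
                   imaginary = stats::rnorm(h * w, sd = scale)), h, w)
  })
}

rdot <- metaloa:::rdot
cnorm <- metaloa:::cnorm

# Explicit double-loop complex 'same' convolution (single in/out channel).
conv_oracle <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  kh <- dim(k)[1]; kw <- dim(k)[2]
  cy <- (kh + 1) / 2; cx <- (kw + 1) / 2
  out <- matrix(0 + 0i, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0 + 0i
    for (p in seq_len(kh)) for (q in seq_len(kw)) {
      ii <- i + p - cy; jj <- j + q - cx
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        acc <- acc + k[p, q] * x[ii, jj]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Central finite differences of a scalar function of a complex image,
# returning the gradient in the package's real-coordinate convention.
fd_grad_image <- function(f, x, h = 1e-5) {
  g <- matrix(0 + 0i, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    d <- matrix(0 + 0i, nrow(x), ncol(x))
    d[i, j] <- h
    re <- (f(x + d) - f(x - d)) / (2 * h)
    d[i, j] <- 1i * h
    im <- (f(x + d) - f(x - d)) / (2 * h)
    g[i, j] <- complex(real = re, imaginary = im)
  }
  g
}

# Brute-force windowed SSIM with a Gaussian window over valid positions.
ssim_oracle <- function(x, y, win_size = 11, sigma = 1.5, k1 = 0.01,
                        k2 = 0.03, L = max(y)) {
  w1 <- exp(-((seq_len(win_size) - (win_size + 1) / 2)^2) / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  half <- (win_size - 1) / 2
  vals <- c()
  for (i in (half + 1):(nrow(x) - half)) {
    for (j in (half + 1):(ncol(x) - half)) {
      px <- x[(i - half):(i + half), (j - half):(j + half)]
      py <- y[(i - half):(i + half), (j - half):(j + half)]
      mx <- sum(W * px); my <- sum(W * py)
      vx <- sum(W * px^2) - mx^2
      vy <- sum(W * py^2) - my^2
      cxy <- sum(W * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

tiny_extractor <- function(seed = 5, delta = 0.01) {
  feature_extractor(n_layers = 2, n_channels = 3, kernel_size = 3,
                    delta = delta, seed = seed)
}

small_problem <- function(h = 8, w = 8, ratio = 0.5, seed = 2,
                          noise_std = 0) {
  x_star <- make_phantom(h, w, n_ellipses = 3, seed = seed)
  mask <- make_radial_mask(h, w, ratio, seed = seed + 1, tol = 0.2)
  y <- forward_op(x_star, mask)
  if (noise_std > 0) y <- add_noise(y, noise_std, seed = seed + 2)
  list(x_star = x_star, mask = mask, y = y)
}
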