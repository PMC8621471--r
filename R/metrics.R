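#' Image-quality metrics: MSE, PSNR, SSIM, NMSE
#'
#' All metrics operate on magnitude images; complex inputs are
#' magnitude-mapped first. `mse()` is the mean squared difference. `psnr()`
#' is `20 * log10(max(|x_star|) / sqrt(MSE(x, x_star)))` in dB (capped at
#' 100 dB for identical images). `nmse()` is `||x - x_star||^2 / ||x||^2`,
#' normalized by the reconstruction; `normalize_by = "reference"` switches
#' the denominator to `||x_star||^2`.
#'
#' @param x reconstruction (complex or numeric matrix).
#' @param x_star ground-truth reference.
#' @return scalar.
#' @export
mse <- function(x, x_star) {
  x <- magnitude(x); x_star <- magnitude(x_star)
  if (!all(dim(x) == dim(x_star))) stop("shape mismatch", call. = FALSE)
  mean((x - x_star)^2)
}

magnitude <- function(x) {
  if (is.complex(x)) Mod(x) else x
}

#' @rdname mse
#' @export
psnr <- function(x, x_star) {
  x_star_m <- magnitude(x_star)
  if (max(x_star_m) == 0) stop("all-zero reference", call. = FALSE)
  m <- mse(x, x_star)
  if (m == 0) return(100)
  min(100, 20 * log10(max(x_star_m) / sqrt(m)))
}

#' @rdname mse
#' @param normalize_by `"reconstruction"` (as defined here) or
#'   `"reference"`.
#' @export
nmse <- function(x, x_star, normalize_by = c("reconstruction", "reference")) {
  normalize_by <- match.arg(normalize_by)
  xm <- magnitude(x); sm <- magnitude(x_star)
  if (!all(dim(xm) == dim(sm))) stop("shape mismatch", call. = FALSE)
  den <- if (normalize_by == "reconstruction") sum(xm^2) else sum(sm^2)
  if (den == 0) stop("zero-norm denominator image", call. = FALSE)
  sum((xm - sm)^2) / den
}

# 1D Gaussian window, unit sum.
gauss_win <- function(size, sigma) {
  t <- seq_len(size) - (size + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable 'valid' correlation of an image with an outer-product window.
filter_valid <- function(img, win) {
  k <- length(win)
  h <- nrow(img); w <- ncol(img)
  rows <- apply(img, 2, function(col) stats::filter(col, win, sides = 2))
  out <- t(apply(rows, 1, function(row) stats::filter(row, win, sides = 2)))
  half <- (k - 1) / 2
  out[(half + 1):(h - half), (half + 1):(w - half), drop = FALSE]
}

#' Structural similarity index (mean over local Gaussian windows)
#'
#' Local means, variances and covariance are computed under an 11x11
#' Gaussian window (sigma 1.5) and combined as
#' `(2 mu_x mu_y + C1)(2 cov + C2) / ((mu_x^2 + mu_y^2 + C1)(var_x + var_y + C2))`
#' with `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, `k1 = 0.01`, `k2 = 0.03`, and `L`
#' the largest pixel value of the reference (overridable). Only windows
#' fully inside the image contribute; `ssim(x, x) == 1` exactly.
#'
#' @inheritParams mse
#' @param win_size odd window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 stabilization constants.
#' @param L dynamic range; default `max(|x_star|)`.
#' @return scalar in (-1, 1].
#' @export
ssim <- function(x, x_star, win_size = 11L, sigma = 1.5, k1 = 0.01,
                 k2 = 0.03, L = NULL) {
  x <- magnitude(x); x_star <- magnitude(x_star)
  if (!all(dim(x) == dim(x_star))) stop("shape mismatch", call. = FALSE)
  if (nrow(x) < win_size || ncol(x) < win_size) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  if (is.null(L)) L <- max(x_star)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  win <- gauss_win(win_size, sigma)
  mu_x <- filter_valid(x, win)
  mu_y <- filter_valid(x_star, win)
  sxx <- filter_valid(x * x, win) - mu_x^2
  syy <- filter_valid(x_star * x_star, win) - mu_y^2
  sxy <- filter_valid(x * x_star, win) - mu_x * mu_y
  mean(((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
         ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)))
}

#' Aggregate metrics over a set of reconstructions
#'
#' @param preds,truths lists of images (equal length).
#' @return object of class `metric_report`: data frame of per-image PSNR,
#'   SSIM, NMSE plus `mean` and `sd` attributes.
#' @export
metric_report <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  rows <- mapply(function(p, t) {
    c(psnr = psnr(p, t), ssim = ssim(p, t), nmse = nmse(p, t))
  }, preds, truths)
  df <- as.data.frame(t(rows))
  structure(df, class = c("metric_report", "data.frame"),
            mean = colMeans(df), sd = apply(df, 2, stats::sd))
}

#' @export
print.metric_report <- function(x, ...) {
  m <- attr(x, "mean"); s <- attr(x, "sd")
  cat(sprintf("PSNR %.4f +/- %.4f  SSIM %.4f +/- %.4f  NMSE %.4f +/- %.4f  (n = %d)\n",
              m["psnr"], s["psnr"], m["ssim"], s["ssim"], m["nmse"],
              s["nmse"], nrow(x)))
  invisible(x)
}
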