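#' Smoothed rectified linear activation
#'
#' Piecewise-quadratic C1 smoothing of the ReLU with transition half-width
#' `delta`: zero for `v <= -delta`, `v^2/(4 delta) + v/2 + delta/4` on
#' `(-delta, delta)`, identity for `v >= delta`. Its maximum deviation from
#' the ReLU is `delta/4`, attained at `v = 0`. Applied componentwise to the
#' real and imaginary channels of feature maps.
#'
#' @param v numeric vector.
#' @param delta positive transition half-width (default 0.001).
#' @return numeric vector; `phi_prime()` returns the derivative.
#' @export
phi <- function(v, delta = 0.001) {
  stopifnot(delta > 0)
  ifelse(v <= -delta, 0,
         ifelse(v >= delta, v, v^2 / (4 * delta) + v / 2 + delta / 4))
}

#' @rdname phi
#' @export
phi_prime <- function(v, delta = 0.001) {
  stopifnot(delta > 0)
  ifelse(v <= -delta, 0, ifelse(v >= delta, 1, v / (2 * delta) + 0.5))
}

#' Complex 2D convolution (same-size, zero-padded, no bias)
#'
#' Complex kernels act by true complex multiplication,
#' `(a + ib) * (c + id) = (ac - bd) + i(ad + bc)`, accumulated over input
#' channels. `x` may be an `H x W` complex matrix (one channel) or an
#' `H x W x c_in` array; `w` is a `kh x kw x c_in x c_out` complex array with
#' odd spatial size.
#'
#' @param x complex matrix or 3D array.
#' @param w complex 4D kernel array.
#' @return `H x W x c_out` complex array.
#' @export
complex_conv <- function(x, w) {
  if (!is.complex(x)) storage.mode(x) <- "complex"
  if (!is.complex(w)) storage.mode(w) <- "complex"
  cpp_complex_conv(x, w)
}

#' Learnable feature extractor for the regularizer
#'
#' An `n_layers`-deep complex CNN with `n_channels` kernels per layer of odd
#' spatial size `kernel_size`, no bias, and the smoothed activation [phi()]
#' between layers (none after the last). Weights are Xavier/Glorot
#' initialized, real and imaginary parts independently, deterministically
#' from `seed`.
#'
#' @param n_layers number of convolution layers (default 3).
#' @param n_channels kernels per layer (default 4).
#' @param kernel_size odd spatial size (default 3).
#' @param delta activation half-width (default 0.001, kept fixed).
#' @param seed integer seed for initialization.
#' @param weights optional list of kernel arrays to use instead of random
#'   initialization (dims `kh x kw x c_in x c_out` per layer).
#' @return object of class `feature_extractor` with elements `weights`,
#'   `delta`, `n_layers`, `n_channels`, `kernel_size`.
#' @export
feature_extractor <- function(n_layers = 3, n_channels = 4, kernel_size = 3,
                              delta = 0.001, seed = 1, weights = NULL) {
  stopifnot(kernel_size %% 2 == 1, n_layers >= 1, delta > 0)
  if (is.null(weights)) {
    weights <- with_seed(seed, lapply(seq_len(n_layers), function(q) {
      c_in <- if (q == 1) 1L else n_channels
      c_out <- n_channels
      # Xavier/Glorot uniform bound over the receptive field.
      bound <- sqrt(6 / (kernel_size^2 * (c_in + c_out)))
      n <- kernel_size^2 * c_in * c_out
      array(complex(real = stats::runif(n, -bound, bound),
                    imaginary = stats::runif(n, -bound, bound)),
            dim = c(kernel_size, kernel_size, c_in, c_out))
    }))
  }
  stopifnot(all(vapply(weights, function(w) all(is.finite(Re(w)) & is.finite(Im(w))),
                       logical(1))))
  structure(list(weights = weights, delta = delta,
                 n_layers = length(weights),
                 n_channels = dim(weights[[length(weights)]])[4],
                 kernel_size = dim(weights[[1]])[1]),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %d layers, %d channels, %dx%d complex kernels, delta = %g\n",
              x$n_layers, x$n_channels, x$kernel_size, x$kernel_size, x$delta))
  invisible(x)
}

# Single-layer extractor whose 1x1 kernel is the (real) identity: g(x) = x.
# Useful as a convex oracle configuration.
identity_extractor <- function(delta = 0.001) {
  feature_extractor(weights = list(array(1 + 0i, dim = c(1, 1, 1, 1))),
                    delta = delta)
}

#' Feature-extractor forward pass
#'
#' Applies `w_l * phi(... phi(w_2 * phi(w_1 * x)))`: activation after every
#' convolution except the last. The output is a field of `n_channels`-vector
#' complex features, one per spatial location.
#'
#' @param x complex image matrix.
#' @param fe a [feature_extractor()].
#' @return `H x W x d` complex array of features.
#' @export
g_forward <- function(x, fe) {
  stopifnot(inherits(fe, "feature_extractor"))
  x <- as_complex_image(x)
  cpp_g_forward(x, fe$weights, fe$delta)
}

#' l2,1 norm of a feature field and its epsilon-smoothing
#'
#' `l21_norm()` sums, over spatial locations, the Euclidean norm of the
#' cross-channel complex feature vector (real and imaginary parts pooled).
#' `smoothed_l21()` replaces each norm `s` by `sqrt(s^2 + eps^2) - eps`,
#' which is smooth and sandwiched in `[s - ...]`: per term it lies in
#' `[max(0, s - eps), s]`, so over `m` locations
#' `smoothed <= l21 <= smoothed + m * eps`.
#'
#' @param features `H x W x d` complex array (a matrix is treated as d = 1).
#' @param eps positive smoothing parameter.
#' @return scalar.
#' @export
l21_norm <- function(features) {
  f <- feature_array(features)
  sum(sqrt(apply(Re(f)^2 + Im(f)^2, c(1, 2), sum)))
}

#' @rdname l21_norm
#' @export
smoothed_l21 <- function(features, eps) {
  stopifnot(eps > 0)
  f <- feature_array(features)
  s2 <- apply(Re(f)^2 + Im(f)^2, c(1, 2), sum)
  sum(sqrt(s2 + eps^2) - eps)
}

feature_array <- function(features) {
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  stopifnot(length(dim(features)) == 3)
  if (!is.complex(features)) storage.mode(features) <- "complex"
  features
}

#' Smoothed learned regularizer r_eps and its gradient
#'
#' `r_eps()` evaluates the smoothed l2,1 norm of the extracted features,
#' `sum_j (sqrt(||g_j(x)||^2 + eps^2) - eps)`. `grad_r_eps()` returns its
#' exact gradient with respect to `x` under real-coordinate semantics,
#' computed by a hand-derived backward pass through the convolution
#' transposes and activation gates (finite-difference validated in the test
#' suite). `reg_backprop()` additionally returns the gradient with respect
#' to every kernel.
#'
#' @param x complex image matrix.
#' @param fe a [feature_extractor()].
#' @param eps positive smoothing parameter.
#' @return `r_eps()`: scalar; `grad_r_eps()`: complex image;
#'   `reg_backprop()`: list with `value`, `grad_x`, and (if `want_w`)
#'   `grad_w`.
#' @export
r_eps <- function(x, fe, eps) {
  stopifnot(inherits(fe, "feature_extractor"), eps > 0)
  cpp_reg_value(as_complex_image(x), fe$weights, fe$delta, eps)
}

#' @rdname r_eps
#' @export
grad_r_eps <- function(x, fe, eps) {
  stopifnot(inherits(fe, "feature_extractor"))
  if (eps <= 0) stop("smoothing-required: eps must be positive", call. = FALSE)
  cpp_reg_backprop(as_complex_image(x), fe$weights, fe$delta, eps, FALSE)$grad_x
}

#' @rdname r_eps
#' @param want_w also compute kernel gradients.
#' @export
reg_backprop <- function(x, fe, eps, want_w = FALSE) {
  stopifnot(inherits(fe, "feature_extractor"))
  if (eps <= 0) stop("smoothing-required: eps must be positive", call. = FALSE)
  cpp_reg_backprop(as_complex_image(x), fe$weights, fe$delta, eps, want_w)
}

#' Task-specific regularization weight
#'
#' The regularizer is scaled per task by `kappa = sigmoid(omega)`, an
#' unconstrained scalar mapped into (0, 1).
#'
#' @param omega real scalar.
#' @return object of class `task_weight` with `omega` and `kappa`.
#' @export
task_weight <- function(omega = 0) {
  structure(list(omega = omega, kappa = sigmoid(omega)), class = "task_weight")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Weighted regularizer value and gradient
#'
#' Returns `sigma(omega) * r_eps(x)` and its gradient; the task weight scales
#' both exactly.
#'
#' @inheritParams r_eps
#' @param tw a [task_weight()] (or bare omega scalar).
#' @return list with `value` and `grad`.
#' @export
reg_value_and_grad <- function(x, fe, tw, eps) {
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  bp <- reg_backprop(x, fe, eps)
  list(value = tw$kappa * bp$value, grad = tw$kappa * bp$grad_x)
}
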