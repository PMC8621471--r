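#' Construct a k-space measurement object
#'
#' Holds the (zero-filled) k-space values on the full grid together with the
#' sampling mask that produced them. Values are identically zero wherever the
#' mask is zero.
#'
#' @param values complex matrix of k-space values.
#' @param mask a [sampling_mask()].
#' @param noise_std nonnegative noise level that was added (bookkeeping only).
#' @return object of class `kspace`.
#' @export
kspace <- function(values, mask, noise_std = 0) {
  stopifnot(inherits(mask, "sampling_mask"),
            all(dim(values) == dim(mask$pattern)), noise_std >= 0)
  values[mask$pattern == 0] <- 0 + 0i
  structure(list(values = values, mask = mask, noise_std = noise_std),
            class = "kspace")
}

#' CS-MRI forward operator: masked centered DFT
#'
#' Implements the acquisition model `y = P F x` (noise is added separately by
#' [add_noise()]): the image is mapped to centered orthonormal k-space and
#' unsampled locations are zeroed.
#'
#' @param x complex image matrix.
#' @param mask a [sampling_mask()].
#' @return a [kspace()] object.
#' @export
forward_op <- function(x, mask) {
  x <- as_complex_image(x)
  if (!all(dim(x) == dim(mask$pattern))) stop("shape mismatch", call. = FALSE)
  kspace(mask$pattern * dft2(x), mask)
}

#' Adjoint of the forward operator (zero-filled reconstruction)
#'
#' Applies the inverse centered DFT to the zero-filled k-space grid. This is
#' both the exact adjoint of [forward_op()] under the real inner product and
#' the standard zero-filling baseline/initializer.
#'
#' @param y a [kspace()] object (or a complex matrix plus `mask`).
#' @param mask required when `y` is a bare matrix.
#' @return complex image matrix.
#' @export
adjoint_op <- function(y, mask = NULL) {
  v <- if (inherits(y, "kspace")) y$values * y$mask$pattern else {
    stopifnot(inherits(mask, "sampling_mask"))
    y * mask$pattern
  }
  idft2(v)
}

#' @rdname adjoint_op
#' @export
zero_fill <- function(y) adjoint_op(y)

#' Add circular complex Gaussian noise to sampled k-space locations
#'
#' Each sampled location receives independent Gaussian noise with standard
#' deviation `std / sqrt(2)` per real component (total complex std `std`).
#' Off-mask entries remain exactly zero. Deterministic from `seed`.
#'
#' @param y a [kspace()] object.
#' @param std total complex noise standard deviation, `>= 0`.
#' @param seed integer seed.
#' @return a [kspace()] object.
#' @export
add_noise <- function(y, std, seed) {
  stopifnot(inherits(y, "kspace"))
  if (std < 0) stop("negative std", call. = FALSE)
  if (std == 0) return(y)
  n <- sum(y$mask$pattern)
  noise <- with_seed(seed, complex(real = stats::rnorm(n, sd = std / sqrt(2)),
                                   imaginary = stats::rnorm(n, sd = std / sqrt(2))))
  v <- y$values
  v[y$mask$pattern == 1] <- v[y$mask$pattern == 1] + noise
  kspace(v, y$mask, noise_std = std)
}

#' Data-fidelity term and its gradient
#'
#' `data_fidelity()` returns `0.5 * || P F x - y ||^2` over all real and
#' imaginary components. `grad_data_fidelity()` returns its exact gradient
#' under the real-coordinate semantics (twice the conjugate Wirtinger
#' derivative), `F^H P^H (P F x - y)`, which vanishes exactly at
#' data-consistent `x`.
#'
#' @param x complex image matrix.
#' @param y a [kspace()] object.
#' @return scalar (`data_fidelity`) or complex image (`grad_data_fidelity`).
#' @export
data_fidelity <- function(x, y) {
  stopifnot(inherits(y, "kspace"))
  x <- as_complex_image(x)
  if (!all(dim(x) == dim(y$values))) stop("shape mismatch", call. = FALSE)
  r <- y$mask$pattern * dft2(x) - y$values
  0.5 * sum(Re(r)^2 + Im(r)^2)
}

#' @rdname data_fidelity
#' @export
grad_data_fidelity <- function(x, y) {
  stopifnot(inherits(y, "kspace"))
  x <- as_complex_image(x)
  if (!all(dim(x) == dim(y$values))) stop("shape mismatch", call. = FALSE)
  idft2(y$mask$pattern * (y$mask$pattern * dft2(x) - y$values))
}
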