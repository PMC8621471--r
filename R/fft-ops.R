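#' Centered orthonormal 2D discrete Fourier transform
#'
#' `dft2()` maps an image to k-space with the DC coefficient at the grid
#' center (`floor(H/2) + 1`, `floor(W/2) + 1`) and symmetric `1/sqrt(H*W)`
#' scaling, so the transform is unitary: `sum(Mod(dft2(x))^2) == sum(Mod(x)^2)`
#' and `idft2(dft2(x)) == x` to machine precision. All downstream operators
#' (forward model, adjoints, gradients) inherit this convention.
#'
#' @param x complex (or numeric) matrix, the image.
#' @return complex matrix of the same dimensions, centered k-space.
#' @export
dft2 <- function(x) {
  x <- as_complex_image(x)
  fftshift(stats::fft(x)) / sqrt(length(x))
}

#' @rdname dft2
#' @param k complex matrix, centered k-space values.
#' @export
idft2 <- function(k) {
  stopifnot(is.matrix(k))
  stats::fft(ifftshift(k), inverse = TRUE) / sqrt(length(k))
}

#' Shift the zero-frequency component to the grid center
#'
#' `fftshift()` moves DC from `[1, 1]` to the center; `ifftshift()` is its
#' exact inverse (the two differ for odd dimensions).
#'
#' @param x matrix.
#' @return matrix with quadrants swapped.
#' @export
fftshift <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
    c((floor(w / 2) + 1):w, seq_len(floor(w / 2))), drop = FALSE]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((ceiling(h / 2) + 1):h, seq_len(ceiling(h / 2))),
    c((ceiling(w / 2) + 1):w, seq_len(ceiling(w / 2))), drop = FALSE]
}

#' Index of the DC (k-space center) location after [fftshift()]
#' @param h,w grid dimensions.
#' @return integer vector `c(row, col)`.
#' @export
kspace_center <- function(h, w) c(floor(h / 2) + 1L, floor(w / 2) + 1L)

# Coerce to a complex matrix and validate finiteness.
as_complex_image <- function(x) {
  if (!is.matrix(x)) stop("image must be a matrix", call. = FALSE)
  if (!is.complex(x)) storage.mode(x) <- "complex"
  if (any(!is.finite(Re(x)) | !is.finite(Im(x)))) {
    stop("invalid-image: non-finite entries", call. = FALSE)
  }
  x
}

# Real inner product of two complex matrices (images viewed as vectors of
# real and imaginary coordinates).
rdot <- function(a, b) sum(Re(a) * Re(b) + Im(a) * Im(b))

# Euclidean norm over all real and imaginary components.
cnorm <- function(a) sqrt(sum(Re(a)^2 + Im(a)^2))

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Generators stay pure functions of their seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
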