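#' k-space sampling masks
#'
#' A sampling mask selects which k-space locations are measured. Patterns are
#' binary matrices on the image grid; the recorded `ratio` is always the
#' achieved fraction `sum(pattern) / (H * W)`. Radial and Cartesian masks
#' always include the k-space center; all generators are deterministic
#' functions of their seed.
#'
#' @param pattern binary matrix (0/1).
#' @param family one of `"radial"`, `"cartesian"`, `"poisson"`, `"full"`.
#' @param seed integer seed the pattern was drawn from (or `NA`).
#' @return an object of class `sampling_mask` with elements `pattern`,
#'   `ratio`, `family`, `seed`.
#' @export
sampling_mask <- function(pattern, family, seed = NA_integer_) {
  stopifnot(is.matrix(pattern), all(pattern %in% c(0, 1)))
  structure(
    list(pattern = pattern, ratio = sum(pattern) / length(pattern),
         family = family, seed = seed),
    class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %s %dx%d, ratio %.4f\n", x$family,
              nrow(x$pattern), ncol(x$pattern), x$ratio))
  invisible(x)
}

#' @describeIn sampling_mask fully sampled mask (ratio exactly 1).
#' @param h,w grid dimensions.
#' @export
make_full_mask <- function(h, w) {
  sampling_mask(matrix(1, h, w), "full")
}

# Pixels of one diametral spoke through the k-space center at angle `ang`.
spoke_pixels <- function(h, w, ang) {
  ctr <- kspace_center(h, w)
  rmax <- sqrt(h^2 + w^2) / 2
  t <- seq(-rmax, rmax, by = 0.25)
  i <- pmin(pmax(round(ctr[1] + t * sin(ang)), 1L), h)
  j <- pmin(pmax(round(ctr[2] + t * cos(ang)), 1L), w)
  unique(cbind(i, j))
}

#' Radial (spoke) undersampling mask
#'
#' The pattern is a union of diametral spokes through the k-space center at
#' angles drawn uniformly from the seed. The number of spokes is chosen by
#' bisection so the achieved sampling ratio lands within one percentage point
#' of `target_ratio`; if full spokes overshoot the band, pixels of one final
#' spoke are added outward from the center until the ratio enters it.
#'
#' @param h,w grid dimensions.
#' @param target_ratio requested sampling ratio in (0, 1].
#' @param seed integer seed.
#' @param tol acceptance band around `target_ratio` (default 0.01).
#' @return a [sampling_mask()] of family `"radial"` (or `"full"` when
#'   `target_ratio = 1`).
#' @export
make_radial_mask <- function(h, w, target_ratio, seed, tol = 0.01) {
  stopifnot(target_ratio > 0, target_ratio <= 1)
  if (target_ratio == 1) return(make_full_mask(h, w))
  n_px <- h * w
  # A generous pool of candidate spokes in a fixed seeded order.
  max_spokes <- 4L * max(h, w)
  angles <- with_seed(seed, stats::runif(max_spokes, 0, pi))
  pattern_for <- function(n_spokes) {
    m <- matrix(0, h, w)
    for (ang in angles[seq_len(n_spokes)]) m[spoke_pixels(h, w, ang)] <- 1
    m
  }
  ratio_for <- function(n) sum(pattern_for(n)) / n_px
  if (ratio_for(max_spokes) < target_ratio - tol) {
    stop("ratio-infeasible: target exceeds maximum achievable with all spokes",
         call. = FALSE)
  }
  lo <- 1L; hi <- max_spokes
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ratio_for(mid) < target_ratio) lo <- mid + 1L else hi <- mid
  }
  # lo = smallest spoke count reaching the target; lo-1 undershoots.
  cand <- lo
  if (lo > 1L && abs(ratio_for(lo - 1L) - target_ratio) <
        abs(ratio_for(lo) - target_ratio)) {
    cand <- lo - 1L
  }
  m <- pattern_for(cand)
  if (abs(sum(m) / n_px - target_ratio) > tol) {
    # Full-spoke granularity too coarse: restart from the largest
    # undershooting count and grow the next spoke pixel by pixel, center out.
    m <- pattern_for(lo - 1L)
    extra <- spoke_pixels(h, w, angles[lo])
    ctr <- kspace_center(h, w)
    ord <- order((extra[, 1] - ctr[1])^2 + (extra[, 2] - ctr[2])^2)
    for (r in ord) {
      if (sum(m) / n_px >= target_ratio) break
      m[extra[r, 1], extra[r, 2]] <- 1
    }
  }
  ctr <- kspace_center(h, w)
  m[ctr[1], ctr[2]] <- 1
  msk <- sampling_mask(m, "radial", seed)
  if (abs(msk$ratio - target_ratio) > tol) {
    stop("ratio-infeasible: could not reach target ratio within tolerance",
         call. = FALSE)
  }
  msk
}

#' Random Cartesian (phase-encode line) undersampling mask
#'
#' Selects `round(target_ratio * h)` full k-space rows at random from the
#' seed, always including a fully sampled center band of
#' `max(1, round(center_fraction * h))` rows around the k-space center.
#'
#' @inheritParams make_radial_mask
#' @param center_fraction fraction of rows in the always-on center band.
#' @return a [sampling_mask()] of family `"cartesian"` (or `"full"`).
#' @export
make_cartesian_mask <- function(h, w, target_ratio, seed,
                                center_fraction = 0.04) {
  stopifnot(target_ratio > 0, target_ratio <= 1)
  if (target_ratio == 1) return(make_full_mask(h, w))
  n_rows <- max(1L, round(target_ratio * h))
  n_band <- max(1L, round(center_fraction * h))
  ctr <- kspace_center(h, w)[1]
  band <- seq.int(ctr - (n_band - 1L) %/% 2L, length.out = n_band)
  band <- band[band >= 1 & band <= h]
  if (n_rows < length(band)) {
    stop("ratio-infeasible: target below the always-on center band",
         call. = FALSE)
  }
  rest <- setdiff(seq_len(h), band)
  picked <- with_seed(seed, sample(rest, n_rows - length(band)))
  m <- matrix(0, h, w)
  m[c(band, picked), ] <- 1
  sampling_mask(m, "cartesian", seed)
}

#' Variable-density Poisson undersampling mask
#'
#' Draws exactly `round(target_ratio * h * w)` k-space locations without
#' replacement with probability decaying with distance from the center
#' (density `(1 - r/rmax)^2 + 0.01`), so low frequencies are sampled more
#' densely. Deterministic from the seed; the center point is always kept.
#'
#' @inheritParams make_radial_mask
#' @return a [sampling_mask()] of family `"poisson"` (or `"full"`).
#' @export
make_poisson_mask <- function(h, w, target_ratio, seed) {
  stopifnot(target_ratio > 0, target_ratio <= 1)
  if (target_ratio == 1) return(make_full_mask(h, w))
  n_pick <- max(1L, round(target_ratio * h * w))
  ctr <- kspace_center(h, w)
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((ii - ctr[1])^2 + (jj - ctr[2])^2)
  dens <- (1 - r / max(r))^2 + 0.01
  ctr_idx <- (ctr[2] - 1L) * h + ctr[1]
  idx <- with_seed(seed, sample.int(h * w, n_pick, prob = as.vector(dens)))
  if (!(ctr_idx %in% idx)) idx[1] <- ctr_idx
  m <- matrix(0, h, w)
  m[idx] <- 1
  sampling_mask(m, "poisson", seed)
}

#' Dispatch a mask generator by family name
#' @inheritParams make_radial_mask
#' @param family `"radial"`, `"cartesian"`, `"poisson"`, or `"full"`.
#' @export
make_mask <- function(family, h, w, target_ratio, seed) {
  switch(match.arg(family, c("radial", "cartesian", "poisson", "full")),
         radial    = make_radial_mask(h, w, target_ratio, seed),
         cartesian = make_cartesian_mask(h, w, target_ratio, seed),
         poisson   = make_poisson_mask(h, w, target_ratio, seed),
         full      = make_full_mask(h, w))
}
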