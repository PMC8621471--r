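#' Save and load trained models and task suites
#'
#' Models (phase parameters plus task weights) and generated task suites are
#' stored as single-file R serializations; `export_png()` writes a magnitude
#' image for quick inspection (requires the `png` package).
#'
#' @param pp a [phase_params()].
#' @param omega numeric vector of task-specific scalars.
#' @param path file path.
#' @export
save_model <- function(pp, omega, path) {
  stopifnot(inherits(pp, "phase_params"))
  saveRDS(list(weights = pp$fe$weights, delta = pp$fe$delta,
               alphas = pp$alphas, taus = pp$taus, eps0 = pp_eps0(pp),
               omega = omega),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  fe <- feature_extractor(delta = m$delta, weights = m$weights)
  list(pp = phase_params(fe, m$alphas, m$taus, eps0 = m$eps0),
       omega = m$omega)
}

#' @rdname save_model
#' @param tasks list of [task_bundle()]s.
#' @export
save_suite <- function(tasks, path) {
  saveRDS(tasks, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_suite <- function(path) readRDS(path)

#' @rdname save_model
#' @param img complex or numeric image matrix.
#' @export
export_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for PNG export", call. = FALSE)
  }
  m <- magnitude(img)
  rng <- range(m)
  png::writePNG((m - rng[1]) / max(rng[2] - rng[1], 1e-12), path)
  invisible(path)
}
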