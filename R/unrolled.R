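#' Parameters of the unrolled reconstruction network
#'
#' The network executes exactly `T = length(alphas)` iterations (phases) of
#' the convergent scheme. The feature extractor and the initial smoothing
#' level are shared across phases; the step sizes `alpha_t`, `tau_t` are
#' per-phase learnable scalars. The initial smoothing parameter is stored
#' through a softplus reparameterization so it stays positive during
#' training.
#'
#' @param fe a [feature_extractor()].
#' @param alphas,taus positive per-phase step sizes (equal length `T`).
#' @param eps0 initial smoothing parameter (> 0).
#' @return object of class `phase_params`.
#' @export
phase_params <- function(fe, alphas, taus, eps0 = 0.001) {
  stopifnot(inherits(fe, "feature_extractor"), length(alphas) == length(taus),
            all(alphas > 0), all(taus > 0), eps0 > 0)
  structure(list(fe = fe, alphas = as.numeric(alphas),
                 taus = as.numeric(taus),
                 eps0_raw = softplus_inv(eps0)),
            class = "phase_params")
}

#' @rdname phase_params
#' @param cfg a [loa_config()] supplying `alpha0`, `tau0`, `eps0` defaults.
#' @param n_phases number of phases `T`.
#' @export
init_phase_params <- function(fe, n_phases, cfg = loa_config()) {
  phase_params(fe, rep(cfg$alpha0, n_phases), rep(cfg$tau0, n_phases),
               eps0 = cfg$eps0)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

pp_eps0 <- function(pp) softplus(pp$eps0_raw)

#' Forward pass of the unrolled reconstruction network
#'
#' Identical control flow to [run_loa()] — candidate step, acceptance test,
#' safeguarded line search, smoothing schedule, termination test — but with
#' the per-phase learnable step sizes of `pp` and a fixed phase count.
#' Branch decisions and line-search shrinks are treated as non-differentiable
#' control flow; gradients (see [unrolled_grad()]) flow through the
#' arithmetic of the branch actually taken.
#'
#' @param y a [kspace()] object.
#' @param pp a [phase_params()].
#' @param omega task-specific scalar (kappa = sigmoid(omega)).
#' @param cfg a [loa_config()] supplying the algorithmic constants.
#' @param x0 optional initial image; default `zero_fill(y)`.
#' @param keep_cache retain per-phase intermediates for the backward pass.
#' @return list with final image `x`, per-phase `trace` data frame, and
#'   (optionally) `cache`.
#' @export
unrolled_forward <- function(y, pp, omega = 0, cfg = loa_config(), x0 = NULL,
                             keep_cache = FALSE) {
  stopifnot(inherits(y, "kspace"), inherits(pp, "phase_params"))
  fe <- pp$fe
  kappa <- sigmoid(omega)
  eps0 <- pp_eps0(pp)
  if (is.null(x0)) x0 <- zero_fill(y)
  x <- x0
  n_phases <- length(pp$alphas)
  eps <- eps0; k_shrink <- 0L
  cache <- vector("list", n_phases)
  trace <- vector("list", n_phases)
  val_x <- NULL; grad_r_x <- NULL
  used <- 0L
  for (t in seq_len(n_phases)) {
    alpha <- pp$alphas[t]; tau <- pp$taus[t]
    gf_x <- grad_data_fidelity(x, y)
    if (is.null(grad_r_x)) grad_r_x <- grad_r_eps(x, fe, eps)
    if (is.null(val_x)) val_x <- data_fidelity(x, y) + kappa * r_eps(x, fe, eps)
    grad_phi_x <- gf_x + kappa * grad_r_x
    z <- x - alpha * gf_x
    h <- grad_r_eps(z, fe, eps)
    u <- z - (tau * kappa) * h
    phi_u <- data_fidelity(u, y) + kappa * r_eps(u, fe, eps)
    if (accept_u(x, u, grad_phi_x, val_x, phi_u, cfg$a)) {
      branch <- "u"; x_new <- u; phi_new <- phi_u
      alpha_used <- alpha; shrinks <- 0L
    } else {
      branch <- "v"; alpha_used <- alpha; shrinks <- 0L
      repeat {
        v <- x - alpha_used * grad_phi_x
        phi_v <- data_fidelity(v, y) + kappa * r_eps(v, fe, eps)
        if (is.finite(phi_v) &&
            phi_v - val_x <= -(1 / cfg$a) * cnorm(v - x)^2) break
        alpha_used <- alpha_used * cfg$rho
        shrinks <- shrinks + 1L
        if (shrinks > cfg$max_backtracks || alpha_used < cfg$alpha_floor) {
          if (!is.finite(phi_v) || !is.finite(val_x)) {
            stop("backtrack-limit-exceeded in unrolled phase (non-finite objective)",
                 call. = FALSE)
          }
          # Exploratory parameter values can make the local curvature exceed
          # what the trial budget can match; a zero step (v = x) satisfies
          # the sufficient-descent inequality trivially and keeps the
          # forward pass defined during training.
          alpha_used <- 0
        }
      }
      x_new <- v; phi_new <- phi_v
    }
    grad_r_new <- grad_r_eps(x_new, fe, eps)
    grad_phi_new <- grad_data_fidelity(x_new, y) + kappa * grad_r_new
    gn_new <- cnorm(grad_phi_new)
    if (keep_cache) {
      cache[[t]] <- list(x = x, z = if (branch == "u") z else NULL,
                         h = if (branch == "u") h else NULL,
                         gf_x = gf_x, gr_x = grad_r_x, branch = branch,
                         alpha = alpha, alpha_used = alpha_used,
                         shrinks = shrinks, tau = tau, eps = eps,
                         k_shrink = k_shrink)
    }
    trace[[t]] <- data.frame(phase = t - 1L, value = val_x,
                             grad_norm = cnorm(grad_phi_x), branch = branch,
                             n_trials = shrinks, eps = eps,
                             alpha = alpha_used, tau = tau,
                             value_next = phi_new,
                             step_norm = cnorm(x_new - x))
    x <- x_new
    used <- t
    eps_used <- eps
    if (gn_new < cfg$sigma_alg * cfg$gamma * eps) {
      k_shrink <- k_shrink + 1L
      eps <- cfg$gamma^k_shrink * eps0
      val_x <- NULL; grad_r_x <- NULL
    } else {
      val_x <- phi_new; grad_r_x <- grad_r_new
    }
    if (cfg$sigma_alg * eps_used < cfg$eps_tol) break
  }
  out <- list(x = x, trace = do.call(rbind, trace[seq_len(used)]),
              n_phases_run = used)
  if (keep_cache) out$cache <- cache[seq_len(used)]
  out
}

# Action of K = F^H M F (the normal operator of the masked DFT); Hermitian,
# hence self-adjoint under the real inner product.
normal_op <- function(v, mask) idft2(mask$pattern * dft2(v))

# Central finite-difference step used for all second-order
# (Hessian/mixed-derivative) vector products of the regularizer gradient.
.fd_dir_step <- 1e-6

#' Loss and gradients of the unrolled network for one sample
#'
#' Computes `loss = 0.5 * ||F(y) - x_star||^2` together with its exact
#' gradients with respect to all task-invariant parameters (kernels,
#' per-phase step sizes, initial smoothing level) and the task-specific
#' scalar `omega`, by a hand-coded reverse sweep over the phases actually
#' executed. First-order pieces (conv-stack backward passes) are analytic;
#' the curvature terms `H_r v` and the mixed kernel derivatives are
#' directional central differences of the analytic gradient of `r_eps` —
#' no Hessian is ever formed.
#'
#' @inheritParams unrolled_forward
#' @param x_star ground-truth complex image.
#' @return list with `loss`, `g_weights` (list of kernel gradient arrays),
#'   `g_alphas`, `g_taus`, `g_eps0_raw`, `g_omega`.
#' @export
unrolled_grad <- function(y, pp, omega, x_star, cfg = loa_config(),
                          x0 = NULL) {
  fwd <- unrolled_forward(y, pp, omega, cfg, x0 = x0, keep_cache = TRUE)
  fe <- pp$fe
  kappa <- sigmoid(omega)
  eps0 <- pp_eps0(pp)
  n_phases <- length(pp$alphas)
  lam <- fwd$x - x_star
  loss <- 0.5 * cnorm(lam)^2
  g_alphas <- numeric(n_phases)
  g_taus <- numeric(n_phases)
  g_kappa <- 0
  g_eps0 <- 0
  g_w <- lapply(fe$weights, function(w) array(0 + 0i, dim = dim(w)))
  mask <- y$mask
  for (t in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[t]]
    lam_norm <- cnorm(lam)
    if (lam_norm == 0) break
    dir <- lam / lam_norm
    hstep <- .fd_dir_step
    deps <- 1e-6 * cc$eps
    if (cc$branch == "u") {
      # x+ = z - tau*kappa*h(z), z = x - alpha*grad_f(x)
      g_taus[t] <- g_taus[t] - kappa * rdot(cc$h, lam)
      g_kappa <- g_kappa - cc$tau * rdot(cc$h, lam)
      hp <- grad_r_eps(cc$z, fe, cc$eps + deps)
      hm <- grad_r_eps(cc$z, fe, cc$eps - deps)
      g_eps0 <- g_eps0 - cc$tau * kappa * rdot((hp - hm) / (2 * deps), lam) *
        cfg$gamma^cc$k_shrink
      bp_p <- reg_backprop(cc$z + hstep * dir, fe, cc$eps, want_w = TRUE)
      bp_m <- reg_backprop(cc$z - hstep * dir, fe, cc$eps, want_w = TRUE)
      scale <- -cc$tau * kappa * lam_norm / (2 * hstep)
      for (l in seq_along(g_w)) {
        g_w[[l]] <- g_w[[l]] + scale * (bp_p$grad_w[[l]] - bp_m$grad_w[[l]])
      }
      hr_lam <- (bp_p$grad_x - bp_m$grad_x) / (2 * hstep) * lam_norm
      lam_z <- lam - cc$tau * kappa * hr_lam
      g_alphas[t] <- g_alphas[t] - rdot(cc$gf_x, lam_z)
      lam <- lam_z - cc$alpha * normal_op(lam_z, mask)
    } else {
      # x+ = x - alpha_used * (grad_f(x) + kappa * grad_r(x))
      a_used <- cc$alpha_used
      chain <- cfg$rho^cc$shrinks # alpha_used = rho^s * alpha_t
      gphi <- cc$gf_x + kappa * cc$gr_x
      g_alphas[t] <- g_alphas[t] - chain * rdot(gphi, lam)
      g_kappa <- g_kappa - a_used * rdot(cc$gr_x, lam)
      hp <- grad_r_eps(cc$x, fe, cc$eps + deps)
      hm <- grad_r_eps(cc$x, fe, cc$eps - deps)
      g_eps0 <- g_eps0 - a_used * kappa * rdot((hp - hm) / (2 * deps), lam) *
        cfg$gamma^cc$k_shrink
      bp_p <- reg_backprop(cc$x + hstep * dir, fe, cc$eps, want_w = TRUE)
      bp_m <- reg_backprop(cc$x - hstep * dir, fe, cc$eps, want_w = TRUE)
      scale <- -a_used * kappa * lam_norm / (2 * hstep)
      for (l in seq_along(g_w)) {
        g_w[[l]] <- g_w[[l]] + scale * (bp_p$grad_w[[l]] - bp_m$grad_w[[l]])
      }
      hr_lam <- (bp_p$grad_x - bp_m$grad_x) / (2 * hstep) * lam_norm
      lam <- lam - a_used * (normal_op(lam, mask) + kappa * hr_lam)
    }
  }
  list(loss = loss, g_weights = g_w, g_alphas = g_alphas, g_taus = g_taus,
       g_eps0_raw = g_eps0 * sigmoid(pp$eps0_raw),
       g_omega = g_kappa * kappa * (1 - kappa),
       x_hat = fwd$x, n_phases_run = fwd$n_phases_run)
}
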