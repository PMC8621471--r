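#' Configuration of the convergent learnable optimization algorithm
#'
#' Algorithmic constants of the reconstruction iteration. Defaults follow
#' the values used throughout: acceptance constant `a = 1e5`, smoothing
#' schedule constant `sigma_alg = 1e3`, line-search shrink `rho = 0.9`,
#' smoothing shrink `gamma = 0.9`, initial smoothing `eps0 = 0.001`, initial
#' step sizes `alpha0 = tau0 = 0.01`, termination tolerance
#' `eps_tol = 1e-3`. `sigma_alg` is the schedule constant (distinct from the
#' sigmoid used for task weights).
#'
#' @param a acceptance-test constant (> 0).
#' @param sigma_alg smoothing schedule constant (> 0; the criterion
#'   `||grad|| < sigma_alg * gamma * eps` triggers an eps shrink, and
#'   `sigma_alg * eps < eps_tol` terminates).
#' @param rho line-search shrink factor in (0, 1).
#' @param gamma eps shrink factor in (0, 1).
#' @param eps0 initial smoothing parameter (> 0).
#' @param alpha0,tau0 initial step sizes (> 0).
#' @param eps_tol termination tolerance (>= 0; 0 disables termination by
#'   smoothing level).
#' @param max_phases cap on the number of iterations/phases.
#' @param max_backtracks cap on line-search trials per safeguard step.
#' @param alpha_floor smallest admissible line-search step.
#' @return object of class `loa_config`.
#' @export
loa_config <- function(a = 1e5, sigma_alg = 1e3, rho = 0.9, gamma = 0.9,
                       eps0 = 0.001, alpha0 = 0.01, tau0 = 0.01,
                       eps_tol = 1e-3, max_phases = 50L, max_backtracks = 50L,
                       alpha_floor = 1e-8) {
  stopifnot(a > 0, sigma_alg >= 0, rho > 0, rho < 1, gamma > 0, gamma < 1,
            eps0 > 0, alpha0 > 0, tau0 > 0, eps_tol >= 0, max_phases >= 0)
  structure(list(a = a, sigma_alg = sigma_alg, rho = rho, gamma = gamma,
                 eps0 = eps0, alpha0 = alpha0, tau0 = tau0,
                 eps_tol = eps_tol, max_phases = as.integer(max_phases),
                 max_backtracks = as.integer(max_backtracks),
                 alpha_floor = alpha_floor),
            class = "loa_config")
}

#' Smoothed variational objective and its gradient
#'
#' `phi_eps()` is the data fidelity plus the task-weighted smoothed
#' regularizer, `f(x) + sigma(omega) * r_eps(x)`; `grad_phi_eps()` is the sum
#' of the two exact gradients.
#'
#' @param x complex image matrix.
#' @param y a [kspace()] object.
#' @param fe a [feature_extractor()].
#' @param tw a [task_weight()] (or bare omega).
#' @param eps positive smoothing parameter.
#' @return scalar / complex image.
#' @export
phi_eps <- function(x, y, fe, tw, eps) {
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  data_fidelity(x, y) + tw$kappa * r_eps(x, fe, eps)
}

#' @rdname phi_eps
#' @export
grad_phi_eps <- function(x, y, fe, tw, eps) {
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  grad_data_fidelity(x, y) + tw$kappa * grad_r_eps(x, fe, eps)
}

#' Candidate (u) step: gradient step on f, then on the smoothed regularizer
#'
#' `z = x - alpha * grad f(x)` followed by
#' `u = z - tau * sigma(omega) * grad r_eps(z)` — the fast residual-style
#' update the iteration tries first.
#'
#' @inheritParams phi_eps
#' @param alpha,tau positive step sizes.
#' @return complex image `u`.
#' @export
candidate_u <- function(x, y, fe, tw, eps, alpha, tau) {
  stopifnot(alpha > 0, tau > 0)
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  z <- x - alpha * grad_data_fidelity(x, y)
  z - (tau * tw$kappa) * grad_r_eps(z, fe, eps)
}

#' Acceptance test for the candidate step
#'
#' Pure predicate: `u` is accepted iff `||grad phi_eps(x)|| <= a ||u - x||`
#' and `phi_eps(u) - phi_eps(x) <= -(1/a) ||u - x||^2` (sufficient descent).
#'
#' @param x,u current iterate and candidate.
#' @param grad_phi_at_x gradient of the smoothed objective at `x` (or its
#'   norm as a scalar).
#' @param phi_at_x,phi_at_u objective values at `x` and `u`.
#' @param a acceptance constant.
#' @return logical.
#' @export
accept_u <- function(x, u, grad_phi_at_x, phi_at_x, phi_at_u, a) {
  stopifnot(a > 0)
  gn <- if (length(grad_phi_at_x) == 1L) as.numeric(grad_phi_at_x) else cnorm(grad_phi_at_x)
  d <- cnorm(u - x)
  (gn <= a * d) && (phi_at_u - phi_at_x <= -(1 / a) * d^2)
}

#' Safeguard (v) step with backtracking line search
#'
#' Plain gradient descent on the smoothed objective,
#' `v = x - alpha * grad phi_eps(x)`, with `alpha` shrunk by `rho` until the
#' sufficient-descent condition `phi_eps(v) - phi_eps(x) <= -(1/a)||v - x||^2`
#' holds. Guarantees monotone descent whenever the candidate step fails.
#'
#' @inheritParams phi_eps
#' @param alpha initial step.
#' @param rho shrink factor in (0, 1).
#' @param a acceptance constant.
#' @param max_backtracks trial cap; exceeding it signals
#'   `backtrack-limit-exceeded`.
#' @param grad_x,phi_x optional precomputed gradient/value at `x`.
#' @param alpha_floor smallest admissible step.
#' @return list with `v`, `alpha_final`, `n_trials`.
#' @export
safeguard_v <- function(x, y, fe, tw, eps, alpha, rho, a,
                        max_backtracks = 50L, grad_x = NULL, phi_x = NULL,
                        alpha_floor = 1e-8) {
  stopifnot(alpha > 0, rho > 0, rho < 1)
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  if (is.null(grad_x)) grad_x <- grad_phi_eps(x, y, fe, tw, eps)
  if (is.null(phi_x)) phi_x <- phi_eps(x, y, fe, tw, eps)
  # Stationarity to machine precision: the largest predicted decrease,
  # alpha * ||grad||^2, is below the floating-point resolution of the
  # objective, so no trial step can be certified; the zero step satisfies
  # the sufficient-descent inequality trivially.
  if (alpha * cnorm(grad_x)^2 <= 1e-14 * (1 + abs(phi_x))) {
    return(list(v = x, alpha_final = alpha, n_trials = 0L))
  }
  for (trial in seq_len(max_backtracks)) {
    v <- x - alpha * grad_x
    phi_v <- phi_eps(v, y, fe, tw, eps)
    if (is.finite(phi_v) &&
        phi_v - phi_x <= -(1 / a) * cnorm(v - x)^2) {
      return(list(v = v, alpha_final = alpha, n_trials = trial))
    }
    alpha <- alpha * rho
    if (alpha < alpha_floor) break
  }
  stop("backtrack-limit-exceeded: line search failed (non-finite objective or pathological curvature)",
       call. = FALSE)
}

#' Smoothing-parameter update
#'
#' Returns `gamma * eps` when the gradient norm at the new iterate is below
#' `sigma_alg * gamma * eps` (strict inequality), otherwise `eps` unchanged.
#'
#' @param grad_norm_next `||grad phi_eps(x_{t+1})||`.
#' @param eps current smoothing level.
#' @param cfg a [loa_config()].
#' @return updated eps.
#' @export
eps_update <- function(grad_norm_next, eps, cfg) {
  if (grad_norm_next < cfg$sigma_alg * cfg$gamma * eps) cfg$gamma * eps else eps
}

#' Initialize the iteration state
#'
#' @param x0 initial image (typically the zero-filled reconstruction).
#' @param cfg a [loa_config()].
#' @return object of class `loa_state` with iterate, smoothing level, step
#'   sizes, phase counter and an (initially empty) per-phase trace.
#' @export
loa_state <- function(x0, cfg) {
  structure(list(x = x0, eps = cfg$eps0, alpha = cfg$alpha0, tau = cfg$tau0,
                 phase = 0L, terminated = FALSE, trace = list(),
                 val = NULL, grad = NULL),
            class = "loa_state")
}

# One full iteration of the convergent scheme (candidate step, acceptance
# test, safeguard with line search, smoothing update, termination check).
# Caches the objective value and gradient at the iterate so each quantity is
# computed once per phase.
#' @rdname loa_state
#' @param state a `loa_state`.
#' @param y a [kspace()] object.
#' @param fe a [feature_extractor()].
#' @param tw a [task_weight()] (or bare omega).
#' @export
loa_iterate <- function(state, y, fe, tw, cfg) {
  stopifnot(inherits(state, "loa_state"))
  if (!inherits(tw, "task_weight")) tw <- task_weight(tw)
  x <- state$x; eps <- state$eps
  if (is.null(state$val)) state$val <- phi_eps(x, y, fe, tw, eps)
  if (is.null(state$grad)) state$grad <- grad_phi_eps(x, y, fe, tw, eps)
  phi_x <- state$val; grad_x <- state$grad
  u <- candidate_u(x, y, fe, tw, eps, state$alpha, state$tau)
  phi_u <- phi_eps(u, y, fe, tw, eps)
  n_trials <- 0L
  if (accept_u(x, u, grad_x, phi_x, phi_u, cfg$a)) {
    x_new <- u; phi_new <- phi_u; branch <- "u"; alpha_new <- state$alpha
  } else {
    sg <- safeguard_v(x, y, fe, tw, eps, state$alpha, cfg$rho, cfg$a,
                      cfg$max_backtracks, grad_x = grad_x, phi_x = phi_x,
                      alpha_floor = cfg$alpha_floor)
    x_new <- sg$v
    phi_new <- phi_eps(x_new, y, fe, tw, eps)
    branch <- "v"; alpha_new <- sg$alpha_final; n_trials <- sg$n_trials
  }
  grad_new <- grad_phi_eps(x_new, y, fe, tw, eps)
  gn_new <- cnorm(grad_new)
  eps_next <- eps_update(gn_new, eps, cfg)
  state$trace[[length(state$trace) + 1L]] <- data.frame(
    phase = state$phase, value = phi_x, grad_norm = cnorm(grad_x),
    branch = branch, n_trials = n_trials, eps = eps, alpha = alpha_new,
    tau = state$tau, value_next = phi_new, step_norm = cnorm(x_new - x))
  state$x <- x_new
  state$alpha <- alpha_new
  state$phase <- state$phase + 1L
  if (eps_next != eps) {
    # Smoothing changed: cached value/gradient refer to the old objective.
    state$val <- NULL; state$grad <- NULL
  } else {
    state$val <- phi_new; state$grad <- grad_new
  }
  state$eps <- eps_next
  if (cfg$sigma_alg * eps < cfg$eps_tol) state$terminated <- TRUE
  state
}

#' Run the convergent reconstruction iteration
#'
#' Iterates [loa_iterate()] from the zero-filled initializer (or a given
#' `x0`) until the smoothing-level termination test fires or `max_phases` is
#' reached.
#'
#' @inheritParams phi_eps
#' @param cfg a [loa_config()].
#' @param x0 optional initial image; default `zero_fill(y)`.
#' @return list with the final image `x`, the per-phase `trace` data frame,
#'   and the final `state`.
#' @export
run_loa <- function(y, fe, tw, cfg = loa_config(), x0 = NULL) {
  stopifnot(inherits(y, "kspace"))
  if (is.null(x0)) x0 <- zero_fill(y)
  state <- loa_state(x0, cfg)
  while (state$phase < cfg$max_phases && !state$terminated) {
    state <- loa_iterate(state, y, fe, tw, cfg)
  }
  list(x = state$x, trace = do.call(rbind, state$trace), state = state)
}

# Harmonic combination of the two step sizes in the surrogate-proximal
# derivation: tau = alpha * beta / (alpha + beta). In the learnable network
# tau is a free positive parameter; this helper documents the relation.
harmonic_step <- function(alpha, beta) alpha * beta / (alpha + beta)
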