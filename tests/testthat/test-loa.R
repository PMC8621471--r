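# Reference fixed-step gradient descent on the smoothed objective at a
# frozen smoothing level; used as the convex-case oracle.
reference_gd <- function(y, fe, tw, eps, step, iters, x0) {
  x <- x0
  for (i in seq_len(iters)) {
    x <- x - step * grad_phi_eps(x, y, fe, tw, eps)
  }
  x
}

test_that("smoothed objective and gradient reduce correctly and differentiate", {
  p <- small_problem(8, 8, ratio = 0.6, seed = 12)
  fe <- tiny_extractor()
  eps <- 1e-2
  x <- rand_image(8, 8, 13, scale = 0.5)

  # kappa -> 0 reduces to the data fidelity
  expect_equal(phi_eps(x, p$y, fe, task_weight(-40), eps),
               data_fidelity(x, p$y), tolerance = 1e-12)
  fe0 <- feature_extractor(weights = list(array(0 + 0i, c(3, 3, 1, 2))))
  expect_equal(phi_eps(x, p$y, fe0, task_weight(2), eps),
               data_fidelity(x, p$y))

  g <- grad_phi_eps(x, p$y, fe, task_weight(0.5), eps)
  fd <- fd_grad_image(function(z) phi_eps(z, p$y, fe, task_weight(0.5), eps), x)
  expect_lt(max(Mod(g - fd)) / max(Mod(fd)), 1e-4)
})

test_that("candidate step: fixed points and pure-fidelity reduction", {
  p <- small_problem(8, 8, ratio = 0.6, seed = 14)
  fe <- tiny_extractor()
  # kappa ~ 0 and data-consistent x: u = x
  u <- candidate_u(p$x_star, p$y, fe, task_weight(-40), 1e-2, 0.01, 0.01)
  expect_lt(max(Mod(u - p$x_star)), 1e-10)

  # zero extractor weights: u equals the plain gradient step on f
  fe0 <- feature_extractor(weights = list(array(0 + 0i, c(3, 3, 1, 2))))
  x <- rand_image(8, 8, 15)
  u <- candidate_u(x, p$y, fe0, task_weight(1), 1e-2, 0.3, 0.01)
  expect_equal(u, x - 0.3 * grad_data_fidelity(x, p$y))

  # full mask, kappa = 0, alpha = 1: exact minimizer in one step
  full <- make_full_mask(8, 8)
  y <- forward_op(p$x_star, full)
  u <- candidate_u(x, y, fe, task_weight(-40), 1e-2, 1, 0.01)
  expect_lt(max(Mod(u - p$x_star)), 1e-9)
})

test_that("acceptance predicate agrees with direct inequality evaluation", {
  x <- rand_image(4, 4, 1)
  expect_false(accept_u(x, x, grad_phi_at_x = 1.0, phi_at_x = 5, phi_at_u = 5,
                        a = 1e5))
  expect_true(accept_u(x, x, grad_phi_at_x = 0.0, phi_at_x = 5, phi_at_u = 5,
                       a = 1e5))
  metaloa:::with_seed(99, {
    for (k in 1:20) {
      u <- x + rand_image(4, 4, k) * 0.1
      gn <- stats::runif(1, 0, 2)
      px <- stats::runif(1, 0, 10)
      pu <- px + stats::runif(1, -1, 1)
      a <- stats::runif(1, 0.5, 10)
      d <- cnorm(u - x)
      manual <- (gn <= a * d) && (pu - px <= -(1 / a) * d^2)
      expect_identical(accept_u(x, u, gn, px, pu, a), manual)
    }
  })
})

test_that("safeguard line search descends and terminates as the descent lemma predicts", {
  p <- small_problem(8, 8, ratio = 1, seed = 16)
  fe0 <- feature_extractor(weights = list(array(0 + 0i, c(3, 3, 1, 2))))
  full <- make_full_mask(8, 8)
  y <- forward_op(p$x_star, full)
  x <- rand_image(8, 8, 17)

  # quadratic with 1-Lipschitz gradient: first trial accepted at alpha = 0.01
  sg <- safeguard_v(x, y, fe0, task_weight(0), 1e-2, alpha = 0.01, rho = 0.9,
                    a = 1e5)
  expect_equal(sg$n_trials, 1L)
  expect_equal(sg$alpha_final, 0.01)

  # stationary point: the zero step is returned without any trial
  sg0 <- safeguard_v(p$x_star, y, fe0, task_weight(0), 1e-2, alpha = 0.01,
                     rho = 0.9, a = 1e5)
  expect_equal(sg0$v, p$x_star)
  expect_equal(sg0$n_trials, 0L)

  fe <- tiny_extractor()
  for (seed in 1:10) {
    prob <- small_problem(8, 8, ratio = 0.5, seed = seed + 30)
    x <- rand_image(8, 8, seed + 60, scale = 0.5)
    eps <- 1e-2
    sg <- safeguard_v(x, prob$y, fe, task_weight(0.5), eps, alpha = 0.05,
                      rho = 0.9, a = 1e5)
    expect_lte(phi_eps(sg$v, prob$y, fe, task_weight(0.5), eps),
               phi_eps(x, prob$y, fe, task_weight(0.5), eps))
  }
})

test_that("smoothing level shrinks by gamma exactly when the gradient is small", {
  cfg <- loa_config()
  expect_equal(eps_update(0, 1e-3, cfg), cfg$gamma * 1e-3)
  # boundary: strict inequality, no shrink at equality
  thr <- cfg$sigma_alg * cfg$gamma * 1e-3
  expect_equal(eps_update(thr, 1e-3, cfg), 1e-3)
  expect_equal(eps_update(thr * 0.999, 1e-3, cfg), cfg$gamma * 1e-3)
})

test_that("tau equals the harmonic combination when alpha = beta", {
  expect_equal(metaloa:::harmonic_step(0.3, 0.3), 0.15)
  expect_equal(metaloa:::harmonic_step(0.2, 0.6), 0.2 * 0.6 / 0.8)
})

test_that("iteration descends, prefers the candidate branch, and tracks eps as gamma powers", {
  fe <- tiny_extractor()
  n_u <- 0; n_tot <- 0
  for (seed in 1:5) {
    p <- small_problem(16, 16, ratio = 0.4, seed = seed + 70)
    cfg <- loa_config(max_phases = 15, eps_tol = 0)
    out <- run_loa(p$y, fe, task_weight(0.5), cfg)
    tr <- out$trace
    # descent within constant-eps stretches
    same_eps <- diff(tr$eps) == 0
    expect_true(all(tr$value_next[same_eps] <= tr$value[same_eps] + 1e-10))
    expect_true(all(tr$value_next <= tr$value + 1e-10))
    # eps non-increasing and an exact gamma power
    expect_true(all(diff(tr$eps) <= 0))
    k <- log(tr$eps / cfg$eps0) / log(cfg$gamma)
    expect_lt(max(abs(k - round(k))), 1e-8)
    expect_true(all(diff(round(k)) >= 0))
    n_u <- n_u + sum(tr$branch == "u"); n_tot <- n_tot + nrow(tr)
  }
  expect_gt(n_u / n_tot, 0.5)
})

test_that("stationary start keeps the iterate and shrinks eps", {
  fe0 <- feature_extractor(weights = list(array(0 + 0i, c(3, 3, 1, 2))))
  full <- make_full_mask(8, 8)
  x_star <- rand_image(8, 8, 80)
  y <- forward_op(x_star, full)
  st <- loa_state(x_star, loa_config(eps_tol = 0))
  st2 <- loa_iterate(st, y, fe0, task_weight(0), loa_config(eps_tol = 0))
  expect_equal(st2$x, x_star)
  expect_equal(st2$trace[[1]]$branch, "u")
  expect_equal(st2$eps, 0.9 * 0.001)
})

test_that("least-squares case converges to the zero-filled solution", {
  full <- make_full_mask(8, 8)
  x_star <- rand_image(8, 8, 81)
  y <- forward_op(x_star, full)
  fe <- tiny_extractor()
  cfg <- loa_config(alpha0 = 0.9, max_phases = 200, eps_tol = 0)
  out <- run_loa(y, fe, task_weight(-40), cfg, x0 = rand_image(8, 8, 82))
  expect_lt(data_fidelity(out$x, y), 1e-10)
  expect_lt(max(Mod(out$x - x_star)), 1e-4)
})

test_that("run_loa matches a long-run reference on the smooth convex instance", {
  # 1x1 identity extractor: r_eps is smooth and convex, phi_eps has a unique
  # minimizer; compare against plain gradient descent with a small step at
  # the same frozen smoothing level.
  fe_id <- metaloa:::identity_extractor()
  p <- small_problem(16, 16, ratio = 0.5, seed = 90, noise_std = 0.02)
  eps <- 0.1
  tw <- task_weight(0)
  cfg <- loa_config(alpha0 = 0.5, tau0 = 0.2, eps0 = eps, sigma_alg = 1e-9,
                    eps_tol = 0, max_phases = 300)
  out <- run_loa(p$y, fe_id, tw, cfg)
  expect_true(all(out$trace$eps == eps))
  x_ref <- reference_gd(p$y, fe_id, tw, eps, step = 0.05, iters = 20000,
                        x0 = zero_fill(p$y))
  f_loa <- phi_eps(out$x, p$y, fe_id, tw, eps)
  f_ref <- phi_eps(x_ref, p$y, fe_id, tw, eps)
  expect_lt(abs(f_loa - f_ref) / abs(f_ref), 1e-6)
})
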