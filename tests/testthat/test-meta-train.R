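# Toy bilevel problem with closed-form penalty gradients:
# L_tr = 0.5 (theta - omega)^2, L_val = 0.5 theta^2.
toy_problem <- function(theta0 = 1.5, omega0 = -1) {
  list(
    theta0 = theta0, omega0 = omega0,
    loss = function(theta, omega, batch) {
      if (identical(batch, "tr")) 0.5 * (theta - omega)^2 else 0.5 * theta^2
    },
    grad = function(theta, omega, batch) {
      if (identical(batch, "tr")) {
        list(value = 0.5 * (theta - omega)^2, g_theta = theta - omega,
             g_omega = -(theta - omega))
      } else {
        list(value = 0.5 * theta^2, g_theta = theta, g_omega = 0)
      }
    },
    sample_batches = function(seed) list(train = "tr", val = "val")
  )
}

test_that("reconstruction loss matches its closed forms and a brute-force sum", {
  x <- rand_image(3, 3, 1)
  expect_equal(recon_loss(x, x), 0)
  x_star <- matrix(complex(real = c(1, rep(0, 8)),
                           imaginary = c(0, 1, rep(0, 7))), 3, 3)
  expect_equal(recon_loss(matrix(0 + 0i, 3, 3), x_star), 1)
  y <- rand_image(3, 3, 2)
  brute <- 0
  for (i in 1:3) for (j in 1:3) {
    brute <- brute + 0.5 * ((Re(x[i, j]) - Re(y[i, j]))^2 +
                            (Im(x[i, j]) - Im(y[i, j]))^2)
  }
  expect_equal(recon_loss(x, y), brute)
  expect_error(recon_loss(x, rand_image(4, 4, 3)), "shape")
})

test_that("task loss is additive over batches and ~0 for exact-recovery settings", {
  full <- make_full_mask(8, 8)
  pairs <- lapply(1:3, function(i) {
    x <- make_phantom(8, 8, n_ellipses = 2, seed = i)
    list(y = forward_op(x, full), x_star = x)
  })
  fe <- tiny_extractor()
  cfg <- loa_config(alpha0 = 1, eps_tol = 0)
  pp <- init_phase_params(fe, 1, cfg)
  # kappa ~ 0 on fully sampled noise-free pairs: exact recovery in one phase
  expect_lt(task_loss(pp, -40, pairs, cfg), 1e-18)

  p2 <- small_problem(8, 8, ratio = 0.5, seed = 31)
  pairs2 <- list(list(y = p2$y, x_star = p2$x_star))
  l_all <- task_loss(pp, 0.2, c(pairs, pairs2), cfg)
  expect_equal(l_all, task_loss(pp, 0.2, pairs, cfg) +
                 task_loss(pp, 0.2, pairs2, cfg), tolerance = 1e-12)
  expect_error(task_loss(pp, 0, list(), cfg), "empty")
})

test_that("task-loss omega gradient matches finite differences on a 16x16 pair", {
  p <- small_problem(16, 16, ratio = 0.4, seed = 32, noise_std = 0.01)
  fe <- tiny_extractor(seed = 4)
  cfg <- loa_config(eps_tol = 0)
  pp <- init_phase_params(fe, 2, cfg)
  pairs <- list(list(y = p$y, x_star = p$x_star))
  gr <- task_loss_grad(pp, 0.4, pairs, cfg)
  h <- 1e-6
  fd <- (task_loss(pp, 0.4 + h, pairs, cfg) -
           task_loss(pp, 0.4 - h, pairs, cfg)) / (2 * h)
  expect_lt(abs(fd - gr$g_omega) / max(abs(fd), 1e-8), 1e-3)
})

test_that("penalty objective and gradients match closed forms on the toy quadratic", {
  pb <- toy_problem()
  th <- 1.2; om <- 0.5
  for (lam in c(0, 0.3, 2)) {
    expect_equal(penalty_objective(pb, th, om, "tr", "val", lam),
                 0.5 * th^2 + lam / 2 * (th - om)^2)
    g <- grads_penalty(pb, th, om, "tr", "val", lam)
    expect_equal(g$g_theta, th + lam * (th - om), tolerance = 1e-7)
    expect_equal(g$g_omega, -lam * (th - om), tolerance = 1e-7)
  }
  # at a theta-stationary point of the training loss the penalty vanishes
  expect_equal(penalty_objective(pb, 0.7, 0.7, "tr", "val", 5),
               0.5 * 0.7^2)
})

test_that("penalty gradients match finite differences on a one-task instance", {
  p <- small_problem(8, 8, ratio = 0.6, seed = 33, noise_std = 0.01)
  fe <- tiny_extractor(seed = 6)
  cfg <- loa_config(eps_tol = 0)
  pp <- init_phase_params(fe, 2, cfg)
  mask <- p$mask
  task <- task_bundle("t1", mask,
                      train_pairs = list(list(y = p$y, x_star = p$x_star)),
                      val_pairs = list(list(y = add_noise(p$y, 0.02, 9),
                                            x_star = p$x_star)),
                      test_pairs = list())
  problem <- make_meta_problem(list(task), pp, cfg, 1, 1)
  theta <- problem$theta0
  omega <- 0.2
  btr <- list(list(task = 1L, y = task$train_pairs[[1]]$y, x_star = p$x_star))
  bval <- list(list(task = 1L, y = task$val_pairs[[1]]$y, x_star = p$x_star))
  lam <- 0.05
  g <- grads_penalty(problem, theta, omega, btr, bval, lam)
  h <- 1e-5
  obj <- function(th, om) penalty_objective(problem, th, om, btr, bval, lam)
  idx <- unique(c(metaloa:::with_seed(2, sample(length(theta) - 5L, 10)),
                  length(theta) - 0:4))
  for (k in idx) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    fd <- (obj(tp, omega) - obj(tm, omega)) / (2 * h)
    expect_lt(abs(fd - g$g_theta[k]) / max(abs(fd), 1e-3), 1e-3)
  }
  fd_om <- (obj(theta, omega + h) - obj(theta, omega - h)) / (2 * h)
  expect_lt(abs(fd_om - g$g_omega) / max(abs(fd_om), 1e-4), 1e-3)
})

test_that("cross-task batches have the documented size, disjointness, determinism", {
  tasks <- build_task_suite(ratios = c(0.1, 0.2, 0.3, 0.4), n_train = 5,
                            n_val = 4, n_test = 2, height = 16, width = 16,
                            seed = 3)
  b <- sample_cross_task_batch(tasks, 2, 2, seed = 11)
  expect_length(b$train, 8)  # N = 4 tasks x J_tr = 2
  expect_length(b$val, 8)
  b2 <- sample_cross_task_batch(tasks, 2, 2, seed = 11)
  expect_identical(b, b2)
  # train and val draws come from disjoint pools by construction
  for (tr in b$train) for (vl in b$val) {
    if (tr$task == vl$task) {
      expect_false(identical(tr$y$values, vl$y$values) &&
                     identical(tr$x_star, vl$x_star))
    }
  }
  expect_error(sample_cross_task_batch(tasks, 6, 2, seed = 1), "insufficient")
})

test_that("bilevel training solves the toy quadratic with exact geometric schedules", {
  pb <- toy_problem()
  cfg <- bilevel_config(delta0 = 1e-3, delta_tol = 1e-7, nu_delta = 0.9,
                        lambda0 = 0.1, nu_lambda = 1.05, K = 5,
                        lr_theta = 0.1, lr_omega = 0.1, max_inner = 500,
                        optimizer = "sgd")
  fit <- bilevel_train(pb, cfg, seed = 1)
  expect_lt(abs(fit$theta), 1e-3)
  expect_lt(abs(fit$omega), 1e-3)
  n <- nrow(fit$history)
  expect_equal(fit$history$delta, 1e-3 * 0.9^(0:(n - 1)))
  expect_equal(fit$history$lambda, 0.1 * 1.05^(0:(n - 1)))
  # ran until delta crossed the tolerance
  expect_lt(0.9 * fit$history$delta[n], 1e-7)
})

test_that("stair training grows one phase per stage and respects the cap", {
  tasks <- build_task_suite(ratios = c(0.3), families = "poisson",
                            n_train = 3, n_val = 2, n_test = 1,
                            height = 8, width = 8, seed = 5)
  blc <- bilevel_config(K = 1, max_inner = 1, j_tr = 1, j_val = 1)
  cfg <- loa_config(eps_tol = 0)
  fit1 <- stair_train(tasks, tiny_extractor(), stair_schedule(2, 1, 1),
                      blc, cfg, seed = 1)
  expect_length(fit1$pp$alphas, 1)
  expect_equal(nrow(fit1$stage_history), 1)

  fit3 <- stair_train(tasks, tiny_extractor(), stair_schedule(2, 1, 3),
                      blc, cfg, seed = 1)
  expect_equal(fit3$stage_history$n_phases,
               seq_len(nrow(fit3$stage_history)))
  expect_lte(length(fit3$pp$alphas), 3)
})

test_that("omega adaptation leaves the shared parameters bit-identical and finds the grid optimum", {
  # fixed toy task whose omega-objective has an interior minimum: an
  # edge-detecting extractor strong enough that the optimal weight is
  # neither 0 nor 1
  tasks <- build_task_suite(ratios = c(0.3), families = "radial",
                            n_train = 3, n_val = 1, n_test = 1,
                            height = 16, width = 16, noise_std = 0.05,
                            seed = 8)
  task <- tasks[[1]]
  kd <- array(0 + 0i, c(3, 3, 1, 2))
  kd[2, 2, 1, 1] <- 0.1; kd[2, 3, 1, 1] <- -0.1
  kd[2, 2, 1, 2] <- 0.1; kd[3, 2, 1, 2] <- -0.1
  fe <- feature_extractor(delta = 0.001, weights = list(kd))
  cfg <- loa_config(eps_tol = 0)
  pp <- phase_params(fe, alphas = rep(1, 3), taus = rep(1, 3), eps0 = 0.001)
  theta_before <- metaloa:::pack_phase_params(pp)
  fit <- adapt_unseen_task(pp, task, epochs = 80, seed = 1, cfg = cfg,
                           lr = 0.2)
  expect_identical(metaloa:::pack_phase_params(pp), theta_before)

  # dense grid-search oracle over omega
  grid <- seq(-6, 6, by = 0.05)
  losses <- vapply(grid, function(om) task_loss(pp, om, task$train_pairs, cfg),
                   numeric(1))
  om_star <- grid[which.min(losses)]
  expect_lt(abs(fit$tw$omega - om_star), 0.05)
})
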