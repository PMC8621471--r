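#' One reconstruction task: mask plus paired data splits
#'
#' A task is defined by its sampling mask (family and ratio) and disjoint
#' train/validation/test lists of `(y, x_star)` pairs, all sharing that mask,
#' together with its task-specific weight scalar `omega`.
#'
#' @param task_id identifier (string or integer).
#' @param mask a [sampling_mask()].
#' @param train_pairs,val_pairs,test_pairs lists of `list(y = kspace,
#'   x_star = complex matrix)`.
#' @param omega initial task-specific scalar (default 0, i.e. kappa = 0.5).
#' @return object of class `task_bundle`.
#' @export
task_bundle <- function(task_id, mask, train_pairs, val_pairs, test_pairs,
                        omega = 0) {
  stopifnot(inherits(mask, "sampling_mask"))
  structure(list(task_id = task_id, mask = mask, train_pairs = train_pairs,
                 val_pairs = val_pairs, test_pairs = test_pairs,
                 omega = omega),
            class = "task_bundle")
}

#' Reconstruction loss
#'
#' `0.5 * ||x_hat - x_star||^2` summed over all real and imaginary
#' components.
#'
#' @param x_hat,x_star complex image matrices of equal size.
#' @return nonnegative scalar, zero iff the images are equal.
#' @export
recon_loss <- function(x_hat, x_star) {
  if (!all(dim(x_hat) == dim(x_star))) stop("shape mismatch", call. = FALSE)
  0.5 * cnorm(x_hat - x_star)^2
}

# ---- flat parameter vector <-> phase_params -------------------------------

# Layout: [Re(w1), Im(w1), ..., Re(wl), Im(wl), alphas, taus, eps0_raw].
pack_phase_params <- function(pp) {
  wparts <- unlist(lapply(pp$fe$weights, function(w) c(Re(w), Im(w))))
  c(wparts, pp$alphas, pp$taus, pp$eps0_raw)
}

unpack_phase_params <- function(theta, template) {
  fe <- template$fe
  pos <- 0L
  weights <- lapply(fe$weights, function(w) {
    n <- length(w)
    re <- theta[pos + seq_len(n)]
    im <- theta[pos + n + seq_len(n)]
    pos <<- pos + 2L * n
    array(complex(real = re, imaginary = im), dim = dim(w))
  })
  tt <- length(template$alphas)
  alphas <- theta[pos + seq_len(tt)]; pos <- pos + tt
  taus <- theta[pos + seq_len(tt)]; pos <- pos + tt
  fe2 <- feature_extractor(delta = fe$delta, weights = weights)
  structure(list(fe = fe2, alphas = alphas, taus = taus,
                 eps0_raw = theta[pos + 1L]),
            class = "phase_params")
}

pack_theta_grad <- function(gr) {
  wparts <- unlist(lapply(gr$g_weights, function(g) c(Re(g), Im(g))))
  c(wparts, gr$g_alphas, gr$g_taus, gr$g_eps0_raw)
}

# Keep step sizes strictly positive (and bounded, so the line search stays
# within its trial budget) after an optimizer update.
project_phase_theta <- function(theta, template) {
  nw <- sum(vapply(template$fe$weights, function(w) 2L * length(w), integer(1)))
  tt <- length(template$alphas)
  idx <- nw + seq_len(2L * tt)
  theta[idx] <- pmin(pmax(theta[idx], 1e-8), 2)
  theta
}

#' Task loss of the unrolled network
#'
#' Sum of [recon_loss()] between network reconstruction and ground truth
#' over a batch of pairs. `task_loss_grad()` additionally returns the exact
#' gradients with respect to the flattened task-invariant parameters and
#' `omega` (reverse sweep of [unrolled_grad()], summed over the batch).
#'
#' @param pp a [phase_params()].
#' @param omega task-specific scalar.
#' @param pairs list of `list(y, x_star)`.
#' @param cfg a [loa_config()].
#' @return `task_loss()`: scalar. `task_loss_grad()`: list `value`,
#'   `g_theta`, `g_omega`.
#' @export
task_loss <- function(pp, omega, pairs, cfg = loa_config()) {
  if (length(pairs) == 0) stop("empty batch", call. = FALSE)
  sum(vapply(pairs, function(p) {
    recon_loss(unrolled_forward(p$y, pp, omega, cfg)$x, p$x_star)
  }, numeric(1)))
}

#' @rdname task_loss
#' @export
task_loss_grad <- function(pp, omega, pairs, cfg = loa_config()) {
  if (length(pairs) == 0) stop("empty batch", call. = FALSE)
  total <- NULL
  value <- 0
  g_omega <- 0
  for (p in pairs) {
    gr <- unrolled_grad(p$y, pp, omega, p$x_star, cfg)
    value <- value + gr$loss
    g_omega <- g_omega + gr$g_omega
    gt <- pack_theta_grad(gr)
    total <- if (is.null(total)) gt else total + gt
  }
  list(value = value, g_theta = total, g_omega = g_omega)
}

#' Draw a cross-task mini-batch
#'
#' Per task, draws `j_tr` training and `j_val` validation pairs without
#' replacement; the batches are the unions over all tasks (sizes
#' `N * j_tr` and `N * j_val`). Deterministic from `seed`.
#'
#' @param tasks list of [task_bundle()]s.
#' @param j_tr,j_val pairs per task and split.
#' @param seed integer seed.
#' @return list `train`, `val`: each a list of `list(task, y, x_star)`.
#' @export
sample_cross_task_batch <- function(tasks, j_tr, j_val, seed) {
  with_seed(seed, {
    tr <- list(); vl <- list()
    for (i in seq_along(tasks)) {
      tk <- tasks[[i]]
      if (length(tk$train_pairs) < j_tr || length(tk$val_pairs) < j_val) {
        stop("insufficient data in task ", tk$task_id, call. = FALSE)
      }
      for (j in sample(length(tk$train_pairs), j_tr)) {
        tr[[length(tr) + 1L]] <- c(list(task = i), tk$train_pairs[[j]])
      }
      for (j in sample(length(tk$val_pairs), j_val)) {
        vl[[length(vl) + 1L]] <- c(list(task = i), tk$val_pairs[[j]])
      }
    }
    list(train = tr, val = vl)
  })
}

#' Bilevel training configuration
#'
#' Constants of the penalty-based alternating scheme: the inner loop runs
#' until the squared gradient norm of the penalized objective falls below
#' `delta`, then `delta` shrinks geometrically by `nu_delta` and the penalty
#' weight `lambda` grows by `nu_lambda`, until `delta <= delta_tol`.
#'
#' @param delta0 initial inner tolerance.
#' @param delta_tol outer stopping tolerance.
#' @param nu_delta delta shrink factor in (0, 1).
#' @param lambda0 initial penalty weight.
#' @param nu_lambda lambda growth factor (> 1).
#' @param K inner updates of the task-invariant parameters per update of the
#'   task-specific ones.
#' @param lr_theta,lr_omega Adam step sizes.
#' @param j_tr,j_val per-task mini-batch sizes.
#' @param max_outer cap on outer iterations (an "epoch" is one outer
#'   iteration).
#' @param max_inner cap on inner while-iterations per outer iteration.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param fd_step finite-difference step for the penalty curvature terms.
#' @return object of class `bilevel_config`.
#' @export
bilevel_config <- function(delta0 = 1e-3, delta_tol = 4.35e-6,
                           nu_delta = 0.95, lambda0 = 1e-5,
                           nu_lambda = 1.001, K = 5L, lr_theta = 1e-3,
                           lr_omega = 1e-3, j_tr = 2L, j_val = 2L,
                           max_outer = Inf, max_inner = 200L,
                           optimizer = c("adam", "sgd"), fd_step = 1e-5) {
  stopifnot(nu_delta > 0, nu_delta < 1, nu_lambda > 1, K >= 1)
  structure(list(delta0 = delta0, delta_tol = delta_tol, nu_delta = nu_delta,
                 lambda0 = lambda0, nu_lambda = nu_lambda, K = as.integer(K),
                 lr_theta = lr_theta, lr_omega = lr_omega,
                 j_tr = as.integer(j_tr), j_val = as.integer(j_val),
                 max_outer = max_outer, max_inner = as.integer(max_inner),
                 optimizer = match.arg(optimizer), fd_step = fd_step),
            class = "bilevel_config")
}

#' Penalized single-level objective of the bilevel problem
#'
#' `L(theta, omega; val) + (lambda/2) * ||grad_theta L(theta, omega; tr)||^2`:
#' the validation loss plus a penalty on the first-order optimality residual
#' of the training (lower-level) problem.
#'
#' `grads_penalty()` returns the exact gradients of this objective. The
#' penalty contributes a Hessian-vector product (for theta) and a mixed
#' omega-theta derivative-vector product (for omega), both computed as
#' central finite differences of the first-order gradient along the
#' direction `grad_theta L_tr` — the Hessian is never materialized.
#'
#' @param problem a problem object: list with `loss(theta, omega, batch)` and
#'   `grad(theta, omega, batch)` (the latter returning `value`, `g_theta`,
#'   `g_omega`). See [make_meta_problem()].
#' @param theta flat parameter vector.
#' @param omega vector of task-specific scalars.
#' @param train_batch,val_batch batches understood by the problem functions.
#' @param lam penalty weight (>= 0).
#' @param fd_step finite-difference step.
#' @return `penalty_objective()`: scalar. `grads_penalty()`: list `value`,
#'   `g_theta`, `g_omega`, `train_grad_norm`.
#' @export
penalty_objective <- function(problem, theta, omega, train_batch, val_batch,
                              lam) {
  stopifnot(lam >= 0)
  gtr <- problem$grad(theta, omega, train_batch)
  problem$loss(theta, omega, val_batch) + lam / 2 * sum(gtr$g_theta^2)
}

#' @rdname penalty_objective
#' @export
grads_penalty <- function(problem, theta, omega, train_batch, val_batch, lam,
                          fd_step = 1e-5) {
  stopifnot(lam >= 0)
  gval <- problem$grad(theta, omega, val_batch)
  gtr <- problem$grad(theta, omega, train_batch)
  gn <- sqrt(sum(gtr$g_theta^2))
  g_theta <- gval$g_theta
  g_omega <- gval$g_omega
  if (lam > 0 && gn > 0) {
    dir <- gtr$g_theta / gn
    gp <- problem$grad(theta + fd_step * dir, omega, train_batch)
    gm <- problem$grad(theta - fd_step * dir, omega, train_batch)
    g_theta <- g_theta + lam * (gp$g_theta - gm$g_theta) / (2 * fd_step) * gn
    g_omega <- g_omega + lam * (gp$g_omega - gm$g_omega) / (2 * fd_step) * gn
  }
  list(value = gval$value + lam / 2 * gn^2, g_theta = g_theta,
       g_omega = g_omega, train_grad_norm = gn)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(st, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  st$step <- lr * mhat / (sqrt(vhat) + eps)
  st
}

#' Penalty-based alternating bilevel training
#'
#' Outer loop: sample cross-task mini-batches, then run the inner loop while
#' the squared gradient norm of the penalized objective exceeds `delta` —
#' `K` optimizer updates of the task-invariant `theta` followed by one of
#' the task-specific `omega` — and finally shrink `delta` and grow `lambda`
#' geometrically. Stops when `delta <= delta_tol` (or `max_outer`).
#'
#' @param problem problem object (see [make_meta_problem()]); must provide
#'   `theta0`, `omega0`, `loss`, `grad`, `sample_batches(seed)`, and
#'   optionally `project(theta)`.
#' @param cfg a [bilevel_config()].
#' @param seed integer seed controlling batch sampling.
#' @return list `theta`, `omega`, `history` (one row per outer iteration).
#' @export
bilevel_train <- function(problem, cfg = bilevel_config(), seed = 1) {
  theta <- problem$theta0
  omega <- problem$omega0
  project <- problem$project %||% identity
  ad_t <- adam_init(length(theta))
  ad_o <- adam_init(length(omega))
  delta <- cfg$delta0
  lam <- cfg$lambda0
  history <- list()
  outer <- 0L
  while (delta > cfg$delta_tol && outer < cfg$max_outer) {
    outer <- outer + 1L
    batches <- problem$sample_batches(seed + outer)
    inner <- 0L
    repeat {
      g <- grads_penalty(problem, theta, omega, batches$train, batches$val,
                         lam, cfg$fd_step)
      if (!is.finite(g$value)) {
        stop("non-finite loss during bilevel training (outer ", outer, ")",
             call. = FALSE)
      }
      gsq <- sum(g$g_theta^2) + sum(g$g_omega^2)
      if (gsq <= delta || inner >= cfg$max_inner) break
      inner <- inner + 1L
      for (k in seq_len(cfg$K)) {
        if (cfg$optimizer == "adam") {
          ad_t <- adam_step(ad_t, g$g_theta, cfg$lr_theta)
          theta <- project(theta - ad_t$step)
        } else {
          theta <- project(theta - cfg$lr_theta * g$g_theta)
        }
        if (k < cfg$K) {
          g <- grads_penalty(problem, theta, omega, batches$train,
                             batches$val, lam, cfg$fd_step)
        }
      }
      g <- grads_penalty(problem, theta, omega, batches$train, batches$val,
                         lam, cfg$fd_step)
      if (cfg$optimizer == "adam") {
        ad_o <- adam_step(ad_o, g$g_omega, cfg$lr_omega)
        omega <- omega - ad_o$step
      } else {
        omega <- omega - cfg$lr_omega * g$g_omega
      }
    }
    val_loss <- problem$loss(theta, omega, batches$val)
    tr_loss <- problem$loss(theta, omega, batches$train)
    history[[outer]] <- data.frame(outer = outer, delta = delta, lambda = lam,
                                   loss_val = val_loss, loss_tr = tr_loss,
                                   grad_sq = gsq, inner_iters = inner)
    delta <- cfg$nu_delta * delta
    lam <- cfg$nu_lambda * lam
  }
  list(theta = theta, omega = omega, history = do.call(rbind, history))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the meta-learning problem for a set of reconstruction tasks
#'
#' Wraps the unrolled network, its gradients, and cross-task batch sampling
#' into the problem interface consumed by [bilevel_train()].
#'
#' @param tasks list of [task_bundle()]s.
#' @param pp0 initial [phase_params()].
#' @param cfg a [loa_config()].
#' @param j_tr,j_val per-task batch sizes.
#' @return problem object (list of closures plus `theta0`, `omega0`,
#'   `template`).
#' @export
make_meta_problem <- function(tasks, pp0, cfg = loa_config(), j_tr = 2L,
                              j_val = 2L) {
  template <- pp0
  n_tasks <- length(tasks)
  list(
    theta0 = pack_phase_params(pp0),
    omega0 = vapply(tasks, function(t) t$omega, numeric(1)),
    template = template,
    tasks = tasks,
    loss = function(theta, omega, batch) {
      pp <- unpack_phase_params(theta, template)
      sum(vapply(batch, function(p) {
        recon_loss(unrolled_forward(p$y, pp, omega[p$task], cfg)$x, p$x_star)
      }, numeric(1)))
    },
    grad = function(theta, omega, batch) {
      pp <- unpack_phase_params(theta, template)
      g_theta <- NULL; value <- 0
      g_omega <- numeric(n_tasks)
      for (p in batch) {
        gr <- unrolled_grad(p$y, pp, omega[p$task], p$x_star, cfg)
        value <- value + gr$loss
        g_omega[p$task] <- g_omega[p$task] + gr$g_omega
        gt <- pack_theta_grad(gr)
        g_theta <- if (is.null(g_theta)) gt else g_theta + gt
      }
      list(value = value, g_theta = g_theta, g_omega = g_omega)
    },
    sample_batches = function(seed) {
      sample_cross_task_batch(tasks, j_tr, j_val, seed)
    },
    project = function(theta) project_phase_theta(theta, template)
  )
}

#' Stair schedule for growing the unrolled network
#'
#' @param epochs_per_stage outer iterations of [bilevel_train()] per stage.
#' @param start_phases phases in the first stage (default 1).
#' @param max_phases cap on total phases.
#' @return object of class `stair_schedule`.
#' @export
stair_schedule <- function(epochs_per_stage = 100L, start_phases = 1L,
                           max_phases = 5L) {
  stopifnot(start_phases >= 1, max_phases >= start_phases)
  structure(list(epochs_per_stage = as.integer(epochs_per_stage),
                 start_phases = as.integer(start_phases),
                 max_phases = as.integer(max_phases)),
            class = "stair_schedule")
}

#' Stair training: grow the network one phase at a time
#'
#' Trains with `start_phases` phases, then repeatedly appends one phase
#' (new step sizes at their defaults, all shared parameters kept) and
#' continues training, stopping when the stage-end validation loss fails to
#' decrease or `max_phases` is reached.
#'
#' @param tasks list of [task_bundle()]s.
#' @param fe initial [feature_extractor()].
#' @param schedule a [stair_schedule()].
#' @param bl_cfg a [bilevel_config()].
#' @param cfg a [loa_config()].
#' @param seed integer seed.
#' @return list `pp` (trained [phase_params()]), `omega`, `stage_history`
#'   (per-stage data frame), `history` (concatenated training history).
#' @export
stair_train <- function(tasks, fe, schedule = stair_schedule(),
                        bl_cfg = bilevel_config(), cfg = loa_config(),
                        seed = 1) {
  pp <- init_phase_params(fe, schedule$start_phases, cfg)
  omega <- vapply(tasks, function(t) t$omega, numeric(1))
  stage_rows <- list()
  histories <- list()
  prev_loss <- Inf
  stage <- 0L
  repeat {
    stage <- stage + 1L
    problem <- make_meta_problem(tasks, pp, cfg, bl_cfg$j_tr, bl_cfg$j_val)
    problem$omega0 <- omega
    bl_cfg_stage <- bl_cfg
    bl_cfg_stage$max_outer <- schedule$epochs_per_stage
    fit <- bilevel_train(problem, bl_cfg_stage, seed = seed + 1000L * stage)
    pp <- unpack_phase_params(fit$theta, problem$template)
    omega <- fit$omega
    end_loss <- if (is.null(fit$history)) NA_real_ else
      fit$history$loss_val[nrow(fit$history)]
    stage_rows[[stage]] <- data.frame(stage = stage,
                                      n_phases = length(pp$alphas),
                                      loss_val = end_loss)
    histories[[stage]] <- transform(fit$history, stage = stage)
    if (length(pp$alphas) >= schedule$max_phases) break
    if (is.finite(prev_loss) && end_loss >= prev_loss) break
    prev_loss <- end_loss
    pp <- phase_params(pp$fe, c(pp$alphas, cfg$alpha0),
                       c(pp$taus, cfg$tau0), eps0 = pp_eps0(pp))
  }
  list(pp = pp, omega = omega, stage_history = do.call(rbind, stage_rows),
       history = do.call(rbind, histories))
}

#' Adapt the task-specific weight to an unseen task
#'
#' Freezes all task-invariant parameters and fits only the scalar `omega`
#' of a new task by first-order (Adam) descent on the task loss over its
#' training pairs. The task-invariant parameters are returned bit-identical.
#'
#' @param pp trained [phase_params()] (not modified).
#' @param task a [task_bundle()] for the unseen task.
#' @param epochs number of gradient steps.
#' @param seed integer seed (controls mini-batch draws).
#' @param cfg a [loa_config()].
#' @param lr Adam step size.
#' @param batch_size training pairs per step (default all).
#' @return list `tw` (fitted [task_weight()]), `history`.
#' @export
adapt_unseen_task <- function(pp, task, epochs = 50L, seed = 1,
                              cfg = loa_config(), lr = 0.1,
                              batch_size = NULL) {
  omega <- task$omega
  n <- length(task$train_pairs)
  batch_size <- min(batch_size %||% n, n)
  ad <- adam_init(1L)
  rows <- list()
  for (e in seq_len(epochs)) {
    idx <- if (batch_size < n) {
      with_seed(seed + e, sample(n, batch_size))
    } else seq_len(n)
    gr <- task_loss_grad(pp, omega, task$train_pairs[idx], cfg)
    ad <- adam_step(ad, gr$g_omega, lr)
    omega <- omega - ad$step
    rows[[e]] <- data.frame(epoch = e, loss = gr$value, omega = omega)
  }
  list(tw = task_weight(omega), history = do.call(rbind, rows))
}
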