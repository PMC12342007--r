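# Gradient-based optimization of the regulatory system through the
# stochastic integrator. Gradients are pathwise: Wiener increments and light
# schedules are sampled and then held fixed while the Euler-Maruyama solution
# path is differentiated by reverse-mode accumulation (the clamp at the
# abundance floor contributes a zero subgradient on clamped coordinates).

# ---- flat parameter vector <-> (dense net, log kinetics) -------------------

pack_theta <- function(dense, kin = NULL) {
  th <- c(as.vector(dense$W1), dense$b1, as.vector(dense$W2), dense$b2)
  if (!is.null(kin)) {
    th <- c(th, log(kin$m), log(kin$delta), log(kin$s), log(kin$gamma))
  }
  th
}

unpack_theta <- function(theta, n, h, with_kin) {
  nh <- n * h
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  dense <- list(n = n, h = h,
                W1 = matrix(take(nh * n), nh, n),
                b1 = take(nh),
                W2 = matrix(take(h * n), h, n),
                b2 = take(n),
                log_input = FALSE)
  kin <- NULL
  if (with_kin) {
    kin <- kinetic_params(exp(take(n)), exp(take(n)), exp(take(n)),
                          exp(take(n)), n = n)
  }
  list(dense = dense, kin = kin)
}

# ---- pathwise loss + gradient ---------------------------------------------

# Forward simulate with frozen noise, then reverse-accumulate the gradient of
# the tracking loss with respect to the dense network parameters and
# (optionally) the log kinetic rates. `xi` is NULL for a deterministic run.
loss_and_grad <- function(dense, kin, init, nsteps, dt, u, xi,
                          obj_cfg, sim_cfg, target = circadian_target(),
                          optimize_kinetics = TRUE) {
  n <- dense$n
  h <- dense$h
  noise_on <- !is.null(xi)
  states <- .sim_core_cpp(init$x, init$y, kin$m, kin$delta, kin$s, kin$gamma,
                          dense$W1, dense$b1, dense$W2, dense$b2,
                          dense$log_input, dt, nsteps,
                          if (noise_on) xi else matrix(0, 0, 0),
                          u, sim_cfg$light_target_gene,
                          sim_cfg$noise_threshold, sim_cfg$abundance_floor,
                          noise_on)
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  traj <- new_trajectory(times, states[, seq_len(n), drop = FALSE],
                         states[, n + seq_len(n), drop = FALSE],
                         rep(FALSE, nsteps + 1L), dt)
  idx <- loss_grid_index(traj, obj_cfg)
  rg <- obj_cfg$readout_gene
  y_grid <- states[idx, n + rg]
  gap <- hill_state(y_grid, obj_cfg$S) -
    target_transform(eval_target(times[idx], target), obj_cfg$target_half)
  loss <- sum(gap^2)
  # dL/dy at each grid row
  dl_dy <- 2 * gap * hill_state_grad(y_grid, obj_cfg$S)
  grid_adj <- numeric(nsteps + 1L)
  grid_adj[idx] <- dl_dy

  gW1 <- matrix(0, n * h, n); gb1 <- numeric(n * h)
  gW2 <- matrix(0, h, n);     gb2 <- numeric(n)
  gm <- gdelta <- gs <- ggamma <- numeric(n)

  lam <- numeric(2L * n)
  floor_ <- sim_cfg$abundance_floor
  thr <- sim_cfg$noise_threshold
  sqdt <- sqrt(dt)
  ix <- seq_len(n)
  iy <- n + ix

  for (t in nsteps:1L) {
    lam[n + rg] <- lam[n + rg] + grid_adj[t + 1L]
    mask <- states[t + 1L, ] > floor_
    lp <- lam * mask
    if (!any(lp != 0)) { lam <- lp; next }
    x <- states[t, ix]
    y <- states[t, iy]
    r <- if (dense$log_input) log(y) else log1p(y)
    a <- drop(dense$W1 %*% r) + dense$b1
    hm <- matrix(mish(a), h, n)
    z <- colSums(hm * dense$W2) + dense$b2
    f <- sigmoid(z)
    lpx <- lp[ix]
    lpy <- lp[iy]

    if (optimize_kinetics) {
      gm <- gm + lpx * dt * f
      gdelta <- gdelta - lpx * dt * x
      gs <- gs + lpy * dt * x
      ggamma <- ggamma - lpy * dt * y
    }
    gi <- lpx * dt * kin$m * f * (1 - f)        # upstream into head sums z_i
    gb2 <- gb2 + gi
    gW2 <- gW2 + sweep(hm, 2L, gi, "*")
    q <- as.vector(sweep(dense$W2, 2L, gi, "*")) * mish_grad(a)
    gb1 <- gb1 + q
    gW1 <- gW1 + q %*% t(r)

    # state adjoint for the previous step
    dr_dy <- if (dense$log_input) 1 / y else 1 / (1 + y)
    lam_y <- drop(crossprod(dense$W1, q)) * dr_dy +
      lpy * (1 - kin$gamma * dt)
    lam_x <- lpx * (1 - kin$delta * dt) + lpy * kin$s * dt
    if (noise_on) {
      lam_x <- lam_x + lpx * noise_amplitude_grad(x, thr) * sqdt * xi[ix, t]
      lam_y <- lam_y + lpy * noise_amplitude_grad(y, thr) * sqdt * xi[iy, t]
    }
    lam <- c(lam_x, lam_y)
  }

  g_logkin <- if (optimize_kinetics) {
    c(gm * kin$m, gdelta * kin$delta, gs * kin$s, ggamma * kin$gamma)
  } else NULL
  list(loss = loss, traj = traj,
       grad = c(as.vector(gW1), gb1, as.vector(gW2), gb2, g_logkin))
}

#' Pathwise gradient of the tracking loss
#'
#' Simulates the system with frozen Wiener increments and light schedule,
#' then returns the tracking loss and its exact reverse-mode gradient with
#' respect to the flattened free parameters (dense-form network weights and,
#' optionally, log kinetic rates). The flat layout is
#' `c(W1, b1, W2, b2, log m, log delta, log s, log gamma)`.
#'
#' @param net A `net_params` object.
#' @param kin A [kinetic_params()].
#' @param schedule A `light_schedule` or `NULL` (light off).
#' @param sim_cfg A [sim_config()]; `noise_on` selects stochastic vs
#'   deterministic paths.
#' @param obj_cfg An [objective_config()].
#' @param horizon Trajectory length, days.
#' @param init Initial [system_state()] (default all abundances 10).
#' @param light_cfg A [light_config()].
#' @param xi Optional frozen `(2n) x nsteps` standard-normal matrix; drawn
#'   from `sim_cfg$seed` when noise is on and `xi` is `NULL`.
#' @param optimize_kinetics Include kinetic-rate gradients?
#' @return List with `loss`, `grad` (flat numeric vector), and the
#'   simulated `traj`.
#' @export
tracking_loss_grad <- function(net, kin, schedule = NULL,
                               sim_cfg = sim_config(),
                               obj_cfg = objective_config(), horizon,
                               init = NULL, light_cfg = light_config(),
                               xi = NULL, optimize_kinetics = TRUE) {
  n <- net$n
  if (is.null(init)) init <- system_state(rep(10, n), rep(10, n))
  nsteps <- as.integer(round(horizon / sim_cfg$dt))
  u <- if (is.null(schedule)) rep(0, nsteps) else {
    light_input(seq(0, by = sim_cfg$dt, length.out = nsteps),
                schedule, light_cfg)
  }
  if (sim_cfg$noise_on && is.null(xi)) {
    xi <- local_seed(sim_cfg$seed,
                     matrix(stats::rnorm(2L * n * nsteps), 2L * n, nsteps))
  }
  if (!sim_cfg$noise_on) xi <- NULL
  dense <- net_dense(net)
  loss_and_grad(dense, kin, init, nsteps, sim_cfg$dt, u, xi, obj_cfg,
                sim_cfg, optimize_kinetics = optimize_kinetics)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(npar) {
  list(m = numeric(npar), v = numeric(npar), t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- training configuration and loop --------------------------------------

#' Training configuration
#'
#' @param curriculum A [curriculum_schedule()]; the default grows the fitted
#'   horizon in stages ending at 4 days.
#' @param learning_rate Adam learning rate (default 1e-2).
#' @param batch Replicate stochastic trajectories averaged per gradient step.
#' @param seed Master seed; all per-step noise and schedules derive from it.
#' @param optimize_kinetics Train the kinetic rates (in log space, keeping
#'   them positive) alongside the network weights?
#' @param pretrain_deterministic Prepend a noise-off, light-off fitting stage
#'   at the first curriculum horizon before stochastic training.
#' @param max_minutes Wall-clock budget; training stops gracefully at the
#'   best checkpoint found.
#' @return An object of class `train_config`.
#' @export
train_config <- function(curriculum = curriculum_schedule(),
                         learning_rate = 1e-2, batch = 1L, seed = 1L,
                         optimize_kinetics = TRUE,
                         pretrain_deterministic = TRUE,
                         max_minutes = Inf) {
  if (learning_rate <= 0) stop("train_config: `learning_rate` must be > 0")
  if (batch < 1) stop("train_config: `batch` must be >= 1")
  structure(list(curriculum = curriculum,
                 learning_rate = as.numeric(learning_rate),
                 batch = as.integer(batch), seed = as.integer(seed),
                 optimize_kinetics = isTRUE(optimize_kinetics),
                 pretrain_deterministic = isTRUE(pretrain_deterministic),
                 max_minutes = max_minutes),
            class = "train_config")
}

#' Train the regulatory system on the circadian tracking objective
#'
#' Minimizes the expected tracking loss over stochastic realizations by Adam
#' on the flattened free parameters, under the growing-horizon curriculum.
#' At each optimizer step a fresh batch of light schedules and Wiener paths
#' is sampled and then frozen while the solution path is differentiated
#' (pathwise gradients). With `sim_cfg$noise_on = FALSE` the fit is fully
#' deterministic (light off), which is also used for the optional
#' pretraining stage.
#'
#' @param net Initial `net_params` (e.g. from [init_params()]).
#' @param kin Initial [kinetic_params()].
#' @param cfg A [train_config()].
#' @param sim_cfg A [sim_config()]; its `dt` sets the training resolution.
#' @param obj_cfg An [objective_config()].
#' @param light_cfg A [light_config()] for the entrainment signal.
#' @param init Initial state (default all abundances 10).
#' @return List with `checkpoint` (class `grn_checkpoint`: best-loss `net`,
#'   `kin`, `stage`, `loss_estimate`, `seed`) and `history` (data frame
#'   `step`, `stage`, `horizon_days`, `loss`).
#' @export
train_grn <- function(net, kin, cfg = train_config(),
                      sim_cfg = sim_config(), obj_cfg = objective_config(),
                      light_cfg = light_config(), init = NULL) {
  stopifnot(inherits(net, "net_params"), inherits(kin, "kinetic_params"),
            net$n == kin$n)
  n <- net$n
  h <- net$width_factor * n
  if (is.null(init)) init <- system_state(rep(10, n), rep(10, n))
  dense <- net_dense(net)
  log_input <- dense$log_input
  theta <- pack_theta(dense, if (cfg$optimize_kinetics) kin)
  opt <- adam_state(length(theta))
  t_start <- Sys.time()

  stages <- data.frame(horizon = cfg$curriculum$horizons,
                       steps = cfg$curriculum$steps_per_stage,
                       stochastic = sim_cfg$noise_on)
  if (cfg$pretrain_deterministic && sim_cfg$noise_on) {
    stages <- rbind(data.frame(horizon = stages$horizon[1L],
                               steps = stages$steps[1L],
                               stochastic = FALSE), stages)
  }

  history <- vector("list", sum(stages$steps))
  best <- list(theta = theta, loss = Inf, stage = 0L)
  step_seeds <- derive_seeds(cfg$seed, sum(stages$steps))
  global_step <- 0L
  out_of_time <- FALSE

  for (stage in seq_len(nrow(stages))) {
    horizon <- stages$horizon[stage]
    nsteps_sim <- as.integer(round(horizon / sim_cfg$dt))
    for (step in seq_len(stages$steps[stage])) {
      global_step <- global_step + 1L
      parts <- unpack_theta(theta, n, h, cfg$optimize_kinetics)
      parts$dense$log_input <- log_input
      kin_now <- parts$kin %||% kin
      if (stages$stochastic[stage]) {
        rep_seeds <- derive_seeds(step_seeds[global_step], 2L * cfg$batch)
        acc_loss <- 0
        acc_grad <- NULL
        for (b in seq_len(cfg$batch)) {
          sched <- sample_light_schedule(light_cfg, horizon,
                                         seed = rep_seeds[2L * b - 1L])
          u <- light_input(seq(0, by = sim_cfg$dt,
                               length.out = nsteps_sim),
                           sched, light_cfg)
          xi <- local_seed(rep_seeds[2L * b],
                           matrix(stats::rnorm(2L * n * nsteps_sim),
                                  2L * n, nsteps_sim))
          lg <- loss_and_grad(parts$dense, kin_now, init, nsteps_sim,
                              sim_cfg$dt, u, xi, obj_cfg, sim_cfg,
                              optimize_kinetics = cfg$optimize_kinetics)
          acc_loss <- acc_loss + lg$loss
          acc_grad <- if (is.null(acc_grad)) lg$grad else acc_grad + lg$grad
        }
        loss <- acc_loss / cfg$batch
        grad <- acc_grad / cfg$batch
      } else {
        lg <- loss_and_grad(parts$dense, kin_now, init, nsteps_sim,
                            sim_cfg$dt, rep(0, nsteps_sim), NULL,
                            obj_cfg, sim_cfg,
                            optimize_kinetics = cfg$optimize_kinetics)
        loss <- lg$loss
        grad <- lg$grad
      }
      if (!is.finite(loss) || any(!is.finite(grad))) {
        warning("train_grn: non-finite loss or gradient at stage ", stage,
                " step ", step, "; aborting stage")
        break
      }
      history[[global_step]] <- data.frame(step = global_step,
                                           stage = stage,
                                           horizon_days = horizon,
                                           loss = loss)
      if (loss < best$loss) {
        best <- list(theta = theta, loss = loss, stage = stage)
      }
      upd <- adam_step(opt, theta, grad, cfg$learning_rate)
      theta <- upd$theta
      opt <- upd$state
      if (difftime(Sys.time(), t_start, units = "mins") >
          cfg$max_minutes) {
        out_of_time <- TRUE
        break
      }
    }
    if (out_of_time) break
  }

  parts <- unpack_theta(best$theta, n, h, cfg$optimize_kinetics)
  net_best <- net_from_dense(
    within_dense_loginput(parts$dense, log_input),
    net$width_factor, net$input_transform)
  ckpt <- structure(list(net = net_best, kin = parts$kin %||% kin,
                         stage = best$stage, loss_estimate = best$loss,
                         seed = cfg$seed),
                    class = "grn_checkpoint")
  list(checkpoint = ckpt, history = do.call(rbind, history))
}

within_dense_loginput <- function(dense, log_input) {
  dense$log_input <- log_input
  dense
}

#' @export
print.grn_checkpoint <- function(x, ...) {
  cat(sprintf("grn_checkpoint: n = %d, stage %d, loss estimate %.4g\n",
              x$net$n, x$stage, x$loss_estimate))
  invisible(x)
}

#' Post-training stochastic evaluation
#'
#' Simulates `n_reps` independent stochastic realizations of a trained
#' system (fresh light schedules and Wiener paths per replicate) and returns
#' the tracking loss of each.
#'
#' @param ckpt A `grn_checkpoint` from [train_grn()] (or a list with `net`
#'   and `kin`).
#' @param n_reps Number of replicates (>= 1).
#' @param horizon Days per replicate.
#' @param light_cfg A [light_config()].
#' @param seed Master seed for the replicate draws.
#' @param sim_cfg A [sim_config()].
#' @param obj_cfg An [objective_config()].
#' @param init Initial state (default all abundances 10).
#' @return Numeric vector of `n_reps` losses.
#' @export
evaluate_checkpoint <- function(ckpt, n_reps, horizon,
                                light_cfg = light_config(), seed = 1L,
                                sim_cfg = sim_config(),
                                obj_cfg = objective_config(), init = NULL) {
  stopifnot(n_reps >= 1)
  seeds <- derive_seeds(seed, 2L * n_reps)
  vapply(seq_len(n_reps), function(r) {
    sched <- if (sim_cfg$noise_on) {
      sample_light_schedule(light_cfg, horizon, seed = seeds[2L * r - 1L])
    } else NULL
    cfg_r <- sim_cfg
    cfg_r$seed <- seeds[2L * r]
    traj <- simulate_grn(ckpt$kin, ckpt$net, sched, cfg_r, horizon,
                         init = init, light_cfg = light_cfg)
    tracking_loss(traj, obj_cfg)
  }, numeric(1))
}

#' Persist / restore a training checkpoint
#'
#' A checkpoint directory holds the network and kinetic parameters as JSON
#' ([save_params()] format), a metadata JSON (stage, loss estimate, seed),
#' and optionally the loss history as CSV.
#'
#' @param ckpt A `grn_checkpoint`.
#' @param dir Directory path (created if missing).
#' @param history Optional loss-history data frame from [train_grn()].
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint` a
#'   `grn_checkpoint` (with `history` attached when present on disk).
#' @export
save_checkpoint <- function(ckpt, dir, history = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_params(ckpt$net, ckpt$kin, file.path(dir, "params.json"))
  jsonlite::write_json(list(schema = "tfsde-ckpt-1", stage = ckpt$stage,
                            loss_estimate = ckpt$loss_estimate,
                            seed = ckpt$seed),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  if (!is.null(history)) {
    utils::write.csv(history, file.path(dir, "loss_history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  params <- load_params(file.path(dir, "params.json"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ckpt <- structure(list(net = params$net, kin = params$kin,
                         stage = as.integer(meta$stage),
                         loss_estimate = as.numeric(meta$loss_estimate),
                         seed = as.integer(meta$seed)),
                    class = "grn_checkpoint")
  hist_path <- file.path(dir, "loss_history.csv")
  if (file.exists(hist_path)) {
    attr(ckpt, "history") <- utils::read.csv(hist_path)
  }
  ckpt
}
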