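test_that("pathwise gradients match central finite differences under frozen noise", {
  set.seed(19)
  n <- 3
  net <- init_params(n, seed = 3, scale = 0.3)
  kin <- small_kinetics(n)
  scfg <- sim_config(dt = 0.01, noise_on = TRUE)
  ocfg <- objective_config()
  horizon <- 0.2
  nsteps <- as.integer(round(horizon / scfg$dt))
  xi <- matrix(stats::rnorm(2 * n * nsteps), 2 * n, nsteps)
  sched <- sample_light_schedule(light_config(initial_on = TRUE), horizon,
                                 seed = 5)
  res <- tracking_loss_grad(net, kin, sched, scfg, ocfg, horizon, xi = xi)
  dense <- tfsde:::net_dense(net)
  theta0 <- tfsde:::pack_theta(dense, kin)
  u <- light_input(seq(0, by = scfg$dt, length.out = nsteps), sched,
                   light_config(initial_on = TRUE))
  lossfun <- function(th) {
    parts <- tfsde:::unpack_theta(th, n, dense$h, TRUE)
    parts$dense$log_input <- dense$log_input
    tfsde:::loss_and_grad(parts$dense, parts$kin,
                          system_state(rep(10, n), rep(10, n)),
                          nsteps, scfg$dt, u, xi, ocfg, scfg)$loss
  }
  # sample parameters whose gradient is above the finite-difference noise
  # floor (the loss is O(1), so central differences resolve ~1e-11 at best)
  eligible <- which(abs(res$grad) > 1e-8)
  expect_gt(length(eligible), 10)
  idx <- sample(eligible, 10)
  for (j in idx) {
    eps <- 1e-5 * max(1, abs(theta0[j]))
    tp <- theta0; tp[j] <- tp[j] + eps
    tm <- theta0; tm[j] <- tm[j] - eps
    fd <- (lossfun(tp) - lossfun(tm)) / (2 * eps)
    expect_lt(abs(res$grad[j] - fd) / max(abs(fd), abs(res$grad[j])), 1e-3)
  }
})

test_that("a short deterministic fit halves the tracking loss", {
  n <- 3
  net <- init_params(n, seed = 7, scale = 0.1)
  kin <- kinetic_params(m = 3000, delta = 6, s = 6, gamma = 3, n = n)
  tcfg <- train_config(
    curriculum = curriculum_schedule(horizons = 1, steps_per_stage = 80L),
    learning_rate = 1e-2, seed = 11, pretrain_deterministic = FALSE)
  fit <- train_grn(net, kin, tcfg, sim_config(dt = 0.005, noise_on = FALSE))
  h <- fit$history
  expect_lt(utils::tail(h$loss, 1), 0.5 * h$loss[1])
  # best checkpoint tracks the running minimum
  expect_equal(fit$checkpoint$loss_estimate, min(h$loss))
  expect_true(all(cummin(h$loss) <= h$loss))
  # optimized kinetic rates remain strictly positive
  expect_true(all(fit$checkpoint$kin$m > 0, fit$checkpoint$kin$delta > 0,
                  fit$checkpoint$kin$s > 0, fit$checkpoint$kin$gamma > 0))
})

test_that("training is a no-op at (near-)zero learning rate", {
  n <- 3
  net <- init_params(n, seed = 2, scale = 0.2)
  kin <- small_kinetics(n)
  tcfg <- train_config(
    curriculum = curriculum_schedule(horizons = 0.2, steps_per_stage = 5L),
    learning_rate = 1e-300, seed = 3, pretrain_deterministic = FALSE)
  fit <- train_grn(net, kin, tcfg, sim_config(dt = 0.01, noise_on = FALSE))
  expect_equal(stats::sd(fit$history$loss), 0)
  expect_equal(tfsde:::net_dense(fit$checkpoint$net)$W1,
               tfsde:::net_dense(net)$W1, tolerance = 1e-290)
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("stochastic evaluation is seed-deterministic and noise-off matches training loss", {
  n <- 3
  net <- init_params(n, seed = 4, scale = 0.2)
  kin <- small_kinetics(n)
  ckpt <- list(net = net, kin = kin)
  l1 <- evaluate_checkpoint(ckpt, n_reps = 5, horizon = 1, seed = 8,
                            sim_cfg = sim_config(dt = 0.005))
  l2 <- evaluate_checkpoint(ckpt, n_reps = 5, horizon = 1, seed = 8,
                            sim_cfg = sim_config(dt = 0.005))
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1)) && all(l1 > 0))
  # zero-noise evaluation equals the deterministic training-path loss
  scfg0 <- sim_config(dt = 0.005, noise_on = FALSE)
  l0 <- evaluate_checkpoint(ckpt, n_reps = 1, horizon = 1, seed = 8,
                            sim_cfg = scfg0)
  det <- tracking_loss(simulate_grn(kin, net, NULL, scfg0, 1))
  expect_equal(l0, det)
})

test_that("checkpoints round-trip through a directory", {
  n <- 3
  net <- init_params(n, seed = 5, scale = 0.15)
  kin <- small_kinetics(n)
  ckpt <- structure(list(net = net, kin = kin, stage = 2L,
                         loss_estimate = 1.25, seed = 9L),
                    class = "grn_checkpoint")
  dir <- withr::local_tempdir()
  hist <- data.frame(step = 1:3, stage = 1L, horizon_days = 0.5,
                     loss = c(3, 2, 1))
  save_checkpoint(ckpt, dir, history = hist)
  back <- load_checkpoint(dir)
  expect_identical(back$net$genes, net$genes)
  expect_equal(back$kin$m, kin$m)
  expect_equal(back$loss_estimate, 1.25)
  expect_equal(attr(back, "history")$loss, hist$loss)
})
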