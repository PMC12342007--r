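test_that("drift vanishes at the constant-f fixed point and light only moves gene 2", {
  n <- 3
  net0 <- init_params(n, seed = 1, scale = 0)     # f constant at 0.5
  kin <- small_kinetics(n)
  xstar <- kin$m * 0.5 / kin$delta
  ystar <- kin$s * xstar / kin$gamma
  st <- system_state(xstar, ystar)
  expect_equal(drift(st, kin, net0, u = 0), rep(0, 2 * n), tolerance = 1e-12)
  d0 <- drift(st, kin, net0, u = 0)
  d1 <- drift(st, kin, net0, u = 123.4)
  expect_equal(d1 - d0, c(rep(0, n), 0, 123.4, 0))
  expect_error(system_state(c(-1, 0, 0), c(0, 0, 0)), "nonnegative")
})

test_that("noise amplitude is continuous, monotone, and branch-correct", {
  expect_equal(noise_amplitude(16), 4)
  expect_equal(sqrt(16), 16 / 4)         # both branches at the threshold
  expect_equal(noise_amplitude(100), 10)
  expect_equal(noise_amplitude(4), 1)
  expect_equal(noise_amplitude(0), 0)
  z <- seq(0, 1e6, length.out = 10001)
  expect_true(all(diff(noise_amplitude(z)) > 0))
  expect_error(noise_amplitude(-1), "must be >= 0")
})

test_that("noise-off simulation matches the closed-form linear ODE solution", {
  # f constant at 0.5 makes the system linear; rates are modest so the
  # first-order integrator resolves the transient to ~1e-5 relative error.
  n <- 2
  net0 <- init_params(n, seed = 1, scale = 0)
  kin <- kinetic_params(m = c(50, 80), delta = c(0.12, 0.1),
                        s = c(0.4, 0.3), gamma = c(0.08, 0.06), n = n)
  # start mRNA at its fixed point: x stays constant and y relaxes as a
  # single exponential, which the closed form gives exactly
  x0 <- kin$m * 0.5 / kin$delta
  y0 <- rep(10, n)
  tr <- simulate_grn(kin, net0, NULL, sim_config(dt = 1e-3, noise_on = FALSE),
                     horizon = 1, init = system_state(x0, y0))
  ys <- kin$s * x0 / kin$gamma
  y_cf <- ys + (y0 - ys) * exp(-kin$gamma)
  iT <- nrow(tr$x)
  expect_equal(tr$x[iT, ], x0, tolerance = 1e-12)
  expect_equal(tr$y[iT, ], y_cf, tolerance = 1e-4)
})

test_that("halving dt changes the deterministic endpoint at first order", {
  n <- 3
  net <- init_params(n, seed = 3, scale = 0.3)
  kin <- small_kinetics(n)
  endpoint <- function(dt) {
    tr <- simulate_grn(kin, net, NULL, sim_config(dt = dt, noise_on = FALSE),
                       horizon = 1)
    c(tr$x[nrow(tr$x), ], tr$y[nrow(tr$y), ])
  }
  e1 <- endpoint(4e-3); e2 <- endpoint(2e-3); e3 <- endpoint(1e-3)
  # successive halvings shrink the change by about the Euler order (ratio ~2)
  r <- max(abs(e1 - e2)) / max(abs(e2 - e3))
  expect_gt(r, 1.5)
  expect_lt(r, 3)
})

test_that("seeded stochastic runs are bitwise-reproducible and respect the floor", {
  n <- 3
  net <- init_params(n, seed = 11, scale = 0.3)
  kin <- small_kinetics(n)
  sch <- sample_light_schedule(light_config(), 2, seed = 5)
  cfg <- sim_config(dt = 2e-3, noise_on = TRUE, seed = 99)
  t1 <- simulate_grn(kin, net, sch, cfg, 2)
  t2 <- simulate_grn(kin, net, sch, cfg, 2)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  for (s in 1:20) {
    cfg$seed <- s
    tr <- simulate_grn(kin, net, sch, cfg, 0.5)
    expect_true(all(tr$x >= 0) && all(tr$y >= 0))
  }
})

test_that("zero-amplitude noise equals the deterministic run", {
  n <- 3
  net <- init_params(n, seed = 2, scale = 0.2)
  kin <- small_kinetics(n)
  nsteps <- 250L
  xi0 <- matrix(0, 2 * n, nsteps)  # frozen zero increments
  cfg <- sim_config(dt = 2e-3, noise_on = TRUE)
  tr_zero <- simulate_grn(kin, net, NULL, cfg, 0.5, xi = xi0)
  tr_det <- simulate_grn(kin, net, NULL,
                         sim_config(dt = 2e-3, noise_on = FALSE), 0.5)
  expect_equal(tr_zero$y, tr_det$y, tolerance = 1e-14)
})

test_that("stochastic ensemble mean stays near the deterministic path", {
  n <- 2
  net0 <- init_params(n, seed = 1, scale = 0)
  kin <- kinetic_params(m = 400, delta = 4, s = 4, gamma = 2, n = n)
  det <- simulate_grn(kin, net0, NULL, sim_config(dt = 2e-3, noise_on = FALSE),
                      horizon = 1)
  yT_det <- det$y[nrow(det$y), 1]
  reps <- vapply(1:500, function(s) {
    tr <- simulate_grn(kin, net0, NULL,
                       sim_config(dt = 2e-3, noise_on = TRUE, seed = s),
                       horizon = 1)
    tr$y[nrow(tr$y), 1]
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - yT_det), 3 * se + 0.5)
})

test_that("trajectories round-trip through CSV and invalid configs error", {
  n <- 2
  net <- init_params(n, seed = 6, scale = 0.2)
  kin <- kinetic_params(m = 100, delta = 2, s = 2, gamma = 1, n = n)
  tr <- simulate_grn(kin, net, NULL, sim_config(dt = 0.01, noise_on = TRUE,
                                                seed = 3), 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$y, tr$y, ignore_attr = TRUE)
  expect_equal(back$times, tr$times)
  expect_error(sim_config(dt = -1), "dt")
  expect_error(sim_config(scheme = "implicit_em"), "not implemented")
  expect_error(simulate_grn(kin, net, NULL, sim_config(dt = 1), 0.5),
               "horizon")
})
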