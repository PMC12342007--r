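test_that("crossing times are interpolated and direction-aware", {
  tt <- seq(0, 2, by = 0.01)
  vals <- 1000 + 900 * sin(2 * pi * tt)     # crosses 1000 upward at 0, 1, 2
  # the series starts exactly at the threshold and rises: crossings at 0, 1
  up <- crossing_times(tt, vals, 1000, "up")
  expect_equal(up, c(0, 1), tolerance = 0.01)
  down <- crossing_times(tt, vals, 1000, "down")
  expect_equal(down, c(0.5, 1.5), tolerance = 0.01)
  # monotone decreasing series has no upward crossings
  expect_length(crossing_times(tt, rev(seq_along(tt)) * 1.0, 100, "up"), 0)
  # constant series exactly at the threshold: strict convention, none
  expect_length(crossing_times(tt, rep(1000, length(tt)), 1000, "up"), 0)
  # linear interpolation recovers an off-grid crossing
  t2 <- c(0, 1)
  expect_equal(crossing_times(t2, c(0, 10), 2.5, "up"), 0.25)
})

test_that("the target's readout analog crosses S at every dawn", {
  ocfg <- objective_config()
  tr <- make_shifted_tracking_trajectory(0, 5, ocfg)
  cross <- crossing_times(tr$times, tr$y[, 1], ocfg$S, "up")
  expect_equal(cross, seq_len(5) - 0.5, tolerance = 2 * tr$dt)
})

test_that("daily deviations recover imposed shifts with the early-is-negative sign convention", {
  ocfg <- objective_config()
  for (shift in c(-6, -2.4, 0, 2.4, 6)) {
    tr <- make_shifted_tracking_trajectory(shift, 10, ocfg)
    dv <- daily_deviations(tr, ocfg)
    expect_equal(nrow(dv), 10)
    expect_false(any(dv$censored))
    expect_equal(dv$deviation_hours, rep(shift, 10),
                 tolerance = max(24 * tr$dt, 1e-8))
  }
  # early cell -> negative deviation
  tr_early <- make_shifted_tracking_trajectory(-6, 3, ocfg)
  expect_true(all(daily_deviations(tr_early, ocfg)$deviation_hours < 0))
})

test_that("days without a threshold crossing are censored", {
  ocfg <- objective_config()
  tr <- make_shifted_tracking_trajectory(0, 4, ocfg)
  tr$y[, 1] <- 10  # pinned far below S
  dv <- daily_deviations(tr, ocfg)
  expect_equal(nrow(dv), 4)
  expect_true(all(dv$censored))
  expect_true(all(is.na(dv$deviation_hours)))
  short <- tr
  short$times <- short$times[short$times < 0.9]
  short$y <- short$y[seq_along(short$times), , drop = FALSE]
  expect_error(daily_deviations(short, ocfg), "shorter than one day")
})

test_that("ensemble accounting is exact and seed-deterministic", {
  ck <- list(net = repressilator_net_cached(), kin = repressilator_kinetics(3))
  dev <- ensemble_deviations(ck, d = 3, n_reps = 20, seed = 5,
                             sim_cfg = sim_config(dt = 0.005),
                             init = repressilator_init(3))
  expect_equal(nrow(dev), 20 * 3)
  expect_equal(unique(table(dev$realization_id)), 3L)
  dev2 <- ensemble_deviations(ck, d = 3, n_reps = 20, seed = 5,
                              sim_cfg = sim_config(dt = 0.005),
                              init = repressilator_init(3))
  expect_identical(dev$deviation_hours, dev2$deviation_hours)
})

test_that("percentile summaries are ordered and match order statistics", {
  # constant samples collapse to a point
  const <- data.frame(realization_id = 1L, day = 1:5,
                      deviation_hours = 2.2, censored = FALSE)
  s <- summarize_deviations(const)
  expect_equal(c(s$p5, s$p25, s$p50, s$p75, s$p95), rep(2.2, 5))
  # {-1, 0, 1} has median 0
  three <- data.frame(realization_id = 1L, day = 1:3,
                      deviation_hours = c(-1, 0, 1), censored = FALSE)
  expect_equal(summarize_deviations(three)$p50, 0)
  # uniform(0,1)-hour samples: p5 ~ 0.05, p95 ~ 0.95
  set.seed(12)
  u <- data.frame(realization_id = 1L, day = 1L,
                  deviation_hours = stats::runif(1e5), censored = FALSE)
  su <- summarize_deviations(u)
  expect_equal(su$p5, 0.05, tolerance = 0.2)
  expect_lt(abs(su$p95 - 0.95), 0.01)
  expect_true(su$p5 <= su$p25 && su$p25 <= su$p50 &&
                su$p50 <= su$p75 && su$p75 <= su$p95)
  # random sets keep percentile monotonicity; all-censored input errors
  for (i in 1:20) {
    r <- data.frame(realization_id = 1L, day = 1L,
                    deviation_hours = stats::rnorm(50, sd = 4),
                    censored = FALSE)
    sr <- summarize_deviations(r)
    expect_true(!is.unsorted(c(sr$p5, sr$p25, sr$p50, sr$p75, sr$p95)))
  }
  allc <- data.frame(realization_id = 1L, day = 1:2,
                     deviation_hours = NA_real_, censored = TRUE)
  expect_error(summarize_deviations(allc), "censored")
})

test_that("input-output surfaces have the grid contract and expected monotonicity", {
  net0 <- init_params(4, seed = 1, scale = 0)
  surf0 <- io_surface(net0, gene = 1, inner_points = 5, outer_levels = 2)
  expect_length(surf0$surfaces, 4)           # 2 levels x 2 outer TFs
  expect_true(all(vapply(surf0$surfaces, function(m) all(m == 0.5),
                         logical(1))))
  # 20x20 grid with 3x3 outer levels -> 9 matrices of shape 20x20
  net4 <- init_params(4, seed = 2, scale = 0.3)
  surf <- io_surface(net4, gene = 2, inner_points = 20, outer_levels = 3)
  expect_length(surf$surfaces, 9)
  expect_true(all(vapply(surf$surfaces, function(m)
    all(dim(m) == c(20, 20)) && all(m > 0) && all(m < 1), logical(1))))
  # repressilator: gene 2 is repressed by gene 1 (the row axis)
  netr <- repressilator_net_cached()
  sr <- io_surface(netr, gene = 2, inner = c(1L, 2L), inner_points = 12,
                   outer_levels = 2)
  for (m in sr$surfaces) {
    expect_true(all(diff(m[, 3]) < 0.05))          # non-increasing rows
    expect_lt(m[12, 3], m[1, 3])                   # strictly lower at the top
  }
  expect_error(io_surface(net4, gene = 1, y_max = -10), "log axis")
})

test_that("surface stacks and deviation tables export cleanly", {
  net <- init_params(3, seed = 3, scale = 0.2)
  surf <- io_surface(net, gene = 1, inner_points = 4, outer_levels = 2)
  dir <- withr::local_tempdir()
  write_io_surface(surf, dir)
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  expect_equal(idx$gene, 1)
  expect_true(all(file.exists(file.path(dir, idx$files))))
  m <- as.matrix(utils::read.csv(file.path(dir, idx$files[1]),
                                 header = FALSE))
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(as.numeric(m), as.numeric(surf$surfaces[[1]]),
               tolerance = 1e-12)
})
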