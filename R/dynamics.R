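#' Kinetic rate parameters
#'
#' Per-gene kinetic rates of the mRNA/protein system: maximum mRNA
#' production `m` (molecules/day), mRNA decay `delta` (1/day), protein
#' production per mRNA `s` (1/day), and protein decay `gamma` (1/day).
#' Scalars are recycled across the `n` genes.
#'
#' @param m,delta,s,gamma Strictly positive rate vectors (length `n` or 1).
#' @param n Number of genes; inferred from the longest rate vector if omitted.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(m, delta, s, gamma, n = NULL) {
  n <- as.integer(n %||% max(length(m), length(delta), length(s),
                             length(gamma)))
  out <- list(m = rep_len(as.numeric(m), n),
              delta = rep_len(as.numeric(delta), n),
              s = rep_len(as.numeric(s), n),
              gamma = rep_len(as.numeric(gamma), n), n = n)
  for (nm in c("m", "delta", "s", "gamma")) {
    if (any(!is.finite(out[[nm]])) || any(out[[nm]] <= 0)) {
      stop("kinetic_params: `", nm, "` must be strictly positive and finite")
    }
  }
  structure(out, class = "kinetic_params")
}

#' System state
#'
#' @param x mRNA abundances (molecules, length `n`), all >= 0.
#' @param y protein abundances (molecules, length `n`), all >= 0.
#' @return An object of class `system_state`.
#' @export
system_state <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) {
    stop("system_state: abundances must be nonnegative")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x)),
            class = "system_state")
}

#' Simulation configuration
#'
#' @param dt Integration time step, days (> 0). Default `1e-3`.
#' @param noise_on Include the chemical-Langevin noise terms?
#' @param noise_threshold Abundance below which the noise scale switches
#'   from `sqrt(z)` to `z/4` (default 16, the continuity point).
#' @param abundance_floor Post-step clamping floor, molecules (default 0).
#' @param light_target_gene Index of the TF whose protein production is
#'   boosted by the light signal (default 2).
#' @param scheme Integration scheme; `"euler_maruyama"` is implemented.
#' @param seed Seed for the Wiener increments.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, noise_on = TRUE, noise_threshold = 16,
                       abundance_floor = 0, light_target_gene = 2L,
                       scheme = c("euler_maruyama", "implicit_em"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  if (identical(scheme, "implicit_em")) {
    stop("sim_config: the drift-implicit scheme is not implemented; ",
         "use scheme = \"euler_maruyama\"")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("sim_config: `dt` must be a single positive number (days)")
  }
  if (noise_threshold <= 0) stop("sim_config: `noise_threshold` must be > 0")
  structure(list(dt = as.numeric(dt), noise_on = isTRUE(noise_on),
                 noise_threshold = as.numeric(noise_threshold),
                 abundance_floor = as.numeric(abundance_floor),
                 light_target_gene = as.integer(light_target_gene),
                 scheme = scheme, seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic drift of the regulatory system
#'
#' `dx_i/dt = m_i f_i(y) - delta_i x_i` and
#' `dy_i/dt = s_i x_i - gamma_i y_i`, with the light forcing `u` added to
#' the protein derivative of `light_target_gene` only.
#'
#' @param state A [system_state()].
#' @param kin A [kinetic_params()].
#' @param net A `net_params` object (see [init_params()]).
#' @param u Light forcing rate, molecules/day (>= 0).
#' @param light_target_gene Gene receiving the light boost (default 2).
#' @return Numeric vector of length `2n`: `c(dx, dy)`.
#' @export
drift <- function(state, kin, net, u = 0, light_target_gene = 2L) {
  stopifnot(inherits(state, "system_state"), inherits(kin, "kinetic_params"))
  if (state$n != kin$n || state$n != net$n) {
    stop("drift: state, kinetics and network disagree on n")
  }
  f <- net_forward(net, state$y)
  dx <- kin$m * f - kin$delta * state$x
  dy <- kin$s * state$x - kin$gamma * state$y
  dy[light_target_gene] <- dy[light_target_gene] + u
  c(dx, dy)
}

#' Abundance-dependent noise amplitude
#'
#' Standard-deviation scale of the chemical-Langevin fluctuations of a
#' molecular species with abundance `z`: `sqrt(z)` for `z > threshold`,
#' `z/4` for `z <= threshold`. At the default threshold 16 both branches
#' equal 4, so the amplitude is continuous.
#'
#' @param z Abundances, molecules (>= 0).
#' @param threshold Branch-switch abundance (default 16).
#' @return Nonnegative noise scales.
#' @export
noise_amplitude <- function(z, threshold = 16) {
  if (any(z < 0)) stop("noise_amplitude: abundance must be >= 0")
  ifelse(z > threshold, sqrt(z), z / 4)
}

# d g / d z, used by the pathwise gradients.
noise_amplitude_grad <- function(z, threshold = 16) {
  ifelse(z > threshold, 0.5 / sqrt(z), 0.25)
}

#' Simulate the stochastic regulatory system
#'
#' Integrates the neural-network-driven mRNA/protein SDE over
#' `[0, horizon]` with the Euler-Maruyama scheme. Each of the `2n` state
#' variables receives an independent Wiener increment per step, scaled by
#' [noise_amplitude()] of its own abundance; the light forcing is evaluated
#' at each step's left endpoint (right-continuous schedule convention).
#' Post-step abundances are clamped at the configured floor. With
#' `cfg$noise_on = FALSE` the integration is the deterministic Euler method
#' for the underlying ODE.
#'
#' @param init Initial [system_state()]; default all abundances 10.
#' @param kin A [kinetic_params()].
#' @param net A `net_params` object.
#' @param schedule A `light_schedule` covering `[0, horizon]`; `NULL` means
#'   the light signal is off throughout.
#' @param cfg A [sim_config()].
#' @param horizon Length of the run, days (> `dt`).
#' @param light_cfg A [light_config()] supplying amplitude and exponent of
#'   the forcing pulse.
#' @param xi Optional `(2n) x nsteps` matrix of standard normal draws used
#'   as frozen Wiener increments (advanced use: pathwise gradients); by
#'   default draws are generated from `cfg$seed`.
#' @return An object of class `grn_trajectory`: list with `times`
#'   (length `nsteps + 1`), matrices `x`, `y` (times x genes), logical
#'   `light_on`, and the step `dt`.
#' @export
simulate_grn <- function(kin, net, schedule = NULL, cfg = sim_config(),
                         horizon, init = NULL, light_cfg = light_config(),
                         xi = NULL) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(net, "net_params"))
  n <- kin$n
  if (net$n != n) stop("simulate_grn: network and kinetics disagree on n")
  if (horizon <= cfg$dt) {
    stop("simulate_grn: horizon must exceed the time step dt")
  }
  if (is.null(init)) init <- system_state(rep(10, n), rep(10, n))
  stopifnot(inherits(init, "system_state"), init$n == n)
  nsteps <- round(horizon / cfg$dt)
  if (abs(nsteps * cfg$dt - horizon) > 1e-9 * max(1, horizon)) {
    nsteps <- ceiling(horizon / cfg$dt - 1e-9)
  }
  nsteps <- as.integer(nsteps)
  times <- seq(0, by = cfg$dt, length.out = nsteps + 1L)

  t_left <- times[seq_len(nsteps)]
  if (is.null(schedule)) {
    u <- rep(0, nsteps)
    on_grid <- rep(FALSE, nsteps + 1L)
  } else {
    if (schedule$horizon < horizon - 1e-9) {
      stop("simulate_grn: light schedule does not cover the horizon")
    }
    u <- light_input(t_left, schedule, light_cfg)
    on_grid <- light_state(schedule, pmin(times, schedule$horizon))
  }

  if (cfg$noise_on && is.null(xi)) {
    xi <- local_seed(cfg$seed,
                     matrix(stats::rnorm(2L * n * nsteps), 2L * n, nsteps))
  }
  if (!cfg$noise_on) xi <- matrix(0, 0, 0)

  d <- net_dense(net)
  states <- .sim_core_cpp(init$x, init$y, kin$m, kin$delta, kin$s, kin$gamma,
                          d$W1, d$b1, d$W2, d$b2, d$log_input,
                          cfg$dt, nsteps, xi, u,
                          cfg$light_target_gene, cfg$noise_threshold,
                          cfg$abundance_floor, cfg$noise_on)
  new_trajectory(times, states[, seq_len(n), drop = FALSE],
                 states[, n + seq_len(n), drop = FALSE], on_grid, cfg$dt)
}

new_trajectory <- function(times, x, y, light_on, dt) {
  structure(list(times = times, x = x, y = y,
                 light_on = light_on, dt = dt, n = ncol(x)),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("grn_trajectory: n = %d, %d time points over %.4g days (dt = %g)\n",
              x$n, length(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Export / import a trajectory as CSV
#'
#' Columns `time_days, x1..xn, y1..yn, light_on`, values written at full
#' double precision.
#'
#' @param traj A `grn_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` the reconstructed trajectory.
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- traj$n
  df <- data.frame(time_days = full_precision(traj$times))
  for (i in seq_len(n)) df[[paste0("x", i)]] <- full_precision(traj$x[, i])
  for (i in seq_len(n)) df[[paste0("y", i)]] <- full_precision(traj$y[, i])
  df$light_on <- traj$light_on
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- (ncol(df) - 2L) %/% 2L
  times <- df$time_days
  new_trajectory(times,
                 as.matrix(df[paste0("x", seq_len(n))]),
                 as.matrix(df[paste0("y", seq_len(n))]),
                 as.logical(df$light_on),
                 dt = if (length(times) > 1) times[2] - times[1] else NA_real_)
}
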