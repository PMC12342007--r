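#' Objective configuration
#'
#' Settings of the circadian tracking loss: the cellular on/off switch
#' threshold `S` (molecules; abundance of the readout TF above `S` is the
#' daytime state), the loss-grid increment, the constant of the target's
#' normalizing Hill transform, and which TF is the readout.
#'
#' @param S State-switch threshold, molecules (default `1e3`).
#' @param sample_dt Loss-grid increment, days (default 0.02, i.e. 50 points
#'   per day).
#' @param target_half Constant in the target transform
#'   `v^2 / (target_half + v^2)`; default `0.25 = 0.5^2` so the transform's
#'   half-point sits at the day/night transition `v = 0.5`, mirroring the
#'   abundance transform's half-point at `y = S`.
#' @param readout_gene Index of the tracked TF (default 1).
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(S = 1e3, sample_dt = 0.02, target_half = 0.25,
                             readout_gene = 1L) {
  if (S <= 0) stop("objective_config: `S` must be > 0")
  if (sample_dt <= 0 || sample_dt >= 1) {
    stop("objective_config: `sample_dt` must be in (0, 1) days")
  }
  if (readout_gene < 1) stop("objective_config: invalid `readout_gene`")
  structure(list(S = as.numeric(S), sample_dt = as.numeric(sample_dt),
                 target_half = as.numeric(target_half),
                 readout_gene = as.integer(readout_gene)),
            class = "objective_config")
}

#' Hill transform of the readout abundance
#'
#' `y^2 / (S^2 + y^2)`: maps molecule counts to a normalized cellular state
#' in `[0, 1)`, equal to 0.5 exactly at the switch threshold `S`.
#'
#' @param y Abundances, molecules (>= 0).
#' @param S Switch threshold, molecules.
#' @return Values in `[0, 1)`.
#' @export
hill_state <- function(y, S = 1e3) {
  if (any(y < 0)) stop("hill_state: abundance must be >= 0")
  y^2 / (S^2 + y^2)
}

# d hill_state / d y
hill_state_grad <- function(y, S = 1e3) {
  2 * y * S^2 / (S^2 + y^2)^2
}

#' Hill transform of the target rhythm
#'
#' `v^2 / (half + v^2)`; with the default `half = 0.25` the transform equals
#' 0.5 at the day/night transition value `v = 0.5`.
#'
#' @param v Target values in `[0, 1]`.
#' @param half Transform constant (default 0.25).
#' @return Values in `[0, 1)`.
#' @export
target_transform <- function(v, half = 0.25) {
  stopifnot(all(v >= 0), all(v <= 1))
  v^2 / (half + v^2)
}

#' Loss sampling grid
#'
#' Times `0, sample_dt, 2 sample_dt, ...` strictly below `horizon`
#' (half-open convention), at which the tracking loss is summed.
#'
#' @param horizon End of the grid, days (> 0).
#' @param sample_dt Grid increment, days (> 0).
#' @return Numeric vector of times.
#' @export
loss_grid <- function(horizon, sample_dt = 0.02) {
  if (sample_dt <= 0) stop("loss_grid: `sample_dt` must be > 0")
  if (horizon <= 0) stop("loss_grid: `horizon` must be > 0")
  n_pts <- ceiling(horizon / sample_dt - 1e-9)
  seq(0, by = sample_dt, length.out = n_pts)
}

# Indices into a trajectory's time grid matching the loss grid exactly
# (the integrator's save points must include the loss times; no
# interpolation is permitted in the loss).
loss_grid_index <- function(traj, obj_cfg) {
  grid <- loss_grid(max(traj$times), obj_cfg$sample_dt)
  idx <- round(grid / traj$dt) + 1L
  ok <- idx >= 1L & idx <= length(traj$times) &
    abs(traj$times[pmin(idx, length(traj$times))] - grid) < traj$dt * 1e-6
  if (!all(ok)) {
    stop("tracking_loss: loss grid point outside or misaligned with the ",
         "trajectory time grid; choose dt dividing sample_dt")
  }
  idx
}

#' Circadian tracking loss
#'
#' Sum over the loss grid of the squared gap between the Hill-transformed
#' readout abundance and the Hill-transformed target rhythm:
#' `L = sum_t [ y_t^2/(S^2 + y_t^2) - v_t^2/(half + v_t^2) ]^2`.
#' Trajectory values at grid times are taken from the integrator's own save
#' points (the grid must align with the trajectory's `dt`).
#'
#' @param traj A `grn_trajectory` covering the grid.
#' @param obj_cfg An [objective_config()].
#' @param target A [circadian_target()].
#' @return Nonnegative scalar loss.
#' @export
tracking_loss <- function(traj, obj_cfg = objective_config(),
                          target = circadian_target()) {
  idx <- loss_grid_index(traj, obj_cfg)
  y <- traj$y[idx, obj_cfg$readout_gene]
  v <- eval_target(traj$times[idx], target)
  sum((hill_state(y, obj_cfg$S) -
         target_transform(v, obj_cfg$target_half))^2)
}

#' Growing-horizon curriculum
#'
#' Training first fits a short prefix of the target pattern, then lengthens
#' the fitted time range in stages; the default stages end at the 4-day
#' final training horizon.
#'
#' @param horizons Strictly increasing positive stage horizons, days.
#' @param steps_per_stage Optimizer iterations per stage (scalar or one
#'   per stage).
#' @return An object of class `curriculum_schedule`.
#' @export
curriculum_schedule <- function(horizons = c(0.5, 1, 2, 3, 4),
                                steps_per_stage = 100L) {
  if (!length(horizons) || any(horizons <= 0) ||
      any(diff(horizons) <= 0)) {
    stop("curriculum_schedule: `horizons` must be strictly increasing ",
         "and positive")
  }
  structure(list(horizons = as.numeric(horizons),
                 steps_per_stage = rep_len(as.integer(steps_per_stage),
                                           length(horizons))),
            class = "curriculum_schedule")
}
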