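#' Circadian target rhythm
#'
#' The deterministic daily target that the readout transcription factor (TF 1)
#' must track: \eqn{v(t) = (\sin(2\pi t + \pi) + 1)/2} with \eqn{t} in days.
#' The value crosses 0.5 at every integer (dusk) and half-integer (dawn) day,
#' marking the transitions between night and day; the cell is considered to be
#' in its daytime state while \eqn{v(t) > 0.5}.
#'
#' @param period Period of the rhythm in days. Fixed at 1 for the circadian
#'   problem; kept as a field so the object is self-describing.
#' @return An object of class `circadian_target`.
#' @export
circadian_target <- function(period = 1) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  structure(list(period = period), class = "circadian_target")
}

#' Evaluate the circadian target rhythm
#'
#' @param t Time(s) in days; any finite numeric vector.
#' @param target A [circadian_target()] object.
#' @return `v(t)` in `[0, 1]`, periodic with the target's period.
#' @examples
#' eval_target(c(0, 0.25, 0.5, 0.75))  # 0.5, 0, 0.5, 1
#' @export
eval_target <- function(t, target = circadian_target()) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  (sin(2 * pi * t / target$period + pi) + 1) / 2
}

#' Light signal configuration
#'
#' The external circadian light signal switches on and off at random, with
#' exponentially distributed waiting times between switches. While on, it
#' boosts the production of the light-sensing TF by
#' `amplitude * v(t)^sharpness_exponent`, a sharp daytime pulse peaking at
#' `amplitude` molecules/day at midday.
#'
#' @param mean_wait Mean waiting time between switches, days (> 0).
#' @param initial_on Logical; signal state at time 0 (default off).
#' @param amplitude Peak production boost, molecules/day.
#' @param sharpness_exponent Exponent applied to the target rhythm when
#'   shaping the daylight pulse.
#' @param seed Default seed used when sampling schedules from this config.
#' @return An object of class `light_config`.
#' @export
light_config <- function(mean_wait = 2, initial_on = FALSE, amplitude = 1e6,
                         sharpness_exponent = 4, seed = 1L) {
  if (!is.numeric(mean_wait) || length(mean_wait) != 1L || !is.finite(mean_wait) ||
      mean_wait <= 0) {
    stop("light_config: `mean_wait` must be a single positive number (days)")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("light_config: `amplitude` must be a single nonnegative number")
  }
  stopifnot(is.logical(initial_on), length(initial_on) == 1L)
  structure(
    list(mean_wait = as.numeric(mean_wait), initial_on = initial_on,
         amplitude = as.numeric(amplitude),
         sharpness_exponent = as.numeric(sharpness_exponent),
         seed = as.integer(seed)),
    class = "light_config"
  )
}

#' Sample a realization of the on/off light-switching process
#'
#' Waiting times between consecutive switches (including the wait before the
#' first switch) are i.i.d. exponential with mean `cfg$mean_wait`. The signal
#' starts in `cfg$initial_on` at time 0 and flips state at each switch time.
#'
#' @param cfg A [light_config()].
#' @param horizon Length of the schedule, days (>= 0).
#' @param seed Integer seed; defaults to the config's seed.
#' @return An object of class `light_schedule` with fields `switch_times`,
#'   `initial_on`, `horizon`.
#' @export
sample_light_schedule <- function(cfg = light_config(), horizon,
                                  seed = cfg$seed) {
  if (cfg$mean_wait <= 0) stop("sample_light_schedule: mean_wait must be > 0")
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 0)
  switch_times <- local_seed(seed, {
    if (horizon == 0) numeric(0) else {
      waits <- numeric(0)
      repeat {
        remaining <- horizon - sum(waits)
        k <- max(64L, ceiling(1.5 * remaining / cfg$mean_wait))
        waits <- c(waits, stats::rexp(k, rate = 1 / cfg$mean_wait))
        if (sum(waits) > horizon) break
      }
      ct <- cumsum(waits)
      ct[ct <= horizon]
    }
  })
  light_schedule(switch_times, initial_on = cfg$initial_on, horizon = horizon)
}

#' Construct a light schedule from explicit switch times
#'
#' @param switch_times Strictly increasing switch times within `[0, horizon]`.
#' @param initial_on State before the first switch.
#' @param horizon Schedule horizon, days.
#' @return A `light_schedule` object.
#' @export
light_schedule <- function(switch_times = numeric(0), initial_on = FALSE,
                           horizon) {
  stopifnot(is.numeric(switch_times), is.logical(initial_on),
            length(initial_on) == 1L, is.numeric(horizon),
            length(horizon) == 1L, horizon >= 0)
  if (length(switch_times)) {
    if (any(diff(switch_times) <= 0)) {
      stop("light_schedule: switch_times must be strictly increasing")
    }
    if (min(switch_times) < 0 || max(switch_times) > horizon) {
      stop("light_schedule: switch_times must lie within [0, horizon]")
    }
  }
  structure(list(switch_times = as.numeric(switch_times),
                 initial_on = initial_on, horizon = as.numeric(horizon)),
            class = "light_schedule")
}

#' On/off state of the light signal at given times
#'
#' The state is piecewise constant and right-continuous: evaluation at an
#' exact switch time returns the post-switch state.
#'
#' @param schedule A `light_schedule`.
#' @param t Times in days, each within `[0, horizon]`.
#' @return Logical vector, `TRUE` where the signal is on.
#' @export
light_state <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(t < 0 | t > schedule$horizon)) {
    stop("light_state: time outside schedule horizon [0, ",
         schedule$horizon, "]")
  }
  n_before <- findInterval(t, schedule$switch_times)  # count of switches <= t
  xor(schedule$initial_on, n_before %% 2L == 1L)
}

#' Light-input forcing term
#'
#' Production boost delivered to the light-sensing TF:
#' `amplitude * v(t)^p` while the signal is on, 0 while off.
#'
#' @param t Times in days.
#' @param schedule A `light_schedule` covering `t`.
#' @param cfg The [light_config()] supplying amplitude and exponent.
#' @return Nonnegative rates, molecules/day.
#' @export
light_input <- function(t, schedule, cfg = light_config()) {
  on <- light_state(schedule, t)
  v <- eval_target(t)
  ifelse(on, cfg$amplitude * v^cfg$sharpness_exponent, 0)
}

#' Write / read a light schedule as CSV
#'
#' Two columns (`switch_time_days`, `new_state`) plus comment lines carrying
#' the initial state and horizon, so a schedule round-trips through a single
#' plain-text file.
#'
#' @param schedule A `light_schedule`.
#' @param path File path.
#' @return `write_light_schedule` returns `path` invisibly;
#'   `read_light_schedule` returns the reconstructed `light_schedule`.
#' @export
write_light_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  st <- schedule$switch_times
  states <- if (length(st)) {
    xor(schedule$initial_on, seq_along(st) %% 2L == 1L)
  } else logical(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# initial_on: %s", schedule$initial_on),
    sprintf("# horizon_days: %s", format(schedule$horizon, digits = 17)),
    "switch_time_days,new_state"
  ), con)
  if (length(st)) {
    writeLines(sprintf("%s,%s", format(st, digits = 17), states), con)
  }
  invisible(path)
}

#' @rdname write_light_schedule
#' @export
read_light_schedule <- function(path) {
  header <- readLines(path, n = 2L)
  initial_on <- as.logical(sub("^# initial_on: ", "", header[1L]))
  horizon <- as.numeric(sub("^# horizon_days: ", "", header[2L]))
  df <- utils::read.csv(path, comment.char = "#")
  light_schedule(df$switch_time_days, initial_on = initial_on,
                 horizon = horizon)
}
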