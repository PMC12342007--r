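#' Threshold crossing times of a series
#'
#' Linearly interpolated times at which a sampled series crosses a threshold
#' in the given direction. Strict-crossing convention: a series sitting
#' exactly at the threshold produces no crossings.
#'
#' @param times Increasing time grid.
#' @param values Series values aligned to `times`.
#' @param threshold Crossing level.
#' @param direction `"up"` (below to above) or `"down"`.
#' @return Numeric vector of crossing times (possibly empty).
#' @export
crossing_times <- function(times, values, threshold,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (direction == "down") {
    return(crossing_times(times, -values, -threshold, "up"))
  }
  v0 <- values[-length(values)]
  v1 <- values[-1L]
  hit <- v0 <= threshold & v1 > threshold & v1 > v0
  if (!any(hit)) return(numeric(0))
  i <- which(hit)
  frac <- (threshold - v0[i]) / (v1[i] - v0[i])
  times[i] + frac * (times[i + 1L] - times[i])
}

# Dawn times of the target rhythm (upward crossings of v = 0.5) within
# (0, d]: the target enters its daytime state at t = k + 0.5 for integer k.
target_dawn_times <- function(d) {
  seq_len(d) - 0.5
}

#' Daily circadian tracking deviations of one realization
#'
#' For each day of the trajectory, pairs the target's entry into daytime
#' (its upward crossing of 0.5, at half-integer days) with the cell's
#' nearest upward crossing of the readout TF abundance above the switch
#' threshold `S`, within a +/- 12 h window. The deviation is
#' `(cell time - target time) * 24` hours: negative when the cell enters its
#' daytime state early, positive when late. A day with no crossing inside
#' the window is censored.
#'
#' @param traj A `grn_trajectory` spanning an integer number of days >= 1.
#' @param obj_cfg An [objective_config()] (supplies `S` and the readout).
#' @param realization_id Integer label stored with the samples.
#' @return Data frame with columns `realization_id`, `day`,
#'   `deviation_hours` (`NA` when censored), `censored`.
#' @export
daily_deviations <- function(traj, obj_cfg = objective_config(),
                             realization_id = 1L) {
  d <- floor(max(traj$times) + 1e-9)
  if (d < 1) stop("daily_deviations: trajectory shorter than one day")
  y <- traj$y[, obj_cfg$readout_gene]
  cell_cross <- crossing_times(traj$times, y, obj_cfg$S, "up")
  dawns <- target_dawn_times(d)
  dev <- vapply(dawns, function(td) {
    if (!length(cell_cross)) return(NA_real_)
    gaps <- cell_cross - td
    gaps <- gaps[abs(gaps) <= 0.5]
    if (!length(gaps)) return(NA_real_)
    gaps[which.min(abs(gaps))] * 24
  }, numeric(1))
  data.frame(realization_id = as.integer(realization_id),
             day = seq_len(d),
             deviation_hours = dev,
             censored = is.na(dev))
}

#' Ensemble of daily deviations over stochastic replicates
#'
#' Simulates `n_reps` independent stochastic realizations of `d` days from a
#' trained checkpoint (fresh light schedule and Wiener path per replicate)
#' and collects every daily deviation, censored days included: exactly
#' `n_reps * d` samples.
#'
#' @param ckpt A `grn_checkpoint` (or list with `net` and `kin`).
#' @param d Days per realization (>= 1).
#' @param n_reps Number of realizations (>= 1).
#' @param light_cfg A [light_config()]; its `mean_wait` is the erraticness
#'   of the entrainment signal.
#' @param seed Master seed.
#' @param sim_cfg A [sim_config()].
#' @param obj_cfg An [objective_config()].
#' @param init Initial state (default all abundances 10).
#' @return Data frame as in [daily_deviations()], `n_reps * d` rows. A
#'   replicate whose simulation fails is recorded with all days censored and
#'   noted in the `failed` attribute.
#' @export
ensemble_deviations <- function(ckpt, d, n_reps,
                                light_cfg = light_config(), seed = 1L,
                                sim_cfg = sim_config(),
                                obj_cfg = objective_config(), init = NULL) {
  stopifnot(n_reps >= 1, d >= 1)
  seeds <- derive_seeds(seed, 2L * n_reps)
  failed <- integer(0)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sched <- sample_light_schedule(light_cfg, d, seed = seeds[2L * r - 1L])
    cfg_r <- sim_cfg
    cfg_r$seed <- seeds[2L * r]
    res <- tryCatch({
      traj <- simulate_grn(ckpt$kin, ckpt$net, sched, cfg_r, d,
                           init = init, light_cfg = light_cfg)
      daily_deviations(traj, obj_cfg, realization_id = r)
    }, error = function(e) {
      failed <<- c(failed, r)
      data.frame(realization_id = r, day = seq_len(d),
                 deviation_hours = NA_real_, censored = TRUE)
    })
    out[[r]] <- res
  }
  res <- do.call(rbind, out)
  attr(res, "failed") <- failed
  res
}

#' Percentile summary of deviation samples
#'
#' The 5th, 25th, 50th, 75th and 95th percentiles of the uncensored
#' deviations, with sample accounting.
#'
#' @param samples Data frame from [daily_deviations()] /
#'   [ensemble_deviations()].
#' @return Object of class `percentile_summary`: list with `p5`, `p25`,
#'   `p50`, `p75`, `p95` (hours), `n_samples`, `n_censored`.
#' @export
summarize_deviations <- function(samples) {
  dev <- samples$deviation_hours[!samples$censored]
  if (!length(dev)) {
    stop("summarize_deviations: all samples censored; no usable deviations")
  }
  q <- stats::quantile(dev, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  structure(list(p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
                 n_samples = nrow(samples),
                 n_censored = sum(samples$censored)),
            class = "percentile_summary")
}

#' @export
print.percentile_summary <- function(x, ...) {
  cat(sprintf(
    "deviation percentiles (h): p5 %.3g  p25 %.3g  p50 %.3g  p75 %.3g  p95 %.3g  (%d samples, %d censored)\n",
    x$p5, x$p25, x$p50, x$p75, x$p95, x$n_samples, x$n_censored))
  invisible(x)
}

#' Input-output surfaces of a regulatory network
#'
#' Evaluates one gene's transcription-rate function over a grid of TF
#' abundances: two inner axes (default TFs 1 and 2) are swept over a grid
#' that is uniform in `log10(1 + y)`, while the remaining TFs are held at
#' each combination of a small number of levels on the same scale, one
#' output matrix per combination.
#'
#' @param net A `net_params` object.
#' @param gene Index of the output gene.
#' @param inner Two TF indices forming the matrix axes (rows = first).
#' @param inner_points Grid points per inner axis.
#' @param outer_levels Levels per remaining TF.
#' @param y_max Upper abundance bound, molecules (> 0).
#' @return List of class `io_surface`: `surfaces` (list of matrices, values
#'   in (0,1)), `inner`, `inner_abund` (axis abundances), `outer` (data
#'   frame of the outer-level abundances per matrix).
#' @export
io_surface <- function(net, gene, inner = c(1L, 2L), inner_points = 20L,
                       outer_levels = 3L, y_max = 1e4) {
  stopifnot(inherits(net, "net_params"), gene >= 1, gene <= net$n,
            length(inner) == 2L, all(inner >= 1), all(inner <= net$n))
  if (y_max <= 0) stop("io_surface: `y_max` must be > 0 on a log axis")
  n <- net$n
  axis_vals <- function(k) 10^seq(0, log10(1 + y_max), length.out = k) - 1
  inner_abund <- axis_vals(inner_points)
  outer_genes <- setdiff(seq_len(n), inner)
  outer_grid <- if (length(outer_genes)) {
    do.call(expand.grid,
            stats::setNames(rep(list(axis_vals(outer_levels)),
                                length(outer_genes)),
                            paste0("tf", outer_genes)))
  } else data.frame(row.names = 1)
  surfaces <- lapply(seq_len(nrow(outer_grid)), function(g) {
    pts <- as.matrix(expand.grid(row = inner_abund, col = inner_abund))
    Y <- matrix(0, nrow(pts), n)
    Y[, inner[1]] <- pts[, 1]
    Y[, inner[2]] <- pts[, 2]
    for (j in seq_along(outer_genes)) {
      Y[, outer_genes[j]] <- outer_grid[g, j]
    }
    matrix(net_forward(net, Y)[, gene], inner_points, inner_points)
  })
  structure(list(surfaces = surfaces, gene = gene, inner = inner,
                 inner_abund = inner_abund, outer = outer_grid),
            class = "io_surface")
}

#' Export an input-output surface stack
#'
#' Writes one CSV matrix per outer-level combination plus an `index.json`
#' describing the gene, axes and levels.
#'
#' @param surf An `io_surface` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_io_surface <- function(surf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("surface_gene%d_%03d.csv", surf$gene,
                   seq_along(surf$surfaces))
  for (i in seq_along(surf$surfaces)) {
    utils::write.table(surf$surfaces[[i]], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(schema = "tfsde-surface-1", gene = surf$gene, inner = surf$inner,
         inner_abundances = surf$inner_abund,
         outer_levels = surf$outer, files = files),
    file.path(dir, "index.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Export deviation samples as CSV
#'
#' @param samples Data frame from [ensemble_deviations()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_deviations_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
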