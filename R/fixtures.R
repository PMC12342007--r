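# Hand-built regulatory rules and oracle trajectories: everything needed to
# exercise the simulator, objective, training and analysis code without a
# long optimization run.

#' Hill regulatory rule
#'
#' A classical one-regulator Hill input-output function standing in for a
#' learned network: repression `K^h / (K^h + y_r^h)` or activation
#' `y_r^h / (K^h + y_r^h)`.
#'
#' @param regulator Index of the regulating TF.
#' @param K Half-max abundance, molecules (> 0).
#' @param h Hill coefficient (> 0).
#' @param mode `"repression"` or `"activation"`.
#' @return Object of class `hill_rule`.
#' @export
hill_rule <- function(regulator, K, h = 2, mode = c("repression",
                                                    "activation")) {
  mode <- match.arg(mode)
  if (K <= 0 || h <= 0) stop("hill_rule: `K` and `h` must be > 0")
  structure(list(regulator = as.integer(regulator), K = as.numeric(K),
                 h = as.numeric(h), mode = mode), class = "hill_rule")
}

#' Evaluate a Hill rule
#'
#' @param rule A [hill_rule()].
#' @param y Abundance vector (or matrix with genes in columns).
#' @return Values in (0, 1) (1 attained only in limits).
#' @export
hill_rule_eval <- function(rule, y) {
  yr <- if (is.matrix(y)) y[, rule$regulator] else y[rule$regulator]
  act <- yr^rule$h / (rule$K^rule$h + yr^rule$h)
  if (rule$mode == "repression") 1 - act else act
}

#' Cyclic-repression (repressilator) rule set
#'
#' Gene `i` is repressed by gene `i - 1` (mod `n`): the classic ring circuit
#' whose odd-size version sustains limit-cycle oscillations. The even ring
#' may settle to a fixed point instead; it is used for input-output surface
#' tests, not oscillation tests.
#'
#' @param n Ring size, 3 or 4.
#' @param K Half-max abundance of each repression edge.
#' @param h Hill coefficient.
#' @return List of `n` [hill_rule()]s.
#' @export
make_repressilator <- function(n = 3L, K = 500, h = 2) {
  if (!n %in% c(3L, 4L)) stop("make_repressilator: `n` must be 3 or 4")
  lapply(seq_len(n), function(i) {
    hill_rule(regulator = if (i == 1L) n else i - 1L, K = K, h = h,
              mode = "repression")
  })
}

#' Default kinetics and initial state for the repressilator fixture
#'
#' Uniform rates `m = 30000`/day, `delta = 12`/day, `s = 12`/day,
#' `gamma = 6`/day keep protein counts in the 10^2-10^4 molecule range while
#' making the maximal protein level (`s m / (gamma delta) = 5000`) an order
#' of magnitude above the repression half-max `K = 500`, which puts the
#' 3-gene ring's loop gain well past the Hopf threshold at Hill coefficient
#' 2: the deterministic ring then sustains limit-cycle oscillations with a
#' sub-day period. `repressilator_init` supplies the matching staggered
#' initial state (decade-spaced abundances across the ring) that breaks the
#' rotational symmetry, without which trajectories linger near the unstable
#' symmetric fixed point.
#'
#' @param n Number of genes.
#' @return `repressilator_kinetics`: a [kinetic_params()];
#'   `repressilator_init`: a [system_state()].
#' @export
repressilator_kinetics <- function(n = 3L) {
  kinetic_params(m = 30000, delta = 12, s = 12, gamma = 6, n = n)
}

#' @rdname repressilator_kinetics
#' @export
repressilator_init <- function(n = 3L) {
  system_state(100 / 10^(seq_len(n) - 1L), 500 / 10^(seq_len(n) - 1L))
}

# ---- fitting a network to a rule set ---------------------------------------

# Single-gene dense net evaluated on a matrix of transformed inputs R (N x n).
gene_net_forward <- function(par, R, h) {
  n <- ncol(R)
  W1 <- matrix(par[seq_len(h * n)], h, n)
  b1 <- par[h * n + seq_len(h)]
  w2 <- par[h * n + h + seq_len(h)]
  b2 <- par[h * n + 2L * h + 1L]
  A <- R %*% t(W1)
  A <- sweep(A, 2L, b1, "+")
  Hm <- mish(A)
  sigmoid(drop(Hm %*% w2) + b2)
}

gene_net_obj <- function(par, R, target, h) {
  f <- gene_net_forward(par, R, h)
  mean((f - target)^2)
}

gene_net_grad <- function(par, R, target, h) {
  n <- ncol(R)
  N <- nrow(R)
  W1 <- matrix(par[seq_len(h * n)], h, n)
  b1 <- par[h * n + seq_len(h)]
  w2 <- par[h * n + h + seq_len(h)]
  A <- sweep(R %*% t(W1), 2L, b1, "+")
  Hm <- mish(A)
  z <- drop(Hm %*% w2) + par[h * n + 2L * h + 1L]
  f <- sigmoid(z)
  dz <- 2 * (f - target) * f * (1 - f) / N
  dw2 <- drop(crossprod(Hm, dz))
  db2 <- sum(dz)
  dA <- (dz %*% t(w2)) * mish_grad(A)
  db1 <- colSums(dA)
  dW1 <- crossprod(dA, R)           # h x n
  c(as.vector(dW1), db1, dw2, db2)
}

#' Fit a regulatory network to a set of Hill rules
#'
#' Least-squares fit of the two-layer network architecture to prescribed
#' per-gene Hill rules over a log-spaced abundance grid, producing
#' `net_params` whose [net_forward()] reproduces a known circuit (e.g. the
#' repressilator ring) to within `tol`.
#'
#' @param rules List of [hill_rule()]s, one per gene.
#' @param n Number of genes (defaults to `length(rules)`).
#' @param seed Seed for grid sampling and initialization.
#' @param tol Maximum absolute error required on the training grid.
#' @param y_max Upper abundance bound of the fitting grid, molecules.
#' @param n_points Number of abundance vectors in the fitting grid.
#' @param width_factor Hidden width per input (default 5, the standard
#'   architecture).
#' @return A `net_params` object; the achieved training-grid error is
#'   attached as attribute `fit_error`. Errors above `tol` abort.
#' @export
fit_net_to_rules <- function(rules, n = length(rules), seed = 1L,
                             tol = 0.05, y_max = 1e4, n_points = 400L,
                             width_factor = 5L) {
  stopifnot(length(rules) == n)
  h <- as.integer(width_factor) * n
  grid <- fit_grid(n, n_points, y_max, seed)
  R <- log1p(grid)
  seeds <- derive_seeds(seed, 3L * n)
  genes <- vector("list", n)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    target <- hill_rule_eval(rules[[i]], grid)
    best <- NULL
    for (attempt in 1:3) {
      par0 <- local_seed(seeds[3L * (i - 1L) + attempt],
                         stats::rnorm(h * n + 2L * h + 1L, sd = 0.5))
      opt <- stats::optim(par0, gene_net_obj, gene_net_grad,
                          R = R, target = target, h = h,
                          method = "L-BFGS-B",
                          control = list(maxit = 600L))
      err <- max(abs(gene_net_forward(opt$par, R, h) - target))
      if (is.null(best) || err < best$err) best <- list(par = opt$par,
                                                        err = err)
      if (best$err <= tol) break
    }
    if (best$err > tol) {
      stop(sprintf(
        "fit_net_to_rules: gene %d missed tol %.3g (achieved %.3g)",
        i, tol, best$err))
    }
    errs[i] <- best$err
    W1 <- matrix(best$par[seq_len(h * n)], h, n)
    b1 <- best$par[h * n + seq_len(h)]
    w2 <- best$par[h * n + h + seq_len(h)]
    b2 <- best$par[h * n + 2L * h + 1L]
    genes[[i]] <- list(l1_alpha = matrix(b1 / n, h, n), l1_beta = W1,
                       head_alpha = rep(b2 / h, h), head_beta = w2)
  }
  net <- net_params(n, genes, width_factor = as.integer(width_factor),
                    input_transform = "log1p")
  attr(net, "fit_error") <- max(errs)
  net
}

# Log-uniform abundance vectors in [0, y_max], plus the zero corner.
fit_grid <- function(n, n_points, y_max, seed) {
  pts <- local_seed(seed, {
    matrix(10^stats::runif(n_points * n, 0, log10(1 + y_max)) - 1,
           n_points, n)
  })
  rbind(pts, 0)
}

#' Shifted perfect-tracking trajectory (analysis oracle)
#'
#' Builds a trajectory whose readout TF abundance, passed through the
#' objective's Hill transform, equals the transformed target rhythm delayed
#' by `shift_hours` exactly; other genes are held constant. Feeding it to
#' [daily_deviations()] must recover `shift_hours` on every day, and with
#' zero shift its [tracking_loss()] is 0.
#'
#' @param shift_hours Time shift in hours, within +/- 12.
#' @param d Whole days spanned (>= 1).
#' @param obj_cfg An [objective_config()].
#' @param n Number of genes in the synthetic trajectory.
#' @param dt Sampling step, days (must divide `obj_cfg$sample_dt`).
#' @return A `grn_trajectory`.
#' @export
make_shifted_tracking_trajectory <- function(shift_hours, d,
                                             obj_cfg = objective_config(),
                                             n = 4L, dt = 0.002) {
  if (abs(shift_hours) > 12) {
    stop("make_shifted_tracking_trajectory: |shift| must be <= 12 h")
  }
  times <- seq(0, d, by = dt)
  v <- eval_target(times - shift_hours / 24)
  vt <- target_transform(v, obj_cfg$target_half)
  y1 <- obj_cfg$S * sqrt(vt / (1 - vt))
  y <- matrix(10, length(times), n)
  y[, obj_cfg$readout_gene] <- y1
  x <- matrix(10, length(times), n)
  new_trajectory(times, x, y, rep(FALSE, length(times)), dt)
}
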