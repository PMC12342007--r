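#' Mish activation
#'
#' `mish(r) = r * tanh(softplus(r))`, evaluated with an overflow-safe
#' softplus so large positive and negative arguments behave correctly.
#'
#' @param r Numeric vector.
#' @return `mish(r)`, same shape as `r`.
#' @export
mish <- function(r) {
  r * tanh(softplus(r))
}

# Numerically stable softplus log(1 + e^r) = max(r, 0) + log1p(e^-|r|).
softplus <- function(r) {
  pmax(r, 0) + log1p(exp(-abs(r)))
}

# d mish / dr, needed by the pathwise gradients.
mish_grad <- function(r) {
  sp <- softplus(r)
  th <- tanh(sp)
  sig <- 1 / (1 + exp(-r))
  th + r * (1 - th^2) * sig
}

#' Logistic sigmoid
#'
#' @param r Numeric vector.
#' @return `1 / (1 + exp(-r))`, strictly in (0, 1) for finite `r`.
#' @export
sigmoid <- function(r) {
  1 / (1 + exp(-r))
}

#' Per-gene regulatory networks
#'
#' Each gene's relative transcription rate \eqn{f_i(\mathbf{y}) \in (0,1)} is
#' computed by a small two-layer network: `n` inputs (transformed TF
#' abundances), one hidden layer of `width_factor * n` mish units, and a
#' sigmoid head. Every input-to-hidden edge carries its own affine pair
#' (alpha, beta), as does every hidden-to-head edge, giving
#' `10 n^3 + 10 n^2` scalar parameters across the `n` genes at the default
#' width factor of 5. Per-node the alphas collapse to a single bias
#' (their sum), so a dense-layer evaluation is used internally.
#'
#' `init_params` draws all alphas and betas i.i.d. from
#' `Normal(0, scale^2)`; with `scale = 0` every output is exactly 0.5.
#'
#' @param n Number of transcription factors (genes), >= 1.
#' @param seed Integer seed; draws are reproducible.
#' @param scale Standard deviation of the initial parameter distribution.
#' @param width_factor Hidden-layer width per input (default 5).
#' @param input_transform How protein abundances enter the network:
#'   `"log1p"` (default; defined at zero abundance) or `"log"`.
#' @return An object of class `net_params`: a list with `n`,
#'   `width_factor`, `input_transform`, and per-gene matrices
#'   `l1_alpha`, `l1_beta` (hidden x n) and vectors `head_alpha`,
#'   `head_beta` (length hidden).
#' @export
init_params <- function(n, seed = 1L, scale = 0.1, width_factor = 5L,
                        input_transform = c("log1p", "log")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("init_params: `n` must be a positive integer")
  }
  input_transform <- match.arg(input_transform)
  n <- as.integer(n)
  h <- as.integer(width_factor) * n
  genes <- local_seed(seed, lapply(seq_len(n), function(i) {
    list(
      l1_alpha   = matrix(stats::rnorm(h * n, sd = scale), h, n),
      l1_beta    = matrix(stats::rnorm(h * n, sd = scale), h, n),
      head_alpha = stats::rnorm(h, sd = scale),
      head_beta  = stats::rnorm(h, sd = scale)
    )
  }))
  net_params(n, genes, width_factor = as.integer(width_factor),
             input_transform = input_transform)
}

#' @rdname init_params
#' @param genes List of per-gene parameter sets (see return value).
#' @export
net_params <- function(n, genes, width_factor = 5L,
                       input_transform = "log1p") {
  n <- as.integer(n)
  h <- as.integer(width_factor) * n
  stopifnot(length(genes) == n)
  for (g in genes) {
    stopifnot(identical(dim(g$l1_alpha), c(h, n)),
              identical(dim(g$l1_beta), c(h, n)),
              length(g$head_alpha) == h, length(g$head_beta) == h)
    if (!all(vapply(g, function(p) all(is.finite(p)), logical(1)))) {
      stop("net_params: all parameters must be finite")
    }
  }
  structure(list(n = n, width_factor = as.integer(width_factor),
                 input_transform = input_transform, genes = genes),
            class = "net_params")
}

#' @export
print.net_params <- function(x, ...) {
  cat(sprintf("net_params: %d genes, %d hidden units/gene, %d parameters (%s inputs)\n",
              x$n, x$width_factor * x$n, net_param_count(x),
              x$input_transform))
  invisible(x)
}

#' Number of scalar parameters in a network
#'
#' @param net A `net_params` object.
#' @return Integer count (`10 n^3 + 10 n^2` at width factor 5).
#' @export
net_param_count <- function(net) {
  h <- net$width_factor * net$n
  net$n * (2L * h * net$n + 2L * h)
}

# Dense-layer equivalent of the per-edge parameterization: per-node bias is
# the row sum of the alphas, the betas are the weights. Returns stacked
# matrices shared by the fast forward pass and the C++ integrator:
#   W1 ((n*h) x n, gene blocks stacked), b1 (n*h),
#   W2 (h x n, one column per gene), b2 (n).
net_dense <- function(net) {
  n <- net$n
  h <- net$width_factor * n
  W1 <- do.call(rbind, lapply(net$genes, function(g) g$l1_beta))
  b1 <- unlist(lapply(net$genes, function(g) rowSums(g$l1_alpha)),
               use.names = FALSE)
  W2 <- vapply(net$genes, function(g) g$head_beta, numeric(h))
  b2 <- vapply(net$genes, function(g) sum(g$head_alpha), numeric(1))
  list(n = n, h = h, W1 = W1, b1 = b1, W2 = matrix(W2, h, n), b2 = b2,
       log_input = identical(net$input_transform, "log"))
}

# Rebuild per-edge net_params from a dense form, distributing each node bias
# uniformly across its edges (the per-edge alphas are degenerate: only their
# sum enters the computation).
net_from_dense <- function(dense, width_factor, input_transform) {
  n <- dense$n
  h <- dense$h
  genes <- lapply(seq_len(n), function(i) {
    rows <- ((i - 1L) * h + 1L):(i * h)
    list(
      l1_alpha   = matrix(dense$b1[rows] / n, h, n),
      l1_beta    = dense$W1[rows, , drop = FALSE],
      head_alpha = rep(dense$b2[i] / h, h),
      head_beta  = dense$W2[, i]
    )
  })
  net_params(n, genes, width_factor = width_factor,
             input_transform = input_transform)
}

net_input <- function(net, y) {
  if (identical(net$input_transform, "log")) log(y) else log1p(y)
}

#' Evaluate the regulatory networks
#'
#' Maps a vector of TF protein abundances to the `n` relative transcription
#' rates. Abundances are log-transformed on entry (see
#' [init_params()] `input_transform`); every output lies strictly in (0, 1).
#'
#' @param net A `net_params` object.
#' @param y Nonnegative abundance vector of length `n`, or a matrix with
#'   `n` columns (one row per evaluation point).
#' @return Rate-fraction vector of length `n`, or a matrix of the same
#'   row count as `y`.
#' @export
net_forward <- function(net, y) {
  stopifnot(inherits(net, "net_params"))
  d <- net_dense(net)
  if (is.matrix(y)) {
    if (ncol(y) != net$n) stop("net_forward: y must have n = ", net$n,
                               " columns")
    if (any(y < 0)) stop("net_forward: abundances must be >= 0")
    r <- net_input(net, y)                       # N x n
    a <- r %*% t(d$W1)                           # N x (n*h)
    a <- sweep(a, 2L, d$b1, "+")
    hmat <- mish(a)
    z <- vapply(seq_len(net$n), function(i) {
      cols <- ((i - 1L) * d$h + 1L):(i * d$h)
      hmat[, cols, drop = FALSE] %*% d$W2[, i] + d$b2[i]
    }, numeric(nrow(y)))
    sigmoid(matrix(z, nrow(y), net$n))
  } else {
    if (length(y) != net$n) stop("net_forward: y must have length n = ",
                                 net$n)
    if (any(y < 0)) stop("net_forward: abundances must be >= 0")
    r <- net_input(net, y)
    a <- drop(d$W1 %*% r) + d$b1
    hvec <- mish(a)
    hm <- matrix(hvec, d$h, net$n)               # column per gene
    sigmoid(colSums(hm * d$W2) + d$b2)
  }
}

#' Serialize network parameters to JSON
#'
#' Writes the per-edge parameterization with explicit shape metadata; the
#' round trip is exact for finite doubles.
#'
#' @param net A `net_params` object.
#' @param path Output path (`.json`).
#' @return `write_net_params` returns `path` invisibly; `read_net_params`
#'   the reconstructed object.
#' @export
write_net_params <- function(net, path) {
  obj <- list(
    schema = "tfsde-net-1",
    n = net$n,
    width_factor = net$width_factor,
    input_transform = net$input_transform,
    genes = lapply(net$genes, function(g) list(
      layer1_alpha = g$l1_alpha,
      layer1_beta = g$l1_beta,
      head_alpha = g$head_alpha,
      head_beta = g$head_beta
    ))
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_net_params
#' @export
read_net_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "tfsde-net-1")) {
    stop("read_net_params: unsupported schema: ",
         obj$schema %||% "<missing>")
  }
  n <- as.integer(obj$n)
  h <- as.integer(obj$width_factor) * n
  as_mat <- function(rows) {  # list of rows (row-major) -> h x n matrix
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  genes <- lapply(obj$genes, function(g) {
    list(l1_alpha = as_mat(g$layer1_alpha),
         l1_beta = as_mat(g$layer1_beta),
         head_alpha = as.numeric(unlist(g$head_alpha)),
         head_beta = as.numeric(unlist(g$head_beta)))
  })
  net_params(n, genes, width_factor = as.integer(obj$width_factor),
             input_transform = obj$input_transform)
}
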