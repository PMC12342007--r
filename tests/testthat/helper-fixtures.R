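# Shared fixtures, built once per test run (the repressilator fit is the
# only moderately expensive constructor).

small_kinetics <- function(n = 3L) {
  kinetic_params(m = c(300, 200, 400)[seq_len(n)],
                 delta = c(6, 5, 7)[seq_len(n)],
                 s = c(6, 4, 5)[seq_len(n)],
                 gamma = c(3, 2, 4)[seq_len(n)], n = n)
}

repressilator_net_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_net_to_rules(make_repressilator(3L, K = 500, h = 2),
                                 n = 3L, seed = 1L, tol = 0.05)
    }
    cache
  }
})

# Local maxima / minima of a subsampled series (peak detection for
# oscillation checks).
series_peaks <- function(values, by = 10L) {
  sub <- values[seq(1L, length(values), by = by)]
  list(peaks = sub[which(diff(sign(diff(sub))) == -2) + 1L],
       troughs = sub[which(diff(sign(diff(sub))) == 2) + 1L])
}
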