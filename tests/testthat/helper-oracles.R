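# Independent brute-force oracles and shared fixtures. The oracles use
# plain double loops and no code paths from the package internals beyond
# the documented data layouts.

naive_shell_pairs <- function(points, eps, d_eps, theiler = 0) {
  N <- nrow(points)
  out <- NULL
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (j - i <= theiler) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d >= eps && d <= eps + d_eps) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

naive_growth <- function(points, pairs, t_max, dt = 1) {
  N <- nrow(points)
  ts <- seq(0, t_max, by = dt)
  ln_eps <- numeric(length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    acc <- rep(NA_real_, nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (max(i, j) + t > N) next
      d <- sqrt(sum((points[i + t, ] - points[j + t, ])^2))
      if (d > 0) acc[r] <- log(d)
    }
    ln_eps[k] <- mean(acc, na.rm = TRUE)
  }
  list(t = ts, ln_eps_t = ln_eps)
}

# mean |Lambda(t)| divergence summary recomputed from exported pieces only
naive_divergence_summary <- function(x, m, L, t_eval) {
  pts <- phase_embed(x, m, L)
  s <- sd(x)
  pairs <- find_shell_pairs(pts, list(eps = 0.1 * s, d_eps = s),
                            theiler = (m - 1) * L + 1)
  pairs <- pairs[pmax(pairs[, 1], pairs[, 2]) + t_eval <= nrow(pts), ,
                 drop = FALSE]
  g <- naive_growth(pts, pairs, t_eval)
  mean(abs(g$ln_eps_t[-1] - g$ln_eps_t[1]))
}

# small labelled synthetic feature table, computed once per test run
cached_features <- local({
  env <- new.env()
  function(n_per_class = 50, seed = 101) {
    key <- paste0("ft", n_per_class, "_", seed)
    if (is.null(env[[key]])) {
      ds <- gen_dataset(n_per_class, n_per_class, cfg = generator_config(),
                        seed = seed)
      env[[key]] <- feature_table(ds$epochs)
    }
    env[[key]]
  }
})

sine_epoch <- function(freq, fs = 256, n = 1024, amp = 1, channels = 1) {
  tt <- seq_len(n) / fs
  eeg_epoch(matrix(rep(amp * sin(2 * pi * freq * tt), channels),
                   nrow = channels, byrow = TRUE), fs)
}
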