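#' Fit the scale-dependent Lyapunov exponent of a series
#'
#' The central estimator of the package. The scalar series is delay-embedded
#' (dimension `m`, delay `L`), within-shell vector pairs are evolved into
#' error-growth curves for a cascade of shells (first shell 1/10 of the
#' signal SD, successive shells shrinking by 1/2), the curves are
#' differentiated into SDLE curves lambda(eps), averaged, and the scaling
#' law `lambda ~ -gamma ln eps` is fitted; the feature scales eps1/eps2/eps3
#' and their lambdas are read off the scaling region.
#'
#' @param x Numeric series (e.g. one EEG channel, microvolts).
#' @param m Embedding dimension (default 2).
#' @param L Embedding delay in samples (default 1, appropriate for 256 Hz
#'   EEG).
#' @param n_shells,first_fraction,shrink Shell cascade; see [build_shells()].
#' @param theiler Theiler exclusion window in samples; default
#'   `(m - 1) * L + 1`.
#' @param dt Evolution step in samples (default 1).
#' @param t_max Longest evolution time in samples (default 64, a quarter of
#'   a 4 s epoch at 256 Hz).
#' @param min_pairs Shells with fewer qualifying pairs are dropped
#'   (default 10).
#' @param max_pairs Optional cap on pairs per shell; beyond it an evenly
#'   spaced deterministic subsample is used (default `Inf`).
#' @param r2_min Scaling-region goodness-of-fit threshold (default 0.95).
#' @return Object of class `sdle`: list with the embedding parameters,
#'   `shells`, per-shell `growth` and `curves`, the averaged `curve`, the
#'   scaling `fit`, and `features` (an `sdle_features` object).
#' @seealso [epoch_sdle()] for the multi-channel per-epoch version.
#' @examples
#' x <- as.vector(stats::arima.sim(list(ar = 0.9), 1024))
#' f <- sdle(x)
#' coef(f)
#' @export
sdle <- function(x, m = 2, L = 1, n_shells = 4, first_fraction = 0.1,
                 shrink = 0.5, theiler = (m - 1) * L + 1, dt = 1,
                 t_max = 64, min_pairs = 10, max_pairs = Inf,
                 r2_min = 0.95) {
  x <- as.numeric(x)
  points <- phase_embed(x, m, L)
  shells <- build_shells(x, n_shells, first_fraction, shrink)
  N <- nrow(points)
  d <- as.vector(stats::dist(points))
  ii <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  jj <- sequence((N - 1L):1L) + ii
  pre <- which(d >= min(shells$eps) &
                 d <= max(shells$eps + shells$d_eps) &
                 (jj - ii) > theiler)
  d0 <- d[pre]; i0 <- ii[pre]; j0 <- jj[pre]

  growth <- vector("list", n_shells)
  curves <- vector("list", n_shells)
  n_pairs <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    eps <- shells$eps[s]
    sel <- which(d0 >= eps & d0 <= eps + shells$d_eps[s])
    n_pairs[s] <- length(sel)
    if (length(sel) < min_pairs) {
      message("shell ", shells$index[s], " (eps = ", signif(eps, 3),
              ") has ", length(sel), " pairs (< ", min_pairs, "); dropped")
      next
    }
    if (length(sel) > max_pairs)
      sel <- sel[round(seq(1, length(sel), length.out = max_pairs))]
    pairs <- cbind(i = i0[sel], j = j0[sel])
    growth[[s]] <- error_growth(points, pairs, t_max = t_max, dt = dt,
                                shell = shells[s, ])
    curves[[s]] <- sdle_from_growth(growth[[s]])
  }
  kept <- !vapply(curves, is.null, TRUE)
  if (!any(kept))
    stop("estimation error: no shell retained at least ", min_pairs,
         " pairs")
  curve <- average_sdle(curves[kept])
  fit <- fit_scaling(curve, r2_min = r2_min)
  g_largest <- growth[[which(kept)[1]]]     # largest retained shell
  feats <- sdle_features(curve, fit, growth = g_largest)
  structure(list(n = length(x), sd = stats::sd(x),
                 m = m, L = L, theiler = theiler, dt = dt, t_max = t_max,
                 shells = shells, n_pairs = n_pairs, kept = kept,
                 growth = growth[kept], curves = curves[kept],
                 curve = curve, fit = fit, features = feats,
                 channels = NULL, call = match.call()),
            class = "sdle")
}

#' Per-epoch, channel-averaged SDLE
#'
#' The per-epoch SDLE used for classification: the epoch is band-pass and
#' notch filtered, restricted to its `n_strongest` channels, the SDLE curve
#' is estimated per channel, the channel curves are averaged on a common
#' scale grid, and the scaling law and features are extracted from the
#' averaged curve. `eps_inf` and `T_db` are the channel means of the
#' per-channel values.
#'
#' @param epoch An [eeg_epoch].
#' @param cfg A [preprocess_config]; its `n_strongest` controls channel
#'   selection.
#' @param filter Apply [filter_epoch()] first (default TRUE).
#' @param max_pairs Per-shell pair cap (default 1000; a mean over 1000
#'   pairs is statistically ample and keeps large batch runs fast).
#' @param ... Passed to [sdle()] (`m`, `L`, `n_shells`, ...).
#' @return Object of class `sdle` whose `channels` element lists the
#'   selected channels.
#' @export
epoch_sdle <- function(epoch, cfg = preprocess_config(), filter = TRUE,
                       max_pairs = 1000, ...) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (filter) epoch <- filter_epoch(epoch, cfg)
  k <- min(cfg$n_strongest, nrow(epoch$data))
  epoch <- select_strongest(epoch, k)
  fits <- lapply(seq_len(nrow(epoch$data)), function(r)
    sdle(epoch$data[r, ], max_pairs = max_pairs, ...))
  curve <- average_sdle(lapply(fits, `[[`, "curve"))
  fit <- fit_scaling(curve)
  feats <- sdle_features(curve, fit)
  feats$eps_inf <- mean(vapply(fits, function(f) f$features$eps_inf, 0),
                        na.rm = TRUE)
  tdb <- vapply(fits, function(f) as.numeric(f$features$T_db), 0)
  feats$T_db <- if (all(is.na(tdb))) NA_real_ else mean(tdb, na.rm = TRUE)
  out <- fits[[1]]
  out$growth <- NULL
  out$curves <- lapply(fits, `[[`, "curve")
  out$curve <- curve
  out$fit <- fit
  out$features <- feats
  out$channels <- epoch$channel_names
  out$call <- match.call()
  out
}

#' @export
print.sdle <- function(x, ...) {
  cat("Scale-dependent Lyapunov exponent fit\n")
  cat(sprintf("  series: n = %d, sd = %.3g; embedding m = %d, L = %d\n",
              x$n, x$sd, x$m, x$L))
  if (!is.null(x$channels))
    cat("  channels averaged:", paste(x$channels, collapse = " "), "\n")
  print(x$fit)
  print(x$features)
  invisible(x)
}

#' @export
summary.sdle <- function(object, ...) {
  structure(list(fit = object), class = "summary.sdle")
}

#' @export
print.summary.sdle <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("Shells (eps, thickness, pairs):\n")
  print(cbind(f$shells, pairs = f$n_pairs, kept = f$kept))
  cat(sprintf("Averaged curve: %d points, ln(eps) in [%.3f, %.3f]\n",
              nrow(f$curve), min(f$curve$ln_eps), max(f$curve$ln_eps)))
  invisible(x)
}

#' @export
coef.sdle <- function(object, ...) {
  f <- object$features
  c(gamma = object$fit$gamma, lam1 = f$lam1, lam2 = f$lam2, lam3 = f$lam3,
    lam_bar = f$lam_bar)
}

#' Plot an SDLE fit
#'
#' `type = "sdle"` draws lambda(eps) against ln(eps) with the scaling
#' region and the fitted line; `type = "growth"` draws the per-shell
#' error-growth curves ln(eps_t) vs t.
#'
#' @param x An `sdle` object.
#' @param type `"sdle"` or `"growth"`.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.sdle <- function(x, type = c("sdle", "growth"), ...) {
  type <- match.arg(type)
  if (type == "growth") {
    if (is.null(x$growth) || length(x$growth) == 0L)
      stop("no growth curves stored on this object")
    rng <- range(unlist(lapply(x$growth, `[[`, "ln_eps_t")))
    graphics::plot(NA, xlim = c(0, x$t_max), ylim = rng,
                   xlab = "t (samples)", ylab = "ln eps_t", ...)
    for (s in seq_along(x$growth))
      graphics::lines(x$growth[[s]]$t, x$growth[[s]]$ln_eps_t, col = s)
    return(invisible(x))
  }
  graphics::plot(x$curve$ln_eps, x$curve$lambda, xlab = "ln eps",
                 ylab = "lambda(eps)", pch = 16, cex = 0.6, ...)
  reg <- x$fit$region
  graphics::abline(v = reg, lty = 3)
  xs <- seq(reg[1], reg[2], length.out = 50)
  graphics::lines(xs, x$fit$intercept + x$fit$slope * xs, col = 2, lwd = 2)
  invisible(x)
}
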