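# Scale-dependent Lyapunov exponent (SDLE) machinery: shells of pairwise
# phase-space distances, within-shell error-growth curves, their local
# slopes lambda(eps), the scaling-law fit lambda ~ -gamma ln eps, and the
# derived per-epoch features.

#' Build the shell cascade for a series
#'
#' Shell sizes follow the reproducibility recipe: the first (largest) shell
#' is 1/10 of the standard deviation of the signal and successive shells
#' shrink by a factor of 1/2; four shells by default. Each shell is the
#' annulus `[eps, eps + d_eps)` with `d_eps = eps` (one-octave shells), so
#' the cascade tiles a contiguous range of scales.
#'
#' @param x Numeric series (must not be constant).
#' @param n_shells Number of shells (default 4).
#' @param first_fraction Size of the first shell as a fraction of `sd(x)`
#'   (default 0.1).
#' @param shrink Shrink factor between successive shells (default 0.5).
#' @return Data frame with columns `index` (0 = largest), `eps` (inner
#'   diameter) and `d_eps` (thickness), in signal units.
#' @export
build_shells <- function(x, n_shells = 4, first_fraction = 0.1,
                         shrink = 0.5) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate input: constant series has no scale for shells")
  size <- first_fraction * s * shrink^(seq_len(n_shells) - 1)
  data.frame(index = seq_len(n_shells) - 1L, eps = size, d_eps = size)
}

as_shell <- function(shell) {
  if (is.data.frame(shell)) {
    stopifnot(nrow(shell) == 1L)
    shell <- as.list(shell)
  }
  if (is.null(shell$d_eps)) stop("shell must carry 'eps' and 'd_eps'")
  shell
}

#' Find within-shell vector pairs
#'
#' All index pairs (i, j), i < j, whose phase-space vectors satisfy
#' `eps <= ||V_i - V_j||_2 <= eps + d_eps` and whose temporal separation
#' exceeds the Theiler window (suppressing trivially correlated temporal
#' neighbours). The result is in lexicographic order.
#'
#' @param points Phase-space points from [phase_embed()] (rows are vectors).
#' @param shell One row of [build_shells()], or a list with `eps`, `d_eps`.
#' @param theiler Theiler exclusion: pairs with `|i - j| <= theiler` are
#'   dropped (default 0, no exclusion).
#' @return Two-column integer matrix of pair indices (possibly 0 rows).
#' @export
find_shell_pairs <- function(points, shell, theiler = 0) {
  points <- as.matrix(points)
  shell <- as_shell(shell)
  N <- nrow(points)
  if (N < 2L) return(cbind(i = integer(0), j = integer(0)))
  d <- as.vector(stats::dist(points))
  ii <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  jj <- sequence((N - 1L):1L) + ii
  sel <- d >= shell$eps & d <= shell$eps + shell$d_eps & (jj - ii) > theiler
  # dist() enumerates (1,2),(1,3),... which is already lexicographic
  cbind(i = ii[sel], j = jj[sel])
}

#' Evolve within-shell pairs into an error-growth curve
#'
#' For evolution times t = 0, dt, 2 dt, ... <= t_max, computes the mean over
#' pairs of `ln ||V_{i+t} - V_{j+t}||` (logarithm inside the average). Pairs
#' whose evolved indices run past the last vector are dropped at each t, and
#' `pair_count` records the survivors; pairs with numerically zero evolved
#' separation are excluded from that t's average.
#'
#' @param points Phase-space points from [phase_embed()].
#' @param pairs Two-column index matrix from [find_shell_pairs()].
#' @param t_max Largest evolution time in samples (default 64).
#' @param dt Evolution time step in samples (default 1).
#' @param shell Optional shell spec carried along for reporting.
#' @return Object of class `error_growth`: list with `t`, `ln_eps_t`,
#'   `pair_count`, `shell`.
#' @export
error_growth <- function(points, pairs, t_max = 64, dt = 1, shell = NULL) {
  points <- as.matrix(points)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("estimation error: no pairs to evolve")
  N <- nrow(points)
  i <- pairs[, 1]; j <- pairs[, 2]
  mx <- pmax(i, j)
  o <- order(mx)
  i <- i[o]; j <- j[o]; mx <- mx[o]
  ts <- seq(0, t_max, by = dt)
  ln_eps <- numeric(length(ts))
  cnt <- integer(length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    n_ok <- findInterval(N - t, mx)
    if (n_ok == 0L) {
      warning("all pairs exhausted at t = ", t, "; curve truncated")
      ts <- ts[seq_len(k - 1L)]
      ln_eps <- ln_eps[seq_len(k - 1L)]
      cnt <- cnt[seq_len(k - 1L)]
      break
    }
    it <- i[seq_len(n_ok)] + t
    jt <- j[seq_len(n_ok)] + t
    ss <- rowSums((points[it, , drop = FALSE] - points[jt, , drop = FALSE])^2)
    pos <- ss > 0
    ln_eps[k] <- mean(log(ss[pos])) / 2
    cnt[k] <- sum(pos)
  }
  structure(list(t = ts, ln_eps_t = ln_eps, pair_count = cnt, shell = shell),
            class = "error_growth")
}

#' Differentiate an error-growth curve into an SDLE curve
#'
#' The SDLE at scale `ln eps_t` is the local slope
#' `(ln eps_{t+dt} - ln eps_t) / dt`, attached to the abscissa `ln eps_t`.
#' Negative values are legitimate: the mean separation need not grow
#' monotonically. Points are returned sorted by scale (coincident scales
#' are averaged) so the curve is a function of `ln eps`.
#'
#' @param curve An `error_growth` object (>= 2 points).
#' @return Object of class `sdle_curve`: data frame with `ln_eps`, `lambda`.
#' @export
sdle_from_growth <- function(curve) {
  ln <- curve$ln_eps_t
  if (length(ln) < 2L) stop("need at least 2 growth points")
  dt <- diff(curve$t)
  lam <- diff(ln) / dt
  ln_eps <- ln[-length(ln)]
  o <- order(ln_eps)
  ln_eps <- ln_eps[o]; lam <- lam[o]
  # merge numerically coincident abscissae so the grid is strictly increasing
  grp <- cumsum(c(TRUE, diff(ln_eps) > 1e-12))
  out <- data.frame(
    ln_eps = as.vector(tapply(ln_eps, grp, mean)),
    lambda = as.vector(tapply(lam, grp, mean)))
  class(out) <- c("sdle_curve", "data.frame")
  out
}

#' Average several SDLE curves onto a common scale grid
#'
#' Interpolates each curve onto the union of all abscissae and takes the
#' arithmetic mean of lambda at every grid point covered by at least one
#' curve (curves contribute only within their own scale range). This is the
#' simplified combination of the four shell curves into a single curve; it
#' is also used to average curves across channels.
#'
#' @param curves List of `sdle_curve` objects (>= 1).
#' @return A single `sdle_curve`.
#' @export
average_sdle <- function(curves) {
  if (inherits(curves, "sdle_curve")) return(curves)
  curves <- curves[!vapply(curves, is.null, TRUE)]
  if (length(curves) == 0L) stop("no curves to average")
  if (length(curves) == 1L) return(curves[[1]])
  lo <- max(vapply(curves, function(cv) min(cv$ln_eps), 0))
  hi <- min(vapply(curves, function(cv) max(cv$ln_eps), 0))
  if (lo > hi)
    warning("SDLE curves cover disjoint scale ranges; concatenating")
  grid <- sort(unique(unlist(lapply(curves, `[[`, "ln_eps"))))
  vals <- vapply(curves, function(cv) {
    if (nrow(cv) < 2L) {
      out <- rep(NA_real_, length(grid))
      out[which.min(abs(grid - cv$ln_eps))] <- cv$lambda
      return(out)
    }
    stats::approx(cv$ln_eps, cv$lambda, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  lam <- rowMeans(as.matrix(vals), na.rm = TRUE)
  keep <- is.finite(lam)
  out <- data.frame(ln_eps = grid[keep], lambda = lam[keep])
  class(out) <- c("sdle_curve", "data.frame")
  out
}

#' Fit the SDLE scaling law
#'
#' Least-squares fit of `lambda = -gamma ln eps + c` over the longest
#' contiguous window of the curve with `r^2 >= r2_min` (windows of at least
#' `min_frac` of the curve, and at least 5 points; among equally long
#' windows the larger-scale one wins). If no window qualifies the full curve
#' is fitted and flagged `degraded`.
#'
#' @param curve An `sdle_curve` (>= 5 points).
#' @param r2_min Minimum r-squared for a window to count as scaling
#'   (default 0.95).
#' @param min_frac Minimum window length as a fraction of the curve
#'   (default 0.4).
#' @return Object of class `scaling_fit`: list with `gamma` (positive slope
#'   magnitude), `intercept`, `region` (ln eps bounds), `r2`, `degraded`.
#' @export
fit_scaling <- function(curve, r2_min = 0.95, min_frac = 0.4) {
  x <- curve$ln_eps; y <- curve$lambda
  n <- length(x)
  if (n < 5L) stop("need at least 5 SDLE points to fit the scaling law")
  xm <- x - mean(x); ym <- y - mean(y)          # centred for stability
  cx <- c(0, cumsum(xm)); cy <- c(0, cumsum(ym))
  cxx <- c(0, cumsum(xm^2)); cyy <- c(0, cumsum(ym^2))
  cxy <- c(0, cumsum(xm * ym))
  eps0 <- .Machine$double.eps
  # all windows of one length at once, via prefix-sum differences
  win_stats <- function(len) {
    a <- seq_len(n - len + 1L); b <- a + len - 1L
    Sx <- cx[b + 1L] - cx[a]; Sy <- cy[b + 1L] - cy[a]
    Sxx <- cxx[b + 1L] - cxx[a]; Syy <- cyy[b + 1L] - cyy[a]
    Sxy <- cxy[b + 1L] - cxy[a]
    vx <- Sxx - Sx^2 / len; vy <- Syy - Sy^2 / len
    cvy <- Sxy - Sx * Sy / len
    slope <- ifelse(vx > 0, cvy / vx, 0)
    r2 <- ifelse(vy <= eps0 * pmax(1, Syy), 1,
                 ifelse(vx <= 0, 0, cvy^2 / (vx * vy)))
    list(a = a, slope = slope, r2 = r2,
         mean_x = Sx / len + mean(x), mean_y = Sy / len + mean(y))
  }
  len_min <- max(5L, ceiling(min_frac * n))
  best <- NULL
  for (len in seq(n, len_min, by = -1L)) {
    st <- win_stats(len)
    ok <- which(st$r2 >= r2_min)
    if (length(ok) > 0L) {                    # last start = largest scales
      k <- ok[length(ok)]
      best <- list(a = st$a[k], b = st$a[k] + len - 1L,
                   slope = st$slope[k], r2 = st$r2[k],
                   intercept = st$mean_y[k] - st$slope[k] * st$mean_x[k])
      break
    }
  }
  degraded <- is.null(best)
  if (degraded) {
    st <- win_stats(n)
    best <- list(a = 1L, b = n, slope = st$slope[1], r2 = st$r2[1],
                 intercept = st$mean_y[1] - st$slope[1] * st$mean_x[1])
  }
  structure(list(gamma = abs(best$slope), slope = best$slope,
                 intercept = best$intercept,
                 region = c(x[best$a], x[best$b]), r2 = best$r2,
                 degraded = degraded),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "SDLE scaling fit: gamma = %.4f, region ln(eps) in [%.3f, %.3f], r2 = %.4f%s\n",
    x$gamma, x$region[1], x$region[2], x$r2,
    if (x$degraded) " (degraded: no window met r2_min)" else ""))
  invisible(x)
}

#' Extract the per-epoch SDLE features
#'
#' Reads the three feature scales off the scaling region: `eps1` is its
#' smallest scale, `eps3` its boundary (largest) scale, `eps2` the geometric
#' midpoint (arithmetic midpoint in `ln eps`). The corresponding lambdas are
#' interpolated from the averaged SDLE curve, and `lam_bar` is their mean.
#' When a largest-shell growth curve is supplied, `eps_inf` (the attractor
#' size, where the growth curve saturates) and the error-doubling time
#' `T_db` are added.
#'
#' @param curve Averaged `sdle_curve`.
#' @param fit A `scaling_fit` for that curve.
#' @param growth Optional largest-shell `error_growth` curve.
#' @return Object of class `sdle_features`: list with `lam1`, `lam2`,
#'   `lam3`, `lam_bar`, `eps1`, `eps2`, `eps3`, `eps_inf`, `T_db`.
#' @export
sdle_features <- function(curve, fit, growth = NULL) {
  reg <- fit$region
  if (diff(reg) <= 0) stop("empty scaling region")
  ln3 <- c(reg[1], mean(reg), reg[2])
  lam <- stats::approx(curve$ln_eps, curve$lambda, xout = ln3, rule = 2)$y
  eps_inf <- NA_real_
  t_db <- NA_real_
  if (!is.null(growth)) {
    ln <- growth$ln_eps_t
    tail_n <- max(2L, length(ln) %/% 4L)
    eps_inf <- exp(mean(ln[(length(ln) - tail_n + 1L):length(ln)]))
    t_db <- error_doubling_time(growth)
  }
  structure(list(lam1 = lam[1], lam2 = lam[2], lam3 = lam[3],
                 lam_bar = mean(lam),
                 eps1 = exp(ln3[1]), eps2 = exp(ln3[2]), eps3 = exp(ln3[3]),
                 eps_inf = eps_inf, T_db = t_db),
            class = "sdle_features")
}

#' @export
print.sdle_features <- function(x, ...) {
  cat(sprintf("SDLE features: lam1 = %.4f, lam2 = %.4f, lam3 = %.4f, lam_bar = %.4f\n",
              x$lam1, x$lam2, x$lam3, x$lam_bar))
  cat(sprintf("  scales eps1/eps2/eps3 = %.4g / %.4g / %.4g", x$eps1, x$eps2, x$eps3))
  if (is.finite(x$eps_inf)) cat(sprintf(", eps_inf = %.4g", x$eps_inf))
  if (is.finite(x$T_db)) cat(sprintf(", T_db = %.2f samples", x$T_db))
  cat("\n")
  invisible(x)
}

#' Error-doubling time of a growth curve
#'
#' The first time at which the mean pair separation doubles, i.e. the first
#' crossing of `ln eps_0 + ln 2`, located by linear interpolation in t. By
#' the telescoping identity, integrating the SDLE over `[0, T_db]` returns
#' `ln 2`. Returns `NA` (with attribute `reached = FALSE`) when the curve
#' never doubles.
#'
#' @param growth An `error_growth` curve.
#' @return Doubling time in samples, or `NA`.
#' @export
error_doubling_time <- function(growth) {
  ln <- growth$ln_eps_t
  target <- ln[1] + log(2)
  above <- which(ln >= target)
  if (length(above) == 0L)
    return(structure(NA_real_, reached = FALSE))
  k <- above[1]
  if (k == 1L) return(structure(0, reached = TRUE))
  t0 <- growth$t[k - 1L]; t1 <- growth$t[k]
  frac <- (target - ln[k - 1L]) / (ln[k] - ln[k - 1L])
  structure(t0 + frac * (t1 - t0), reached = TRUE)
}
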