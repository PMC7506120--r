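#' Delay-coordinate phase-space reconstruction
#'
#' Maps a scalar series to the vectors
#' `V_i = (x(i), x(i+L), ..., x(i+(m-1)L))`, the exact sliding-window
#' embedding with no normalization. The first column reproduces
#' `x[1:(n-(m-1)L)]`.
#'
#' @param x Numeric series with `length(x) > (m-1)*L`.
#' @param m Embedding dimension (>= 1).
#' @param L Delay in samples (>= 1).
#' @return Numeric matrix with `n - (m-1)*L` rows and `m` columns; the row
#'   index is the origin sample index of each vector.
#' @export
phase_embed <- function(x, m = 2, L = 1) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m); L <- as.integer(L)
  if (m < 1L || L < 1L) stop("need m >= 1 and L >= 1")
  N <- n - (m - 1L) * L
  if (N < 2L)
    stop("series too short: need more than ", (m - 1L) * L + 1L,
         " samples for m = ", m, ", L = ", L)
  out <- vapply(seq_len(m) - 1L, function(k) x[(1L + k * L):(N + k * L)],
                numeric(N))
  if (N == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' Time-dependent exponent curve
#'
#' The mean log-separation growth of within-shell pairs,
#' `Lambda(t) = < ln ||V_{i+t} - V_{j+t}|| - ln ||V_i - V_j|| >`, as a
#' function of evolution time. This is the dynamical diagnostic used to
#' choose the embedding: for a well-unfolded regular signal the curve stays
#' near zero, for noise it jumps to the attractor-size plateau, and for a
#' chaotic signal it grows.
#'
#' @param x Numeric series.
#' @param m,L Embedding parameters.
#' @param shell Shell spec (list with `eps`, `d_eps`); default the first
#'   (largest) shell of [build_shells()].
#' @param t_max Largest evolution time (default 32).
#' @param theiler Theiler window; default `(m-1)*L + 1`.
#' @return Data frame with columns `t` and `Lambda` (`Lambda[t=0] = 0`).
#' @export
time_dependent_exponent <- function(x, m = 2, L = 1, shell = NULL,
                                    t_max = 32, theiler = (m - 1) * L + 1) {
  points <- phase_embed(x, m, L)
  if (is.null(shell)) shell <- build_shells(x, n_shells = 1)[1, ]
  pairs <- find_shell_pairs(points, shell, theiler = theiler)
  # keep the ensemble fixed over the whole horizon: pairs that would run
  # off the end of the series before t_max would otherwise change the
  # averaging set from one t to the next and bias the curve
  if (nrow(pairs) > 0L)
    pairs <- pairs[pmax(pairs[, 1], pairs[, 2]) + t_max <= nrow(points), ,
                   drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("estimation error: no pairs in shell [", signif(shell$eps, 3), ", ",
         signif(shell$eps + shell$d_eps, 3), "]")
  g <- error_growth(points, pairs, t_max = t_max, dt = 1, shell = shell)
  data.frame(t = g$t, Lambda = g$ln_eps_t - g$ln_eps_t[1])
}

# divergence summary used by the embedding-selection criterion: mean of
# |Lambda(t)| over t = 1..t_eval. The absolute value penalises both
# divergence and collapse (a degenerate embedding, e.g. delay = half period
# of a sinusoid, produces near-zero evolved separations whose signed mean
# would spuriously look "minimal"). A wide shell (0.1 SD to ~1.1 SD) is
# used so that coarsely sampled periodic signals, whose pairwise distances
# live on a discrete grid, still populate it at every candidate.
divergence_summary <- function(x, m, L, t_eval) {
  s <- stats::sd(x)
  shell <- list(eps = 0.1 * s, d_eps = s)
  tde <- time_dependent_exponent(x, m, L, shell = shell, t_max = t_eval)
  mean(abs(tde$Lambda[-1]))
}

dominant_period <- function(x) {
  n <- length(x)
  a <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]
  if (all(a == 0)) return(Inf)
  n / which.max(a)
}

#' Select the embedding delay
#'
#' Chooses the delay making the reconstructed motion most uniform: the
#' candidate minimizing the early-time divergence summary of the
#' time-dependent exponent curve. For a sinusoid this recovers the
#' quarter-period delay. Ties (within numerical tolerance) break to the
#' smallest candidate.
#'
#' @param x Numeric series.
#' @param m Embedding dimension used during evaluation (default 2).
#' @param L_candidates Candidate delays (default 1:20).
#' @param t_eval Evaluation horizon in samples; default the dominant period
#'   of the series or 32, whichever is smaller.
#' @return The selected delay (integer).
#' @export
select_delay <- function(x, m = 2, L_candidates = 1:20, t_eval = NULL) {
  if (length(L_candidates) == 0L) stop("no delay candidates")
  L_candidates <- sort(unique(as.integer(L_candidates)))
  if (is.null(t_eval))
    t_eval <- max(4L, min(32L, as.integer(round(dominant_period(x)))))
  s <- vapply(L_candidates, function(L) {
    tryCatch(divergence_summary(x, m, L, t_eval), error = function(e) Inf)
  }, 0)
  if (all(!is.finite(s)))
    stop("input error: no delay candidate is feasible for this series")
  # near-ties (within 2% of the minimum) break to the smallest delay
  L_candidates[which(s <= min(s) * 1.02 + 1e-12)[1]]
}

#' Select the embedding dimension
#'
#' Returns the smallest candidate dimension whose divergence summary is
#' within `tol` (relative) of the minimum over the candidates -- the
#' divergence should be minimal at an adequate dimension and "not much
#' larger" is read as within tolerance of that minimum. Falls back to the
#' largest candidate, with a warning, when no summary is finite.
#'
#' @param x Numeric series.
#' @param L Delay (default 1).
#' @param m_candidates Ascending candidate dimensions (default 2:6).
#' @param tol Relative tolerance around the minimum (default 0.10).
#' @param t_eval Evaluation horizon; see [select_delay()].
#' @return The selected dimension (integer).
#' @export
select_dimension <- function(x, L = 1, m_candidates = 2:6, tol = 0.10,
                             t_eval = NULL) {
  m_candidates <- sort(unique(as.integer(m_candidates)))
  if (length(m_candidates) == 1L) return(m_candidates)
  if (is.null(t_eval))
    t_eval <- max(4L, min(32L, as.integer(round(dominant_period(x)))))
  s <- vapply(m_candidates, function(m) {
    tryCatch(divergence_summary(x, m, L, t_eval), error = function(e) NA_real_)
  }, 0)
  if (all(!is.finite(s))) {
    warning("no candidate dimension is feasible; returning the largest")
    return(m_candidates[length(m_candidates)])
  }
  s_min <- min(s, na.rm = TRUE)
  m_candidates[which(s <= s_min * (1 + tol) + 1e-12)[1]]
}
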