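test_that("shell sizes follow the 1/10-SD halving cascade", {
  x <- rnorm(2048)
  x <- x / sd(x) * 10                      # SD exactly 10
  sh <- build_shells(x)
  expect_equal(sh$eps, c(1, 0.5, 0.25, 0.125))
  expect_equal(sh$d_eps, sh$eps)           # one-octave shells
  expect_equal(nrow(build_shells(x, n_shells = 1)), 1)
  expect_equal(build_shells(x, n_shells = 1)$eps, 1)
  expect_equal(build_shells(3 * x)$eps, 3 * sh$eps)
  expect_error(build_shells(rep(1, 100)), "degenerate")
})

test_that("find_shell_pairs matches hand-checked and brute-force results", {
  pts <- rbind(c(0, 0), c(0, 0.05), c(1, 1))
  got <- find_shell_pairs(pts, list(eps = 0, d_eps = 0.1))
  expect_equal(unname(got), cbind(1L, 2L))
  expect_equal(nrow(find_shell_pairs(pts, list(eps = 50, d_eps = 1))), 0)
  for (s in 1:5) {
    set.seed(s)
    cloud <- matrix(rnorm(400), ncol = 2)
    shell <- list(eps = 0.3, d_eps = 0.3)
    got <- find_shell_pairs(cloud, shell, theiler = 3)
    ref <- naive_shell_pairs(cloud, 0.3, 0.3, theiler = 3)
    expect_equal(unname(got), unname(ref))
  }
})

test_that("error growth averages logs and tracks exact constructions", {
  # two pairs with separations e^1 and e^3 -> mean log separation 2
  pts <- matrix(c(0, exp(1), 100, 100 + exp(3)), ncol = 1)
  g <- error_growth(pts, rbind(c(1, 2), c(3, 4)), t_max = 0)
  expect_equal(g$ln_eps_t[1], 2)
  # separations that double each step -> slope ln 2 exactly
  pts2 <- matrix(2^(1:24), ncol = 1)
  g2 <- error_growth(pts2, cbind(1:8, 3:10), t_max = 6)
  expect_equal(unique(round(diff(g2$ln_eps_t), 12)), round(log(2), 12))
})

test_that("the shell-pair-growth-SDLE chain matches a naive implementation", {
  for (s in 1:5) {
    set.seed(s)
    x <- as.vector(arima.sim(list(ar = 0.9), 300))
    pts <- phase_embed(x, 2, 1)
    sh <- build_shells(x)
    for (r in 1:2) {
      pairs <- find_shell_pairs(pts, sh[r, ], theiler = 2)
      ref_pairs <- naive_shell_pairs(pts, sh$eps[r], sh$d_eps[r], theiler = 2)
      expect_equal(unname(pairs), unname(ref_pairs))
      if (nrow(pairs) == 0) next
      g <- suppressWarnings(error_growth(pts, pairs, t_max = 30))
      ref <- naive_growth(pts, ref_pairs, 30)
      expect_lt(max(abs(g$ln_eps_t - ref$ln_eps_t[seq_along(g$ln_eps_t)])),
                1e-9)
      cv <- sdle_from_growth(g)
      ref_lam <- diff(ref$ln_eps_t)[seq_len(length(g$t) - 1)]
      ref_ln <- ref$ln_eps_t[seq_len(length(g$t) - 1)]
      o <- order(ref_ln)
      expect_lt(max(abs(sort(cv$ln_eps) - sort(ref_ln))), 1e-9)
      expect_lt(max(abs(cv$lambda[match(round(ref_ln, 9),
                                        round(cv$ln_eps, 9))] - ref_lam),
                    na.rm = TRUE), 1e-9)
    }
  }
})

test_that("SDLE curves from analytic growth laws are exact", {
  # exact exponential growth: lambda constant at the rate
  g <- structure(list(t = 0:20, ln_eps_t = -3 + 0.1 * (0:20),
                      pair_count = rep(10L, 21), shell = NULL),
                 class = "error_growth")
  cv <- sdle_from_growth(g)
  expect_equal(cv$lambda, rep(0.1, 20))
  expect_equal(cv$ln_eps, -3 + 0.1 * (0:19))
  # constant separation: lambda 0
  gc <- structure(list(t = 0:10, ln_eps_t = rep(-2, 11),
                       pair_count = rep(10L, 11), shell = NULL),
                  class = "error_growth")
  expect_equal(sdle_from_growth(gc)$lambda, 0)
  # power-law-ish growth: matches closed-form finite differences
  ln <- -3 + 0.8 * log(1 + 0:30)
  gp <- structure(list(t = 0:30, ln_eps_t = ln, pair_count = rep(10L, 31),
                       shell = NULL), class = "error_growth")
  cvp <- sdle_from_growth(gp)
  expect_equal(cvp$lambda, diff(ln), tolerance = 1e-12)
  expect_true(all(diff(cvp$lambda) < 0))   # declines as scale grows
})

test_that("average_sdle combines curves on a common grid", {
  cv <- sdle_from_growth(structure(
    list(t = 0:10, ln_eps_t = -2 + 0.2 * (0:10), pair_count = rep(5L, 11),
         shell = NULL), class = "error_growth"))
  avg4 <- average_sdle(list(cv, cv, cv, cv))
  expect_equal(avg4$lambda, cv$lambda)
  expect_equal(avg4$ln_eps, cv$ln_eps)
  cv_off <- cv
  cv_off$lambda <- cv$lambda + 0.5
  avg <- average_sdle(list(cv, cv_off))
  expect_equal(avg$lambda, cv$lambda + 0.25)
  # general interpolation oracle on a shell quartet from a real epoch
  f <- sdle(filter_epoch(gen_background(generator_config(), seed = 3))$data[1, ])
  grid <- sort(unique(unlist(lapply(f$curves, `[[`, "ln_eps"))))
  ref <- rowMeans(sapply(f$curves, function(cv)
    approx(cv$ln_eps, cv$lambda, xout = grid, rule = 1)$y), na.rm = TRUE)
  keep <- is.finite(ref)
  got <- average_sdle(f$curves)
  expect_lt(max(abs(got$lambda - ref[keep])), 1e-9)
})

test_that("fit_scaling recovers exact and noisy scaling laws", {
  ln_eps <- seq(-4, -1, length.out = 40)
  exact <- structure(data.frame(ln_eps = ln_eps,
                                lambda = -0.5 * ln_eps + 0.2),
                     class = c("sdle_curve", "data.frame"))
  fit <- fit_scaling(exact)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-10)
  expect_equal(fit$region, c(-4, -1))
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_false(fit$degraded)
  flat <- structure(data.frame(ln_eps = ln_eps, lambda = rep(0.3, 40)),
                    class = c("sdle_curve", "data.frame"))
  expect_equal(fit_scaling(flat)$gamma, 0)
  # recovery under 1% noise, 30 points, 20 seeds
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    ln <- seq(-4, -1, length.out = 30)
    lam <- -0.5 * ln + 0.2
    noisy <- structure(data.frame(
      ln_eps = ln, lambda = lam + rnorm(30, 0, 0.01 * mean(abs(lam)))),
      class = c("sdle_curve", "data.frame"))
    abs(fit_scaling(noisy)$gamma - 0.5) / 0.5
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("features read the scaling region scales off the curve", {
  ln_eps <- seq(-4, -1, length.out = 61)
  cv <- structure(data.frame(ln_eps = ln_eps, lambda = -0.5 * ln_eps),
                  class = c("sdle_curve", "data.frame"))
  fit <- fit_scaling(cv)
  f <- sdle_features(cv, fit)
  expect_equal(f$lam1, 2.0, tolerance = 1e-9)
  expect_equal(f$lam2, 1.25, tolerance = 1e-9)
  expect_equal(f$lam3, 0.5, tolerance = 1e-9)
  expect_equal(f$lam_bar, 1.25, tolerance = 1e-9)
  expect_equal(f$eps1, exp(-4))
  expect_equal(f$eps3, exp(-1))
  expect_equal(f$eps2, exp(-2.5))
  expect_equal(f$lam_bar, mean(c(f$lam1, f$lam2, f$lam3)))
})

test_that("error-doubling time matches closed forms and the integral of lambda", {
  g <- structure(list(t = 0:100, ln_eps_t = -3 + 0.1 * (0:100),
                      pair_count = rep(10L, 101), shell = NULL),
                 class = "error_growth")
  expect_equal(as.numeric(error_doubling_time(g)), log(2) / 0.1,
               tolerance = 1e-12)
  flatg <- structure(list(t = 0:10, ln_eps_t = rep(-2, 11),
                          pair_count = rep(10L, 11), shell = NULL),
                     class = "error_growth")
  tdb <- error_doubling_time(flatg)
  expect_true(is.na(tdb))
  expect_false(attr(tdb, "reached"))
  # telescoping identity on a real noisy epoch
  x <- filter_epoch(gen_background(generator_config(), seed = 77))$data[1, ]
  fit <- sdle(x)
  gg <- fit$growth[[1]]
  tdb <- as.numeric(error_doubling_time(gg))
  expect_true(is.finite(tdb))
  lam_t <- diff(gg$ln_eps_t) / diff(gg$t)
  k <- floor(tdb)
  integral <- sum(lam_t[seq_len(k)]) + (tdb - k) * lam_t[k + 1]
  expect_lt(abs(integral - log(2)), 0.01)
})

test_that("SDLE is equivariant under amplitude scaling", {
  x <- filter_epoch(gen_background(generator_config(), seed = 5))$data[2, ]
  f1 <- sdle(x)
  f2 <- sdle(7 * x)
  expect_equal(f2$curve$ln_eps, f1$curve$ln_eps + log(7), tolerance = 1e-9)
  expect_equal(f2$curve$lambda, f1$curve$lambda, tolerance = 1e-9)
})

test_that("white-noise SDLE is statistically symmetric under time reversal", {
  lam_fwd <- lam_rev <- numeric(6)
  for (s in 1:6) {
    set.seed(400 + s)
    z <- rnorm(1024)
    lam_fwd[s] <- sdle(z)$features$lam_bar
    lam_rev[s] <- sdle(rev(z))$features$lam_bar
  }
  expect_lt(abs(mean(lam_rev - lam_fwd)), sd(lam_fwd) + sd(lam_rev))
})

test_that("epileptiform epochs show smaller small-scale SDLE than normal", {
  ft <- cached_features()
  m <- tapply(ft$lam1, ft$label, mean)
  expect_lt(m[["epileptiform"]], m[["normal"]])
})

test_that("sdle objects print, summarise and expose coefficients", {
  f <- sdle(filter_epoch(gen_background(generator_config(), seed = 6))$data[1, ])
  expect_output(print(f), "scaling fit")
  expect_output(print(summary(f)), "Shells")
  co <- coef(f)
  expect_named(co, c("gamma", "lam1", "lam2", "lam3", "lam_bar"))
  expect_equal(co[["lam_bar"]],
               mean(c(co[["lam1"]], co[["lam2"]], co[["lam3"]])))
  pdf(NULL)
  plot(f); plot(f, type = "growth")
  dev.off()
})
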