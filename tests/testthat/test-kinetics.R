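test_that("trace normalization follows its definitions", {
  tr <- kinetic_trace(1:3, c(1, 2, 4), kind = "densitometry")
  expect_equal(normalize_trace(tr, "max")$value, c(0.25, 0.5, 1))
  const <- kinetic_trace(1:3, c(2, 2, 2))
  expect_equal(normalize_trace(const, "max")$value, c(1, 1, 1))
  mm <- normalize_trace(kinetic_trace(1:5, c(3, 9, 4, 7, 5)), "minmax")
  expect_equal(range(mm$value), c(0, 1))
  expect_error(normalize_trace(const, "minmax"),
               class = "flimstorm_degenerate_trace")
})

test_that("noiseless sigmoids are recovered to four significant figures", {
  truth <- sigmoid_params(3.7, 3.3, 2, 4)
  tr <- simulate_lifetime_timecourse(truth, seq(0, 8, 0.25), noise_sd = 0)
  f <- fit_sigmoid(tr)
  expect_equal(f$L0, 3.7, tolerance = 1e-4)
  expect_equal(f$Linf, 3.3, tolerance = 1e-4)
  expect_equal(f$k, 2, tolerance = 1e-4)
  expect_equal(f$t50, 4, tolerance = 1e-4)
  expect_equal(f$lag, 3, tolerance = 1e-3)
  expect_equal(lag_time(f), 3, tolerance = 1e-3)
  # rising trace (e.g. fibril densitometry): same form with L0 < Linf
  up <- simulate_lifetime_timecourse(sigmoid_params(0, 1, 1.5, 3),
                                     seq(0, 8, 0.25), noise_sd = 0,
                                     kind = "densitometry")
  fu <- fit_sigmoid(up)
  expect_equal(fu$t50, 3, tolerance = 1e-4)
})

test_that("optimizer never loses to a coarse grid with profiled amplitudes", {
  set.seed(61)
  tr <- simulate_lifetime_timecourse(sigmoid_params(3.7, 3.1, 1.2, 3),
                                     seq(0, 7, 0.5), noise_sd = 0.05)
  f <- fit_sigmoid(tr)
  t <- tr$time_hr; y <- tr$value
  best_grid <- Inf
  for (k in seq(0.2, 8, by = 0.2)) for (t50 in seq(0, 7, by = 0.25)) {
    g <- 1 / (1 + exp(k * (t - t50)))
    co <- tryCatch(stats::lm.fit(cbind(1, g), y)$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co)) next
    rss <- sum((y - co[1L] - co[2L] * g)^2)
    if (rss < best_grid) best_grid <- rss
  }
  expect_lte(f$rss, best_grid + 1e-9)
})

test_that("lag time uses the tangent construction with clamping", {
  mk <- function(k, t50) structure(list(L0 = 3.7, Linf = 3.3, k = k, t50 = t50,
                                        lag = t50 - 2 / k, rss = 0,
                                        converged = TRUE),
                                   class = "sigmoid_fit")
  expect_equal(lag_time(mk(4, 1)), 0.5)
  expect_equal(lag_time(mk(1, 0.5)), 0)          # clamped: lag-free kinetics
  expect_equal(lag_time(mk(1e6, 5)), 5, tolerance = 1e-5)
})

test_that("half-time offsets recover constructed shifts with correct sign", {
  tt <- seq(0, 10, 0.25)
  a <- simulate_lifetime_timecourse(sigmoid_params(3.7, 3.3, 2, 5), tt, 0)
  b <- simulate_lifetime_timecourse(sigmoid_params(3.7, 3.3, 2, 4), tt, 0)
  expect_equal(as.numeric(half_time_offset(a, a)), 0, tolerance = 1e-6)
  # `a` transitions 1 hr later than `b`: positive offset
  expect_equal(as.numeric(half_time_offset(a, b)), 1, tolerance = 1e-3)
  expect_equal(as.numeric(half_time_offset(b, a)), -1, tolerance = 1e-3)
})

test_that("lag estimation is accurate across the lag range", {
  # truth lags 0, 1, 2.5, 4 hr; noise 0.03 ns; median |error| <= 0.25 hr
  tt <- seq(0, 10, 0.5)
  for (lag_true in c(0, 1, 2.5, 4)) {
    k <- 2
    truth <- sigmoid_params(3.7, 3.3, k, lag_true + 2 / k)
    errs <- vapply(1:20, function(s) {
      tr <- simulate_lifetime_timecourse(truth, tt, 0.03, seed = 100 + s)
      abs(lag_time(fit_sigmoid(tr)) - lag_true)
    }, 0)
    expect_lte(stats::median(errs), 0.25)
  }
})

test_that("paired t test matches hand arithmetic and the null identity", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # d = {1, 2, 3}: t = 2 / (1 / sqrt(3)) = 3.4641, df = 2, p ~ 0.0742
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  expect_warning(z <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_equal(z$p_value, 0)
  expect_error(paired_t_test(1, 2), class = "flimstorm_invalid_input")
})

test_that("paired t test matches the reference implementation", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(3:12, 1L)
    a <- rnorm(n); b <- rnorm(n)
    mine <- paired_t_test(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher LSD reproduces the worked ANOVA example and protects the null", {
  g <- fisher_lsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
  expect_equal(attr(g, "mse"), 1)
  expect_equal(attr(g, "df2"), 6L)
  pair_ac <- g[g$comparison == "a vs c", ]
  expect_equal(pair_ac$statistic, (2 - 6) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(pair_ac$p_value, 0.00271, tolerance = 1e-2)
  # identical groups: F ~ 0, nothing significant
  null <- fisher_lsd(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_lt(attr(null, "F"), 1e-10)
  expect_false(any(null$significant))
  expect_error(fisher_lsd(list(1:3, 1:3)), class = "flimstorm_invalid_input")
  expect_error(fisher_lsd(list(1:3, 1:3, 5)), class = "flimstorm_invalid_input")
})

test_that("Fisher LSD matches an aov-based reference on random data", {
  set.seed(72)
  for (rep in 1:30) {
    groups <- lapply(1:3, function(i) rnorm(sample(4:8, 1L), mean = i / 2))
    mine <- fisher_lsd(groups)
    ref <- reference_lsd(groups)
    expect_equal(mine$statistic, ref$statistic, tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p_value, tolerance = 1e-9)
    expect_equal(attr(mine, "p_omnibus"), ref$p_omnibus, tolerance = 1e-9)
  }
})

test_that("lagged and lag-free kinetics are distinguished with common endpoints", {
  # the in-cell contrast: 40-residue-like lagged kinetics vs 42-residue-like
  # immediate aggregation, identical endpoint truth
  tt <- seq(0, 8, 0.5)
  lag40 <- sigmoid_params(3.7, 3.33, 2, 2.5 + 1)
  lag42 <- sigmoid_params(3.7, 3.33, 2, 0.5)
  lags40 <- lags42 <- e40 <- e42 <- numeric(8)
  for (s in 1:8) {
    f40 <- fit_sigmoid(simulate_lifetime_timecourse(lag40, tt, 0.03, seed = 200 + s))
    f42 <- fit_sigmoid(simulate_lifetime_timecourse(lag42, tt, 0.03, seed = 300 + s))
    lags40[s] <- lag_time(f40); lags42[s] <- lag_time(f42)
    e40[s] <- f40$Linf; e42[s] <- f42$Linf
  }
  expect_gt(stats::median(lags40), 1)
  expect_lt(stats::median(lags42), 0.5)
  expect_gt(paired_t_test(e40, e42)$p_value, 0.05)
})
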