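uniform_cube <- function(per_pixel, nr = 8L, nc = 8L, nch = 16L) {
  # equal counts in every channel; per-pixel total = per_pixel
  decay_cube(array(per_pixel / nch, c(nr, nc, nch)), 25 / nch)
}

test_that("binning factor selection hits the photon target window", {
  expect_identical(choose_binning(uniform_cube(400)), 1L)   # 9 * 400 = 3600
  expect_identical(choose_binning(uniform_cube(4000)), 0L)
  expect_identical(choose_binning(uniform_cube(10), max_factor = 3L), 3L)
  # direct arithmetic oracle over b = 0..3 for the 400-photon case
  s <- matrix(400, 8, 8)
  meds <- vapply(0:3, function(b) stats::median(oracle_box_sum(s, b)), 0)
  expect_identical(min(which(meds >= 3500)) - 1L, 1L)
  expect_error(choose_binning(uniform_cube(400), mask = matrix(FALSE, 8, 8)),
               class = "flimstorm_invalid_input")
  expect_error(choose_binning(uniform_cube(400), target_min = 5000,
                              target_max = 3500),
               class = "flimstorm_invalid_parameter")
})

test_that("sliding-window binning matches its definition and is linear", {
  set.seed(21)
  cube <- decay_cube(array(rpois(7 * 6 * 4, 20), c(7, 6, 4)), 25 / 4)
  expect_identical(unclass(bin_cube(cube, 0)), unclass(cube))
  for (b in 1:2) {
    bc <- bin_cube(cube, b)
    for (ch in 1:4)
      expect_equal(bc[, , ch], oracle_box_sum(cube[, , ch], b))
  }
  # centre pixel of a 3x3 cube at b=1 sums all nine histograms
  c3 <- decay_cube(array(rpois(3 * 3 * 4, 30), c(3, 3, 4)), 25 / 4)
  expect_equal(bin_cube(c3, 1)[2, 2, ], apply(c3, 3L, sum))
  # linearity: bin(c1 + c2) = bin(c1) + bin(c2)
  c2 <- decay_cube(array(rpois(7 * 6 * 4, 10), c(7, 6, 4)), 25 / 4)
  lhs <- bin_cube(decay_cube(unclass(cube) + unclass(c2), 25 / 4), 1)
  expect_equal(unclass(lhs), unclass(bin_cube(cube, 1)) + unclass(bin_cube(c2, 1)))
})

test_that("noiseless monoexponential decays are recovered exactly", {
  i <- delta_irf(256, 25)
  shape <- flimstorm:::decay_model_shape(2.0, i)
  f <- fit_decay(decay_curve(1e6 * shape, i$channel_width), i)
  expect_lt(abs(f$tau - 2.0), 1e-3)
  expect_lt(f$background / f$amplitude, 1e-4)
})

test_that("channel-delay kernel matches direct numerical integration", {
  for (tau in c(0.8, 3.3)) {
    q <- flimstorm:::decay_kernel(tau, 16L, 25 / 16)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_equal(q, oracle_decay_kernel(tau, 16L, 25 / 16), tolerance = 1e-5)
  }
})

test_that("Poisson MLE agrees with the brute-force likelihood grid search", {
  i <- simulate_irf(0.2, 256L, 25)
  dc <- simulate_decay(decay_truth(3.7, 5000, 0.9), i, seed = 1)
  f <- fit_decay(dc, i, method = "mle")
  tau_grid <- oracle_grid_tau(dc, i, tau_range = c(3, 4.5), step = 0.001)
  expect_lt(abs(f$tau - tau_grid), 0.01)
})

test_that("decay fitting rejects bad inputs with typed errors", {
  i <- simulate_irf(n_channels = 64L)
  weak <- simulate_decay(decay_truth(3.5, 50), i, seed = 1)
  expect_error(fit_decay(weak, i), class = "flimstorm_insufficient_photons")
  other <- simulate_irf(n_channels = 128L)
  strong <- simulate_decay(decay_truth(3.5, 5000), i, seed = 1)
  expect_error(fit_decay(strong, other), class = "flimstorm_grid_error")
})

test_that("least-squares fitting also recovers simulated lifetimes", {
  i <- simulate_irf(0.2, 128L, 25)
  set.seed(31)
  taus <- replicate(25, fit_decay(simulate_decay(decay_truth(3.3, 4500, 0.95), i),
                                  i, method = "lsq")$tau)
  expect_lt(abs(mean(taus) - 3.3), 0.08)
})

test_that("lifetime maps separate monomer-like and fibril-like regions", {
  i <- simulate_irf(0.2, 128L, 25)
  tau <- matrix(3.7, 6, 8)
  tau[, 5:8] <- 3.3
  cube <- simulate_tcspc_image(decay_truth_map(tau, 4200, 0.95), i, seed = 9)
  map <- fit_lifetime_map(cube, i, mask = matrix(TRUE, 6, 8))
  expect_true(all(map$converged))
  left <- col(tau) <= 4
  m_mono <- region_mean_lifetime(map, left)$mean_tau
  m_fib <- region_mean_lifetime(map, !left)$mean_tau
  expect_gt(m_mono - m_fib, 0.3)
  # the fit is deterministic: same cube gives the identical map
  map2 <- fit_lifetime_map(cube, i, mask = matrix(TRUE, 6, 8))
  expect_identical(map$tau, map2$tau)
})

test_that("an all-zero cube yields only non-converged pixels", {
  i <- simulate_irf(n_channels = 32L)
  cube <- decay_cube(array(0, c(4, 4, 32)), i$channel_width)
  map <- fit_lifetime_map(cube, i)
  expect_false(any(map$converged))
  expect_error(region_mean_lifetime(map), class = "flimstorm_empty_region")
})

fake_map <- function(tau_values, nr = 10L, nc = 10L) {
  tau <- matrix(tau_values, nr, nc)
  structure(list(tau = tau, amplitude = tau * 0, background = tau * 0,
                 chi2 = tau * 0 + 1, photons = tau * 0 + 4000,
                 converged = matrix(TRUE, nr, nc), binning_factor = 0L,
                 mask = matrix(TRUE, nr, nc), channel_width = 25 / 256,
                 method = "mle"),
            class = "lifetime_map")
}

test_that("lifetime histograms are conserved, unit-normalized, and broaden for mixtures", {
  m1 <- fake_map(3.5)
  h <- lifetime_histogram(m1, bin_width = 0.05)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$normalized), 1)
  # empty region: empty histogram, no error
  h0 <- lifetime_histogram(m1, region = matrix(FALSE, 10, 10))
  expect_length(h0$counts, 0L)
  # mixture of 3.3 and 3.7 with fit noise is broader than either component
  set.seed(41)
  pure_a <- fake_map(3.3 + rnorm(100, 0, 0.04))
  pure_b <- fake_map(3.7 + rnorm(100, 0, 0.04))
  mix <- fake_map(c(3.3 + rnorm(50, 0, 0.04), 3.7 + rnorm(50, 0, 0.04)))
  sd_of <- function(m) stats::sd(m$tau[m$converged])
  expect_gt(sd_of(mix), sd_of(pure_a))
  expect_gt(sd_of(mix), sd_of(pure_b))
})

test_that("region mean lifetime uses two-level (per-image) averaging", {
  s1 <- region_mean_lifetime(fake_map(3.5))
  expect_equal(s1$mean_tau, 3.5)
  expect_equal(s1$sem_tau, 0)
  maps <- list(fake_map(3.4), fake_map(3.5), fake_map(3.6))
  s3 <- region_mean_lifetime(maps)
  expect_equal(s3$mean_tau, 3.5)
  expect_equal(s3$sem_tau, stats::sd(c(3.4, 3.5, 3.6)) / sqrt(3))
  expect_equal(s3$n_images, 3L)
  # a map with many more pixels must not dominate: equal per-image weights
  big <- fake_map(3.0, nr = 40L, nc = 40L)
  small <- fake_map(3.6, nr = 4L, nc = 4L)
  expect_equal(region_mean_lifetime(list(big, small))$mean_tau, 3.3)
})

test_that("monotone discrimination: more fibril-like pixels lower the mean", {
  fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(fracs, function(fr) {
    n_fib <- round(100 * fr)
    region_mean_lifetime(fake_map(c(rep(3.3, n_fib), rep(3.7, 100 - n_fib))))$mean_tau
  }, 0)
  expect_true(all(diff(means) < 0))
})
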