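cam <- camera_model(pixel_size = 100, psf_sigma = 150, background_rate = 2,
                    read_noise_sd = 0)

# sampled (not pixel-integrated) Gaussian spot, the exact model of fit_spot
sampled_spot <- function(nr, nc, x0, y0, i0, s_px, bg = 0) {
  gx <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  gy <- matrix(seq_len(nr) - 0.5, nr, nc)
  i0 * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * s_px^2)) + bg
}

test_that("candidate detection finds isolated maxima and nothing else", {
  expect_equal(nrow(detect_candidates(matrix(3, 20, 20))), 0L)
  set.seed(1)
  fr <- matrix(rpois(400, 2), 20, 20)
  fr[10, 12] <- fr[10, 12] + 50 * stats::mad(fr)
  cand <- detect_candidates(fr, threshold_k = 6)
  expect_equal(nrow(cand), 1L)
  expect_equal(unname(unlist(cand[1L, c("row", "col")])), c(10, 12))
})

test_that("detection matches a brute-force scan on well-separated spots", {
  set.seed(2)
  fr <- matrix(rpois(48 * 48, 2), 48, 48)
  centres <- expand.grid(row = c(8, 20, 32, 44), col = c(10, 24, 38))[1:10, ]
  for (k in seq_len(10)) fr[centres$row[k], centres$col[k]] <- 400
  cand <- detect_candidates(fr, threshold_k = 6)
  expect_equal(nrow(cand), 10L)
  # oracle: exhaustive all-pixels scan with the same rule
  thr <- stats::median(fr) + 6 * stats::mad(fr)
  hits <- list()
  for (i in 2:47) for (j in 2:47) {
    nb <- fr[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (fr[i, j] > thr && sum(nb < fr[i, j]) == 8L)
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  oracle <- do.call(rbind, hits)
  expect_equal(nrow(oracle), 10L)
  got <- cand[order(cand$row, cand$col), c("row", "col")]
  ora <- oracle[order(oracle[, 1L], oracle[, 2L]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(ora))
})

test_that("Gaussian spot fitting recovers a noiseless subpixel centre", {
  fr <- sampled_spot(15, 15, x0 = 7.3, y0 = 8.6, i0 = 100, s_px = 1.5, bg = 1)
  sf <- fit_spot(fr, list(row = 9, col = 8), cam, window = 9L)
  expect_true(sf$accepted)
  expect_lt(abs(sf$x / 100 - 7.3), 1e-3)
  expect_lt(abs(sf$y / 100 - 8.6), 1e-3)
})

test_that("spot fitting rejects dim and border candidates with typed reasons", {
  fr <- sampled_spot(15, 15, 7.5, 7.5, i0 = 2, s_px = 1.5, bg = 0)
  sf <- fit_spot(fr, list(row = 8, col = 8), cam, window = 7L, N_min = 100)
  expect_false(sf$accepted)
  expect_equal(sf$reason, "too-few-photons")
  sf2 <- fit_spot(fr, list(row = 2, col = 8), cam, window = 7L)
  expect_false(sf2$accepted)
  expect_equal(sf2$reason, "border")
})

test_that("Thompson precision formula and limits", {
  # a -> 0, b = 0: the shot-noise term s/sqrt(N) dominates
  expect_equal(thompson_precision(1e4, 150, 0.01, 0), 1.5, tolerance = 1e-6)
  # independent hand-expanded arithmetic for s=150, a=100, N=500, b=3
  by_hand <- sqrt(150^2 / 500 + 100^2 / (12 * 500) +
                    8 * pi * 150^4 * 3^2 / (100^2 * 500^2))
  expect_equal(thompson_precision(500, 150, 100, 3), by_hand)
  # strictly decreasing in N
  ns <- c(100, 200, 500, 1000, 5000)
  expect_true(all(diff(thompson_precision(ns, 150, 100, 3)) < 0))
  expect_error(thompson_precision(-5, 150, 100, 3),
               class = "flimstorm_invalid_parameter")
})

test_that("localization counts follow the blinking statistics", {
  em <- emitter_set(data.frame(x = 800, y = 800), photons_mean = 2000,
                    on_probability = 0.3)
  mv <- simulate_blinking_movie(em, cam, 600, fov = c(16L, 16L), seed = 12)
  tab <- localize_stack(mv)
  expected <- 600 * 0.3
  expect_lt(abs(nrow(tab) - expected), 3 * sqrt(600 * 0.3 * 0.7))
  # dark movie: empty table
  dark <- simulate_blinking_movie(emitter_set(data.frame(x = 800, y = 800),
                                              on_probability = 0),
                                  cam, 20, fov = c(16L, 16L), seed = 13)
  expect_equal(nrow(localize_stack(dark)), 0L)
})

test_that("frame order does not affect the localization set", {
  em <- emitter_set(data.frame(x = 750, y = 820), photons_mean = 1500,
                    on_probability = 0.4)
  mv <- simulate_blinking_movie(em, cam, 60, fov = c(16L, 16L), seed = 14)
  tab <- localize_stack(mv)
  perm <- sample(60)
  tab_p <- localize_stack(structure(mv[, , perm], camera = cam))
  key <- function(t) sort(round(t$x_nm, 6) + 1e6 * round(t$y_nm, 6))
  expect_equal(key(tab), key(tab_p))
})

test_that("density rendering conserves counts and matches the naive binner", {
  one <- make_loc_table(x = 123.4, y = 567.8)
  sr1 <- render_density(one, bin_size = 10)
  expect_equal(sum(sr1), 1L)
  expect_equal(attr(sr1, "n_rendered"), 1L)
  set.seed(15)
  tab <- make_loc_table(x = runif(200, 0, 900), y = runif(200, 0, 700))
  for (bin in c(7, 10, 33)) {
    sr <- render_density(tab, bin)
    expect_equal(sum(sr), 200L)
    ora <- oracle_bin_counts(tab$x_nm, tab$y_nm, bin, attr(sr, "origin"),
                             ncol(sr), nrow(sr))
    expect_equal(unclass(sr), ora, ignore_attr = TRUE)
  }
})

test_that("a rendered uniform disc occupies the expected support", {
  set.seed(16)
  th <- runif(1e4, 0, 2 * pi); r <- 80 * sqrt(runif(1e4))
  tab <- make_loc_table(500 + r * cos(th), 500 + r * sin(th))
  sr <- render_density(tab, 10)
  occ <- which(unclass(sr) > 0, arr.ind = TRUE)
  expect_equal(diff(range(occ[, 1L])) + 1L, 16L, tolerance = 0.08)
  expect_equal(diff(range(occ[, 2L])) + 1L, 16L, tolerance = 0.08)
})

test_that("resolution combines precision and Nyquist sampling limits", {
  # dense limit: precision term dominates, 2.355 * 25 nm
  set.seed(17)
  dense <- make_loc_table(runif(5000, 0, 200), runif(5000, 0, 200),
                          precision = 25)
  sr <- render_density(dense, 10)
  expect_equal(as.numeric(estimate_resolution(dense, sr)), 2.355 * 25,
               tolerance = 1e-9)
  # doubling the precision doubles the precision-limited term
  dense2 <- dense; dense2$precision_nm <- 50
  expect_equal(attr(estimate_resolution(dense2, sr), "precision_term"),
               2 * attr(estimate_resolution(dense, sr), "precision_term"))
  # sparse limit: 100 localizations on a 10x10 grid over 1 um^2 at 5 nm
  # precision -> 2 / sqrt(1e-4 nm^-2) = 200 nm
  g <- expand.grid(x = seq(50, 950, by = 100), y = seq(50, 950, by = 100))
  sparse <- make_loc_table(g$x, g$y, precision = 5)
  sr_sp <- render_density(sparse, 100, extent = c(0, 1000, 0, 1000))
  expect_equal(as.numeric(estimate_resolution(sparse, sr_sp)), 200)
  expect_error(estimate_resolution(make_loc_table(numeric(0), numeric(0)), sr),
               class = "flimstorm_invalid_input")
})
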