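# Independent brute-force oracles used across the suite. These deliberately
# use naive algorithms (grid searches, nested loops, recursion-free flood
# fill, direct numerical integration) so that they share no code path with
# the implementations they check.

# Profile-likelihood grid search for the decay lifetime: brute force over a
# tau grid, profiling the background fraction at every grid point, using the
# same Poisson likelihood as the fitter.
oracle_grid_tau <- function(curve, irf_obj, tau_range = c(2, 6), step = 0.001) {
  y <- curve$counts
  n_tot <- sum(y)
  nch <- irf_obj$n_channels
  taus <- seq(tau_range[1L], tau_range[2L], by = step)
  nll <- vapply(taus, function(tt) {
    shape <- flimstorm:::decay_model_shape(tt, irf_obj)
    stats::optimize(function(f) {
      mu <- n_tot * ((1 - f) * shape + f / nch) + 1e-12
      sum(mu) - sum(y * log(mu))
    }, c(0, 0.999), tol = 1e-10)$objective
  }, 0)
  taus[which.min(nll)]
}

# Channel-delay kernel by direct numerical double integration (independent
# of the closed form in the package).
oracle_decay_kernel <- function(tau, n, dt, n_sub = 400L) {
  win <- n * dt
  norm <- tau * (1 - exp(-win / tau))
  p_per <- function(w) exp(-(w %% win) / tau) / norm
  s_grid <- (seq_len(n_sub) - 0.5) / n_sub * dt
  vapply(seq_len(n) - 1L, function(k) {
    mean(vapply(s_grid, function(s) {
      stats::integrate(function(t) p_per(t - s), k * dt, (k + 1) * dt,
                       rel.tol = 1e-10)$value
    }, 0))
  }, 0)
}

# Mean of an exponential arrival time folded modulo the window.
oracle_folded_exp_mean <- function(tau, win) {
  dens <- function(t) exp(-t / tau) / (tau * (1 - exp(-win / tau)))
  stats::integrate(function(t) t * dens(t), 0, win, rel.tol = 1e-12)$value
}

# Naive O(X*Y*(2b+1)^2) neighbourhood summation.
oracle_box_sum <- function(m, b) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -b:b) for (dj in -b:b) {
      a <- i + di; bb <- j + dj
      if (a >= 1 && a <= nr && bb >= 1 && bb <= nc) acc <- acc + m[a, bb]
    }
    out[i, j] <- acc
  }
  out
}

# Stack-based flood fill, 8-connected; labels in raster discovery order.
oracle_flood_labels <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
    if (!fg[ii, jj] || lab[ii, jj] > 0L) next
    cur <- cur + 1L
    stack <- list(c(ii, jj))
    lab[ii, jj] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1L] + di; b <- p[2L] + dj
        if (a >= 1L && a <= nr && b >= 1L && b <= nc &&
            fg[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# Canonical renumbering by first appearance in column-major order, so two
# labelings can be compared as partitions.
canonical_labels <- function(lab) {
  v <- as.vector(lab)
  nz <- v[v > 0L]
  v[v > 0L] <- match(nz, unique(nz))
  matrix(v, nrow(lab), ncol(lab))
}

# Exhaustive max pairwise distance over all point pairs.
oracle_max_pairwise <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Naive double-loop 2-D histogram with half-open bins.
oracle_bin_counts <- function(x, y, bin, origin, nx, ny) {
  counts <- matrix(0L, ny, nx)
  for (k in seq_along(x)) {
    j <- floor((x[k] - origin[1L]) / bin) + 1L
    i <- floor((y[k] - origin[2L]) / bin) + 1L
    if (j >= 1L && j <= nx && i >= 1L && i <= ny)
      counts[i, j] <- counts[i, j] + 1L
  }
  counts
}

# Reference protected LSD built on stats::aov for the pooled error term.
reference_lsd <- function(groups, alpha = 0.05) {
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  av <- stats::aov(y ~ g, data = df)
  ms <- summary(av)[[1L]]
  mse <- ms["Residuals", "Mean Sq"]
  df2 <- ms["Residuals", "Df"]
  p_omni <- ms["g", "Pr(>F)"]
  means <- tapply(df$y, df$g, mean)
  ns <- tapply(df$y, df$g, length)
  pairs <- utils::combn(length(groups), 2L)
  t_stat <- p_val <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    t_stat[k] <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    p_val[k] <- 2 * stats::pt(-abs(t_stat[k]), df2)
  }
  list(statistic = t_stat, p_value = p_val, p_omnibus = p_omni, mse = mse,
       df2 = df2)
}

# Small localization table built directly from coordinates (bypassing the
# movie stage) for tests that exercise rendering/morphometry in isolation.
make_loc_table <- function(x, y, precision = 10, pixel_size = 100) {
  n <- length(x)
  localization_table(
    data.frame(frame = seq_len(n), x_nm = x, y_nm = y,
               photons = rep(2000, n), sigma_nm = rep(150, n),
               background = rep(2, n), precision_nm = rep(precision, n)),
    pixel_size = pixel_size)
}
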