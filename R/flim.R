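# Exact channel-delay kernel of the periodic monoexponential decay: the
# probability that a photon excited uniformly within one channel is counted
# k channels later, under the exponential density e^(-t/tau) folded over the
# window T (late photons wrap to the next period). Both the excitation
# spread within the source channel and the binning of the arrival time are
# integrated analytically, so the kernel matches channel-histogram data
# without discretization bias. For k >= 1 the kernel is geometric in
# exp(-dt/tau); k = 0 carries the self-channel mass plus the wrapped tail.
decay_kernel <- function(tau, n, dt) {
  win <- n * dt
  amp <- 1 / (tau * (1 - exp(-win / tau)))
  k <- seq_len(n) - 1L
  c1 <- amp * tau^2 / dt * (1 - exp(-dt / tau)) * (exp(dt / tau) - 1)
  q <- c1 * exp(-k * dt / tau)
  q[1L] <- amp * tau * (exp(-win / tau) * ((tau / dt) * (exp(dt / tau) - 1) - 1) +
                          1 - (tau / dt) * (1 - exp(-dt / tau)))
  q
}

# Model shape: the channel-delay kernel circularly convolved with the IRF
# channel histogram, normalized to unit sum.
decay_model_shape <- function(tau, irf_obj) {
  n <- irf_obj$n_channels
  d <- decay_kernel(tau, n, irf_obj$channel_width)
  conv <- Re(stats::fft(stats::fft(irf_obj$amplitudes) * stats::fft(d),
                        inverse = TRUE)) / n
  conv <- pmax(conv, 0)
  conv / sum(conv)
}

#' Choose the photon-binning factor for a TCSPC image
#'
#' Returns the smallest factor `b` such that after summing each pixel's decay
#' over its (2b+1) x (2b+1) neighbourhood, the median masked pixel holds at
#' least `target_min` photons; binning is increased until roughly
#' `target_min`–`target_max` photons/pixel are available for fitting. Returns
#' `max_factor` if no factor suffices.
#'
#' @param cube A `decay_cube`.
#' @param mask Logical matrix of pixels to consider; `NULL` means all.
#' @param target_min,target_max Target photons/pixel window (default
#'   3500–5000).
#' @param max_factor Largest factor tried.
#' @return Integer binning factor in `[0, max_factor]`.
#' @export
choose_binning <- function(cube, mask = NULL, target_min = 3500,
                           target_max = 5000, max_factor = 3L) {
  stopifnot(inherits(cube, "decay_cube"))
  if (target_min >= target_max)
    stopf("`target_min` must be below `target_max`",
          class = "flimstorm_invalid_parameter")
  if (max_factor < 0) stopf("`max_factor` must be >= 0",
                            class = "flimstorm_invalid_parameter")
  s <- rowSums(cube, dims = 2L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(s), ncol(s))
  if (!any(mask)) stopf("mask selects no pixels", class = "flimstorm_invalid_input")
  for (b in 0:max_factor) {
    if (stats::median(box_sum(s, b)[mask]) >= target_min) return(as.integer(b))
  }
  as.integer(max_factor)
}

#' Sliding-window binning of a decay cube
#'
#' Each output pixel's histogram is the channel-wise sum over its
#' (2b+1) x (2b+1) neighbourhood, truncated at the image edge. Image
#' dimensions are unchanged (resolution-preserving binning, the convention of
#' commercial TCSPC analysis software).
#'
#' @param cube A `decay_cube`.
#' @param b Binning factor (>= 0); `b = 0` is the identity.
#' @return A `decay_cube` of the same dimensions.
#' @export
bin_cube <- function(cube, b) {
  stopifnot(inherits(cube, "decay_cube"))
  b <- as.integer(b)
  if (b < 0L) stopf("`b` must be >= 0", class = "flimstorm_invalid_parameter")
  if (b == 0L) return(cube)
  out <- array(0, dim(cube))
  for (ch in seq_len(dim(cube)[3L])) out[, , ch] <- box_sum(cube[, , ch], b)
  decay_cube(out, attr(cube, "channel_width"))
}

#' Fit a monoexponential decay with instrument response
#'
#' Fits `F(t) = A * (IRF (*) exp(-t/tau)) + B` to a photon-arrival histogram.
#' The default `mle` method maximizes the Poisson log-likelihood of the
#' counts — correct at TCSPC count levels — by a profile search over `tau`
#' (the background fraction is profiled out analytically constrained
#' optimization at each `tau`). The `lsq` method minimizes Neyman-weighted
#' squared residuals (weights `1/max(y, 1)`), the convention of common
#' commercial fitting tools. The reduced chi-square is reported for both.
#' `tau` is constrained to `tau_limits`; coarse-scan ties are broken towards
#' the smallest `tau`.
#'
#' @param curve A [decay_curve()].
#' @param irf An [irf()] on the same channel grid.
#' @param method `"mle"` (default) or `"lsq"`.
#' @param tau_limits Search bounds for `tau` in ns.
#' @param min_photons Required photons in the curve (default 100).
#' @return A `decay_fit` with `tau` (ns), `amplitude` (decay photons),
#'   `background` (photons/channel), `chi2_reduced`, `photons_used`,
#'   `converged`, `method`.
#' @export
fit_decay <- function(curve, irf, method = c("mle", "lsq"),
                      tau_limits = c(0.1, 10), min_photons = 100) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "decay_curve"), inherits(irf, "irf"))
  if (length(curve$counts) != irf$n_channels ||
      abs(curve$channel_width - irf$channel_width) >
        1e-9 * irf$channel_width)
    stopf("decay curve and IRF are on different channel grids",
          class = "flimstorm_grid_error")
  y <- curve$counts
  n_tot <- sum(y)
  if (n_tot < min_photons)
    stopf("insufficient photons for fitting (%d < %d)", n_tot, min_photons,
          class = "flimstorm_insufficient_photons")
  nch <- irf$n_channels
  eps <- 1e-12

  if (method == "mle") {
    # mu = N * ((1-f) * C_tau + f/nch); at the Poisson MLE the fitted total
    # equals the observed total, so (tau, f) parameterizes the full
    # (tau, A, B) optimum.
    nll_f <- function(f, shape) {
      mu <- n_tot * ((1 - f) * shape + f / nch) + eps
      sum(mu) - sum(y * log(mu))
    }
    profile <- function(tau) {
      shape <- decay_model_shape(tau, irf)
      o <- stats::optimize(nll_f, c(0, 0.999), shape = shape, tol = 1e-10)
      c(nll = o$objective, f = o$minimum)
    }
    fit <- tryCatch({
      taus <- exp(seq(log(tau_limits[1L]), log(tau_limits[2L]), length.out = 80L))
      prof <- vapply(taus, function(tt) profile(tt)["nll"], 0)
      i <- which.min(prof)                       # which.min takes the first: smallest tau on ties
      lo <- taus[max(1L, i - 1L)]; hi <- taus[min(length(taus), i + 1L)]
      opt <- stats::optimize(function(tt) profile(tt)["nll"], c(lo, hi), tol = 1e-8)
      tau_hat <- opt$minimum
      f_hat <- profile(tau_hat)[["f"]]
      list(tau = tau_hat, A = n_tot * (1 - f_hat), B = n_tot * f_hat / nch,
           ok = TRUE)
    }, error = function(e) list(tau = NA_real_, A = NA_real_, B = NA_real_,
                                ok = FALSE))
  } else {
    w <- 1 / pmax(y, 1)
    # for fixed tau, mu = A*C + B is linear: weighted LS in (A, B) is closed
    # form, with a non-negativity fallback for B
    lin_fit <- function(shape) {
      sw <- sum(w); swc <- sum(w * shape); swc2 <- sum(w * shape^2)
      swy <- sum(w * y); swcy <- sum(w * shape * y)
      det <- swc2 * sw - swc^2
      A <- (swcy * sw - swc * swy) / det
      B <- (swy * swc2 - swc * swcy) / det
      if (B < 0) { B <- 0; A <- swcy / swc2 }
      if (A < 0) A <- 0
      c(A = A, B = B)
    }
    obj <- function(tau) {
      shape <- decay_model_shape(tau, irf)
      ab <- lin_fit(shape)
      sum(w * (y - ab["A"] * shape - ab["B"])^2)
    }
    fit <- tryCatch({
      taus <- exp(seq(log(tau_limits[1L]), log(tau_limits[2L]), length.out = 80L))
      prof <- vapply(taus, obj, 0)
      i <- which.min(prof)
      lo <- taus[max(1L, i - 1L)]; hi <- taus[min(length(taus), i + 1L)]
      opt <- stats::optimize(obj, c(lo, hi), tol = 1e-8)
      tau_hat <- opt$minimum
      ab <- lin_fit(decay_model_shape(tau_hat, irf))
      list(tau = tau_hat, A = ab[["A"]], B = ab[["B"]], ok = TRUE)
    }, error = function(e) list(tau = NA_real_, A = NA_real_, B = NA_real_,
                                ok = FALSE))
  }

  mu <- if (fit$ok) fit$A * decay_model_shape(fit$tau, irf) + fit$B else rep(NA_real_, nch)
  chi2 <- if (fit$ok) sum((y - mu)^2 / pmax(y, 1)) / (nch - 3L) else NA_real_
  structure(list(tau = fit$tau, amplitude = fit$A, background = fit$B,
                 chi2_reduced = chi2, photons_used = n_tot,
                 converged = fit$ok, method = method,
                 curve = curve, irf = irf, fitted_counts = mu),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Monoexponential TCSPC decay fit (", x$method, ")\n", sep = "")
  if (x$converged) {
    cat(sprintf("  tau = %.4f ns  amplitude = %.1f photons  background = %.3f /channel\n",
                x$tau, x$amplitude, x$background))
    cat(sprintf("  photons used = %d   reduced chi2 = %.3f\n",
                as.integer(x$photons_used), x$chi2_reduced))
  } else cat("  fit did not converge\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(tau = object$tau, amplitude = object$amplitude,
    background = object$background)
}

#' @export
fitted.decay_fit <- function(object, ...) object$fitted_counts

#' @export
residuals.decay_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$curve$counts - object$fitted_counts
  if (type == "pearson") r <- r / sqrt(pmax(object$fitted_counts, 1e-12))
  r
}

#' @export
logLik.decay_fit <- function(object, ...) {
  mu <- pmax(object$fitted_counts, 1e-12)
  y <- object$curve$counts
  structure(sum(stats::dpois(round(y), mu, log = TRUE)), df = 3L,
            class = "logLik")
}

#' @export
plot.decay_fit <- function(x, ...) {
  t_mid <- (seq_along(x$curve$counts) - 0.5) * x$curve$channel_width
  graphics::plot(t_mid, x$curve$counts, type = "h", col = "grey60",
                 xlab = "time (ns)", ylab = "photons", log = "y",
                 ylim = c(max(0.5, min(x$curve$counts[x$curve$counts > 0])),
                          max(x$curve$counts)), ...)
  if (x$converged) graphics::lines(t_mid, x$fitted_counts, col = "red3", lwd = 2)
  invisible(x)
}

#' Fit a per-pixel lifetime map
#'
#' Applies [choose_binning()], [bin_cube()] and per-pixel [fit_decay()] over
#' the masked pixels of a TCSPC cube. Pixels whose fit fails or that carry
#' fewer than `min_photons` after binning are flagged non-converged and
#' excluded from summaries; the map itself is always returned.
#'
#' @param cube A `decay_cube`.
#' @param irf An [irf()].
#' @param mask Logical matrix; `NULL` derives one by Otsu thresholding of
#'   the photon-sum image.
#' @param method Passed to [fit_decay()].
#' @param target_min,target_max,max_factor Passed to [choose_binning()].
#' @param binning Fixed binning factor; `NULL` (default) selects it
#'   automatically.
#' @param min_photons Minimum photons/pixel after binning.
#' @return A `lifetime_map`: matrices `tau`, `amplitude`, `background`,
#'   `chi2`, `photons`, `converged`, plus `binning_factor`, `mask`,
#'   `channel_width`.
#' @export
fit_lifetime_map <- function(cube, irf, mask = NULL, method = "mle",
                             target_min = 3500, target_max = 5000,
                             max_factor = 3L, binning = NULL,
                             min_photons = 100) {
  stopifnot(inherits(cube, "decay_cube"), inherits(irf, "irf"))
  s <- rowSums(cube, dims = 2L)
  if (is.null(mask)) mask <- otsu_mask(s)
  b <- if (is.null(binning))
    choose_binning(cube, mask, target_min, target_max, max_factor)
  else as.integer(binning)
  bc <- bin_cube(cube, b)
  d <- dim(bc)
  tau <- amp <- bg <- chi2 <- phot <- matrix(NA_real_, d[1L], d[2L])
  conv <- matrix(FALSE, d[1L], d[2L])
  dt <- attr(bc, "channel_width")
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    if (!mask[i, j]) next
    cts <- bc[i, j, ]
    phot[i, j] <- sum(cts)
    if (phot[i, j] < min_photons) next
    f <- tryCatch(fit_decay(decay_curve(cts, dt), irf, method = method,
                            min_photons = min_photons),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      tau[i, j] <- f$tau; amp[i, j] <- f$amplitude; bg[i, j] <- f$background
      chi2[i, j] <- f$chi2_reduced
      conv[i, j] <- TRUE
    }
  }
  structure(list(tau = tau, amplitude = amp, background = bg, chi2 = chi2,
                 photons = phot, converged = conv, binning_factor = b,
                 mask = mask, channel_width = dt, method = method),
            class = "lifetime_map")
}

# Otsu threshold of the photon-sum image; all-TRUE mask for a blank image
# (every pixel then simply fails the photon cut downstream).
otsu_mask <- function(s) {
  mx <- max(s)
  if (mx <= 0) return(matrix(TRUE, nrow(s), ncol(s)))
  thr <- EBImage::otsu(EBImage::Image(s / mx)) * mx
  s > thr
}

#' @export
print.lifetime_map <- function(x, ...) {
  n_conv <- sum(x$converged)
  cat(sprintf("Lifetime map %d x %d, binning factor %d, %d converged pixels\n",
              nrow(x$tau), ncol(x$tau), x$binning_factor, n_conv))
  if (n_conv > 0)
    cat(sprintf("  tau: mean %.3f ns, range [%.3f, %.3f] ns\n",
                mean(x$tau[x$converged]), min(x$tau[x$converged]),
                max(x$tau[x$converged])))
  invisible(x)
}

#' @export
summary.lifetime_map <- function(object, ...) {
  taus <- object$tau[object$converged]
  out <- list(n_pixels = length(object$tau), n_converged = length(taus),
              binning_factor = object$binning_factor,
              mean_tau = if (length(taus)) mean(taus) else NA_real_,
              sd_tau = if (length(taus) > 1) stats::sd(taus) else NA_real_)
  class(out) <- "summary.lifetime_map"
  out
}

#' @export
print.summary.lifetime_map <- function(x, ...) {
  cat(sprintf("Lifetime map: %d/%d converged pixels (binning %d)\n",
              x$n_converged, x$n_pixels, x$binning_factor))
  cat(sprintf("  mean tau %.3f ns, SD %.3f ns\n", x$mean_tau, x$sd_tau))
  invisible(x)
}

#' @export
plot.lifetime_map <- function(x, ...) {
  z <- x$tau
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "fluorescence lifetime (ns)", ...)
  invisible(x)
}

#' @export
as.data.frame.lifetime_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  data.frame(row = idx[, 1L], col = idx[, 2L], tau = x$tau[idx],
             amplitude = x$amplitude[idx], background = x$background[idx],
             chi2 = x$chi2[idx], photons = x$photons[idx],
             converged = x$converged[idx])
}

#' Per-pixel lifetime frequency histogram
#'
#' Histograms the converged pixel lifetimes of a region and normalizes the
#' counts to unit maximum, the convention used for per-pixel lifetime
#' frequency panels in FLIM figures.
#'
#' @param map A `lifetime_map`.
#' @param region Logical matrix selecting pixels; `NULL` means all.
#' @param bin_width Histogram bin width in ns (> 0).
#' @return A `lifetime_histogram` with `breaks`, `mids`, `counts`,
#'   `normalized` (unit maximum). Empty regions give empty histograms.
#' @export
lifetime_histogram <- function(map, region = NULL, bin_width = 0.05) {
  stopifnot(inherits(map, "lifetime_map"))
  check_scalar_pos(bin_width, "bin_width")
  sel <- map$converged
  if (!is.null(region)) sel <- sel & region
  taus <- map$tau[sel]
  if (length(taus) == 0L) {
    return(structure(list(breaks = numeric(0), mids = numeric(0),
                          counts = numeric(0), normalized = numeric(0),
                          bin_width = bin_width),
                     class = "lifetime_histogram"))
  }
  lo <- floor(min(taus) / bin_width) * bin_width
  hi <- ceiling(max(taus) / bin_width + 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- graphics::hist(taus, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  structure(list(breaks = breaks, mids = utils::head(breaks, -1L) + bin_width / 2,
                 counts = counts, normalized = counts / max(counts),
                 bin_width = bin_width),
            class = "lifetime_histogram")
}

#' @export
print.lifetime_histogram <- function(x, ...) {
  cat(sprintf("Lifetime histogram: %d bins, %d pixels\n",
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.lifetime_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$normalized, type = "s", xlab = "lifetime (ns)",
                 ylab = "normalized frequency", ...)
  invisible(x)
}

#' Mean lifetime across independent images
#'
#' Two-level averaging: the mean over converged region pixels is computed per
#' image, and these per-image means are then averaged, reported with the SEM
#' across images. Images are weighted equally regardless of pixel count.
#'
#' @param maps A `lifetime_map` or list of them.
#' @param region Logical matrix (recycled across maps) or list of matrices;
#'   `NULL` means all converged pixels.
#' @param region_label Optional label carried into the summary.
#' @return A `lifetime_summary` with `mean_tau`, `sem_tau`, `n_images`,
#'   `region_label`, `per_image_means`.
#' @export
region_mean_lifetime <- function(maps, region = NULL, region_label = NA_character_) {
  if (inherits(maps, "lifetime_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "lifetime_map")))
  regions <- if (is.null(region)) vector("list", length(maps))
    else if (is.list(region)) region else rep(list(region), length(maps))
  means <- numeric(0)
  for (k in seq_along(maps)) {
    sel <- maps[[k]]$converged
    if (!is.null(regions[[k]])) sel <- sel & regions[[k]]
    taus <- maps[[k]]$tau[sel]
    if (length(taus) > 0L) means <- c(means, mean(taus))
  }
  if (length(means) == 0L)
    stopf("region contains no converged pixels in any map",
          class = "flimstorm_empty_region")
  ms <- mean_sem(means)
  structure(list(mean_tau = ms$mean, sem_tau = ms$sem, n_images = ms$n,
                 region_label = region_label, per_image_means = means),
            class = "lifetime_summary")
}

#' @export
print.lifetime_summary <- function(x, ...) {
  cat(sprintf("Mean lifetime %.3f +/- %.3f ns (SEM, n = %d images%s)\n",
              x$mean_tau, x$sem_tau, x$n_images,
              if (is.na(x$region_label)) "" else paste0(", region ", x$region_label)))
  invisible(x)
}
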