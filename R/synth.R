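#' Instrument response function (IRF) on a TCSPC channel grid
#'
#' Constructs an IRF object from per-channel amplitudes. The IRF is the
#' measured temporal response of a TCSPC system to an instantaneous pulse;
#' observed decays are its convolution with the molecular decay, so every
#' decay fit in this package carries an `irf` alongside the data.
#'
#' @param amplitudes Non-negative per-channel weights; normalized to sum 1.
#' @param channel_width Channel width in ns.
#' @return An object of class `irf` with fields `amplitudes`, `channel_width`,
#'   `centroid` (ns), `n_channels`, `window` (ns).
#' @export
irf <- function(amplitudes, channel_width) {
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stopf("IRF amplitudes must be finite and non-negative",
          class = "flimstorm_invalid_parameter")
  check_scalar_pos(channel_width, "channel_width")
  s <- sum(amplitudes)
  if (s <= 0) stopf("IRF amplitudes must not all be zero",
                    class = "flimstorm_invalid_parameter")
  a <- amplitudes / s
  n <- length(a)
  t_mid <- (seq_len(n) - 0.5) * channel_width
  structure(list(amplitudes = a, channel_width = channel_width,
                 centroid = sum(t_mid * a), n_channels = n,
                 window = n * channel_width),
            class = "irf")
}

#' Simulate a Gaussian instrument response
#'
#' Discretized Gaussian IRF centred at a quarter of the TCSPC window, the
#' standard surrogate when only the width of the measured response (from
#' reflected excitation light) is known. Defaults follow a 40 MHz pulsed
#' source: a 25 ns window divided into 256 channels and a 0.2 ns FWHM.
#'
#' @param fwhm Full width at half maximum in ns.
#' @param n_channels Number of TCSPC channels (>= 8).
#' @param window TCSPC window in ns (laser repetition period).
#' @return An `irf` object.
#' @export
simulate_irf <- function(fwhm = 0.2, n_channels = 256L, window = 25) {
  check_scalar_pos(fwhm, "fwhm")
  check_scalar_pos(window, "window")
  if (!is.numeric(n_channels) || n_channels < 8)
    stopf("`n_channels` must be >= 8", class = "flimstorm_invalid_parameter")
  n_channels <- as.integer(n_channels)
  centre <- window / 4
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  edges <- seq(0, window, length.out = n_channels + 1L)
  amp <- stats::pnorm(edges[-1L], centre, sdev) -
    stats::pnorm(edges[-(n_channels + 1L)], centre, sdev)
  irf(amp, window / n_channels)
}

#' Idealized delta-function IRF
#'
#' All response in a single channel; useful for analytic checks where the
#' convolution must reduce to a pure exponential.
#'
#' @param n_channels Number of channels.
#' @param window Window in ns.
#' @param at Position of the delta in ns (default `window/4`).
#' @return An `irf` object.
#' @export
delta_irf <- function(n_channels = 256L, window = 25, at = window / 4) {
  n_channels <- as.integer(n_channels)
  dt <- window / n_channels
  a <- numeric(n_channels)
  a[min(n_channels, floor(at / dt) + 1L)] <- 1
  irf(a, dt)
}

#' Ground-truth parameters of a monoexponential TCSPC decay
#'
#' @param tau Fluorescence lifetime in ns (> 0).
#' @param n_photons Total photons to draw (>= 0).
#' @param amplitude_fraction Fraction of photons from the decay (the rest are
#'   uniform background), in \[0, 1\].
#' @return A `decay_truth` object.
#' @export
decay_truth <- function(tau, n_photons, amplitude_fraction = 1) {
  check_scalar_pos(tau, "tau")
  check_fraction(amplitude_fraction, "amplitude_fraction")
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 0)
    stopf("`n_photons` must be a single count >= 0",
          class = "flimstorm_invalid_parameter")
  structure(list(tau = tau, amplitude_fraction = amplitude_fraction,
                 background_fraction = 1 - amplitude_fraction,
                 n_photons = as.integer(round(n_photons))),
            class = "decay_truth")
}

#' Photon-arrival histogram (TCSPC decay curve)
#'
#' @param counts Non-negative integer counts per channel.
#' @param channel_width Channel width in ns.
#' @return A `decay_curve` with `counts`, `channel_width`, `total_photons`.
#' @export
decay_curve <- function(counts, channel_width) {
  if (any(counts < 0)) stopf("decay counts must be non-negative")
  check_scalar_pos(channel_width, "channel_width")
  structure(list(counts = as.numeric(counts), channel_width = channel_width,
                 total_photons = sum(counts)),
            class = "decay_curve")
}

#' Simulate a TCSPC decay curve
#'
#' Draws exactly `truth$n_photons` photon arrival times. With probability
#' `amplitude_fraction` a photon arises from the IRF convolved with an
#' exponential decay of lifetime `tau`; arrival times later than the window
#' are folded back periodically (incomplete decay of long lifetimes under a
#' finite repetition period). Remaining photons are uniform background.
#' Re-excitation pile-up is not modelled; count rates in the experiments this
#' emulates are kept below 1% of the repetition rate, where pile-up is
#' negligible.
#'
#' @param truth A [decay_truth()].
#' @param irf An [irf()] defining the channel grid and response.
#' @param seed Optional integer seed.
#' @return A [decay_curve()].
#' @export
simulate_decay <- function(truth, irf, seed = NULL) {
  stopifnot(inherits(truth, "decay_truth"), inherits(irf, "irf"))
  set_seed_if(seed)
  nch <- irf$n_channels
  dt <- irf$channel_width
  if (truth$n_photons == 0L) return(decay_curve(integer(nch), dt))
  arr <- sample_arrivals(truth, irf)
  idx <- pmin(nch, floor(arr$t / dt) + 1L)
  decay_curve(tabulate(idx, nbins = nch), dt)
}

# Continuous photon arrival times before histogramming: excitation time t0
# drawn from the IRF (uniform within the chosen channel), exponential delay
# folded into the window for signal photons, uniform arrivals for background.
sample_arrivals <- function(truth, irf) {
  n <- truth$n_photons
  dt <- irf$channel_width
  win <- irf$window
  n_sig <- stats::rbinom(1L, n, truth$amplitude_fraction)
  t0 <- t <- numeric(0)
  if (n_sig > 0L) {
    ch <- sample.int(irf$n_channels, n_sig, replace = TRUE,
                     prob = irf$amplitudes)
    t0 <- (ch - 1L) * dt + stats::runif(n_sig) * dt
    t <- (t0 + stats::rexp(n_sig, rate = 1 / truth$tau)) %% win
  }
  if (n - n_sig > 0L) {
    t <- c(t, stats::runif(n - n_sig, 0, win))
    t0 <- c(t0, rep(NA_real_, n - n_sig))
  }
  data.frame(t = t, t0 = t0, signal = !is.na(t0))
}

#' Per-pixel ground-truth grid for a TCSPC image
#'
#' Scalars are recycled to the dimensions of `tau`.
#'
#' @param tau Matrix of lifetimes (ns).
#' @param n_photons Matrix or scalar photon budgets.
#' @param amplitude_fraction Matrix or scalar decay fractions.
#' @return A `decay_truth_map`.
#' @export
decay_truth_map <- function(tau, n_photons, amplitude_fraction = 1) {
  if (!is.matrix(tau)) stopf("`tau` must be a matrix", class = "flimstorm_shape_error")
  expand <- function(x, name) {
    if (length(x) == 1L) return(matrix(x, nrow(tau), ncol(tau)))
    if (!is.matrix(x) || !all(dim(x) == dim(tau)))
      stopf("`%s` must match the dimensions of `tau`", name,
            class = "flimstorm_shape_error")
    x
  }
  structure(list(tau = tau, n_photons = expand(n_photons, "n_photons"),
                 amplitude_fraction = expand(amplitude_fraction, "amplitude_fraction")),
            class = "decay_truth_map")
}

#' Simulate a TCSPC image cube
#'
#' Assembles per-pixel simulated decays into an (rows x cols x channels)
#' photon-count cube.
#'
#' @param truth_map A [decay_truth_map()].
#' @param irf An [irf()].
#' @param seed Optional integer seed.
#' @return A `decay_cube`: numeric array `[row, col, channel]` with attribute
#'   `channel_width` (ns).
#' @export
simulate_tcspc_image <- function(truth_map, irf, seed = NULL) {
  stopifnot(inherits(truth_map, "decay_truth_map"), inherits(irf, "irf"))
  set_seed_if(seed)
  d <- dim(truth_map$tau)
  cube <- array(0, c(d[1L], d[2L], irf$n_channels))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    tr <- decay_truth(truth_map$tau[i, j], truth_map$n_photons[i, j],
                      truth_map$amplitude_fraction[i, j])
    cube[i, j, ] <- simulate_decay(tr, irf)$counts
  }
  decay_cube(cube, irf$channel_width)
}

#' TCSPC decay cube constructor
#'
#' @param counts Numeric array `[row, col, channel]`, non-negative.
#' @param channel_width Channel width in ns.
#' @return A `decay_cube`.
#' @export
decay_cube <- function(counts, channel_width) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stopf("decay cube must be a 3-D array [row, col, channel]",
          class = "flimstorm_shape_error")
  if (any(counts < 0)) stopf("decay cube counts must be non-negative")
  check_scalar_pos(channel_width, "channel_width")
  structure(counts, channel_width = channel_width, class = "decay_cube")
}

#' Ground-truth blinking emitters decorating an aggregate shape
#'
#' Places fluorophores uniformly over a compact 2-D aggregate footprint:
#' `"sphere"` is the projected disc of an approximately spherical aggregate;
#' `"rod"` is an elongated 3:1 rectangle. `size` is the longest dimension
#' (maximal caliper extent) of the shape in nm, matching how aggregate sizes
#' are measured downstream; for the rod the rectangle is scaled so its
#' diagonal equals `size`.
#'
#' @param kind `"sphere"` or `"rod"`.
#' @param size Longest dimension in nm (> 0).
#' @param n_fluorophores Number of emitters (>= 1).
#' @param center Centre (x, y) in nm.
#' @param angle Rod orientation in radians; default drawn uniformly.
#' @param photons_mean Expected photons per on-frame.
#' @param on_probability Per-frame on probability in \[0, 1\].
#' @param shape_label Label identifying the aggregate.
#' @param seed Optional integer seed.
#' @return An `emitter_set`: data.frame `x`, `y` (nm), `shape_label`, with
#'   attributes `photons_mean` and `on_probability`.
#' @export
simulate_aggregate_emitters <- function(kind = c("sphere", "rod"), size,
                                        n_fluorophores, center = c(0, 0),
                                        angle = NULL, photons_mean = 2000,
                                        on_probability = 0.02,
                                        shape_label = 1L, seed = NULL) {
  kind <- match.arg(kind)
  check_scalar_pos(size, "size")
  if (!is.numeric(n_fluorophores) || n_fluorophores < 1)
    stopf("`n_fluorophores` must be >= 1", class = "flimstorm_invalid_parameter")
  check_scalar_pos(photons_mean, "photons_mean")
  check_fraction(on_probability, "on_probability")
  set_seed_if(seed)
  n <- as.integer(n_fluorophores)
  if (kind == "sphere") {
    r <- (size / 2) * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
  } else {
    len <- 3 * size / sqrt(10)          # diagonal of a 3:1 rectangle == size
    wid <- len / 3
    if (is.null(angle)) angle <- stats::runif(1L, 0, pi)
    u <- stats::runif(n, -len / 2, len / 2)
    v <- stats::runif(n, -wid / 2, wid / 2)
    x <- u * cos(angle) - v * sin(angle)
    y <- u * sin(angle) + v * cos(angle)
  }
  emitter_set(data.frame(x = x + center[1L], y = y + center[2L],
                         shape_label = shape_label),
              photons_mean = photons_mean, on_probability = on_probability)
}

#' Emitter set constructor
#'
#' @param positions data.frame with `x`, `y` in nm and `shape_label`.
#' @param photons_mean Expected photons per on-frame (> 0).
#' @param on_probability Per-frame on probability in \[0, 1\].
#' @return An `emitter_set`.
#' @export
emitter_set <- function(positions, photons_mean = 2000, on_probability = 0.02) {
  stopifnot(is.data.frame(positions), all(c("x", "y") %in% names(positions)))
  if (is.null(positions$shape_label)) positions$shape_label <- 1L
  check_scalar_pos(photons_mean, "photons_mean")
  check_fraction(on_probability, "on_probability")
  structure(positions, photons_mean = photons_mean,
            on_probability = on_probability,
            class = c("emitter_set", "data.frame"))
}

#' Combine emitter sets (e.g. several aggregates in one field)
#'
#' Photon statistics are taken from the first set.
#'
#' @param ... `emitter_set` objects.
#' @return A single `emitter_set`.
#' @export
combine_emitters <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "emitter_set")))
  df <- do.call(rbind, lapply(sets, as.data.frame))
  emitter_set(df, photons_mean = attr(sets[[1L]], "photons_mean"),
              on_probability = attr(sets[[1L]], "on_probability"))
}

#' EMCCD camera model for blinking-movie simulation
#'
#' Gaussian read noise on top of Poisson photon counting approximates the
#' EMCCD gain register at the photon levels simulated here.
#'
#' @param pixel_size Pixel size in nm (the `a` of the Thompson precision
#'   formula).
#' @param psf_sigma PSF standard deviation in nm (the `s` of the Thompson
#'   formula).
#' @param background_rate Background photons/pixel/frame (Poisson mean).
#' @param read_noise_sd Read noise SD in photons (>= 0).
#' @return A `camera_model`.
#' @export
camera_model <- function(pixel_size = 100, psf_sigma = 150,
                         background_rate = 2, read_noise_sd = 0) {
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(psf_sigma, "psf_sigma")
  check_scalar_pos(background_rate, "background_rate", allow_zero = TRUE)
  check_scalar_pos(read_noise_sd, "read_noise_sd", allow_zero = TRUE)
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_rate = background_rate,
                 read_noise_sd = read_noise_sd),
            class = "camera_model")
}

#' Simulate a widefield blinking movie (dSTORM raw data)
#'
#' Each frame, each emitter switches on independently with its per-frame
#' `on_probability` (memoryless blinking). On-emitters contribute
#' Poisson-distributed photons through a pixel-integrated Gaussian PSF;
#' Poisson background and Gaussian read noise are added, and frames are
#' clipped at zero. Pixel `(i, j)` (0-based) covers
#' `[j*a, (j+1)*a) x [i*a, (i+1)*a)` nm with `x` along columns.
#'
#' @param emitters An [emitter_set()].
#' @param camera A [camera_model()].
#' @param n_frames Number of frames (>= 1).
#' @param fov Field of view in pixels `c(nx, ny)`; default covers the
#'   emitters with a 5 PSF-sigma margin.
#' @param seed Optional integer seed.
#' @return A `frame_stack`: array `[row, col, frame]` with attribute `camera`.
#' @export
simulate_blinking_movie <- function(emitters, camera, n_frames, fov = NULL,
                                    seed = NULL) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(camera, "camera_model"))
  if (!is.numeric(n_frames) || n_frames < 1)
    stopf("`n_frames` must be >= 1", class = "flimstorm_invalid_parameter")
  set_seed_if(seed)
  a <- camera$pixel_size
  s_px <- camera$psf_sigma / a
  if (is.null(fov)) {
    margin <- 5 * camera$psf_sigma
    nx <- ceiling((max(emitters$x) + margin) / a)
    ny <- ceiling((max(emitters$y) + margin) / a)
    fov <- c(max(nx, 8L), max(ny, 8L))
  }
  nx <- as.integer(fov[1L]); ny <- as.integer(fov[2L])
  n_frames <- as.integer(n_frames)
  p_on <- attr(emitters, "on_probability")
  nbar <- attr(emitters, "photons_mean")
  n_em <- nrow(emitters)
  # pixel-integrated PSF weights, precomputed per emitter over +/-4 sigma
  half <- ceiling(4 * s_px)
  ex <- emitters$x / a; ey <- emitters$y / a      # in pixel units
  psf <- vector("list", n_em)
  for (k in seq_len(n_em)) {
    jc <- floor(ex[k]); ic <- floor(ey[k])
    js <- max(0L, jc - half):min(nx - 1L, jc + half)
    is <- max(0L, ic - half):min(ny - 1L, ic + half)
    wx <- stats::pnorm(js + 1, ex[k], s_px) - stats::pnorm(js, ex[k], s_px)
    wy <- stats::pnorm(is + 1, ey[k], s_px) - stats::pnorm(is, ey[k], s_px)
    psf[[k]] <- list(rows = is + 1L, cols = js + 1L, w = outer(wy, wx))
  }
  stack <- array(0, c(ny, nx, n_frames))
  for (f in seq_len(n_frames)) {
    lam <- matrix(camera$background_rate, ny, nx)
    on <- stats::runif(n_em) < p_on
    for (k in which(on)) {
      p <- psf[[k]]
      lam[p$rows, p$cols] <- lam[p$rows, p$cols] + nbar * p$w
    }
    fr <- matrix(stats::rpois(length(lam), lam), ny, nx)
    if (camera$read_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, camera$read_noise_sd), ny, nx)
    stack[, , f] <- pmax(fr, 0)
  }
  structure(stack, camera = camera, class = "frame_stack")
}

#' Sigmoid parameters for an aggregation time course
#'
#' The decreasing logistic `L(t) = Linf + (L0 - Linf) / (1 + exp(k*(t - t50)))`
#' describes the drop in fluorescence lifetime as labelled peptide converts
#' into amyloid; `L0 > Linf` gives a falling trace. The lag phase is
#' `t50 - 2/k` (tangent construction).
#'
#' @param L0 Baseline value (ns for lifetime traces).
#' @param Linf Plateau value.
#' @param k Rate constant (1/hr, > 0).
#' @param t50 Midpoint (hr).
#' @return A `sigmoid_params` list.
#' @export
sigmoid_params <- function(L0, Linf, k, t50) {
  check_scalar_pos(k, "k")
  if (L0 == Linf) stopf("`L0` must differ from `Linf`",
                        class = "flimstorm_invalid_parameter")
  structure(list(L0 = L0, Linf = Linf, k = k, t50 = t50),
            class = "sigmoid_params")
}

sigmoid_value <- function(p, t) p$Linf + (p$L0 - p$Linf) / (1 + exp(p$k * (t - p$t50)))

#' Simulate a lifetime-versus-time aggregation trace
#'
#' Sigmoid plus i.i.d. Gaussian noise; the expectation is monotone
#' non-increasing when `L0 > Linf`.
#'
#' @param fit_truth A [sigmoid_params()].
#' @param times Strictly increasing sampling times (hr).
#' @param noise_sd Gaussian noise SD (readout units, >= 0).
#' @param seed Optional integer seed.
#' @param kind Readout kind label.
#' @return A [kinetic_trace()].
#' @export
simulate_lifetime_timecourse <- function(fit_truth, times, noise_sd = 0.03,
                                         seed = NULL, kind = "lifetime") {
  stopifnot(inherits(fit_truth, "sigmoid_params"))
  if (is.unsorted(times, strictly = TRUE))
    stopf("`times` must be strictly increasing", class = "flimstorm_invalid_input")
  check_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  set_seed_if(seed)
  v <- sigmoid_value(fit_truth, times)
  if (noise_sd > 0) v <- v + stats::rnorm(length(times), 0, noise_sd)
  kinetic_trace(times, v, kind = kind)
}
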