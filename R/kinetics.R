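#' Kinetic trace constructor
#'
#' A time-resolved summary readout: lifetime (ns), fluorescence intensity or
#' densitometry versus time.
#'
#' @param times Strictly increasing times in hours.
#' @param values Readout values.
#' @param errors Optional per-point SD/SEM.
#' @param kind `"lifetime"`, `"intensity"` or `"densitometry"`.
#' @return A `kinetic_trace` data.frame (`time_hr`, `value`, optional `sem`)
#'   with attribute `kind`.
#' @export
kinetic_trace <- function(times, values, errors = NULL,
                          kind = c("lifetime", "intensity", "densitometry")) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stopf("`times` and `values` lengths differ", class = "flimstorm_invalid_input")
  if (is.unsorted(times, strictly = TRUE))
    stopf("`times` must be strictly increasing", class = "flimstorm_invalid_input")
  df <- data.frame(time_hr = times, value = values)
  if (!is.null(errors)) {
    if (length(errors) != length(times))
      stopf("`errors` length differs", class = "flimstorm_invalid_input")
    df$sem <- errors
  }
  structure(df, kind = kind, class = c("kinetic_trace", "data.frame"))
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace (%s): %d points over %.2f-%.2f hr\n",
              attr(x, "kind"), nrow(x), min(x$time_hr), max(x$time_hr)))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$time_hr, x$value, xlab = "time (hr)",
                 ylab = attr(x, "kind"), pch = 16, ...)
  if (!is.null(x$sem))
    graphics::arrows(x$time_hr, x$value - x$sem, x$time_hr, x$value + x$sem,
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Normalize a kinetic trace
#'
#' `"max"` divides by the maximum (the convention for fibril-quantity
#' densitometry reported relative to the maximum value); `"minmax"` rescales
#' to span exactly \[0, 1\].
#'
#' @param trace A [kinetic_trace()].
#' @param mode `"max"` or `"minmax"`.
#' @return A `kinetic_trace` with rescaled values.
#' @export
normalize_trace <- function(trace, mode = c("max", "minmax")) {
  mode <- match.arg(mode)
  if (nrow(trace) == 0L) stopf("empty trace", class = "flimstorm_invalid_input")
  v <- trace$value
  if (mode == "max") {
    if (max(v) == 0) stopf("maximum is zero; cannot normalize",
                           class = "flimstorm_degenerate_trace")
    v <- v / max(v)
  } else {
    rng <- range(v)
    if (diff(rng) == 0)
      stopf("zero range; cannot min-max normalize",
            class = "flimstorm_degenerate_trace")
    v <- (v - rng[1L]) / diff(rng)
  }
  kinetic_trace(trace$time_hr, v, errors = trace$sem, kind = attr(trace, "kind"))
}

#' Fit a sigmoid to an aggregation time course
#'
#' Least-squares fit of the logistic
#' `L(t) = Linf + (L0 - Linf) / (1 + exp(k (t - t50)))` with `k > 0`
#' (decreasing when `L0 > Linf`, rising when `L0 < Linf`), using
#' Levenberg-Marquardt from a grid of starting values (`t50` over the time
#' span, several rates). The lag phase is the tangent construction
#' `t50 - 2/k`: the intersection of the maximal-slope tangent with the
#' baseline, the standard convention in amyloid aggregation kinetics.
#'
#' @param trace A [kinetic_trace()] with >= 5 points.
#' @param n_starts Number of `t50` starting values.
#' @return A `sigmoid_fit` with `L0`, `Linf`, `k`, `t50`, `lag`
#'   (`t50 - 2/k`, unclamped), `rss`, `converged` and the trace.
#' @export
fit_sigmoid <- function(trace, n_starts = 7L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (nrow(trace) < 5L)
    stopf("need >= 5 time points to fit a sigmoid",
          class = "flimstorm_invalid_input")
  t <- trace$time_hr; y <- trace$value
  span <- diff(range(t))
  resid_fn <- function(p) y - (p[2L] + (p[1L] - p[2L]) /
                                 (1 + exp(p[3L] * (t - p[4L]))))
  best <- NULL
  t50_starts <- seq(min(t) + 0.1 * span, max(t) - 0.1 * span,
                    length.out = n_starts)
  k_starts <- c(0.5, 1, 2, 5, 10) / span
  for (t50s in t50_starts) for (ks in k_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(L0 = y[1L], Linf = y[length(y)],
                                 k = ks * 4, t50 = t50s),
                         fn = resid_fn,
                         lower = c(-Inf, -Inf, 1e-6, min(t) - span),
                         upper = c(Inf, Inf, Inf, max(t) + span),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    # info 0 = improper input; 5 = evaluation budget reached, which in flat
    # valleys (transition partly outside the window) still yields the
    # least-squares optimum — keep its rss rather than discard it
    if (is.null(fit) || fit$info == 0L || !all(is.finite(fit$par))) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop(errorCondition("sigmoid fit failed from every start",
                        rss = NA_real_,
                        class = c("flimstorm_fit_failure", "error", "condition")))
  p <- best$par
  structure(list(L0 = p[["L0"]], Linf = p[["Linf"]], k = p[["k"]],
                 t50 = p[["t50"]], lag = p[["t50"]] - 2 / p[["k"]],
                 rss = best$rss, converged = TRUE, trace = trace),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Sigmoid fit of aggregation time course\n")
  cat(sprintf("  L0 = %.4f  Linf = %.4f  k = %.4f /hr  t50 = %.4f hr\n",
              x$L0, x$Linf, x$k, x$t50))
  cat(sprintf("  lag (t50 - 2/k) = %.4f hr  rss = %.4g\n", x$lag, x$rss))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(L0 = object$L0, Linf = object$Linf, k = object$k, t50 = object$t50)
}

#' @export
predict.sigmoid_fit <- function(object, times = object$trace$time_hr, ...) {
  object$Linf + (object$L0 - object$Linf) /
    (1 + exp(object$k * (times - object$t50)))
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$trace$value - predict(object)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  plot(x$trace, ...)
  tt <- seq(min(x$trace$time_hr), max(x$trace$time_hr), length.out = 200L)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::abline(v = max(0, x$lag), lty = 2, col = "grey40")
  invisible(x)
}

#' Lag time of an aggregation time course
#'
#' The tangent-construction lag `t50 - 2/k`, clamped at zero: kinetics whose
#' tangent intercept falls before time zero show no detectable lag phase.
#'
#' @param fit A converged `sigmoid_fit`.
#' @return Lag time in hours (>= 0).
#' @export
lag_time <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"), isTRUE(fit$converged))
  max(0, fit$t50 - 2 / fit$k)
}

#' Half-time offset between two paired kinetic readouts
#'
#' Fits each trace independently and returns `t50(a) - t50(b)`: positive
#' when readout `a` lags behind (transitions later than) readout `b`, e.g. a
#' lifetime decrease that is slower than the rise of fibril-specific
#' immunoreactivity.
#'
#' @param trace_a,trace_b [kinetic_trace()] objects.
#' @return Offset in hours, with attribute `fits`.
#' @export
half_time_offset <- function(trace_a, trace_b) {
  fa <- fit_sigmoid(trace_a)
  fb <- fit_sigmoid(trace_b)
  structure(fa$t50 - fb$t50, fits = list(a = fa, b = fb))
}
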