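stopf <- function(fmt, ..., class = "flimstorm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

check_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stopf("`%s` must be a single %s number, got %s", name,
          if (allow_zero) "non-negative" else "positive",
          paste(format(x), collapse = ","),
          class = "flimstorm_invalid_parameter")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must lie in [0, 1]", name, class = "flimstorm_invalid_parameter")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stopf("`seed` must be a single integer", class = "flimstorm_invalid_parameter")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Edge-truncated sliding-window (2b+1)x(2b+1) box sum via an integral image.
box_sum <- function(m, b) {
  b <- as.integer(b)
  if (b < 0L) stopf("binning factor must be >= 0", class = "flimstorm_invalid_parameter")
  if (b == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs <- cbind(0, t(apply(cs, 1L, cumsum)))
  r1 <- pmax(seq_len(nr) - b, 1L); r2 <- pmin(seq_len(nr) + b, nr)
  c1 <- pmax(seq_len(nc) - b, 1L); c2 <- pmin(seq_len(nc) + b, nc)
  cs[r2 + 1L, c2 + 1L, drop = FALSE] - cs[r1, c2 + 1L, drop = FALSE] -
    cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
}

# mean +/- standard error; n == 1 gives SEM 0 (degenerate, warned on by callers
# that care).
mean_sem <- function(x) {
  n <- length(x)
  list(mean = mean(x), sem = if (n > 1L) stats::sd(x) / sqrt(n) else 0, n = n)
}
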