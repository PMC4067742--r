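stat_result <- function(method, statistic, df, p_value, comparison,
                        significant = NA, stars = "") {
  data.frame(method = method, comparison = comparison, statistic = statistic,
             df = df, p_value = p_value, significant = significant,
             stars = stars, stringsAsFactors = FALSE)
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Paired Student's t test
#'
#' Two-sided paired t test: `t = mean(d) / (sd(d)/sqrt(n))` on the
#' differences `d = a - b`, with `n - 1` degrees of freedom.
#'
#' @param a,b Paired samples of equal length >= 2.
#' @param comparison Label for the comparison.
#' @return A `stat_result` data.frame row: `method`, `comparison`,
#'   `statistic`, `df`, `p_value`, `significant` (at 0.05), `stars`.
#' @export
paired_t_test <- function(a, b, comparison = "a vs b") {
  if (length(a) != length(b))
    stopf("paired samples must have equal length", class = "flimstorm_invalid_input")
  n <- length(a)
  if (n < 2L) stopf("need n >= 2 pairs", class = "flimstorm_invalid_input")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero variance of differences with nonzero mean: p -> 0")
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  out <- stat_result("paired_t", t_stat, n - 1L, p, comparison,
                     significant = p < 0.05, stars = significance_stars(p))
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Protected Fisher's least significant difference test
#'
#' One-way ANOVA provides the pooled mean squared error; every group pair is
#' then compared with `t = (mean_i - mean_j) / sqrt(MSE (1/n_i + 1/n_j))` on
#' `N - g` degrees of freedom (two-sided). The pairwise tests are protected:
#' comparisons are only declared significant when the omnibus F test rejects
#' at `alpha`. Stars follow the conventional thresholds 0.05, 0.01, 0.001,
#' 0.0001.
#'
#' @param groups Named (or unnamed) list of >= 3 numeric samples, each with
#'   n >= 2.
#' @param alpha Protection level for the omnibus gate.
#' @return A `stat_result` data.frame, one row per pair, with attributes
#'   `F`, `df1`, `df2`, `p_omnibus`, `mse`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 3L) stopf("need >= 3 groups", class = "flimstorm_invalid_input")
  ns <- lengths(groups)
  if (any(ns < 2L)) stopf("every group needs n >= 2",
                          class = "flimstorm_invalid_input")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(g))
  n_tot <- sum(ns)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / n_tot
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  ssb <- sum(ns * (means - grand)^2)
  df1 <- g - 1L; df2 <- n_tot - g
  mse <- ssw / df2
  f_stat <- (ssb / df1) / mse
  p_omni <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  protected_ok <- p_omni < alpha
  pairs <- utils::combn(g, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    t_stat <- if (se == 0) 0 else (means[i] - means[j]) / se
    p <- 2 * stats::pt(-abs(t_stat), df = df2)
    stat_result("fisher_lsd", t_stat, df2, p,
                paste(names(groups)[i], "vs", names(groups)[j]),
                significant = protected_ok && p < alpha,
                stars = if (protected_ok) significance_stars(p) else "")
  })
  out <- do.call(rbind, rows)
  attr(out, "F") <- f_stat
  attr(out, "df1") <- df1
  attr(out, "df2") <- df2
  attr(out, "p_omnibus") <- p_omni
  attr(out, "mse") <- mse
  class(out) <- c("stat_result", "data.frame")
  out
}

#' @export
print.stat_result <- function(x, ...) {
  if (!is.null(attr(x, "F")))
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g%s\n",
                attr(x, "df1"), attr(x, "df2"), attr(x, "F"),
                attr(x, "p_omnibus"),
                if (attr(x, "p_omnibus") < 0.05) "" else "  (pairwise tests not protected)"))
  for (k in seq_len(nrow(x)))
    cat(sprintf("  %-18s t = %8.4f  df = %3d  p = %.4g %s\n",
                x$comparison[k], x$statistic[k], x$df[k], x$p_value[k],
                x$stars[k]))
  invisible(x)
}
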