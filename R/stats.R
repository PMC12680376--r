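#' One-sample sign-flip permutation t-test
#'
#' Tests whether per-subject scores have zero mean by randomly flipping the
#' sign of each score and recomputing the one-sample t statistic. When the
#' full flip space is small (2^n <= n_perm) it is enumerated exhaustively
#' and the p-value is the exact proportion of assignments at least as
#' extreme; otherwise `n_perm` random flips are drawn and the observed
#' statistic is counted among them ("+1/+1" convention), guaranteeing a
#' valid p-value.
#'
#' @param values numeric vector of per-subject scores (>= 3 finite values).
#' @param n_perm number of random flips (default 5000).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param seed integer seed for the sampled branch.
#' @return a `permutation_result` list: `statistic` (observed t), `p`,
#'   `n_draws`, `exhaustive`, `degenerate`, `seed`.
#' @export
sign_flip_perm_test <- function(values, n_perm = 5000L,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                seed = 1L) {
  alternative <- match.arg(alternative)
  values <- values[is.finite(values)]
  n <- length(values)
  assert_config(n >= 3L, "need at least 3 finite values")
  if (all(values == 0))
    return(structure(list(statistic = NaN, p = 1, n_draws = 0L,
                          exhaustive = FALSE, degenerate = TRUE,
                          seed = seed),
                     class = "permutation_result"))
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  t_obs <- tstat(values)
  extreme <- switch(alternative,
                    two.sided = function(t) abs(t) >= abs(t_obs) - 1e-12,
                    greater = function(t) t >= t_obs - 1e-12,
                    less = function(t) t <= t_obs + 1e-12)
  if (2^n <= n_perm) {
    # exhaustive enumeration of all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    mu <- as.vector(signs %*% values) / n
    ss <- sum(values^2)  # invariant under sign flips
    sdv <- sqrt((ss - n * mu^2) / (n - 1))
    ts <- mu / (sdv / sqrt(n))
    p <- mean(extreme(ts))
    structure(list(statistic = t_obs, p = p, n_draws = nrow(signs),
                   exhaustive = TRUE, degenerate = FALSE, seed = seed),
              class = "permutation_result")
  } else {
    with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                      n_perm, n)
      mu <- as.vector(signs %*% values) / n
      ss <- sum(values^2)  # invariant under sign flips
      sdv <- sqrt(pmax(0, (ss - n * mu^2) / (n - 1)))
      ts <- mu / (sdv / sqrt(n))
      p <- (1 + sum(extreme(ts))) / (1 + n_perm)
      structure(list(statistic = t_obs, p = p, n_draws = n_perm,
                     exhaustive = FALSE, degenerate = FALSE, seed = seed),
                class = "permutation_result")
    })
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1, returned in
#' the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted vector of the same length.
#' @export
fdr_bh <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  assert_config(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
                "p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  adj
}

#' Sidak adjustment for m comparisons
#'
#' `1 - (1 - p)^m`, capped at 1.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of comparisons in the family (>= 1).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  assert_config(length(m) == 1L && m >= 1, "m must be a single count >= 1")
  assert_config(all(p >= 0 & p <= 1, na.rm = TRUE),
                "p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' Omega-squared effect size from ANOVA quantities
#'
#' `omega^2 = (ss_effect - df_effect * ms_error) / (ss_total + ms_error)`,
#' the less biased alternative to eta-squared. May be slightly negative for
#' null effects and is reported as computed.
#'
#' @param ss_effect effect sum of squares.
#' @param df_effect effect degrees of freedom.
#' @param ms_error error mean square.
#' @param ss_total total sum of squares (> 0).
#' @return omega-squared value (NaN with a warning if the denominator is 0).
#' @export
omega_squared <- function(ss_effect, df_effect, ms_error, ss_total) {
  assert_config(ss_total > 0, "ss_total must be > 0")
  assert_config(ms_error >= 0, "ms_error must be >= 0")
  denom <- ss_total + ms_error
  if (denom == 0) {
    warning("omega_squared: zero denominator, returning NaN")
    return(NaN)
  }
  (ss_effect - df_effect * ms_error) / denom
}

#' Flag extreme outliers by the interquartile-range rule
#'
#' Flags values above `Q3 + k * IQR` or below `Q1 - k * IQR`, with quartiles
#' by linear interpolation (type 7). The default `k = 3` is the extreme-
#' outlier screen used for participant exclusion.
#'
#' @param values numeric vector (n >= 4).
#' @param k IQR multiplier (default 3).
#' @return logical vector of flags.
#' @export
iqr_outlier_flags <- function(values, k = 3) {
  assert_config(length(values) >= 4L, "need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  iqr <- q[2] - q[1]
  values > q[2] + k * iqr | values < q[1] - k * iqr
}
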