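#' Jarque-Bera normality test
#'
#' Moment-based normality check used to gate the choice of two-group test:
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with sample (population-moment)
#' skewness S and kurtosis K, referred to its asymptotic chi-square(2)
#' distribution. At the small group sizes typical here (around 13) the
#' asymptotic p is anti-conservative in the tails; a warning notes this and
#' a Monte-Carlo p is available.
#'
#' @param x numeric sample, `n >= 3`, nonzero variance.
#' @param alpha gate level (default 0.05).
#' @param mc_reps if > 0, also compute a Monte-Carlo p from this many
#'   normal samples of the same size (seeded locally for reproducibility).
#' @param quiet suppress the small-sample warning.
#' @return list with `statistic`, `p`, `is_normal` (p >= alpha), `n`, and
#'   `p_mc` when requested.
#' @export
jarque_bera <- function(x, alpha = 0.05, mc_reps = 0L, quiet = TRUE) {
  n <- length(x)
  if (n < 3) jdnet_stop("jdnet_bad_input", "Jarque-Bera needs n >= 3")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) jdnet_stop("jdnet_degenerate_sample", "zero-variance sample")
  s <- mean((x - mu)^3) / m2^1.5
  k <- mean((x - mu)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  if (!quiet && n < 30) {
    warning(sprintf("Jarque-Bera chi-square reference is asymptotic; n = %d is small", n))
  }
  out <- list(statistic = jb, p = p, is_normal = p >= alpha, n = n)
  if (mc_reps > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(20210L + n)
    sims <- replicate(mc_reps, {
      z <- stats::rnorm(n)
      mz <- mean(z); v2 <- mean((z - mz)^2)
      sz <- mean((z - mz)^3) / v2^1.5
      kz <- mean((z - mz)^4) / v2^2
      n / 6 * (sz^2 + (kz - 3)^2 / 4)
    })
    out$p_mc <- (1 + sum(sims >= jb)) / (mc_reps + 1)
  }
  out
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with the p-value taken from the exact permutation
#' distribution of the rank sum, computed by a counting dynamic program over
#' (doubled, hence integer) midranks. Ties are handled exactly through the
#' midrank distribution rather than by falling back to a normal
#' approximation. Two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (rank sum of `a`), `p`, `n_a`, `n_b`.
#' @export
exact_ranksum <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  n_total <- length(x)
  r2 <- as.integer(round(2 * rank(x)))   # doubled midranks: integers
  w_obs <- sum(r2[seq_len(n_a)])
  max_s <- sum(sort(r2, decreasing = TRUE)[seq_len(n_a)])
  # dp[k + 1, s + 1] = number of k-subsets of the midranks with sum s
  dp <- matrix(0, n_a + 1, max_s + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    for (k in seq(n_a, 1)) {
      cols <- seq_len(max_s + 1 - v)
      dp[k + 1, cols + v] <- dp[k + 1, cols + v] + dp[k, cols]
    }
  }
  counts <- dp[n_a + 1, ]
  total <- sum(counts)                   # choose(n_total, n_a), exact in doubles
  p_lo <- sum(counts[seq_len(w_obs + 1)]) / total
  p_hi <- sum(counts[seq(w_obs + 1, max_s + 1)]) / total
  list(statistic = w_obs / 2, p = min(1, 2 * min(p_lo, p_hi)),
       n_a = n_a, n_b = n_total - n_a)
}

#' Normal approximation to the rank-sum p
#'
#' Continuity-corrected normal approximation with the usual tie correction;
#' used only as a large-sample cross-check of [exact_ranksum()].
#'
#' @inheritParams exact_ranksum
#' @return two-sided approximate p.
#' @export
ranksum_normal_approx <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  n_b <- length(b)
  n <- n_a + n_b
  r <- rank(x)
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  ties <- table(x)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Normality-gated two-group comparison
#'
#' The per-metric group test: both groups are screened with [jarque_bera()];
#' if both pass, an unpaired two-sample Student t-test (pooled variance by
#' default) is used, otherwise the exact Wilcoxon rank-sum test. Degenerate
#' case: all values identical across both groups gives p = 1.
#'
#' @param a,b numeric samples (each `n >= 3`).
#' @param alpha significance and gate level (default 0.05).
#' @param welch use the Welch t-statistic instead of pooled variance.
#' @return list with `test` ("t" or "ranksum"), `statistic`, `p`,
#'   `significant`, `normal_a`, `normal_b`, group means and SDs.
#' @export
compare_groups <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 3 || length(b) < 3) {
    jdnet_stop("jdnet_bad_input", "each group needs n >= 3")
  }
  if (stats::var(c(a, b)) == 0) {
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                significant = FALSE, normal_a = NA, normal_b = NA,
                mean_a = mean(a), sd_a = 0, mean_b = mean(b), sd_b = 0))
  }
  norm_a <- if (stats::var(a) > 0) jarque_bera(a, alpha)$is_normal else FALSE
  norm_b <- if (stats::var(b) > 0) jarque_bera(b, alpha)$is_normal else FALSE
  if (norm_a && norm_b) {
    tt <- stats::t.test(a, b, var.equal = !welch)
    test <- "t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    rs <- exact_ranksum(a, b)
    test <- "ranksum"
    statistic <- rs$statistic
    p <- rs$p
  }
  list(test = test, statistic = statistic, p = p, significant = p < alpha,
       normal_a = norm_a, normal_b = norm_b,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b))
}

#' Chauvenet outlier screen
#'
#' Classical Chauvenet criterion: flag `x[i]` when
#' `n * P(|Z| >= |x[i] - mean| / sd) < 0.5` under a fitted normal model.
#' Reported only; values are never removed by default.
#'
#' @param x numeric sample, `n >= 4`.
#' @return integer indices of flagged values (possibly empty).
#' @export
chauvenet_outliers <- function(x) {
  n <- length(x)
  if (n < 4) jdnet_stop("jdnet_bad_input", "Chauvenet screen needs n >= 4")
  s <- stats::sd(x)
  if (s == 0) return(integer(0))
  z <- abs(x - mean(x)) / s
  which(n * 2 * stats::pnorm(-z) < 0.5)
}

#' Interquartile-range outlier screen
#'
#' Tukey fences: flag values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with
#' quartiles by the linear-interpolation convention (`stats::quantile`
#' type 7).
#'
#' @param x numeric sample, `n >= 4`.
#' @return integer indices of flagged values (possibly empty).
#' @export
iqr_outliers <- function(x) {
  if (length(x) < 4) jdnet_stop("jdnet_bad_input", "IQR screen needs n >= 4")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  which(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
}
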