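#' Delay embedding of a rescaled channel
#'
#' Reconstructs a state space from a scalar series by stacking delayed
#' copies: column i is `c(u[i], u[i + tau], ..., u[i + (m - 1) * tau])`.
#' Columns run over `i = 1 ... N - n` with trailing margin `n = m * tau`,
#' so with the defaults (`m = 2`, `tau = 1`) a series of length N yields
#' `N - 2` state vectors.
#'
#' @param u numeric vector, typically a rescaled channel in [0, 1].
#' @param m embedding dimension (default 2).
#' @param tau delay in samples (default 1).
#' @return an `m` x `(N - m * tau)` matrix whose columns are state vectors.
#' @export
embed_delay <- function(u, m = 2L, tau = 1L) {
  stopifnot(m >= 1, tau >= 1)
  n <- m * tau
  p <- length(u) - n
  if (p < 1) {
    jdnet_stop("jdnet_too_short", "series of length %d too short for m=%d, tau=%d (needs > %d samples)",
               length(u), m, tau, n)
  }
  idx <- outer(seq_len(m) - 1L, seq_len(p), function(k, i) i + k * tau)
  matrix(u[idx], nrow = m, ncol = p)
}

#' Intra-channel distance matrix of a state space
#'
#' Pairwise distance between state vectors. The default `"range"` variant is
#' the operational definition used throughout this pipeline:
#' `max(max(X_i) - min(X_j), max(X_j) - min(X_i))`, i.e. the largest spread
#' between the extremes of the two vectors. `"chebyshev"` is the textbook
#' maximum norm `max_k |X_i[k] - X_j[k]|`; the two disagree in general (the
#' range variant has a nonzero diagonal equal to each column's own range,
#' which downstream steps never use).
#'
#' @param x state-space matrix from [embed_delay()] (columns are vectors).
#' @param norm `"range"` (default) or `"chebyshev"`.
#' @return symmetric `ncol(x)` x `ncol(x)` matrix with entries in [0, 1]
#'   when the input lies in [0, 1].
#' @export
channel_distance_matrix <- function(x, norm = c("range", "chebyshev")) {
  norm <- match.arg(norm)
  if (!is.matrix(x) || ncol(x) < 1) {
    jdnet_stop("jdnet_empty_input", "state space must be a matrix with at least one column")
  }
  if (norm == "range") {
    hi <- apply(x, 2, max)
    lo <- apply(x, 2, min)
    pmax(outer(hi, lo, "-"), t(outer(hi, lo, "-")))
  } else {
    p <- ncol(x)
    d <- matrix(0, p, p)
    for (k in seq_len(nrow(x))) {
      d <- pmax(d, abs(outer(x[k, ], x[k, ], "-")))
    }
    d
  }
}

#' Joint distance matrix of two channels
#'
#' Entrywise geometric combination of two channels' distance matrices:
#' `JD = 1 - sqrt((1 - D1) * (1 - D2))`. Both inputs must lie in [0, 1] so
#' the square root stays real; the result is again in [0, 1] and symmetric,
#' and `joint_distance_matrix(D, D)` returns `D` exactly.
#'
#' @param d1,d2 distance matrices of equal size with entries in [0, 1].
#' @return the joint distance matrix.
#' @export
joint_distance_matrix <- function(d1, d2) {
  if (!all(dim(d1) == dim(d2))) {
    jdnet_stop("jdnet_shape_mismatch", "distance matrices differ in size")
  }
  if (max(d1) > 1 || max(d2) > 1 || min(d1) < 0 || min(d2) < 0) {
    jdnet_stop("jdnet_domain", "distance matrix entries must lie in [0, 1]")
  }
  1 - sqrt((1 - d1) * (1 - d2))
}

#' Doane bin count for a joint distance histogram
#'
#' Doane's rule corrects Sturges' rule for skewness:
#' `B = 1 + log2(n_obv) + log2(1 + |g1| / sigma_g1)` with
#' `sigma_g1 = sqrt(6 (n_obv - 2) / ((n_obv + 1)(n_obv + 3)))`, where `g1`
#' is the (population) skewness of the off-diagonal joint distances and
#' `n_obv` counts those entries — both triangles, `(N - n)^2 - (N - n)` for
#' a `(N - n)`-square matrix. `B` is rounded half away from zero and floored
#' at 2 so the entropy normalization stays defined.
#'
#' @param jd a joint distance matrix, or a numeric vector already holding
#'   the off-diagonal entries (in which case `n_obv = length(jd)`).
#' @return list with `bins` (integer), `b_raw`, `g1`, `sigma_g1`, `n_obv`.
#' @export
doane_bins <- function(jd) {
  if (is.matrix(jd)) {
    values <- jd[row(jd) != col(jd)]
  } else {
    values <- as.numeric(jd)
  }
  n_obv <- length(values)
  if (n_obv < 4) {
    jdnet_stop("jdnet_too_few_obs", "Doane's rule needs at least 4 observations, got %d", n_obv)
  }
  g1 <- moment_skewness(values)
  sigma_g1 <- sqrt(6 * (n_obv - 2) / ((n_obv + 1) * (n_obv + 3)))
  b_raw <- 1 + log2(n_obv) + log2(1 + abs(g1) / sigma_g1)
  bins <- max(2, round_half_away(b_raw))
  list(bins = as.integer(bins), b_raw = b_raw, g1 = g1,
       sigma_g1 = sigma_g1, n_obv = n_obv)
}

#' Histogram masses of joint distances
#'
#' Equal-width histogram over `[min(values), max(values)]` with `bins` bins;
#' the rightmost bin is closed. Counts are normalized to masses summing to
#' one. Degenerate spread (all values equal) puts all mass in the first bin.
#'
#' @param values numeric vector of joint distances (off-diagonal entries).
#' @param bins integer number of bins.
#' @return list with `counts` and `rho` (masses summing to 1).
#' @export
jd_histogram <- function(values, bins) {
  stopifnot(bins >= 1, length(values) >= 1)
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) {
    counts <- c(length(values), rep(0, bins - 1))
  } else {
    idx <- pmin(floor((values - lo) / (hi - lo) * bins), bins - 1) + 1
    counts <- tabulate(idx, nbins = bins)
  }
  list(counts = counts, rho = counts / sum(counts))
}

#' Joint distribution entropy from histogram masses
#'
#' Normalized Shannon entropy of the joint-distance histogram:
#' `JDistEn = -1/log2(Bins) * sum(rho_t * log2(rho_t))`, empty bins
#' excluded. The result lies in [0, 1]: 0 when all mass sits in one bin
#' (no coupling), 1 for a uniform histogram (full coupling).
#'
#' @param rho numeric vector of histogram masses summing to 1.
#' @param bins the bin count used for normalization (>= 2).
#' @return scalar coupling value in [0, 1].
#' @export
jdisten_from_histogram <- function(rho, bins) {
  if (bins < 2) {
    jdnet_stop("jdnet_normalization", "entropy normalization needs at least 2 bins")
  }
  if (abs(sum(rho) - 1) > 1e-8 || any(rho < 0)) {
    jdnet_stop("jdnet_domain", "histogram masses must be nonnegative and sum to 1")
  }
  nz <- rho[rho > 0]
  -sum(nz * log2(nz)) / log2(bins)
}

#' JDistEn coupling of one channel pair
#'
#' Plain-R composition of the per-pair pipeline: delay embedding, per-channel
#' distance matrices, joint distance matrix, Doane binning, normalized
#' entropy. [coupling_matrix()] computes the same quantity for all pairs via
#' compiled code; this function is the readable reference path.
#'
#' @param u1,u2 rescaled channels (equal length, values in [0, 1]).
#' @inheritParams embed_delay
#' @inheritParams channel_distance_matrix
#' @return scalar JDistEn value in [0, 1].
#' @export
pair_jdisten <- function(u1, u2, m = 2L, tau = 1L, norm = c("range", "chebyshev")) {
  norm <- match.arg(norm)
  stopifnot(length(u1) == length(u2))
  d1 <- channel_distance_matrix(embed_delay(u1, m, tau), norm)
  d2 <- channel_distance_matrix(embed_delay(u2, m, tau), norm)
  jd <- joint_distance_matrix(d1, d2)
  db <- doane_bins(jd)
  h <- jd_histogram(jd[row(jd) != col(jd)], db$bins)
  jdisten_from_histogram(h$rho, db$bins)
}

#' Pairwise JDistEn coupling matrix
#'
#' Computes the joint-distribution-entropy coupling between every unordered
#' pair of channels of a rescaled recording, returning a symmetric weighted
#' adjacency matrix with zero diagonal (self-coupling is undefined and the
#' diagonal is excluded from all downstream thresholding). Per-channel
#' distance summaries are computed once and reused across the pairs the
#' channel participates in; the inner loops are compiled.
#'
#' @param x channels x samples matrix of rescaled signals in [0, 1], e.g.
#'   the `$data` of [preprocess_subject()]'s result.
#' @inheritParams embed_delay
#' @inheritParams channel_distance_matrix
#' @return channels x channels symmetric matrix of couplings in [0, 1],
#'   diagonal 0, dimnames carried over from `rownames(x)`.
#' @export
coupling_matrix <- function(x, m = 2L, tau = 1L, norm = c("range", "chebyshev")) {
  norm <- match.arg(norm)
  if (!is.matrix(x) || nrow(x) < 2) {
    jdnet_stop("jdnet_empty_input", "need a matrix with at least 2 channels")
  }
  n <- m * tau
  p <- ncol(x) - n
  if (p < 3) {
    jdnet_stop("jdnet_too_short",
               "channels of length %d leave %d state vectors; need >= 3 (n_obv >= 6) for m=%d, tau=%d",
               ncol(x), max(p, 0), m, tau)
  }
  if (min(x) < 0 || max(x) > 1) {
    jdnet_stop("jdnet_domain", "channels must be rescaled to [0, 1]; see rescale_channel()")
  }
  w <- cpp_coupling_matrix(x, as.integer(m), as.integer(tau), norm == "chebyshev")
  if (!is.null(rownames(x))) dimnames(w) <- list(rownames(x), rownames(x))
  w
}
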