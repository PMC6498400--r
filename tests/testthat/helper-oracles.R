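# Independent straight-line oracles used to validate the pipeline. These
# deliberately re-derive everything with explicit loops and share no code
# with the package internals.

# Joint-distribution-entropy coupling of two raw channels: rescaling, delay
# embedding, range-norm distance matrices, joint distance, Doane binning,
# normalized entropy -- translated term by term from the definitions.
oracle_jdisten_pair <- function(u1, u2, m = 2, tau = 1) {
  rescale <- function(u) (u - min(u)) / (max(u) - min(u))
  u1 <- rescale(u1)
  u2 <- rescale(u2)
  n <- m * tau
  N <- length(u1)
  P <- N - n
  emb <- function(u) {
    X <- matrix(NA_real_, m, P)
    for (i in seq_len(P)) {
      for (k in seq_len(m)) X[k, i] <- u[i + (k - 1) * tau]
    }
    X
  }
  dmat <- function(X) {
    D <- matrix(NA_real_, P, P)
    for (i in seq_len(P)) {
      for (j in seq_len(P)) {
        D[i, j] <- max(max(X[, i]) - min(X[, j]), max(X[, j]) - min(X[, i]))
      }
    }
    D
  }
  D1 <- dmat(emb(u1))
  D2 <- dmat(emb(u2))
  JD <- matrix(NA_real_, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      JD[i, j] <- 1 - sqrt((1 - D1[i, j]) * (1 - D2[i, j]))
    }
  }
  vals <- c()
  for (i in seq_len(P)) {
    for (j in seq_len(P)) if (i != j) vals <- c(vals, JD[i, j])
  }
  n_obv <- P^2 - P
  mu <- sum(vals) / n_obv
  m2 <- sum((vals - mu)^2) / n_obv
  m3 <- sum((vals - mu)^3) / n_obv
  g1 <- if (m2 > 0) m3 / m2^1.5 else 0
  sigma_g1 <- sqrt(6 * (n_obv - 2) / ((n_obv + 1) * (n_obv + 3)))
  B <- 1 + log2(n_obv) + log2(1 + abs(g1) / sigma_g1)
  bins <- max(2, sign(B) * floor(abs(B) + 0.5))
  lo <- min(vals)
  hi <- max(vals)
  if (hi <= lo) return(0)
  counts <- numeric(bins)
  for (v in vals) {
    t <- floor((v - lo) / (hi - lo) * bins)
    if (t > bins - 1) t <- bins - 1
    counts[t + 1] <- counts[t + 1] + 1
  }
  h <- 0
  for (t in seq_len(bins)) {
    if (counts[t] > 0) {
      rho <- counts[t] / n_obv
      h <- h - rho * log2(rho)
    }
  }
  h / log2(bins)
}

# Full coupling matrix via the pair oracle (raw channels in rows).
oracle_coupling_matrix <- function(x, m = 2, tau = 1) {
  nc <- nrow(x)
  w <- matrix(0, nc, nc)
  for (a in seq_len(nc - 1)) {
    for (b in (a + 1):nc) {
      w[a, b] <- w[b, a] <- oracle_jdisten_pair(x[a, ], x[b, ], m, tau)
    }
  }
  w
}

# Floyd-Warshall all-pairs shortest paths on a logical adjacency matrix.
oracle_fw <- function(adj) {
  v <- nrow(adj)
  d <- matrix(Inf, v, v)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(v)) {
    for (i in seq_len(v)) {
      for (j in seq_len(v)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Per-node clustering by triangle enumeration; degree < 2 gets 0.
oracle_clustering <- function(adj) {
  v <- nrow(adj)
  sapply(seq_len(v), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    closed <- sum(apply(pairs, 2, function(p) adj[p[1], p[2]]))
    closed / ncol(pairs)
  })
}

# Mean shortest path over ordered reachable pairs of the largest component.
oracle_path_length <- function(adj) {
  d <- oracle_fw(adj)
  comp_of <- rep(NA_integer_, nrow(adj))
  cid <- 0
  for (i in seq_len(nrow(adj))) {
    if (is.na(comp_of[i])) {
      cid <- cid + 1
      comp_of[is.finite(d[i, ])] <- cid
    }
  }
  big <- which(comp_of == which.max(tabulate(comp_of)))
  dd <- d[big, big, drop = FALSE]
  mean(dd[row(dd) != col(dd)])
}

# Per-node eccentricity within each node's own component.
oracle_eccentricity <- function(adj) {
  d <- oracle_fw(adj)
  sapply(seq_len(nrow(adj)), function(i) {
    reach <- is.finite(d[i, ])
    max(d[i, reach])
  })
}

# Random symmetric weight matrix with zero diagonal.
random_weights <- function(v) {
  w <- matrix(0, v, v)
  w[upper.tri(w)] <- stats::runif(v * (v - 1) / 2)
  w + t(w)
}

# Random binary network at a given edge count via the package binarizer.
random_binary_network <- function(v, e) {
  w <- random_weights(v)
  bn <- binarize_fixed_density(w, e / (v * (v - 1) / 2))
  stopifnot(bn$e == e)
  bn
}

# Small epoched recording of white noise, for plumbing tests.
noise_recording <- function(channels = 3, samples = 40, epochs = 4,
                            fs = 256, prestim = 0) {
  epoched_recording(array(stats::rnorm(channels * samples * epochs),
                          c(channels, samples, epochs)),
                    fs, prestim)
}

# Reduced-scale cohort geometry used throughout the simulation tests: short
# epochs keep the joint-distance matrices small while preserving the full
# 23-87 epoch range and the 13 vs 14 group design.
test_cohort_spec <- function(seed, between_a = 0, between_b = 0.6,
                             noise_sd = 0.5, ...) {
  cohort_spec(channels = 16L, epoch_len = 110L, prestim = 16L,
              between_a = between_a, between_b = between_b,
              model = source_model(16L, 8L, noise_sd = noise_sd),
              seed = seed, ...)
}
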