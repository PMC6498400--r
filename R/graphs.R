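# Top-e edge selection shared by binarize_fixed_density() and
# random_reference(). Ties at the threshold break by (row, column) order of
# the upper triangle so quantized weights binarize deterministically.
binarize_top_e <- function(w, e) {
  v <- nrow(w)
  iu <- which(upper.tri(w))
  rw <- row(w)[iu]
  cl <- col(w)[iu]
  ord <- order(-w[iu], rw, cl)
  keep <- iu[ord[seq_len(e)]]
  adj <- matrix(FALSE, v, v)
  adj[keep] <- TRUE
  adj <- adj | t(adj)
  dimnames(adj) <- dimnames(w)
  adj
}

#' Binarize a coupling matrix at fixed edge density
#'
#' Keeps the strongest `round(density * V(V-1)/2)` off-diagonal couplings
#' (round half away from zero) as edges of an undirected unweighted graph,
#' so every subject's network has the same edge count regardless of the
#' spread of its coupling values. At the default density 0.10 a 128-channel
#' matrix yields exactly 813 edges. Threshold ties break deterministically
#' by (row, column) position.
#'
#' @param w symmetric weighted adjacency with zero diagonal, e.g. from
#'   [coupling_matrix()].
#' @param density fraction of node pairs kept as edges, in (0, 1].
#' @return an object of class `binary_network`: list with `adj` (logical
#'   symmetric matrix), `v`, `e`, `density`.
#' @export
binarize_fixed_density <- function(w, density = 0.10) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    jdnet_stop("jdnet_bad_input", "coupling matrix must be square")
  }
  if (max(abs(w - t(w))) > 0) jdnet_stop("jdnet_bad_input", "coupling matrix must be symmetric")
  if (any(diag(w) != 0)) jdnet_stop("jdnet_bad_input", "coupling matrix must have zero diagonal")
  if (!(density > 0 && density <= 1)) jdnet_stop("jdnet_bad_input", "density must be in (0, 1]")
  v <- nrow(w)
  e <- as.integer(round_half_away(density * v * (v - 1) / 2))
  if (e == 0) warning("edge budget rounds to 0; returning an empty graph")
  structure(list(adj = binarize_top_e(w, e), v = v, e = e, density = density),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.3g)\n", x$v, x$e, x$density))
  invisible(x)
}

as_igraph <- function(bn) {
  igraph::graph_from_adjacency_matrix(bn$adj, mode = "undirected", diag = FALSE)
}

largest_component_nodes <- function(g) {
  comp <- igraph::components(g)
  which(comp$membership == which.max(comp$csize))
}

#' Clustering coefficient
#'
#' Per-node local clustering: the fraction of a node's neighbour pairs that
#' are themselves connected. Nodes of degree < 2 get coefficient 0. The
#' network-level value `c_mean` is the mean over all nodes.
#'
#' @param bn a [binarize_fixed_density()] network.
#' @return list with `per_node` and `c_mean`.
#' @export
clustering_coefficient <- function(bn) {
  g <- as_igraph(bn)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(per_node = cc, c_mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes,
#' computed within the largest connected component when the graph is
#' disconnected (sparse fixed-density networks need not be connected, and
#' infinite distances are excluded rather than imputed).
#'
#' @param bn a [binarize_fixed_density()] network.
#' @return list with `l_mean` and `component_size`.
#' @export
characteristic_path_length <- function(bn) {
  g <- as_igraph(bn)
  nodes <- largest_component_nodes(g)
  if (length(nodes) < 2) {
    jdnet_stop("jdnet_undefined_metric", "largest component has < 2 nodes; path length undefined")
  }
  sub <- igraph::induced_subgraph(g, nodes)
  d <- igraph::distances(sub)
  list(l_mean = mean(d[row(d) != col(d)]), component_size = length(nodes))
}

#' Node eccentricity
#'
#' A node's eccentricity is its maximum shortest-path distance to any other
#' node of its connected component (0 for an isolated node). The
#' subject-level summary is taken over the largest component: the mean by
#' default, or the maximum (the component's diameter).
#'
#' @param bn a [binarize_fixed_density()] network.
#' @param summary `"mean"` (default) or `"max"`.
#' @return list with `per_node` (all nodes, own component), `ecc` (the
#'   summary over the largest component) and `component_size`.
#' @export
network_eccentricity <- function(bn, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  g <- as_igraph(bn)
  ecc <- igraph::eccentricity(g)
  nodes <- largest_component_nodes(g)
  val <- if (summary == "mean") mean(ecc[nodes]) else max(ecc[nodes])
  list(per_node = unname(ecc), ecc = val, component_size = length(nodes))
}

#' Random reference networks
#'
#' Erdos-Renyi-style references for small-world normalization: symmetric
#' matrices of independent uniform weights are thresholded at the same
#' fixed edge count as the observed network (equivalent to uniform-random
#' e-edge graphs), and clustering / path length are averaged over the
#' references. Fully reproducible from `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param v node count.
#' @param e edge count per reference.
#' @param n_rand number of reference graphs (default 10).
#' @param seed integer seed.
#' @return list with `c_random`, `l_random`, `n_rand`, `seed`.
#' @export
random_reference <- function(v, e, n_rand = 10L, seed = 1L) {
  stopifnot(n_rand >= 1, e >= 0, e <= v * (v - 1) / 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cs <- numeric(n_rand)
  ls <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    w <- matrix(0, v, v)
    w[upper.tri(w)] <- stats::runif(v * (v - 1) / 2)
    w <- w + t(w)
    bn <- structure(list(adj = binarize_top_e(w, e), v = v, e = e,
                         density = e / (v * (v - 1) / 2)),
                    class = "binary_network")
    cs[r] <- clustering_coefficient(bn)$c_mean
    ls[r] <- characteristic_path_length(bn)$l_mean
  }
  list(c_random = mean(cs), l_random = mean(ls), n_rand = n_rand, seed = seed)
}

#' Small-world quotient
#'
#' `Q = (C_actual / C_random) / (L_actual / L_random)`: clustering relative
#' to random references, discounted by the relative path length. Q >> 1
#' indicates a small-world topology (much more clustered than random at
#' near-random path length); uniform-random graphs self-normalize to Q
#' around 1.
#'
#' @param c_actual,l_actual observed clustering and path length.
#' @param c_random,l_random reference means from [random_reference()].
#' @return scalar Q.
#' @export
small_world_q <- function(c_actual, c_random, l_actual, l_random) {
  if (!(c_random > 0 && l_random > 0 && l_actual > 0)) {
    jdnet_stop("jdnet_undefined_metric",
               "small-world quotient undefined (c_random=%g, l_actual=%g, l_random=%g)",
               c_random, l_actual, l_random)
  }
  (c_actual / c_random) / (l_actual / l_random)
}

#' All network metrics for one subject
#'
#' Binarization-side summary of a subject's network: clustering,
#' characteristic path length, eccentricity, the random-reference means and
#' the small-world quotient.
#'
#' @param bn a [binarize_fixed_density()] network.
#' @param n_rand number of random reference graphs.
#' @param seed seed for the reference graphs.
#' @param ecc_summary eccentricity summary, `"mean"` or `"max"`.
#' @return one-row `data.frame` with columns `clustering`, `path_length`,
#'   `eccentricity`, `c_random`, `l_random`, `q`, `component_size`, `v`, `e`.
#' @export
network_metrics <- function(bn, n_rand = 10L, seed = 1L, ecc_summary = "mean") {
  cc <- clustering_coefficient(bn)
  pl <- characteristic_path_length(bn)
  ec <- network_eccentricity(bn, ecc_summary)
  rr <- random_reference(bn$v, bn$e, n_rand, seed)
  q <- small_world_q(cc$c_mean, rr$c_random, pl$l_mean, rr$l_random)
  data.frame(clustering = cc$c_mean, path_length = pl$l_mean,
             eccentricity = ec$ecc, c_random = rr$c_random,
             l_random = rr$l_random, q = q,
             component_size = pl$component_size, v = bn$v, e = bn$e)
}
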