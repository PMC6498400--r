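test_that("fixed-density binarization keeps exactly the strongest pairs", {
  w4 <- matrix(0, 4, 4)
  w4[upper.tri(w4)] <- c(.9, .1, .2, .8, .3, .7)  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  w4 <- w4 + t(w4)
  bn <- binarize_fixed_density(w4, 0.5)
  expect_equal(bn$e, 3L)
  expect_true(bn$adj[1, 2] && bn$adj[1, 4] && bn$adj[3, 4])
  expect_equal(sum(bn$adj) / 2, 3)

  full <- binarize_fixed_density(random_weights(6), 1)
  expect_equal(sum(full$adj) / 2, 15)
  expect_false(any(diag(full$adj)))

  set.seed(7)
  big <- binarize_fixed_density(random_weights(128), 0.10)
  expect_equal(big$e, 813L)
  expect_equal(sum(big$adj) / 2, 813)
})

test_that("threshold ties resolve deterministically by position", {
  set.seed(17)
  w <- random_weights(12)
  wq <- round(w, 1)                       # heavy quantization: many ties
  b1 <- binarize_fixed_density(wq, 0.2)
  b2 <- binarize_fixed_density(wq, 0.2)
  expect_identical(b1$adj, b2$adj)
  expect_equal(sum(b1$adj) / 2, b1$e)
})

test_that("clustering matches hand values and the triangle oracle", {
  tri <- binarize_fixed_density(random_weights(3), 1)
  expect_equal(clustering_coefficient(tri)$per_node, rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.9
  bn <- binarize_fixed_density(star, 0.5)
  expect_equal(clustering_coefficient(bn)$c_mean, 0)

  # 4-cycle a-b-c-d plus chord a-c
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[3, 4] <- w[1, 4] <- w[1, 3] <- 0.9
  w <- pmax(w, t(w))
  bn2 <- structure(list(adj = w > 0, v = 4L, e = 5L, density = 5 / 6),
                   class = "binary_network")
  cc <- clustering_coefficient(bn2)
  expect_equal(cc$per_node, c(2 / 3, 1, 2 / 3, 1))
  expect_equal(cc$c_mean, 5 / 6)
})

test_that("path length and eccentricity match hand values on small graphs", {
  k5 <- binarize_fixed_density(random_weights(5), 1)
  expect_equal(characteristic_path_length(k5)$l_mean, 1)
  expect_equal(network_eccentricity(k5)$per_node, rep(1, 5))

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 3] <- 1
  bn <- structure(list(adj = (path3 + t(path3)) > 0, v = 3L, e = 2L, density = 2 / 3),
                  class = "binary_network")
  expect_equal(characteristic_path_length(bn)$l_mean, 4 / 3)
  ec <- network_eccentricity(bn)
  expect_equal(ec$per_node, c(2, 1, 2))
  expect_equal(ec$ecc, 5 / 3)

  # two disjoint triangles: metrics on the largest (first) component
  adj <- matrix(FALSE, 6, 6)
  adj[1:3, 1:3] <- TRUE; adj[4:6, 4:6] <- TRUE; diag(adj) <- FALSE
  bn2 <- structure(list(adj = adj, v = 6L, e = 6L, density = 0.4),
                   class = "binary_network")
  pl <- characteristic_path_length(bn2)
  expect_equal(pl$l_mean, 1)
  expect_equal(pl$component_size, 3)

  # isolated node has eccentricity 0
  adj3 <- matrix(FALSE, 3, 3)
  adj3[1, 2] <- adj3[2, 1] <- TRUE
  bn3 <- structure(list(adj = adj3, v = 3L, e = 1L, density = 1 / 3),
                   class = "binary_network")
  expect_equal(network_eccentricity(bn3)$per_node[3], 0)

  empty <- structure(list(adj = matrix(FALSE, 3, 3), v = 3L, e = 0L, density = 0),
                     class = "binary_network")
  expect_error(characteristic_path_length(empty), class = "jdnet_undefined_metric")
})

test_that("metrics agree exactly with Floyd-Warshall and triangle oracles", {
  set.seed(27)
  for (rep in 1:40) {
    v <- sample(3:7, 1)
    e <- sample(seq_len(v * (v - 1) / 2), 1)
    bn <- random_binary_network(v, e)
    expect_equal(clustering_coefficient(bn)$per_node, oracle_clustering(bn$adj))
    expect_equal(network_eccentricity(bn)$per_node, oracle_eccentricity(bn$adj))
    expect_equal(characteristic_path_length(bn)$l_mean, oracle_path_length(bn$adj))
  }
})

test_that("shortest paths and eccentricities never increase when an edge is added", {
  set.seed(37)
  done <- 0
  while (done < 15) {
    v <- sample(5:7, 1)
    bn <- random_binary_network(v, sample(seq(v, v * (v - 1) / 2 - 1), 1))
    d0 <- oracle_fw(bn$adj)
    free <- which(!bn$adj & upper.tri(bn$adj))
    if (length(free) == 0 || any(!is.finite(d0))) next   # want connected graphs
    done <- done + 1
    pick <- if (length(free) == 1) free else sample(free, 1)
    adj2 <- bn$adj
    adj2[pick] <- TRUE
    adj2 <- adj2 | t(adj2)
    expect_true(all(oracle_fw(adj2) <= d0))
    bn2 <- structure(list(adj = adj2, v = v, e = bn$e + 1L, density = 0),
                     class = "binary_network")
    expect_true(all(network_eccentricity(bn2)$per_node <=
                      network_eccentricity(bn)$per_node))
  }
})

test_that("random references are reproducible and behave like Erdos-Renyi graphs", {
  r1 <- random_reference(20, 190, n_rand = 3, seed = 9)
  expect_equal(r1$c_random, 1)           # complete graph
  expect_equal(r1$l_random, 1)

  r2 <- random_reference(40, 80, n_rand = 5, seed = 13)
  r3 <- random_reference(40, 80, n_rand = 5, seed = 13)
  expect_identical(r2, r3)

  # ER local clustering concentrates near the density
  r4 <- random_reference(128, 813, n_rand = 10, seed = 23)
  expect_lt(abs(r4$c_random - 0.1), 0.02)
})

test_that("small-world quotient arithmetic and guards", {
  expect_equal(small_world_q(0.4, 0.2, 2.0, 1.6), 1.6)
  expect_equal(small_world_q(0.3, 0.3, 1.5, 1.5), 1)
  expect_error(small_world_q(0.4, 0, 2, 1.6), class = "jdnet_undefined_metric")
})

test_that("network_metrics assembles a consistent one-row summary", {
  set.seed(47)
  bn <- random_binary_network(16, 12)
  m <- network_metrics(bn, n_rand = 5, seed = 3)
  expect_s3_class(m, "data.frame")
  expect_equal(nrow(m), 1)
  expect_equal(m$v, 16)
  expect_equal(m$e, 12)
  expect_equal(m$q, (m$clustering / m$c_random) / (m$path_length / m$l_random))
})
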