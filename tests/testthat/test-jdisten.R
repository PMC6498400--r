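test_that("delay embedding builds the documented state vectors", {
  X <- embed_delay(c(0, 1, 0.5, 0.25), m = 2, tau = 1)
  expect_equal(X, matrix(c(0, 1, 1, 0.5), 2))

  u <- runif(10)
  expect_equal(embed_delay(u, m = 1, tau = 3), matrix(u[1:7], 1))

  expect_error(embed_delay(c(0.1, 0.9), m = 2, tau = 1), class = "jdnet_too_short")
})

test_that("range-norm distances follow the max-spread formula, including the diagonal", {
  X <- matrix(c(0.2, 0.4, 0.3, 0.5), 2)
  D <- channel_distance_matrix(X, "range")
  expect_equal(D[1, 2], 0.3)             # max(0.4 - 0.3, 0.5 - 0.2)
  expect_equal(D[2, 1], 0.3)
  expect_equal(D[1, 1], 0.2)             # a column's own range, not 0

  const <- matrix(0.4, 2, 5)
  expect_equal(channel_distance_matrix(const, "range"), matrix(0, 5, 5))

  # Chebyshev variant disagrees with the range variant in general
  expect_equal(channel_distance_matrix(X, "chebyshev")[1, 2], 0.1)
  expect_equal(diag(channel_distance_matrix(X, "chebyshev")), c(0, 0))
})

test_that("joint distance matrix is the entrywise geometric combination", {
  D <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_identical(joint_distance_matrix(D, D), D)
  expect_equal(joint_distance_matrix(matrix(1), matrix(0)), matrix(1))
  z <- matrix(0, 3, 3)
  expect_equal(joint_distance_matrix(z, z), z)
  expect_error(joint_distance_matrix(matrix(1.2), matrix(0.5)),
               class = "jdnet_domain")
})

test_that("Doane's rule gives the documented counts and handles degenerate skewness", {
  v <- rep(c(1, 2, 3, 4, 5), 4)          # 20 values, symmetric: g1 = 0
  db <- doane_bins(v)
  expect_equal(db$g1, 0)
  expect_equal(db$b_raw, 1 + log2(20))
  expect_equal(db$bins, 5L)
  expect_equal(db$sigma_g1, sqrt(6 * 18 / (21 * 23)))

  const <- doane_bins(rep(0.3, 16))
  expect_equal(const$g1, 0)
  expect_equal(const$bins, round(1 + log2(16)))

  expect_error(doane_bins(c(1, 2, 3)), class = "jdnet_too_few_obs")
})

test_that("entropy limits: uniform histogram gives 1, point mass gives 0", {
  expect_equal(jdisten_from_histogram(rep(1 / 7, 7), 7), 1)
  expect_equal(jdisten_from_histogram(c(1, 0, 0, 0), 4), 0)
  expect_equal(jdisten_from_histogram(c(0.5, 0.5), 2), 1)
  expect_error(jdisten_from_histogram(1, 1), class = "jdnet_normalization")
})

test_that("histogram masses are conserved", {
  set.seed(5)
  for (rep in 1:20) {
    v <- runif(sample(10:100, 1))
    h <- jd_histogram(v, sample(2:10, 1))
    expect_equal(sum(h$rho), 1, tolerance = 1e-12)
    expect_true(all(h$rho >= 0))
    expect_equal(sum(h$counts), length(v))
  }
})

test_that("coupling matrix is symmetric, zero-diagonal, in [0,1], and matches the pair path", {
  set.seed(31)
  x <- matrix(runif(4 * 15), 4)
  w <- coupling_matrix(x)
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 4))
  expect_true(all(w >= 0 & w <= 1))
  for (a in 1:3) {
    for (b in (a + 1):4) {
      expect_equal(w[a, b], pair_jdisten(x[a, ], x[b, ]), tolerance = 1e-12)
    }
  }
  # identical channels reduce to the single-channel joint distance
  x2 <- rbind(x[1, ], x[1, ])
  expect_equal(coupling_matrix(x2)[1, 2], pair_jdisten(x[1, ], x[1, ]), tolerance = 1e-12)
})

test_that("pipeline coupling equals the straight-line oracle on small recordings", {
  set.seed(41)
  for (rep in 1:10) {
    nc <- sample(2:4, 1)
    ns <- sample(8:12, 1)
    raw <- matrix(rnorm(nc * ns), nc)
    resc <- t(apply(raw, 1, rescale_channel))
    expect_equal(coupling_matrix(resc), oracle_coupling_matrix(raw),
                 tolerance = 1e-12)
  }
})

test_that("coupling is invariant to positive affine maps of the raw channels", {
  set.seed(51)
  raw <- matrix(rnorm(3 * 20), 3)
  resc <- t(apply(raw, 1, rescale_channel))
  w0 <- coupling_matrix(resc)
  raw2 <- raw * 3.7 + 11
  resc2 <- t(apply(raw2, 1, rescale_channel))
  expect_equal(coupling_matrix(resc2), w0, tolerance = 1e-12)
})

test_that("chebyshev-norm variant runs the same contract", {
  set.seed(61)
  x <- matrix(runif(3 * 15), 3)
  w <- coupling_matrix(x, norm = "chebyshev")
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 3))
  expect_true(all(w >= 0 & w <= 1))
  expect_false(isTRUE(all.equal(w, coupling_matrix(x, norm = "range"))))
})

test_that("coupling rejects short or out-of-range input with classed errors", {
  expect_error(coupling_matrix(matrix(runif(8), 2, 4)), class = "jdnet_too_short")
  expect_error(coupling_matrix(matrix(2 * runif(20), 2)), class = "jdnet_domain")
  expect_error(coupling_matrix(matrix(runif(10), 1)), class = "jdnet_empty_input")
})
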