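test_that("storage validates input and is one-shot", {
  expect_error(hopfield_store(list()), "at least one")
  expect_error(hopfield_store(list(c(1, 2), c(1, 2, 3))), "equal lengths")
  expect_error(hopfield_store(matrix(1, 1, 2), beta = -1), "positive")

  st <- hopfield_store(matrix(c(0.2, 0.8), 1, 2))
  r <- hopfield_retrieve(st, c(0.9, 0.1))
  expect_equal(r$pattern, c(0.2, 0.8))  # single memory always retrieved
  expect_equal(sum(r$weights), 1)
})

test_that("duplicate stored rows merge their softmax weight", {
  set.seed(1)
  a <- runif(50); b <- runif(50)
  st1 <- hopfield_store(rbind(a, b))
  st2 <- hopfield_store(rbind(a, a, b))
  q <- a + rnorm(50, sd = 0.01)
  r1 <- hopfield_retrieve(st1, q)
  r2 <- hopfield_retrieve(st2, q)
  expect_equal(r1$pattern, r2$pattern, tolerance = 1e-10)
  expect_equal(r2$weights[1] + r2$weights[2], r1$weights[1],
               tolerance = 1e-10)
})

test_that("the low-beta limit retrieves the mean stored pattern", {
  set.seed(2)
  X <- matrix(runif(5 * 20), 5)
  st <- hopfield_store(X, beta = 1e-9)
  r <- hopfield_retrieve(st, runif(20), max_steps = 1L)
  expect_equal(r$pattern, colMeans(X), tolerance = 1e-4)
})

test_that("corrupted cues retrieve the brute-force nearest stored scene", {
  probes <- scene_probes(200, seed = 31)
  st <- hopfield_store(probes$x, beta = 20)
  hits <- 0L
  for (i in 1:100) {
    img <- unflatten_image(probes$x[i, ], c(64L, 64L, 3L))
    q <- flatten_image(corrupt_partial(img, 0.1, seed = 1000 + i))
    r <- hopfield_retrieve(st, q)
    # independent oracle: exhaustive Euclidean nearest neighbour
    nn <- which.min(colSums((t(probes$x) - q)^2))
    hits <- hits + (max(abs(r$pattern - probes$x[nn, ])) < 1e-6)
  }
  expect_gte(hits, 99L)
})

test_that("replay retrieves stored patterns, symmetrically for equivalent memories", {
  probes <- scene_probes(100, seed = 41)
  st <- hopfield_store(probes$x, beta = 20)
  rep <- hopfield_replay(st, 200, seed = 42)
  dist_to_store <- apply(rep$samples, 1, function(s) {
    min(colMeans(abs(t(probes$x) - s)))
  })
  expect_lt(max(dist_to_store), 1e-4)

  # two patterns equivalent under a pixel permutation are replayed equally
  # often (iid noise is permutation-invariant): binomial 3 sigma around 0.5
  a <- probes$x[1, ]
  st2 <- hopfield_store(rbind(a, rev(a)), beta = 20)
  rep2 <- hopfield_replay(st2, 1000, seed = 43)
  n_first <- sum(apply(rep2$samples, 1, function(s) {
    mean(abs(s - a)) < mean(abs(s - rev(a)))
  }))
  expect_lt(abs(n_first - 500), 3 * sqrt(1000 * 0.25))
})

test_that("higher beta sharpens retrieval and one step suffices at beta 20", {
  probes <- scene_probes(50, seed = 51)
  q <- flatten_image(corrupt_partial(
    unflatten_image(probes$x[3, ], c(64L, 64L, 3L)), 0.1, seed = 52))
  maxw <- vapply(c(0.001, 0.01, 0.1, 1, 20), function(b) {
    st <- hopfield_store(probes$x, beta = b)
    max(hopfield_retrieve(st, q, max_steps = 1L)$weights)
  }, numeric(1))
  expect_true(all(diff(maxw) >= -1e-12))

  st <- hopfield_store(probes$x, beta = 20)
  one <- hopfield_retrieve(st, q, max_steps = 1L)
  conv <- hopfield_retrieve(st, q)
  expect_lt(mean(abs(one$pattern - conv$pattern)), 1e-4)
  expect_true(conv$converged)
})

test_that("retrieval rejects malformed queries", {
  st <- hopfield_store(matrix(runif(10), 2))
  expect_error(hopfield_retrieve(st, c(1, NA, 1, 1, 1)), "finite")
  expect_error(hopfield_retrieve(st, 1:4), "length")
})
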