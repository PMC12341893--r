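test_that("nearest-neighbour means match pairwise enumeration", {
  expect_equal(nn_mean_distance(rbind(c(0, 0), c(1, 0))), 1)
  # unit-square corners: each corner's nearest neighbour is a side, not the
  # diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(nn_mean_distance(sq), 1)
  # collinear points at 0, 1, 3
  col3 <- cbind(c(0, 1, 3), 0)
  expect_equal(nn_mean_distance(col3), 4 / 3)
  # random configurations against a brute-force oracle
  set.seed(2)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    x <- matrix(runif(2 * n), n, 2)
    dm <- as.matrix(dist(x))
    diag(dm) <- Inf
    expect_equal(nn_mean_distance(x), mean(apply(dm, 1, min)),
                 tolerance = 1e-12)
  }
  # Minkowski r = 1 oracle
  x <- rbind(c(0, 0), c(0.3, 0.4), c(1, 1))
  dm <- as.matrix(dist(x, method = "minkowski", p = 1))
  diag(dm) <- Inf
  expect_equal(nn_mean_distance(x, r = 1), mean(apply(dm, 1, min)),
               tolerance = 1e-12)
  expect_error(nn_mean_distance(matrix(0, 1, 2)), "at least 2")
})

test_that("the randomness ratio separates clustered, random and grid-like
          configurations", {
  set.seed(4)
  # two tight, distant clusters
  cl <- rbind(matrix(rnorm(32, 0, 0.01), 16, 2),
              matrix(rnorm(32, 5, 0.01), 16, 2))
  expect_lt(spatial_randomness(cl, n_random = 2000, seed = 1), 1)
  # regular grid
  g <- as.matrix(expand.grid(x = (0:7) / 7, y = (0:3) / 3))
  expect_gt(spatial_randomness(g, n_random = 2000, seed = 2), 1)
  # uniform configurations average near 1 when the null shares their
  # support (the bounding-box default is upward-biased by O(1/n) here,
  # because the box shrinks inside the true support)
  Rs <- sapply(1:40, function(i) {
    spatial_randomness(matrix(runif(64), 32, 2), n_random = 1000,
                       seed = 100 + i, support = rbind(c(0, 1), c(0, 1)))
  })
  expect_lt(abs(mean(Rs) - 1), 0.05)
})

test_that("the ratio is deterministic, scale-invariant and degenerate-safe", {
  set.seed(6)
  x <- matrix(runif(40), 20, 2)
  r1 <- spatial_randomness(x, n_random = 500, seed = 9)
  expect_identical(r1, spatial_randomness(x, n_random = 500, seed = 9))
  expect_equal(spatial_randomness(10 * x, n_random = 500, seed = 9), r1,
               tolerance = 1e-10)
  expect_warning(R0 <- spatial_randomness(matrix(1, 5, 2), n_random = 10,
                                          seed = 1),
                 "degenerate")
  expect_equal(R0, 0)
})

test_that("shrinking within-cluster spread monotonically lowers mean R", {
  means <- sapply(c(0.8, 0.3, 0.05), function(s) {
    set.seed(42)
    mean(sapply(1:15, function(i) {
      x <- rbind(matrix(rnorm(32, 0, s), 16, 2),
                 matrix(rnorm(32, 4, s), 16, 2))
      spatial_randomness(x, n_random = 500, seed = 500 + i)
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("posterior-sample randomness summarizes per-sample ratios and the
          prior is calibrated", {
  ws <- fx("ws")
  samples <- array(rep(fx("lc_control")$coords, each = 4), c(4, 32, 2),
                   dimnames = list(NULL, ws$word_id, NULL))
  fit <- fake_fit(samples)
  rr <- randomness_over_samples(fit, n_random = 500, seed = 3)
  expect_length(rr$R, 4)
  expect_equal(rr$sd, 0, tolerance = 1e-12)

  # prior draws (no data) are uniform, so their mean R is near 1
  empty <- data.frame(word1 = character(0), word2 = character(0),
                      word3 = character(0), choice = character(0),
                      participant_id = character(0))
  pf <- bmds(empty, quick_cfg(warmup = 100, iter = 500), seed = 8,
             word_ids = ws$word_id, align = "none")
  pr <- randomness_over_samples(pf, n_random = 500, seed = 4)
  expect_lt(abs(pr$mean - 1), 0.1)
})

test_that("KS comparison matches a brute-force ECDF sweep", {
  expect_equal(compare_R_distributions(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(compare_R_distributions(c(1, 2), c(10, 11))$D, 1)
  # hand-computable case
  expect_equal(compare_R_distributions(c(1, 2, 3), c(1.5, 2.5))$D, 1 / 3,
               tolerance = 1e-12)
  # random cases against an ECDF maximum-gap oracle
  set.seed(8)
  for (i in 1:10) {
    a <- round(runif(sample(5:30, 1)), 2)
    b <- round(runif(sample(5:30, 1)), 2)
    grid <- sort(unique(c(a, b)))
    Do <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                         numeric(1))))
    expect_equal(compare_R_distributions(a, b)$D, Do, tolerance = 1e-12)
  }
  expect_error(compare_R_distributions(numeric(0), 1:3), "nonempty")
})

test_that("control-like and sv-like posterior R distributions differ", {
  ws <- fx("ws")
  fit_c <- bmds(fx("resp_control"), quick_cfg(warmup = 400, iter = 800),
                seed = 23, word_ids = ws$word_id)
  fit_s <- bmds(fx("resp_sv"), quick_cfg(warmup = 400, iter = 800),
                seed = 23, word_ids = ws$word_id)
  rc <- randomness_over_samples(fit_c, n_random = 1000, seed = 5)
  rs <- randomness_over_samples(fit_s, n_random = 1000, seed = 5)
  ks <- compare_R_distributions(rc, rs)
  expect_gt(ks$D, 0.2)
  expect_lt(ks$p, 0.001)
})
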