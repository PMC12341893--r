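test_that("the log posterior decomposes into prior and per-trial likelihood
          terms", {
  cfg <- bmds_config()
  coords <- rbind(a = c(0.2, 0.2), b = c(0.8, 0.2), c = c(0.5, 0.719615))
  empty <- data.frame(word1 = character(0), word2 = character(0),
                      word3 = character(0), choice = character(0))
  lp0 <- bmds_log_posterior(coords, deltas = c(p1 = 1), empty, cfg)
  # uniform prior on the unit square contributes log-density 0
  expect_equal(lp0, dgamma(1, 2, 1, log = TRUE), tolerance = 1e-12)

  # one equilateral trial adds log(1/3)
  one <- data.frame(word1 = "a", word2 = "b", word3 = "c", choice = "a",
                    participant_id = "p1")
  lp1 <- bmds_log_posterior(coords, c(p1 = 1), one, cfg)
  expect_equal(lp1 - lp0, log(1 / 3), tolerance = 1e-4)

  # additivity over independent trials
  two <- rbind(one, data.frame(word1 = "a", word2 = "b", word3 = "c",
                               choice = "c", participant_id = "p1"))
  lp2 <- bmds_log_posterior(coords, c(p1 = 1), two, cfg)
  p_each <- triad_choice_prob(coords, c("a", "b", "c"), delta = 1)
  expect_equal(lp2 - lp0, log(p_each[["a"]]) + log(p_each[["c"]]),
               tolerance = 1e-10)

  # outside the support the posterior vanishes
  bad <- coords; bad[1, 1] <- 1.4
  expect_equal(bmds_log_posterior(bad, c(p1 = 1), one, cfg), -Inf)
  expect_equal(bmds_log_posterior(coords, c(p1 = -1), one, cfg), -Inf)
})

test_that("the likelihood is invariant to rigid motions of the
          configuration", {
  set.seed(3)
  coords <- matrix(runif(16, 0.3, 0.7), 8, 2,
                   dimnames = list(letters[1:8], NULL))
  resp <- data.frame(word1 = letters[c(1, 2, 5)],
                     word2 = letters[c(3, 4, 6)],
                     word3 = letters[c(2, 6, 7)],
                     choice = letters[c(3, 6, 5)],
                     participant_id = "p1")
  resp$word3 <- letters[c(8, 6, 7)]  # keep words distinct per trial
  cfg <- bmds_config()
  lp <- bmds_log_posterior(coords, c(p1 = 2), resp, cfg)
  ctr <- colMeans(coords)
  rot <- sweep(sweep(coords, 2, ctr) %*% rotation2(0.3), 2, ctr, `+`)
  dimnames(rot) <- dimnames(coords)
  expect_true(all(rot >= 0 & rot <= 1))
  lp_rot <- bmds_log_posterior(rot, c(p1 = 2), resp, cfg)
  expect_equal(lp, lp_rot, tolerance = 1e-10)
})

test_that("with no data the sampler reproduces the uniform prior", {
  empty <- data.frame(word1 = character(0), word2 = character(0),
                      word3 = character(0), choice = character(0),
                      participant_id = character(0))
  fit <- bmds(empty, quick_cfg(warmup = 200, iter = 1000), seed = 3,
              word_ids = sprintf("w%02d", 1:8), align = "none")
  expect_equal(mean(fit$samples), 0.5, tolerance = 0.05)
  expect_gt(sd(as.vector(fit$samples)), 0.2)  # uniform sd ~ 0.29
})

test_that("fits are deterministic given the seed", {
  lc <- fx("lc_control")
  td <- fx("td")
  rs <- simulate_triad_responses(lc, td, participant_profile(delta = 3),
                                 seed = 31)
  f1 <- bmds(rs, quick_cfg(), seed = 7, word_ids = fx("ws")$word_id)
  f2 <- bmds(rs, quick_cfg(), seed = 7, word_ids = fx("ws")$word_id)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$delta, f2$delta)
  f3 <- bmds(rs, quick_cfg(), seed = 8, word_ids = fx("ws")$word_id)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("alignment removes rigid transforms and preserves distances", {
  set.seed(11)
  base <- matrix(runif(20), 10, 2,
                 dimnames = list(sprintf("w%02d", 1:10), NULL))
  ns <- 12
  samples <- array(NA_real_, c(ns, 10, 2),
                   dimnames = list(NULL, rownames(base), c("dim1", "dim2")))
  for (i in seq_len(ns)) {
    th <- runif(1, 0, 2 * pi)
    shift <- runif(2, -0.2, 0.2)
    samples[i, , ] <- sweep(base %*% rotation2(th), 2, shift, `+`)
  }
  fit <- fake_fit(samples, aligned = FALSE)
  al <- align_samples(fit)
  # all samples collapse onto a common configuration
  for (i in 2:ns) {
    expect_equal(al$samples[i, , ], al$samples[1, , ], tolerance = 1e-8)
  }
  # rigid alignment is an isometry: distance matrices unchanged
  for (i in seq_len(ns)) {
    expect_equal(as.vector(dist(al$samples[i, , ])),
                 as.vector(dist(samples[i, , ])), tolerance = 1e-10)
  }
  # the aligned mean of rotated copies recovers the base shape (up to a
  # rigid transform): compare distance matrices
  expect_equal(as.vector(dist(al$posterior_mean)),
               as.vector(dist(base)), tolerance = 1e-8)
})

test_that("a modest simulated cohort is recovered above chance", {
  fit <- bmds(fx("resp_control")[fx("resp_control")$participant_id %in%
                                   sprintf("co%02d", 1:4), ],
              quick_cfg(warmup = 400, iter = 800), seed = 13,
              word_ids = fx("ws")$word_id,
              align = "reference", reference = fx("lc_control")$coords)
  expect_equal(dim(fit$samples), c(50, 32, 2))
  r <- cor(as.vector(dist(fx("lc_control")$coords)),
           as.vector(dist(coef(fit))))
  expect_gt(r, 0.5)
  # per-participant determinism draws are positive and participant-labelled
  expect_equal(ncol(fit$delta), 4)
  expect_true(all(fit$delta > 0))
})

test_that("rejecting non-2D configurations and bad responses", {
  expect_error(bmds_config(n_dims = 3), "2 latent dimensions")
  expect_error(bmds_config(minkowski_r = 0.5), ">= 1")
  bad <- data.frame(word1 = "a", word2 = "b", word3 = "c", choice = "z",
                    participant_id = "p1")
  expect_error(bmds(bad, quick_cfg(), seed = 1), "not part of their triad")
})
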