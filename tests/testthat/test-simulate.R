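test_that("triad choice probabilities follow the exponential-decay rule", {
  # collinear points: d(A,B) = 1, d(A,C) = 2, d(B,C) = 3
  x <- rbind(A = c(0, 0), B = c(1, 0), C = c(-2, 0))
  p <- triad_choice_prob(x, c("A", "B", "C"), delta = 1)
  z <- exp(-1) + exp(-2) + exp(-3)
  expect_equal(unname(p), c(exp(-3), exp(-2), exp(-1)) / z,
               tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["C"]), 0.66524, tolerance = 1e-4)

  # equilateral triangle: uniform
  eq <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2))
  expect_equal(unname(triad_choice_prob(eq, c("a", "b", "c"), delta = 2)),
               rep(1 / 3, 3), tolerance = 1e-12)

  # Minkowski exponents agree on axis-aligned collinear points
  p1 <- triad_choice_prob(x, c("A", "B", "C"), delta = 1.3, r = 1)
  p2 <- triad_choice_prob(x, c("A", "B", "C"), delta = 1.3, r = 2)
  expect_equal(p1, p2, tolerance = 1e-12)

  # coincident pair at distance 0 forces the far word odd as delta grows
  y <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  p <- triad_choice_prob(y, c("a", "b", "c"), delta = 50)
  expect_gt(unname(p["c"]), 0.999)

  expect_error(triad_choice_prob(x, c("A", "B", "C"), delta = 0),
               "positive")
  expect_error(triad_choice_prob(x, c("A", "A", "B"), delta = 1),
               "distinct")
})

test_that("choice probabilities sum to one and entropy falls with
          determinism", {
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(runif(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
    p <- triad_choice_prob(x, c("a", "b", "c"), delta = runif(1, 0.1, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  x <- rbind(a = c(0, 0), b = c(0.8, 0), c = c(0.3, 0.9))
  ent <- sapply(c(0.5, 1, 2, 4, 8), function(d) {
    p <- triad_choice_prob(x, c("a", "b", "c"), delta = d)
    -sum(p * log(p))
  })
  expect_true(all(diff(ent) < 0))
})

test_that("latent configurations are linear maps of z-scored norms", {
  ws <- fx("ws")
  W <- matrix(0, 2, length(PREDICTOR_FEATURES),
              dimnames = list(NULL, PREDICTOR_FEATURES))
  W[1, "concreteness"] <- 1
  lc <- make_latent_config(ws, W, noise_sd = 0, seed = 1, rescale = FALSE)
  z <- (ws$concreteness - mean(ws$concreteness)) / sd(ws$concreteness)
  expect_equal(unname(lc$coords[, 1]), z, tolerance = 1e-12)
  expect_equal(unname(lc$coords[, 2]), rep(0, 32), tolerance = 1e-12)

  # noise-free control preset: OLS on the norms recovers the loadings
  lcc <- make_latent_config(ws, "control_like", noise_sd = 0, seed = 1,
                            rescale = FALSE)
  rr <- regress_dimension(setNames(lcc$coords[, 1], ws$word_id), ws)
  expect_gt(rr$beta[rr$predictor == "concreteness"], 0.5)
  expect_gt(rr$beta[rr$predictor == "valence"], 0.4)
  others <- rr$beta[!rr$predictor %in% c("concreteness", "valence")]
  expect_true(all(abs(others) < 1e-8))

  # sv preset carries no concreteness information on either dimension
  lcs <- make_latent_config(ws, "sv_like", noise_sd = 0, seed = 1,
                            rescale = FALSE)
  for (dm in 1:2) {
    rs <- regress_dimension(setNames(lcs$coords[, dm], ws$word_id), ws)
    expect_lt(abs(rs$beta[rs$predictor == "concreteness"]), 1e-8)
  }

  ws0 <- fx("ws")
  ws0$prevalence <- 0.99
  expect_error(make_latent_config(ws0, "control_like", seed = 1),
               "prevalence")
})

test_that("simulated triad responders are reproducible and lapse-only
          responders are uniform", {
  lc <- fx("lc_control")
  td <- fx("td")
  r1 <- simulate_triad_responses(lc, td, participant_profile(delta = 3),
                                 seed = 9)
  r2 <- simulate_triad_responses(lc, td, participant_profile(delta = 3),
                                 seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 192)
  expect_true(all(r1$choice == r1$word1 | r1$choice == r1$word2 |
                    r1$choice == r1$word3))

  # lapse = 1: position of the odd word is uniform over the three slots
  prof <- participant_profile(delta = 3, lapse = 1 - 1e-12)
  rl <- do.call(rbind, lapply(1:15, function(i)
    simulate_triad_responses(lc, td, prof, seed = 400 + i)))
  slot <- ifelse(rl$choice == rl$word1, 1,
                 ifelse(rl$choice == rl$word2, 2, 3))
  freq <- table(slot) / length(slot)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("pairwise responders follow the instruction polarity and the
          kappa limits", {
  ws <- fx("ws")
  pd <- fx("pd")
  # kappa -> large, no lapses: the higher-rated word is always chosen under
  # the positive-pole instruction
  prof <- participant_profile(kappa_conc = 1e7, kappa_val = 1e7,
                              lapse = 0)
  rp <- simulate_pair_responses(ws, pd, prof, seed = 21)
  conc <- setNames(ws$concreteness, ws$word_id)
  cc <- rp[rp$task == "pair_conc", ]
  more_concrete <- ifelse(conc[cc$word_left] > conc[cc$word_right],
                          cc$word_left, cc$word_right)
  expect_true(all(ifelse(cc$instruction == "concrete",
                         cc$choice == more_concrete,
                         cc$choice != more_concrete)))

  # kappa = 0: each side chosen about half the time
  prof0 <- participant_profile(kappa_conc = 0, kappa_val = 0, lapse = 0)
  r0 <- do.call(rbind, lapply(1:5, function(i)
    simulate_pair_responses(ws, pd, prof0, seed = 600 + i)))
  expect_lt(abs(mean(r0$choice == r0$word_left) - 0.5), 0.03)
})

test_that("cohort simulation is deterministic and complete", {
  ws <- fx("ws")
  td <- fx("td")
  pd <- fx("pd")
  gc_ <- generator_config(n_control = 2, n_sv = 1)
  c1 <- simulate_cohort(ws, td, pd, gc_, seed = 5)
  c2 <- simulate_cohort(ws, td, pd, gc_, seed = 5)
  expect_identical(c1$responses, c2$responses)
  expect_equal(length(unique(c1$responses$participant_id)), 3)
  per <- table(c1$responses$participant_id, c1$responses$task)
  expect_true(all(per[, "triad"] == 192))
  expect_true(all(per[, "pair_conc"] == 512))
  expect_true(all(per[, "pair_val"] == 512))
  expect_equal(nrow(c1$participants), 3)
  expect_true(all(c1$participants$delta > 0))
})
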