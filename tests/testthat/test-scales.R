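# minimal two-word pair design for hand-checkable scoring
mini_pair_design <- function() {
  up <- data.frame(word_a = "a", word_b = "b",
                   pair_type = "share_none", stringsAsFactors = FALSE)
  trials <- data.frame(
    task = "concreteness", trial_index = 1:2, block = c(1L, 2L),
    word_left = "a", word_right = "b",
    instruction = c("concrete", "abstract"),
    pair_type = "share_none", stringsAsFactors = FALSE)
  structure(list(unique_pairs = up, trials = trials,
                 word_ids = c("a", "b")), class = "pair_design")
}

test_that("relative scores follow the +1/-1 scoring rule", {
  d <- mini_pair_design()
  # 'a' always judged the more concrete word: chosen under "concrete" only
  rs1 <- data.frame(task = "pair_conc", word_left = "a", word_right = "b",
                    instruction = c("concrete", "abstract"),
                    choice = c("a", "b"), stringsAsFactors = FALSE)
  sc1 <- build_relative_scale(rs1, d, "concreteness")
  expect_equal(sc1$score[sc1$word_id == "a"], 1)
  expect_equal(sc1$score[sc1$word_id == "b"], -1)
  # the same word chosen under both instructions cancels to 0
  rs2 <- rs1; rs2$choice <- c("a", "a")
  sc2 <- build_relative_scale(rs2, d, "concreteness")
  expect_equal(sc2$score[sc2$word_id == "a"], 0)
  expect_equal(sc2$score[sc2$word_id == "b"], 0)
  # swapping the instruction poles negates every score
  rs3 <- rs1; rs3$instruction <- rev(rs3$instruction)
  sc3 <- build_relative_scale(rs3, d, "concreteness")
  expect_equal(sc3$score, -sc1$score)
  # missing trials produce a coverage warning
  expect_warning(build_relative_scale(rs1[1, ], d, "concreteness"),
                 "1 of 2 trials")
})

test_that("a deterministic norm-following responder yields the win-rate
          scale and high rank agreement", {
  ws <- fx("ws")
  pd <- fx("pd")
  prof <- participant_profile(kappa_conc = 1e7, kappa_val = 1e7, lapse = 0)
  rp <- simulate_pair_responses(ws, pd, prof, seed = 33)
  sc <- build_relative_scale(rp, pd, "concreteness")
  expect_true(all(abs(sc$score) <= 1))
  expect_true(all(sc$n_pairs == 16))
  # oracle: score = (wins - losses) / 16 over the word's unique pairs
  conc <- setNames(ws$concreteness, ws$word_id)
  up <- pd$unique_pairs
  expected <- sapply(ws$word_id, function(w) {
    partners <- c(up$word_b[up$word_a == w], up$word_a[up$word_b == w])
    sum(sign(conc[w] - conc[partners])) / length(partners)
  })
  expect_equal(sc$score, unname(expected[sc$word_id]), tolerance = 1e-12)
  kt <- kendall_vs_ratings(sc, ws)
  expect_gt(kt$tau, 0.85)
  expect_lt(kt$p, 1e-6)
})

test_that("Kendall agreement equals a brute-force concordance count", {
  tau_brute <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
        if (sx == 0) tx <- tx + 1
        if (sy == 0) ty <- ty + 1
        if (sx != 0 && sy != 0) {
          if (sx == sy) conc <- conc + 1 else disc <- disc + 1
        }
      }
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  }
  wrap <- function(x, y) {
    n <- length(x)
    rs <- data.frame(word_id = sprintf("w%02d", 1:n), task = "concreteness",
                     score = x, n_pairs = 16, stringsAsFactors = FALSE)
    ws <- data.frame(word_id = rs$word_id, concreteness = y,
                     stringsAsFactors = FALSE)
    kendall_vs_ratings(rs, ws)$tau
  }
  expect_equal(wrap(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(wrap(1:5, 5:1), -1)
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties on purpose
    y <- round(runif(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(wrap(x, y), tau_brute(x, y), tolerance = 1e-12)
  }
  # constant scale: undefined tau, reported as such
  out <- wrap(rep(1, 5), 1:5)
  expect_true(is.na(out))
})

test_that("the single-case t follows the modified-t formula and its
          symmetries", {
  ctrl <- as.numeric(scale(rnorm(74))) * 2 + 12  # exact mean 12, sd 2
  res <- crawford_howell(10, ctrl)
  expect_equal(res$t, -2 / (2 * sqrt(75 / 74)), tolerance = 1e-10)
  expect_equal(res$df, 73)
  expect_equal(res$p, 2 * pt(res$t, 73), tolerance = 1e-10)
  # case at the control mean
  r0 <- crawford_howell(12, ctrl)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # two-tailed symmetry in +/- k SD
  hi <- crawford_howell(12 + 1.7 * 2, ctrl)
  lo <- crawford_howell(12 - 1.7 * 2, ctrl)
  expect_equal(hi$p, lo$p, tolerance = 1e-12)
  expect_equal(hi$t, -lo$t, tolerance = 1e-12)
  # large-n limit approaches the z-score
  big <- as.numeric(scale(rnorm(2e5))) * 2 + 12
  rb <- crawford_howell(10, big)
  expect_equal(rb$t, -1, tolerance = 1e-4)
  # degenerate controls
  expect_warning(rz <- crawford_howell(3, c(1, 1, 1)), "zero control SD")
  expect_true(is.infinite(rz$t) && rz$t > 0)
  expect_error(crawford_howell(1, 2), "at least 2")
  # one-tailed option
  r1 <- crawford_howell(10, ctrl, alternative = "less")
  expect_equal(r1$p, pt(r1$t, 73), tolerance = 1e-12)
})

test_that("Procrustes mapping is exact for similarity-transformed sources
          and localizes planted error", {
  ws <- fx("ws")
  # scores identical to the rating target: a perfect match
  tgt_scores <- function() {
    list(val = data.frame(word_id = ws$word_id, task = "valence",
                          score = ws$valence,
                          n_pairs = 16, stringsAsFactors = FALSE),
         conc = data.frame(word_id = ws$word_id, task = "concreteness",
                           score = ws$concreteness,
                           n_pairs = 16, stringsAsFactors = FALSE))
  }
  s <- tgt_scores()
  pr <- combine_and_procrustes(s$val, s$conc, ws)
  expect_lt(pr$ss, 1e-20)
  expect_equal(sum(pr$per_stimulus$squared_residual), pr$ss,
               tolerance = 1e-12)

  # rotating and doubling the source changes nothing
  src <- cbind(s$val$score, s$conc$score)
  rot <- 2 * src %*% rotation2(pi / 2)
  pr2 <- combine_and_procrustes(
    transform(s$val, score = rot[, 1]),
    transform(s$conc, score = rot[, 2]), ws)
  expect_lt(pr2$ss, 1e-20)

  # uniform-scale invariance of the error
  set.seed(20)
  noisy <- s
  noisy$val$score <- s$val$score + rnorm(32, 0, 0.3)
  pr_n <- combine_and_procrustes(noisy$val, noisy$conc, ws)
  scaled <- noisy
  scaled$val$score <- 3 * noisy$val$score
  scaled$conc$score <- 3 * noisy$conc$score
  pr_s <- combine_and_procrustes(scaled$val, scaled$conc, ws)
  expect_equal(pr_s$ss, pr_n$ss, tolerance = 1e-10)

  # a single perturbed stimulus carries the largest residual
  pert <- s
  k <- 7
  pert$val$score[k] <- pert$val$score[k] + 2
  prp <- combine_and_procrustes(pert$val, pert$conc, ws)
  expect_equal(which.max(prp$per_stimulus$squared_residual), k)
})

test_that("Procrustes error matches an SVD closed-form oracle", {
  ws <- fx("ws")
  set.seed(30)
  val <- data.frame(word_id = ws$word_id, task = "valence",
                    score = runif(32, -1, 1), n_pairs = 16,
                    stringsAsFactors = FALSE)
  conc <- data.frame(word_id = ws$word_id, task = "concreteness",
                     score = runif(32, -1, 1), n_pairs = 16,
                     stringsAsFactors = FALSE)
  pr <- combine_and_procrustes(val, conc, ws)
  # oracle: after centring and unit-norming both configurations, the minimal
  # SS over rotation and scale is 1 - (sum of singular values)^2
  norm_cfg <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  X <- norm_cfg(cbind(ws$valence, ws$concreteness))
  Y <- norm_cfg(cbind(val$score, conc$score))
  sv <- svd(t(X) %*% Y)
  expect_equal(pr$ss, 1 - sum(sv$d)^2, tolerance = 1e-10)
})

test_that("stimulus-error ANOVA flags planted class effects and matches
          manual arithmetic", {
  ws <- fx("ws")
  base <- data.frame(word_id = ws$word_id, word_class = ws$word_class,
                     squared_residual = 0.1, stringsAsFactors = FALSE)
  pr_flat <- structure(list(ss = sum(base$squared_residual),
                            per_stimulus = base),
                       class = "procrustes_result")
  out <- stimulus_error_anova(pr_flat)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)

  planted <- base
  set.seed(9)
  planted$squared_residual <- abs(rnorm(32, 0.1, 0.01)) +
    ifelse(grepl("concrete", planted$word_class), 0.5, 0)
  prp <- structure(list(ss = sum(planted$squared_residual),
                        per_stimulus = planted),
                   class = "procrustes_result")
  outp <- stimulus_error_anova(prp)
  expect_gt(outp$F, 10)
  expect_lt(outp$p, 0.05)

  # two-group toy against hand-computed mean squares
  toy <- data.frame(word_id = paste0("w", 1:6),
                    word_class = rep(c("abstract_positive",
                                       "concrete_positive"), each = 3),
                    squared_residual = c(1, 2, 3, 7, 8, 9),
                    stringsAsFactors = FALSE)
  prt <- structure(list(ss = 30, per_stimulus = toy),
                   class = "procrustes_result")
  x <- toy$squared_residual
  gm <- tapply(x, toy$word_class, mean)
  ssb <- sum(3 * (gm - mean(x))^2)
  ssw <- sum((x - gm[toy$word_class])^2)
  f_manual <- (ssb / 1) / (ssw / 4)
  expect_equal(stimulus_error_anova(prt)$F, f_manual, tolerance = 1e-10)
})
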