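#' Construct a latent 2D word configuration from word norms
#'
#' Computes per-word coordinates as a linear map of z-scored norm features
#' plus Gaussian noise, then rescales each dimension to \[0, 1\] (the support
#' of the inference prior). Two presets encode the group structures the
#' generator emulates: `control_like` loads dimension 1 on concreteness and
#' valence and dimension 2 on dominance (+) and arousal (-); `sv_like` loads
#' both dimensions on valence only (opposite signs), so that concreteness
#' carries no information and the configuration collapses onto a single
#' affective axis.
#'
#' @param ws A `word_set` data frame.
#' @param W A 2 x 8 loading matrix over [PREDICTOR_FEATURES], or a preset
#'   name `"control_like"` / `"sv_like"`.
#' @param noise_sd Gaussian noise SD added per dimension before rescaling.
#' @param seed Integer seed.
#' @param rescale Rescale each dimension to \[0, 1\] (default TRUE).
#' @return A `latent_config` object: list with `coords` (n x 2 matrix, rows
#'   named by word id) and `word_ids`.
#' @examples
#' ws <- synthesize_word_set(seed = 1)
#' lc <- make_latent_config(ws, "control_like", seed = 2)
#' @export
make_latent_config <- function(ws, W = "control_like", noise_sd = 0.3,
                               seed = NULL, rescale = TRUE) {
  if (is.character(W)) W <- latent_weights(W)
  stopifnot(is.matrix(W), nrow(W) == 2, ncol(W) == length(PREDICTOR_FEATURES),
            all(is.finite(W)), noise_sd >= 0)
  Z <- zscore_features(ws, PREDICTOR_FEATURES)
  with_seed(seed, {
    coords <- Z %*% t(W) +
      matrix(rnorm(2 * nrow(Z), 0, noise_sd), ncol = 2)
    if (rescale) coords <- apply(coords, 2, minmax01)
    rownames(coords) <- ws$word_id
    colnames(coords) <- c("dim1", "dim2")
    structure(list(coords = coords, word_ids = ws$word_id),
              class = "latent_config")
  })
}

#' @rdname make_latent_config
#' @param preset Preset name.
#' @export
latent_weights <- function(preset = c("control_like", "sv_like")) {
  preset <- match.arg(preset)
  W <- matrix(0, 2, length(PREDICTOR_FEATURES),
              dimnames = list(c("dim1", "dim2"), PREDICTOR_FEATURES))
  if (preset == "control_like") {
    W["dim1", "concreteness"] <- 0.7
    W["dim1", "valence"] <- 0.6
    W["dim2", "dominance"] <- 0.7
    W["dim2", "arousal"] <- -0.5
  } else {
    W["dim1", "valence"] <- -0.9
    W["dim2", "valence"] <- 0.6
  }
  W
}

zscore_features <- function(ws, features) {
  Z <- sapply(features, function(f) {
    x <- ws[[f]]
    s <- sd(x)
    if (s == 0) {
      stop("zero-variance feature under z-scoring: ", f, call. = FALSE)
    }
    (x - mean(x)) / s
  })
  rownames(Z) <- ws$word_id
  Z
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Participant response profile
#'
#' Bundles the parameters of the stochastic responders: `delta` is the triad
#' response determinism (softmax inverse temperature on pair distances),
#' `kappa_conc` and `kappa_val` are the pairwise discrimination slopes for
#' the concreteness and valence tasks, and `lapse` is the probability of a
#' uniform guess on any trial.
#'
#' @param group `"control_like"` or `"sv_like"` (label only).
#' @param delta Positive determinism parameter.
#' @param kappa_conc,kappa_val Nonnegative logistic slopes.
#' @param lapse Guess probability in \[0, 1).
#' @export
participant_profile <- function(group = "control_like", delta = 3,
                                kappa_conc = 2, kappa_val = 2, lapse = 0.02) {
  stopifnot(delta > 0, kappa_conc >= 0, kappa_val >= 0,
            lapse >= 0, lapse < 1)
  structure(list(group = group, delta = delta, kappa_conc = kappa_conc,
                 kappa_val = kappa_val, lapse = lapse),
            class = "participant_profile")
}

#' Triad odd-one-out choice probabilities
#'
#' The exponential-decay choice rule of the latent-space model: the
#' probability that a word is the odd one out is proportional to
#' `exp(-delta * d)` where `d` is the Minkowski distance between the other
#' two words — the closer the remaining pair, the more likely the third word
#' is odd.
#'
#' @param coords n x 2 coordinate matrix with rownames, or a
#'   `latent_config`.
#' @param triad Character or integer vector of length 3 identifying the
#'   words.
#' @param delta Positive determinism parameter.
#' @param r Minkowski exponent (default 2, Euclidean).
#' @return Named numeric vector of length 3 summing to 1: P(odd = word).
#' @examples
#' x <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 2))
#' triad_choice_prob(x, c("a", "b", "c"), delta = 1)
#' @export
triad_choice_prob <- function(coords, triad, delta, r = 2) {
  coords <- as_coords(coords)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  idx <- resolve_words(coords, triad)
  if (length(unique(idx)) != 3) stop("triad needs 3 distinct words",
                                     call. = FALSE)
  if (!all(is.finite(coords[idx, ]))) stop("non-finite coordinates",
                                           call. = FALSE)
  d <- function(i, j) mink_dist(coords[i, ], coords[j, ], r)
  u <- -delta * c(d(idx[2], idx[3]), d(idx[1], idx[3]), d(idx[1], idx[2]))
  p <- exp(u - max(u))
  p <- p / sum(p)
  names(p) <- if (is.character(triad)) triad else rownames(coords)[idx]
  p
}

mink_dist <- function(a, b, r) {
  dv <- abs(a - b)
  if (r == 2) sqrt(sum(dv^2)) else sum(dv^r)^(1 / r)
}

as_coords <- function(coords) {
  if (inherits(coords, "latent_config")) coords$coords else as.matrix(coords)
}

resolve_words <- function(coords, w) {
  if (is.character(w)) {
    idx <- match(w, rownames(coords))
    if (anyNA(idx)) stop("unknown word id(s): ",
                         paste(w[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  } else as.integer(w)
}

#' Simulate odd-one-out responses to a triad design
#'
#' Per presented trial, with probability `lapse` the odd word is chosen
#' uniformly; otherwise it is sampled from [triad_choice_prob()] under the
#' participant's latent configuration and determinism.
#'
#' @param lc A `latent_config` (or coordinate matrix with row names).
#' @param d A `triad_design`.
#' @param profile A [participant_profile()].
#' @param seed Integer seed.
#' @param r Minkowski exponent.
#' @param participant_id Label stored in the output.
#' @return A data frame with columns `participant_id`, `group`, `task`,
#'   `trial_index`, `word1`, `word2`, `word3`, `choice` (the odd word).
#' @export
simulate_triad_responses <- function(lc, d, profile, seed = NULL, r = 2,
                                     participant_id = "p1") {
  coords <- as_coords(lc)
  stopifnot(inherits(d, "triad_design"))
  if (profile$delta <= 0) stop("delta must be positive", call. = FALSE)
  with_seed(seed, {
    tr <- d$trials
    n <- nrow(tr)
    choice <- character(n)
    for (i in seq_len(n)) {
      triad <- c(tr$word1[i], tr$word2[i], tr$word3[i])
      if (runif(1) < profile$lapse) {
        choice[i] <- sample(triad, 1)
      } else {
        p <- triad_choice_prob(coords, triad, profile$delta, r)
        choice[i] <- sample(triad, 1, prob = p)
      }
    }
    data.frame(participant_id = participant_id, group = profile$group,
               task = "triad", trial_index = tr$trial_index,
               word1 = tr$word1, word2 = tr$word2, word3 = tr$word3,
               choice = choice, stringsAsFactors = FALSE)
  })
}

#' Simulate forced-choice responses to the pairwise design
#'
#' Logistic comparator on the z-scored task attribute: under instruction
#' "concrete" the left word is chosen with probability
#' `plogis(kappa_conc * (c_left - c_right))`; "abstract" flips the sign, and
#' the valence task behaves analogously with `kappa_val`. A lapse mixes in a
#' uniform choice. (The choice model for the pairwise tasks is a package
#' convention; only the triad task has a model-implied response rule.)
#'
#' @param ws A `word_set` data frame.
#' @param d A `pair_design`.
#' @param profile A [participant_profile()].
#' @param seed Integer seed.
#' @param participant_id Label stored in the output.
#' @return Data frame with columns `participant_id`, `group`, `task`
#'   (`pair_conc` / `pair_val`), `trial_index`, `word_left`, `word_right`,
#'   `instruction`, `choice`.
#' @export
simulate_pair_responses <- function(ws, d, profile, seed = NULL,
                                    participant_id = "p1") {
  stopifnot(inherits(d, "pair_design"))
  z <- zscore_features(ws, c("concreteness", "valence"))
  with_seed(seed, {
    tr <- d$trials
    attr_of <- ifelse(tr$task == "concreteness", "concreteness", "valence")
    kappa <- ifelse(tr$task == "concreteness", profile$kappa_conc,
                    profile$kappa_val)
    sign <- ifelse(tr$instruction %in% c("concrete", "positive"), 1, -1)
    if (!all(tr$instruction %in% c("concrete", "abstract", "positive",
                                   "negative"))) {
      stop("unknown instruction in pair design", call. = FALSE)
    }
    dz <- z[cbind(match(tr$word_left, ws$word_id), match(attr_of,
                                                         colnames(z)))] -
      z[cbind(match(tr$word_right, ws$word_id), match(attr_of,
                                                      colnames(z)))]
    p_left <- stats::plogis(kappa * sign * dz)
    lapse_draw <- runif(nrow(tr)) < profile$lapse
    p_left[lapse_draw] <- 0.5
    left <- runif(nrow(tr)) < p_left
    data.frame(participant_id = participant_id, group = profile$group,
               task = ifelse(tr$task == "concreteness", "pair_conc",
                             "pair_val"),
               trial_index = tr$trial_index,
               word_left = tr$word_left, word_right = tr$word_right,
               instruction = tr$instruction,
               choice = ifelse(left, tr$word_left, tr$word_right),
               stringsAsFactors = FALSE)
  })
}

#' Cohort-level generator configuration
#'
#' Distributions from which per-participant profiles are drawn. Determinism
#' `delta` is log-normal (control-like median 3, sv-like median 1.5 by
#' default) so that sv-like responses are noisier; the sv-like preset also
#' sets the concreteness discrimination slope far below the valence slope.
#'
#' @param n_control,n_sv Cohort sizes (defaults 77 and 10).
#' @param noise_sd Latent-configuration noise SD.
#' @param control,sv Per-group profile distribution parameters.
#' @export
generator_config <- function(n_control = 77, n_sv = 10, noise_sd = 0.3,
                             control = list(delta_meanlog = log(3),
                                            delta_sdlog = 0.25,
                                            kappa_conc = 2, kappa_val = 2,
                                            lapse = 0.02),
                             sv = list(delta_meanlog = log(1.5),
                                       delta_sdlog = 0.35,
                                       kappa_conc = 0.3, kappa_val = 2,
                                       lapse = 0.05)) {
  list(n_control = n_control, n_sv = n_sv, noise_sd = noise_sd,
       control = control, sv = sv)
}

#' Simulate a full synthetic cohort
#'
#' Draws one latent configuration per group (control-like and sv-like
#' presets), samples per-participant profiles from the configured
#' distributions and generates complete triad and pairwise response sets.
#' The ground truth (configurations, profiles, weight matrices) is returned
#' for recovery experiments.
#'
#' @param ws A `word_set`.
#' @param triad_design,pair_design Designs built from `ws`.
#' @param gc A [generator_config()].
#' @param seed Integer seed.
#' @return A list with `responses` (long data frame over all participants
#'   and tasks), `participants` (profile table), and `truth` (latent configs
#'   and weights per group).
#' @export
simulate_cohort <- function(ws, triad_design, pair_design,
                            gc = generator_config(), seed = 1) {
  lc_control <- make_latent_config(ws, "control_like", gc$noise_sd,
                                   seed = derive_seed(seed, 1))
  lc_sv <- make_latent_config(ws, "sv_like", gc$noise_sd,
                              seed = derive_seed(seed, 2))
  groups <- c(rep("control_like", gc$n_control), rep("sv_like", gc$n_sv))
  ids <- c(sprintf("HC%03d", seq_len(gc$n_control)),
           sprintf("SV%03d", seq_len(gc$n_sv)))
  resp <- vector("list", length(ids))
  prof_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- groups[i]
    pars <- if (g == "control_like") gc$control else gc$sv
    pseed <- derive_seed(seed, 10 + i)
    prof <- with_seed(pseed, participant_profile(
      group = g,
      delta = rlnorm(1, pars$delta_meanlog, pars$delta_sdlog),
      kappa_conc = pars$kappa_conc, kappa_val = pars$kappa_val,
      lapse = pars$lapse))
    lc <- if (g == "control_like") lc_control else lc_sv
    rt <- simulate_triad_responses(lc, triad_design, prof,
                                   seed = derive_seed(seed, 5000 + i),
                                   participant_id = ids[i])
    rp <- simulate_pair_responses(ws, pair_design, prof,
                                  seed = derive_seed(seed, 9000 + i),
                                  participant_id = ids[i])
    rt2 <- data.frame(participant_id = rt$participant_id, group = rt$group,
                      task = rt$task, trial_index = rt$trial_index,
                      word_left = NA_character_, word_right = NA_character_,
                      instruction = NA_character_,
                      word1 = rt$word1, word2 = rt$word2, word3 = rt$word3,
                      choice = rt$choice, stringsAsFactors = FALSE)
    rp2 <- data.frame(participant_id = rp$participant_id, group = rp$group,
                      task = rp$task, trial_index = rp$trial_index,
                      word_left = rp$word_left, word_right = rp$word_right,
                      instruction = rp$instruction,
                      word1 = NA_character_, word2 = NA_character_,
                      word3 = NA_character_,
                      choice = rp$choice, stringsAsFactors = FALSE)
    resp[[i]] <- rbind(rt2, rp2)
    prof_rows[[i]] <- data.frame(participant_id = ids[i], group = g,
                                 delta = prof$delta,
                                 kappa_conc = prof$kappa_conc,
                                 kappa_val = prof$kappa_val,
                                 lapse = prof$lapse,
                                 stringsAsFactors = FALSE)
  }
  list(responses = do.call(rbind, resp),
       participants = do.call(rbind, prof_rows),
       truth = list(control_like = lc_control, sv_like = lc_sv,
                    W_control = latent_weights("control_like"),
                    W_sv = latent_weights("sv_like")))
}
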