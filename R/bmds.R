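#' Configuration for the Bayesian MDS sampler
#'
#' The model places the latent word coordinates uniformly on an axis-aligned
#' square (default the unit square), generates pairwise Minkowski distances
#' (exponent `minkowski_r`, default 2) and explains each odd-one-out choice
#' through an exponential-decay rule with a per-participant determinism
#' parameter `delta` (Gamma prior). Sampling is random-walk
#' Metropolis-within-Gibbs over per-word coordinate blocks and per-participant
#' `delta`, with step sizes adapted during warmup only; `n_samples` draws
#' (default 50) are retained, evenly thinned from the post-warmup chain.
#'
#' @param minkowski_r Minkowski exponent, >= 1.
#' @param support Numeric length-2: lower/upper bound of the square prior.
#' @param delta_shape,delta_rate Gamma prior on each participant's delta.
#' @param warmup Adaptation iterations (discarded).
#' @param iter Post-warmup iterations before thinning.
#' @param n_samples Retained posterior draws.
#' @param n_dims Latent dimensionality; only 2 is supported.
#' @param rhat_threshold Split-chain convergence threshold on distance
#'   summaries above which a non-convergence warning is recorded.
#' @export
bmds_config <- function(minkowski_r = 2, support = c(0, 1),
                        delta_shape = 2, delta_rate = 1,
                        warmup = 2000, iter = 5000, n_samples = 50,
                        n_dims = 2, rhat_threshold = 1.1) {
  if (minkowski_r < 1) stop("minkowski_r must be >= 1", call. = FALSE)
  if (n_dims != 2) stop("only 2 latent dimensions are supported",
                        call. = FALSE)
  stopifnot(length(support) == 2, support[2] > support[1],
            warmup >= 0, iter >= n_samples, n_samples >= 1)
  structure(list(minkowski_r = minkowski_r, support = support,
                 delta_shape = delta_shape, delta_rate = delta_rate,
                 warmup = warmup, iter = iter, n_samples = n_samples,
                 n_dims = 2, rhat_threshold = rhat_threshold),
            class = "bmds_config")
}

# internal: canonical trial representation from a long response data frame
prepare_triad_data <- function(responses, word_ids = NULL) {
  if ("task" %in% names(responses)) {
    responses <- responses[responses$task == "triad", , drop = FALSE]
  }
  need <- c("word1", "word2", "word3", "choice")
  if (!all(need %in% names(responses))) {
    stop("triad responses need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(responses) > 0) {
    words_used <- unique(c(responses$word1, responses$word2, responses$word3))
  } else {
    words_used <- character(0)
  }
  if (is.null(word_ids)) word_ids <- sort(words_used)
  if (length(setdiff(words_used, word_ids))) {
    stop("responses reference words outside the word set: ",
         paste(setdiff(words_used, word_ids), collapse = ", "),
         call. = FALSE)
  }
  pid <- if ("participant_id" %in% names(responses) && nrow(responses) > 0) {
    factor(responses$participant_id)
  } else {
    factor(rep("p1", nrow(responses)))
  }
  idx <- cbind(match(responses$word1, word_ids),
               match(responses$word2, word_ids),
               match(responses$word3, word_ids))
  odd <- integer(nrow(responses))
  if (nrow(responses) > 0) {
    odd[responses$choice == responses$word1] <- 1L
    odd[responses$choice == responses$word2] <- 2L
    odd[responses$choice == responses$word3] <- 3L
    if (any(odd == 0)) {
      stop("some choices are not part of their triad", call. = FALSE)
    }
  }
  list(idx = idx, odd = odd, pid = as.integer(pid),
       participant_ids = levels(pid), word_ids = word_ids)
}

#' Joint log-posterior of the triad model
#'
#' Sum over trials of the log choice probability of the observed odd word,
#' plus the log prior: uniform coordinates on the support square (-Inf
#' outside) and Gamma(`delta_shape`, `delta_rate`) for each participant's
#' determinism.
#'
#' @param coords n_words x 2 matrix with row names.
#' @param deltas Named (by participant) or unnamed positive vector.
#' @param responses Long triad response data frame (may have 0 rows).
#' @param config A [bmds_config()].
#' @return Scalar log posterior density (unnormalized).
#' @export
bmds_log_posterior <- function(coords, deltas, responses,
                               config = bmds_config()) {
  coords <- as_coords(coords)
  dat <- prepare_triad_data(responses, word_ids = rownames(coords))
  if (any(deltas <= 0)) return(-Inf)
  if (any(coords < config$support[1]) || any(coords > config$support[2])) {
    return(-Inf)
  }
  np <- max(length(deltas), length(dat$participant_ids))
  lp <- sum(stats::dgamma(deltas, config$delta_shape, config$delta_rate,
                          log = TRUE))
  if (nrow(dat$idx) > 0) {
    delta_by_trial <- deltas[dat$pid]
    lp <- lp + sum(.triad_loglik_cpp(coords, dat$idx, dat$odd,
                                     delta_by_trial, config$minkowski_r))
  }
  lp
}

#' Fit the Bayesian multidimensional scaling model to triad responses
#'
#' Pools the odd-one-out responses of one or more participants over a shared
#' latent 2D configuration, with one determinism parameter per participant,
#' and samples the joint posterior by adaptive random-walk
#' Metropolis-within-Gibbs. Retained draws are rigidly aligned (translation +
#' rotation/reflection, no scaling) to a common template — either an iterated
#' mean template or, for recovery studies, a supplied reference
#' configuration — because the likelihood only identifies the configuration
#' up to those transforms.
#'
#' @param responses Long response data frame (columns `word1`..`word3`,
#'   `choice`, optionally `participant_id` and `task`).
#' @param config A [bmds_config()].
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param word_ids Optional word-id vector fixing the coordinate order.
#' @param align `"mean_template"` (default), `"reference"` or `"none"`.
#' @param reference n_words x 2 matrix used when `align = "reference"`.
#' @return A `bmds` object: retained aligned samples (`samples`, array
#'   `n_samples x n_words x 2`), per-participant `delta` draws, the
#'   posterior-mean configuration, acceptance/convergence diagnostics and the
#'   configuration used.
#' @examples
#' \donttest{
#' ws <- synthesize_word_set(seed = 1)
#' td <- build_triad_design(ws, seed = 2)
#' lc <- make_latent_config(ws, "control_like", seed = 3)
#' rs <- simulate_triad_responses(lc, td, participant_profile(), seed = 4)
#' fit <- bmds(rs, bmds_config(warmup = 200, iter = 400), seed = 5)
#' coef(fit)[1:3, ]
#' }
#' @export
bmds <- function(responses, config = bmds_config(), seed = NULL,
                 word_ids = NULL, align = c("mean_template", "reference",
                                            "none"),
                 reference = NULL) {
  align <- match.arg(align)
  dat <- prepare_triad_data(responses, word_ids)
  W <- length(dat$word_ids)
  if (W < 3) stop("need at least 3 words", call. = FALSE)
  P <- max(1L, length(dat$participant_ids))
  r <- config$minkowski_r
  lo <- config$support[1]; hi <- config$support[2]
  n_trials <- nrow(dat$idx)
  trials_of_word <- lapply(seq_len(W), function(w) {
    which(dat$idx[, 1] == w | dat$idx[, 2] == w | dat$idx[, 3] == w)
  })
  trials_of_part <- lapply(seq_len(P), function(p) which(dat$pid == p))

  with_seed(seed, {
    X <- matrix(runif(W * 2, lo, hi), W, 2,
                dimnames = list(dat$word_ids, c("dim1", "dim2")))
    delta <- rep(config$delta_shape / config$delta_rate, P)
    ll <- if (n_trials > 0) {
      .triad_loglik_cpp(X, dat$idx, dat$odd, delta[dat$pid], r)
    } else numeric(0)
    step_x <- rep(0.1 * (hi - lo), W)
    step_d <- rep(0.3, P)
    acc_x <- att_x <- rep(0L, W)
    acc_d <- att_d <- rep(0L, P)

    total <- config$warmup + config$iter
    keep_at <- config$warmup +
      unique(round(seq(config$iter / config$n_samples, config$iter,
                       length.out = config$n_samples)))
    samples <- array(NA_real_, c(length(keep_at), W, 2),
                     dimnames = list(NULL, dat$word_ids, c("dim1", "dim2")))
    delta_draws <- matrix(NA_real_, length(keep_at), P,
                          dimnames = list(NULL, dat$participant_ids))
    k <- 0L
    diag_every <- max(1L, floor(total / 400))
    diag_trace <- numeric(0)

    for (it in seq_len(total)) {
      adapting <- it <= config$warmup
      for (w in seq_len(W)) {
        prop <- X[w, ] + rnorm(2, 0, step_x[w])
        att_x[w] <- att_x[w] + 1L
        if (any(prop < lo) || any(prop > hi)) {
          alpha <- 0
        } else {
          tw <- trials_of_word[[w]]
          if (length(tw) == 0) {
            alpha <- 1
            ll_new <- numeric(0)
          } else {
            Xp <- X; Xp[w, ] <- prop
            ll_new <- .triad_loglik_cpp(Xp, dat$idx[tw, , drop = FALSE],
                                        dat$odd[tw], delta[dat$pid[tw]], r)
            alpha <- exp(min(0, sum(ll_new) - sum(ll[tw])))
          }
          if (runif(1) < alpha) {
            X[w, ] <- prop
            if (length(tw <- trials_of_word[[w]])) ll[tw] <- ll_new
            acc_x[w] <- acc_x[w] + 1L
          }
        }
        if (adapting && att_x[w] %% 50 == 0) {
          rate <- acc_x[w] / att_x[w]
          step_x[w] <- min(hi - lo,
                           max(1e-4, step_x[w] * exp(0.6 * (rate - 0.3))))
        }
      }
      for (p in seq_len(P)) {
        tp <- trials_of_part[[p]]
        prop <- delta[p] * exp(rnorm(1, 0, step_d[p]))
        att_d[p] <- att_d[p] + 1L
        lr <- config$delta_shape * (log(prop) - log(delta[p])) -
          config$delta_rate * (prop - delta[p])
        if (length(tp)) {
          ll_new <- .triad_loglik_cpp(X, dat$idx[tp, , drop = FALSE],
                                      dat$odd[tp],
                                      rep(prop, length(tp)), r)
          lr <- lr + sum(ll_new) - sum(ll[tp])
        }
        if (log(runif(1)) < lr) {
          delta[p] <- prop
          if (length(tp)) ll[tp] <- ll_new
          acc_d[p] <- acc_d[p] + 1L
        }
        if (adapting && att_d[p] %% 50 == 0) {
          rate <- acc_d[p] / att_d[p]
          step_d[p] <- min(5, max(1e-3, step_d[p] * exp(0.6 * (rate - 0.3))))
        }
      }
      if (!adapting) {
        if (it %% diag_every == 0) {
          diag_trace <- c(diag_trace, mean(dist(X)))
        }
        hit <- which(keep_at == it)
        if (length(hit)) {
          k <- k + 1L
          samples[k, , ] <- X
          delta_draws[k, ] <- delta
        }
      }
    }

    rhat <- split_rhat(diag_trace)
    converged <- is.na(rhat) || rhat < config$rhat_threshold
    if (!converged) {
      warning("bmds: split-chain statistic on mean pairwise distance = ",
              round(rhat, 3), " exceeds ", config$rhat_threshold,
              "; treat the fit as non-converged", call. = FALSE)
    }
    fit <- structure(list(
      samples = samples,
      delta = delta_draws,
      posterior_mean = NULL,
      word_ids = dat$word_ids,
      participant_ids = dat$participant_ids,
      n_trials = n_trials,
      aligned = FALSE,
      alignment = "none",
      diagnostics = list(accept_coord = mean(acc_x / pmax(1, att_x)),
                         accept_delta = mean(acc_d / pmax(1, att_d)),
                         rhat_dist = rhat, converged = converged),
      config = config,
      seed = seed
    ), class = "bmds")
    fit$posterior_mean <- apply(fit$samples, c(2, 3), mean)
    if (align != "none") {
      fit <- align_samples(fit, reference = if (align == "reference")
        reference else NULL)
    }
    fit
  })
}

split_rhat <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  half <- floor(n / 2)
  a <- x[seq_len(half)]
  b <- x[seq.int(n - half + 1, n)]
  m <- half
  W <- (var(a) + var(b)) / 2
  B <- m * var(c(mean(a), mean(b)))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Rigidly align posterior samples to a common template
#'
#' The triad likelihood is invariant to translation, rotation and reflection
#' of the configuration, so raw MCMC draws are not directly comparable.
#' Each retained sample is mapped by the rigid transform (translation plus
#' orthogonal rotation/reflection, no scaling) that minimizes its summed
#' squared distance to a template: either a supplied reference configuration
#' or an iterated mean of the aligned samples. Within-sample pairwise
#' distances are unchanged.
#'
#' @param object A `bmds` fit.
#' @param reference Optional n_words x 2 reference configuration (e.g. a
#'   generator's ground truth in a recovery study).
#' @param iterations Mean-template refinement passes (ignored with a
#'   reference).
#' @return The fit with aligned `samples` and recomputed `posterior_mean`.
#' @export
align_samples <- function(object, reference = NULL, iterations = 5) {
  stopifnot(inherits(object, "bmds"))
  S <- object$samples
  ns <- dim(S)[1]
  if (is.null(reference)) {
    ref <- S[1, , ]
    for (pass in seq_len(iterations)) {
      for (i in seq_len(ns)) S[i, , ] <- rigid_align(S[i, , ], ref)
      ref <- apply(S, c(2, 3), mean)
    }
    object$alignment <- "mean_template"
  } else {
    reference <- as_coords(reference)
    if (!is.null(rownames(reference))) {
      reference <- reference[object$word_ids, , drop = FALSE]
    }
    for (i in seq_len(ns)) S[i, , ] <- rigid_align(S[i, , ], reference)
    object$alignment <- "reference"
  }
  object$samples <- S
  object$posterior_mean <- apply(S, c(2, 3), mean)
  object$aligned <- TRUE
  object
}

# translation + rotation/reflection (no scaling) of A onto ref, least squares
rigid_align <- function(A, ref) {
  ca <- colMeans(A); cr <- colMeans(ref)
  Ac <- sweep(A, 2, ca)
  Rc <- sweep(ref, 2, cr)
  sv <- svd(crossprod(Ac, Rc))
  Q <- sv$u %*% t(sv$v)
  out <- Ac %*% Q
  sweep(out, 2, cr, `+`)
}
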