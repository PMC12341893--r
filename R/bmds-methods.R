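#' @export
print.bmds <- function(x, ...) {
  cat("Bayesian MDS fit:", length(x$word_ids), "words,",
      length(x$participant_ids), "participant(s),",
      x$n_trials, "trials\n")
  cat("Retained samples:", dim(x$samples)[1],
      "| alignment:", x$alignment, "\n")
  cat("Acceptance (coords):", round(x$diagnostics$accept_coord, 2),
      "| (delta):", round(x$diagnostics$accept_delta, 2), "\n")
  if (!is.na(x$diagnostics$rhat_dist)) {
    cat("Split-chain statistic (mean pairwise distance):",
        round(x$diagnostics$rhat_dist, 3),
        if (x$diagnostics$converged) "(converged)" else "(NOT converged)",
        "\n")
  }
  invisible(x)
}

#' @export
summary.bmds <- function(object, ...) {
  pm <- object$posterior_mean
  spread <- apply(object$samples, 2, function(s) mean(sqrt(rowSums(
    sweep(s, 2, colMeans(s))^2))))
  dm <- colMeans(object$delta)
  out <- list(
    coordinates = data.frame(word_id = object$word_ids,
                             dim1 = pm[, 1], dim2 = pm[, 2],
                             posterior_spread = spread,
                             stringsAsFactors = FALSE),
    delta = data.frame(participant_id = object$participant_ids,
                       delta_mean = dm,
                       delta_sd = apply(object$delta, 2, sd),
                       stringsAsFactors = FALSE),
    diagnostics = object$diagnostics
  )
  class(out) <- "summary.bmds"
  out
}

#' @export
print.summary.bmds <- function(x, ...) {
  cat("Posterior-mean configuration (first rows):\n")
  print(utils::head(x$coordinates), row.names = FALSE)
  cat("\nPer-participant determinism (delta):\n")
  print(utils::head(x$delta), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bmds <- function(object, ...) object$posterior_mean

#' Predict odd-one-out choice probabilities from a fitted configuration
#'
#' Evaluates the exponential-decay choice rule at the posterior-mean
#' configuration (and posterior-mean delta, averaged over participants
#' unless one is named).
#'
#' @param object A `bmds` fit.
#' @param triads Data frame with columns `word1`, `word2`, `word3`.
#' @param participant_id Optional participant whose delta to use.
#' @param ... Unused.
#' @return Matrix of three choice probabilities per triad row.
#' @export
predict.bmds <- function(object, triads, participant_id = NULL, ...) {
  delta <- if (is.null(participant_id)) {
    mean(object$delta)
  } else {
    mean(object$delta[, participant_id])
  }
  t(apply(triads[, c("word1", "word2", "word3")], 1, function(tr) {
    triad_choice_prob(object$posterior_mean, as.character(tr), delta,
                      object$config$minkowski_r)
  }))
}

#' Simulate odd-one-out responses from a fitted model
#'
#' Draws responses to a triad design from the posterior-mean configuration
#' and delta, i.e. a parametric-bootstrap responder.
#'
#' @param object A `bmds` fit.
#' @param nsim Number of simulated participants.
#' @param seed Integer seed.
#' @param design A `triad_design` over the fitted words.
#' @param ... Unused.
#' @return A list of response data frames (length `nsim`).
#' @export
simulate.bmds <- function(object, nsim = 1, seed = NULL, design, ...) {
  stopifnot(inherits(design, "triad_design"))
  prof <- participant_profile(group = "posterior_mean",
                              delta = mean(object$delta), lapse = 0)
  lapply(seq_len(nsim), function(i) {
    simulate_triad_responses(object$posterior_mean, design, prof,
                             seed = if (is.null(seed)) NULL else
                               derive_seed(seed, i),
                             r = object$config$minkowski_r,
                             participant_id = sprintf("sim%03d", i))
  })
}

#' Per-trial deviance residuals of a triad fit
#'
#' `sqrt(-2 * log P(observed odd word))` at the posterior mean, signed
#' positive; large values mark trials poorly explained by the fitted space.
#'
#' @param object A `bmds` fit.
#' @param responses The response data frame the model was fitted to.
#' @param ... Unused.
#' @return Numeric vector, one value per triad trial.
#' @export
residuals.bmds <- function(object, responses, ...) {
  dat <- prepare_triad_data(responses, word_ids = object$word_ids)
  delta <- colMeans(object$delta)[dat$pid]
  ll <- .triad_loglik_cpp(object$posterior_mean, dat$idx, dat$odd, delta,
                          object$config$minkowski_r)
  sqrt(-2 * ll)
}

#' Plot a fitted semantic configuration
#'
#' Posterior-mean word locations (solid points) with the retained posterior
#' samples behind them (light points), one colour per word class when a word
#' set is supplied.
#'
#' @param x A `bmds` fit.
#' @param ws Optional `word_set` for class colouring.
#' @param show_samples Draw the posterior samples (default TRUE).
#' @param ... Passed to [plot()].
#' @export
plot.bmds <- function(x, ws = NULL, show_samples = TRUE, ...) {
  pm <- x$posterior_mean
  cols <- "black"
  if (!is.null(ws)) {
    pal <- c(abstract_positive = "#1b9e77", abstract_negative = "#d95f02",
             concrete_positive = "#7570b3", concrete_negative = "#e7298a")
    cols <- pal[ws$word_class[match(x$word_ids, ws$word_id)]]
  }
  S <- x$samples
  rng <- range(S, pm)
  plot(pm, type = "n", xlim = rng, ylim = rng,
       xlab = "dimension 1", ylab = "dimension 2", ...)
  if (show_samples) {
    for (i in seq_len(dim(S)[1])) {
      points(S[i, , ], col = grDevices::adjustcolor(cols, 0.15), pch = 16,
             cex = 0.4)
    }
  }
  points(pm, col = cols, pch = 16)
  text(pm, labels = x$word_ids, pos = 3, cex = 0.6, col = cols)
  invisible(x)
}
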