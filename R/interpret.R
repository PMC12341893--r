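#' Regress one latent dimension on the word norms
#'
#' Ordinary least squares with intercept: the per-word coordinate on one
#' dimension as outcome, the eight psycholinguistic predictors
#' (concreteness, valence, age of acquisition, arousal, dominance,
#' orthographic neighbourhood density, length, prevalence) as covariates.
#' Predictors are z-scored by default so coefficient magnitudes are
#' comparable across fits; coordinates are left in their sampled units.
#' Significance is judged two-tailed at |t| > 1.96 with no multiplicity
#' correction.
#'
#' @param coords_dim Numeric per-word coordinate (named by word id, or in
#'   `ws` row order).
#' @param ws A `word_set` data frame.
#' @param standardize Z-score the predictors (default TRUE).
#' @return A `regression_result` data frame: one row per predictor with
#'   `beta`, `se`, `t`, `p` plus the fit size `n` as an attribute.
#' @examples
#' ws <- synthesize_word_set(seed = 1)
#' y <- scale(ws$concreteness)[, 1]
#' regress_dimension(y, ws)
#' @export
regress_dimension <- function(coords_dim, ws, standardize = TRUE) {
  y <- align_outcome(coords_dim, ws)
  if (length(y) < 10) {
    stop("need at least 10 words for the dimension regression",
         call. = FALSE)
  }
  X <- predictor_matrix(ws, standardize)
  ols_result(X, y)
}

predictor_matrix <- function(ws, standardize = TRUE) {
  X <- as.matrix(ws[, PREDICTOR_FEATURES])
  if (standardize) {
    s <- apply(X, 2, sd)
    if (any(s == 0)) {
      stop("zero-variance predictor(s): ",
           paste(PREDICTOR_FEATURES[s == 0], collapse = ", "), call. = FALSE)
    }
    X <- scale(X)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(cbind(`(Intercept)` = 1, X), qr = qrX)
}

align_outcome <- function(y, ws) {
  if (!is.null(names(y))) {
    idx <- match(ws$word_id, names(y))
    if (anyNA(idx)) stop("coordinate names do not cover the word set",
                         call. = FALSE)
    y <- y[idx]
  }
  if (length(y) != nrow(ws)) {
    stop("coordinate length does not match the word set", call. = FALSE)
  }
  as.numeric(y)
}

ols_result <- function(X, y) {
  qrX <- attr(X, "qr") %||% qr(X)
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrX, y)
  res <- y - as.numeric(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(0, diag(XtXinv) * sigma2))
  tv <- ifelse(se > 0, beta / se,
               ifelse(beta == 0, 0, sign(beta) * Inf))
  pv <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  out <- data.frame(predictor = colnames(X), beta = beta, se = se, t = tv,
                    p = pv, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$predictor != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "df") <- df
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Dimension regressions over all retained posterior samples
#'
#' Repeats [regress_dimension()] for each of the retained (aligned) posterior
#' configurations and both dimensions, and summarizes, per dimension and
#' predictor, the distribution of t-values and the fraction of samples with
#' |t| > `t_crit` (1.96, i.e. p < 0.05 two-tailed). Requires an aligned fit:
#' regressing rotation-scattered raw samples would scramble the coefficient
#' patterns.
#'
#' @param fit An aligned `bmds` fit.
#' @param ws A `word_set`.
#' @param standardize Z-score predictors (default TRUE).
#' @param t_crit Significance cut on |t| (default 1.96).
#' @return A `sample_regression` data frame: `dimension`, `predictor`,
#'   `mean_t`, `frac_significant`, plus the full t matrix as attribute
#'   `t_values`.
#' @export
regress_posterior_samples <- function(fit, ws, standardize = TRUE,
                                      t_crit = 1.96) {
  stopifnot(inherits(fit, "bmds"))
  if (!isTRUE(fit$aligned)) {
    stop("posterior samples must be aligned before regression; ",
         "run align_samples() first", call. = FALSE)
  }
  X <- predictor_matrix(ws, standardize)
  ord <- match(fit$word_ids, ws$word_id)
  if (anyNA(ord)) stop("fit words not covered by the word set",
                       call. = FALSE)
  ns <- dim(fit$samples)[1]
  preds <- PREDICTOR_FEATURES
  tvals <- array(NA_real_, c(ns, 2, length(preds)),
                 dimnames = list(NULL, c("dim1", "dim2"), preds))
  Xo <- X[ord, , drop = FALSE]
  attr(Xo, "qr") <- qr(Xo)
  for (s in seq_len(ns)) {
    for (dm in 1:2) {
      rr <- ols_result(Xo, fit$samples[s, , dm])
      tvals[s, dm, ] <- rr$t[match(preds, rr$predictor)]
    }
  }
  out <- do.call(rbind, lapply(1:2, function(dm) {
    data.frame(dimension = paste0("dim", dm), predictor = preds,
               mean_t = apply(tvals[, dm, , drop = FALSE], 3, mean),
               frac_significant = apply(abs(tvals[, dm, , drop = FALSE]) >
                                          t_crit, 3, mean),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(out, "t_values") <- tvals
  class(out) <- c("sample_regression", "data.frame")
  out
}

#' Interpret the dimensions of a bmds fit
#'
#' Posterior-mean regressions for both dimensions plus the per-sample t-value
#' summary, in one report — the per-group (pooled) or per-patient dimension
#' interpretation.
#'
#' @param fit An aligned `bmds` fit.
#' @param ws A `word_set`.
#' @param standardize Z-score predictors (default TRUE).
#' @return List with `posterior_mean` (data frame over dimensions and
#'   predictors) and `samples` (a `sample_regression`).
#' @export
interpret_dimensions <- function(fit, ws, standardize = TRUE) {
  stopifnot(inherits(fit, "bmds"))
  ord <- match(fit$word_ids, ws$word_id)
  pm <- lapply(1:2, function(dm) {
    y <- fit$posterior_mean[, dm]
    names(y) <- fit$word_ids
    rr <- regress_dimension(y, ws, standardize)
    cbind(dimension = paste0("dim", dm), rr)
  })
  list(posterior_mean = do.call(rbind, pm),
       samples = regress_posterior_samples(fit, ws, standardize))
}

#' Fit and interpret a single participant's semantic space
#'
#' Runs a single-participant Bayesian MDS fit on that participant's triad
#' responses and reports the same dimension-interpretation schema as the
#' pooled group analysis.
#'
#' @param responses Long response data frame (one participant's rows are
#'   selected via `participant_id`).
#' @param participant_id The participant to fit.
#' @param ws A `word_set`.
#' @param config A [bmds_config()].
#' @param seed Integer seed.
#' @param reference Optional reference configuration for alignment.
#' @return List with the `fit` and the `interpretation` (see
#'   [interpret_dimensions()]).
#' @export
interpret_patient <- function(responses, participant_id, ws,
                              config = bmds_config(), seed = NULL,
                              reference = NULL) {
  rs <- responses[responses$participant_id == participant_id, , drop = FALSE]
  if (nrow(rs) == 0) stop("no responses for participant ", participant_id,
                          call. = FALSE)
  fit <- bmds(rs, config, seed = seed, word_ids = ws$word_id,
              align = if (is.null(reference)) "mean_template" else
                "reference",
              reference = reference)
  list(fit = fit, interpretation = interpret_dimensions(fit, ws))
}
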