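#' Build a relative scale from pairwise forced-choice responses
#'
#' Scores each word +1 for every trial where it was selected under the
#' positive-pole instruction ("concrete" / "positive"), -1 for every trial
#' where it was selected under the negative-pole instruction ("abstract" /
#' "negative"), 0 when not selected, and averages over the word's unique-pair
#' count (16 in the full design). A perfectly consistent extreme word attains
#' +1 or -1; a word selected in both presentations of every pair cancels to
#' 0.
#'
#' @param responses Long pair-response data frame (columns `task`,
#'   `word_left`, `word_right`, `instruction`, `choice`).
#' @param d The `pair_design` the responses follow.
#' @param task `"concreteness"` or `"valence"`.
#' @return A `relative_scale` data frame: `word_id`, `score` in \[-1, 1\],
#'   `n_pairs`.
#' @export
build_relative_scale <- function(responses, d,
                                 task = c("concreteness", "valence")) {
  task <- match.arg(task)
  stopifnot(inherits(d, "pair_design"))
  tk <- if (task == "concreteness") "pair_conc" else "pair_val"
  rs <- responses[responses$task %in% c(tk, task), , drop = FALSE]
  pos <- c(concreteness = "concrete", valence = "positive")[[task]]
  up <- d$unique_pairs
  n_pairs <- table(factor(c(up$word_a, up$word_b), levels = d$word_ids))
  expected <- 2L * nrow(up)
  if (nrow(rs) < expected) {
    warning("relative scale computed over ", nrow(rs), " of ", expected,
            " trials for the ", task, " task", call. = FALSE)
  }
  sgn <- ifelse(rs$instruction == pos, 1, -1)
  raw <- tapply(sgn, factor(rs$choice, levels = d$word_ids), sum)
  raw[is.na(raw)] <- 0
  out <- data.frame(word_id = d$word_ids,
                    task = task,
                    score = as.numeric(raw) / as.numeric(n_pairs),
                    n_pairs = as.integer(n_pairs),
                    stringsAsFactors = FALSE)
  class(out) <- c("relative_scale", "data.frame")
  out
}

#' Kendall agreement between a relative scale and the word norms
#'
#' Tie-corrected Kendall rank correlation (tau-b, asymptotic p) between the
#' per-word relative scores and the corresponding norm rating
#' (concreteness or valence): only the relative ordering of words matters.
#'
#' @param rs A `relative_scale`.
#' @param ws A `word_set`.
#' @return List with `tau` and `p` (`tau = NA` with a note for a constant
#'   scale).
#' @export
kendall_vs_ratings <- function(rs, ws) {
  stopifnot(nrow(rs) >= 3)
  rating <- ws[[rs$task[1]]][match(rs$word_id, ws$word_id)]
  if (sd(rs$score) == 0 || sd(rating) == 0) {
    return(list(tau = NA_real_, p = NA_real_,
                note = "undefined for a constant scale"))
  }
  kt <- suppressWarnings(cor.test(rs$score, rating, method = "kendall"))
  list(tau = unname(kt$estimate), p = unname(kt$p.value))
}

#' Crawford-Howell single-case t-test
#'
#' Compares one individual's score with a small normative control sample:
#' `t = (case - mean(controls)) / (sd(controls) * sqrt((n + 1) / n))` on
#' `n - 1` degrees of freedom, the standard modified t of the single-case
#' literature.
#'
#' @param case_value The patient's score.
#' @param control_values Numeric vector of control scores (n >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `single_case_result`: list with `t`, `df`, `p`, `case`,
#'   `control_mean`, `control_sd`, `n`, and `zero_sd` flag.
#' @examples
#' crawford_howell(10, rnorm(74, 12, 2))
#' @export
crawford_howell <- function(case_value, control_values,
                            alternative = c("two.sided", "less",
                                            "greater")) {
  alternative <- match.arg(alternative)
  n <- length(control_values)
  if (n < 2) stop("need at least 2 control values", call. = FALSE)
  m <- mean(control_values)
  s <- sd(control_values)
  zero_sd <- s == 0
  tv <- if (zero_sd) {
    if (case_value == m) 0 else sign(case_value - m) * Inf
  } else {
    (case_value - m) / (s * sqrt((n + 1) / n))
  }
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(abs(tv), df, lower.tail = FALSE),
              less = pt(tv, df),
              greater = pt(tv, df, lower.tail = FALSE))
  if (zero_sd) {
    warning("zero control SD: t reported as ",
            if (is.infinite(tv)) "infinite" else "0", call. = FALSE)
  }
  structure(list(t = tv, df = df, p = p, case = case_value,
                 control_mean = m, control_sd = s, n = n,
                 zero_sd = zero_sd, alternative = alternative),
            class = "single_case_result")
}

#' @export
print.single_case_result <- function(x, ...) {
  cat(sprintf("Crawford-Howell single-case test: t(%d) = %.3f, p = %.4g\n",
              x$df, x$t, x$p))
  cat(sprintf("  case %.3f vs controls %.3f (SD %.3f, n = %d)\n",
              x$case, x$control_mean, x$control_sd, x$n))
  invisible(x)
}

#' Map combined relative scales onto the rating configuration
#'
#' Forms the 2D response-derived configuration (valence score, concreteness
#' score per word), the 2D target from the ratings, centres the columns of
#' both and normalizes each configuration to unit total sum of squares, then
#' fits a Procrustes transformation (translation, rotation/reflection and
#' isotropic scaling) minimizing the sum of squared residuals. The
#' configuration-level normalization makes the error invariant to any
#' similarity transform of either input. Higher SS means a worse match with
#' the norm-based semantic plane.
#'
#' @param val_scale,conc_scale `relative_scale` objects over the same words.
#' @param ws A `word_set`.
#' @return A `procrustes_result`: list with `ss` (total error),
#'   `per_stimulus` (data frame of squared residuals), `rotation`, `scale`,
#'   `translation`.
#' @export
combine_and_procrustes <- function(val_scale, conc_scale, ws) {
  stopifnot(identical(val_scale$word_id, conc_scale$word_id))
  ord <- match(val_scale$word_id, ws$word_id)
  if (anyNA(ord)) stop("scales cover words outside the word set",
                       call. = FALSE)
  src <- cbind(valence = val_scale$score, concreteness = conc_scale$score)
  tgt <- cbind(valence = ws$valence[ord], concreteness = ws$concreteness[ord])
  src_n <- center_unit(src)
  tgt_n <- center_unit(tgt)
  if (any(!is.finite(src_n))) {
    stop("degenerate (constant) relative scales: Procrustes undefined",
         call. = FALSE)
  }
  pr <- vegan::procrustes(X = tgt_n, Y = src_n, scale = TRUE,
                          symmetric = FALSE)
  res2 <- rowSums((pr$Yrot - pr$X)^2)
  structure(list(
    ss = sum(res2),
    per_stimulus = data.frame(word_id = val_scale$word_id,
                              word_class = ws$word_class[ord],
                              squared_residual = res2,
                              stringsAsFactors = FALSE),
    rotation = pr$rotation,
    scale = pr$scale,
    translation = pr$translation
  ), class = "procrustes_result")
}

# centre the columns and scale the whole configuration to unit total SS
center_unit <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  ss <- sqrt(sum(x^2))
  if (ss == 0) x * NaN else x / ss
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat("Procrustes mapping onto the rating configuration: SS =",
      signif(x$ss, 4), "\n")
  worst <- x$per_stimulus[which.max(x$per_stimulus$squared_residual), ]
  cat("Largest stimulus-specific error:", worst$word_id,
      sprintf("(%.4f)\n", worst$squared_residual))
  invisible(x)
}

#' One-way ANOVA of stimulus-specific Procrustes errors over word classes
#'
#' Tests whether the per-stimulus squared residuals of a Procrustes mapping
#' differ between the four word classes.
#'
#' @param pr A `procrustes_result`.
#' @param ws Optional `word_set` (classes are taken from the result when
#'   omitted).
#' @return List with `F`, `p` and the per-class mean squared residuals.
#' @export
stimulus_error_anova <- function(pr, ws = NULL) {
  df <- pr$per_stimulus
  if (!is.null(ws)) {
    df$word_class <- ws$word_class[match(df$word_id, ws$word_id)]
  }
  counts <- table(df$word_class)
  if (any(counts < 2)) stop("need at least 2 stimuli per class",
                            call. = FALSE)
  cls <- factor(df$word_class)
  if (var(df$squared_residual) == 0) {
    return(list(F = 0, p = 1,
                class_means = tapply(df$squared_residual, cls, mean)))
  }
  a <- anova(lm(squared_residual ~ cls, data = df))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       class_means = tapply(df$squared_residual, cls, mean))
}
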