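#' Triad duplicate-trial consistency
#'
#' Proportion of flagged duplicate triads answered with the same odd word in
#' both presentations. Duplicates with a missing response in either
#' presentation are dropped from the denominator with a warning.
#'
#' @param responses One participant's triad responses (columns
#'   `trial_index`, `choice`).
#' @param d The `triad_design`.
#' @return A `consistency_result`: list with `task`, `n_eligible`,
#'   `n_consistent`, `proportion`.
#' @export
triad_consistency <- function(responses, d) {
  stopifnot(inherits(d, "triad_design"))
  dup <- d$trials[d$trials$is_repeat, , drop = FALSE]
  if (nrow(dup) == 0) stop("design contains no duplicate trials",
                           call. = FALSE)
  ch <- setNames(responses$choice, responses$trial_index)
  a <- ch[as.character(dup$trial_index)]
  b <- ch[as.character(dup$repeat_of)]
  ok <- !is.na(a) & !is.na(b)
  if (any(!ok)) {
    warning(sum(!ok), " duplicate trial(s) without both responses excluded",
            call. = FALSE)
  }
  n_elig <- sum(ok)
  n_cons <- sum(a[ok] == b[ok])
  structure(list(task = "triad", n_eligible = n_elig,
                 n_consistent = n_cons,
                 proportion = if (n_elig > 0) n_cons / n_elig else
                   NA_real_),
            class = "consistency_result")
}

#' Pairwise opposite-instruction consistency
#'
#' Every unique pair is presented twice per task with opposite instructions;
#' a pair is consistent when the word selected under the positive-pole
#' instruction differs from the word selected under the negative-pole
#' instruction (picking the same word as both "most concrete" and "most
#' abstract" is inconsistent).
#'
#' @param responses One participant's pair responses.
#' @param d The `pair_design`.
#' @param task `"concreteness"` or `"valence"`.
#' @return A `consistency_result`.
#' @export
pair_consistency <- function(responses, d,
                             task = c("concreteness", "valence")) {
  task <- match.arg(task)
  stopifnot(inherits(d, "pair_design"))
  tk <- if (task == "concreteness") "pair_conc" else "pair_val"
  rs <- responses[responses$task %in% c(tk, task), , drop = FALSE]
  key <- paste(pmin(rs$word_left, rs$word_right),
               pmax(rs$word_left, rs$word_right))
  pos <- c(concreteness = "concrete", valence = "positive")[[task]]
  split_ch <- split(data.frame(choice = rs$choice,
                               positive_pole = rs$instruction == pos,
                               stringsAsFactors = FALSE), key)
  complete <- vapply(split_ch, function(g) {
    nrow(g) == 2 && sum(g$positive_pole) == 1
  }, logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " pair(s) without both instruction trials ",
            "excluded", call. = FALSE)
  }
  cons <- vapply(split_ch[complete], function(g) {
    g$choice[g$positive_pole] != g$choice[!g$positive_pole]
  }, logical(1))
  structure(list(task = task, n_eligible = sum(complete),
                 n_consistent = sum(cons),
                 proportion = if (any(complete)) mean(cons) else NA_real_),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("%s consistency: %d / %d = %.3f\n", x$task, x$n_consistent,
              x$n_eligible, x$proportion))
  invisible(x)
}

#' Consistency table for a whole cohort
#'
#' @param responses Long cohort response data frame.
#' @param triad_design,pair_design The study designs.
#' @return Data frame: `participant_id`, `task`, `n_eligible`,
#'   `n_consistent`, `proportion`.
#' @export
cohort_consistency <- function(responses, triad_design, pair_design) {
  ids <- unique(responses$participant_id)
  rows <- list()
  for (id in ids) {
    rs <- responses[responses$participant_id == id, , drop = FALSE]
    for (res in list(triad_consistency(rs[rs$task == "triad", ],
                                       triad_design),
                     pair_consistency(rs, pair_design, "concreteness"),
                     pair_consistency(rs, pair_design, "valence"))) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = id, task = res$task, n_eligible = res$n_eligible,
        n_consistent = res$n_consistent, proportion = res$proportion,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
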