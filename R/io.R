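# CSV/JSON schemas for every artefact the package produces. Readers check
# required columns and name the missing ones; writers emit plain UTF-8 CSV.

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read and write package artefacts as CSV
#'
#' Plain-text serializers with round-trip identity: writing an object and
#' reading the file back reproduces it. Word-norm CSVs carry `word_id`, the
#' nine norms and `word_class`; triad-design CSVs `trial_index`,
#' `word1`..`word3`, `is_repeat`, `repeat_of`; pair-design CSVs the trial
#' table (`task`, `trial_index`, `block`, `word_left`, `word_right`,
#' `instruction`, `pair_type`); response CSVs the long response format; and
#' posterior CSVs one row per sample x word (`sample_index`, `word_id`,
#' `dim1`, `dim2`).
#'
#' @param ws,d,responses,fit Objects to serialize.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return the path
#'   invisibly.
#' @name semspace-io
NULL

#' @rdname semspace-io
#' @export
write_word_set <- function(ws, path) {
  write.csv(as.data.frame(ws), path, row.names = FALSE)
  invisible(path)
}

#' @rdname semspace-io
#' @export
read_word_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("word_id", NORM_FEATURES, "word_class"),
                "word norms CSV")
  if (anyDuplicated(df$word_id)) {
    stop("word norms CSV: duplicated word_id", call. = FALSE)
  }
  class(df) <- c("word_set", "data.frame")
  df
}

#' @rdname semspace-io
#' @export
write_triad_design <- function(d, path) {
  write.csv(d$trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname semspace-io
#' @export
read_triad_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("trial_index", "word1", "word2", "word3", "is_repeat",
                      "repeat_of"), "triad design CSV")
  word_ids <- sort(unique(c(df$word1, df$word2, df$word3)))
  structure(list(trials = df, word_ids = word_ids,
                 n_words = length(word_ids)),
            class = "triad_design")
}

#' @rdname semspace-io
#' @export
write_pair_design <- function(d, path) {
  write.csv(d$trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname semspace-io
#' @export
read_pair_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("task", "trial_index", "block", "word_left",
                      "word_right", "instruction", "pair_type"),
                "pair design CSV")
  one <- df[df$task == df$task[1], , drop = FALSE]
  key <- paste(pmin(one$word_left, one$word_right),
               pmax(one$word_left, one$word_right))
  first <- !duplicated(key)
  up <- data.frame(word_a = pmin(one$word_left, one$word_right)[first],
                   word_b = pmax(one$word_left, one$word_right)[first],
                   pair_type = one$pair_type[first],
                   stringsAsFactors = FALSE)
  word_ids <- sort(unique(c(df$word_left, df$word_right)))
  structure(list(unique_pairs = up, trials = df, word_ids = word_ids),
            class = "pair_design")
}

#' @rdname semspace-io
#' @export
write_responses <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname semspace-io
#' @export
read_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "task", "trial_index", "choice"),
                "responses CSV")
  df
}

#' @rdname semspace-io
#' @export
write_posterior <- function(fit, path) {
  ns <- dim(fit$samples)[1]
  df <- do.call(rbind, lapply(seq_len(ns), function(i) {
    data.frame(sample_index = i, word_id = fit$word_ids,
               dim1 = fit$samples[i, , 1], dim2 = fit$samples[i, , 2],
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname semspace-io
#' @export
read_posterior <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_index", "word_id", "dim1", "dim2"),
                "posterior CSV")
  df
}

#' @rdname semspace-io
#' @export
write_delta_draws <- function(fit, path) {
  ns <- dim(fit$samples)[1]
  df <- do.call(rbind, lapply(seq_len(ns), function(i) {
    data.frame(sample_index = i, participant_id = fit$participant_ids,
               delta = fit$delta[i, ], stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
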