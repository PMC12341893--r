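#' Word-norm features used throughout the package
#'
#' The nine psycholinguistic norms carried by a word set, and the eight of
#' them used as regression predictors when interpreting latent dimensions
#' (log10 frequency serves only as an inclusion filter and matching variable).
#'
#' @format Character vectors of column names.
#' @name norm_features
#' @export
NORM_FEATURES <- c("concreteness", "valence", "arousal", "dominance", "aoa",
                   "log10_frequency", "orth_nd", "length", "prevalence")

#' @rdname norm_features
#' @export
PREDICTOR_FEATURES <- c("concreteness", "valence", "aoa", "arousal",
                        "dominance", "orth_nd", "length", "prevalence")

#' @rdname norm_features
#' @export
WORD_CLASSES <- c("abstract_positive", "abstract_negative",
                  "concrete_positive", "concrete_negative")

#' Classify a word into a concreteness x valence quadrant
#'
#' Applies the stimulus inclusion rules: words with concreteness in
#' \[1.5, 2.5\] are abstract and in \[4, 5\] concrete (1-5 scale); words with
#' valence in \[2, 4) are negative and in (4, 6\] positive (1-7 scale).
#' Mid-scale concreteness, out-of-range valence (including the ambiguous
#' boundary value 4), log10 frequency below 1 and prevalence below 0.98 lead
#' to exclusion.
#'
#' @param concreteness,valence,log10_frequency,prevalence Numeric ratings for
#'   one word (vectors are accepted and classified elementwise).
#' @return A character vector with one of `"abstract_positive"`,
#'   `"abstract_negative"`, `"concrete_positive"`, `"concrete_negative"`, or
#'   an exclusion code `"excluded:mid_concreteness"`,
#'   `"excluded:out_of_range_valence"`, `"excluded:low_frequency"`,
#'   `"excluded:low_prevalence"`.
#' @examples
#' classify_word(2.0, 5.0, 2.9, 0.99)  # "abstract_positive"
#' classify_word(3.2, 5.0, 2.9, 0.99)  # excluded: mid-scale concreteness
#' @export
classify_word <- function(concreteness, valence, log10_frequency, prevalence) {
  n <- max(length(concreteness), length(valence), length(log10_frequency),
           length(prevalence))
  concreteness <- rep_len(concreteness, n)
  valence <- rep_len(valence, n)
  log10_frequency <- rep_len(log10_frequency, n)
  prevalence <- rep_len(prevalence, n)
  if (anyNA(concreteness) || anyNA(valence) || anyNA(log10_frequency) ||
      anyNA(prevalence)) {
    stop("classify_word: missing or NaN rating values", call. = FALSE)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    if (log10_frequency[i] < 1) {
      out[i] <- "excluded:low_frequency"
    } else if (prevalence[i] < 0.98) {
      out[i] <- "excluded:low_prevalence"
    } else if (concreteness[i] >= 1.5 && concreteness[i] <= 2.5) {
      out[i] <- paste0("abstract_", valence_pole(valence[i]))
    } else if (concreteness[i] >= 4 && concreteness[i] <= 5) {
      out[i] <- paste0("concrete_", valence_pole(valence[i]))
    } else {
      out[i] <- "excluded:mid_concreteness"
    }
    if (endsWith(out[i], "_none")) out[i] <- "excluded:out_of_range_valence"
  }
  out
}

# valence 4.0 sits on the boundary of both printed intervals; treated as
# neither pole (excluded)
valence_pole <- function(v) {
  if (v >= 2 && v < 4) "negative" else if (v > 4 && v <= 6) "positive"
  else "none"
}

#' Default generator configuration for the synthetic 32-word set
#'
#' Class means and standard deviations of the manipulated features
#' (concreteness, valence) per quadrant, and pooled means/SDs of the nuisance
#' features, reproducing the class statistics of a well-matched quadrant
#' stimulus set.
#' Nuisance features are sampled identically across classes so that they are
#' matched by construction.
#'
#' @return A list with elements `manipulated` (per-class mean/sd for
#'   concreteness and valence) and `nuisance` (pooled mean/sd per feature).
#' @export
word_set_config <- function() {
  list(
    manipulated = list(
      concreteness = list(
        abstract_positive = c(mean = 2.04, sd = 0.3),
        abstract_negative = c(mean = 2.03, sd = 0.3),
        concrete_positive = c(mean = 4.4, sd = 0.3),
        concrete_negative = c(mean = 4.4, sd = 0.3)
      ),
      valence = list(
        abstract_positive = c(mean = 5.2, sd = 0.4),
        abstract_negative = c(mean = 2.6, sd = 0.4),
        concrete_positive = c(mean = 5.3, sd = 0.4),
        concrete_negative = c(mean = 2.8, sd = 0.4)
      )
    ),
    nuisance = list(
      aoa = c(mean = 8.3, sd = 1.5),
      arousal = c(mean = 4.5, sd = 0.7),
      dominance = c(mean = 4.4, sd = 0.6),
      orth_nd = c(mean = 2.4, sd = 2.5),
      length = c(mean = 6.9, sd = 1.6),
      log10_frequency = c(mean = 2.5, sd = 0.6),
      prevalence = c(mean = 0.99, sd = 0.01)
    )
  )
}

#' Generate a synthetic word set with the four-quadrant class structure
#'
#' Draws `per_class` words per quadrant. Concreteness and valence are sampled
#' from per-class normal distributions and redrawn until the word passes
#' [classify_word()] for its intended class; nuisance features come from
#' class-independent truncated normals so classes are matched on them.
#' Orthographic neighbourhood density and length are rounded to nonnegative
#' integers; prevalence is clamped to \[0.98, 1\] and log10 frequency to at
#' least 1 so every generated word passes the inclusion filters.
#'
#' @param per_class Words per quadrant class (default 8, giving 32 words).
#' @param config Feature configuration, see [word_set_config()].
#' @param seed Integer seed; the same seed and config reproduce the set.
#' @param max_tries Resampling budget per word before a configuration error.
#' @return A `word_set` data frame with columns `word_id`, the nine norms and
#'   `word_class`.
#' @examples
#' ws <- synthesize_word_set(seed = 1)
#' table(ws$word_class)
#' @export
synthesize_word_set <- function(per_class = 8, config = word_set_config(),
                                seed = NULL, max_tries = 1000) {
  with_seed(seed, {
    rows <- vector("list", 4 * per_class)
    k <- 0
    for (cl in WORD_CLASSES) {
      for (i in seq_len(per_class)) {
        k <- k + 1
        rows[[k]] <- draw_word(cl, config, max_tries)
      }
    }
    ws <- do.call(rbind, rows)
    ws$word_id <- sprintf("w%02d", seq_len(nrow(ws)))
    ws <- ws[, c("word_id", NORM_FEATURES, "word_class")]
    class(ws) <- c("word_set", "data.frame")
    ws
  })
}

draw_word <- function(cl, config, max_tries) {
  man <- config$manipulated
  nui <- config$nuisance
  for (try in seq_len(max_tries)) {
    conc <- rnorm(1, man$concreteness[[cl]]["mean"],
                  man$concreteness[[cl]]["sd"])
    val <- rnorm(1, man$valence[[cl]]["mean"], man$valence[[cl]]["sd"])
    freq <- max(1, rnorm(1, nui$log10_frequency["mean"],
                         nui$log10_frequency["sd"]))
    prev <- min(1, max(0.98, rnorm(1, nui$prevalence["mean"],
                                   nui$prevalence["sd"])))
    if (identical(classify_word(conc, val, freq, prev), cl)) {
      return(data.frame(
        word_id = NA_character_,
        concreteness = conc,
        valence = val,
        arousal = trunc_norm(nui$arousal, 1, 7),
        dominance = trunc_norm(nui$dominance, 1, 7),
        aoa = trunc_norm(nui$aoa, 0, Inf),
        log10_frequency = freq,
        orth_nd = round(trunc_norm(nui$orth_nd, 0, Inf)),
        length = max(1, round(trunc_norm(nui$length, 1, Inf))),
        prevalence = prev,
        word_class = cl,
        stringsAsFactors = FALSE
      ))
    }
  }
  stop("synthesize_word_set: could not draw a valid '", cl,
       "' word in ", max_tries, " tries; check the configuration",
       call. = FALSE)
}

trunc_norm <- function(ms, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, ms["mean"], ms["sd"])
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, ms["mean"]))
}

#' Check class matching of a word set
#'
#' Per feature: class means and SDs plus a one-way ANOVA across the four
#' classes. Manipulated features (concreteness, valence) are expected to
#' differ (small p); nuisance features to be matched.
#'
#' @param ws A `word_set` data frame.
#' @param alpha Flagging threshold for the ANOVA p-value (default 0.05).
#' @return A data frame with one row per feature: class means/SDs, `F`, `p`
#'   and a logical `differs` flag.
#' @export
check_matching <- function(ws, alpha = 0.05) {
  stopifnot(is.data.frame(ws))
  counts <- table(ws$word_class)
  if (any(counts < 2)) {
    stop("check_matching: every class needs at least 2 words", call. = FALSE)
  }
  cls <- factor(ws$word_class, levels = WORD_CLASSES)
  out <- lapply(NORM_FEATURES, function(f) {
    x <- ws[[f]]
    m <- tapply(x, cls, mean)
    s <- tapply(x, cls, sd)
    if (var(x) == 0) {
      Fv <- 0; p <- 1
    } else {
      a <- anova(lm(x ~ cls))
      Fv <- a[["F value"]][1]; p <- a[["Pr(>F)"]][1]
      if (is.na(Fv)) { Fv <- 0; p <- 1 }
    }
    data.frame(feature = f,
               mean_abstract_positive = m[["abstract_positive"]],
               mean_abstract_negative = m[["abstract_negative"]],
               mean_concrete_positive = m[["concrete_positive"]],
               mean_concrete_negative = m[["concrete_negative"]],
               sd_abstract_positive = s[["abstract_positive"]],
               sd_abstract_negative = s[["abstract_negative"]],
               sd_concrete_positive = s[["concrete_positive"]],
               sd_concrete_negative = s[["concrete_negative"]],
               F = Fv, p = p, differs = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.word_set <- function(x, ...) {
  cat("Word set:", nrow(x), "words,",
      length(unique(x$word_class)), "classes\n")
  print(table(x$word_class))
  invisible(x)
}
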