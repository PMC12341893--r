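#' Build a balanced triad (odd-one-out) design
#'
#' Selects a subset of word triples under the study's balance constraints:
#' `n_trials` presented trials of which `n_duplicates` are exact repeats of
#' earlier triads (for response-consistency checks), every word presented the
#' same number of times across presented trials (3 * n_trials / n_words), and
#' no unordered word pair contained in more than `pair_cap` distinct triads.
#' Construction proceeds in stages: random balanced sampling favouring word
#' pairs not yet used, a hill-climbing pass replacing triads that contain
#' pairs occurring in only one triad, and a final selection of duplicates that
#' exactly restores per-word balance.
#'
#' @param ws A `word_set` data frame or a character vector of word ids.
#' @param n_trials Total presented trials (default 192).
#' @param n_duplicates Number of presented trials that repeat an earlier triad
#'   (default 24).
#' @param pair_cap Maximum number of distinct triads containing any pair
#'   (default 6).
#' @param opt_iter Iteration budget of the singleton-pair replacement pass.
#' @param seed Integer seed for reproducibility.
#' @param max_restarts Rebuild attempts before giving up.
#' @return A `triad_design` object: list with `trials` (data frame
#'   `trial_index`, `word1`, `word2`, `word3`, `is_repeat`, `repeat_of`),
#'   `word_ids` and `n_words`.
#' @examples
#' ws <- synthesize_word_set(seed = 1)
#' d <- build_triad_design(ws, seed = 2)
#' design_stats(d)$word_counts
#' @export
build_triad_design <- function(ws, n_trials = 192, n_duplicates = 24,
                               pair_cap = 6, opt_iter = 10000, seed = NULL,
                               max_restarts = 50) {
  word_ids <- if (is.data.frame(ws)) ws$word_id else as.character(ws)
  W <- length(word_ids)
  if (W < 4) stop("triad design needs at least 4 words", call. = FALSE)
  if (n_duplicates < 0 || n_duplicates >= n_trials) {
    stop("invalid duplicate count", call. = FALSE)
  }
  if ((3 * n_trials) %% W != 0) {
    stop("infeasible config: 3 * n_trials must be divisible by the number ",
         "of words for exact per-word balance", call. = FALSE)
  }
  target <- 3L * n_trials / W          # presentations per word
  n_unique <- n_trials - n_duplicates
  if (n_unique > choose(W, 3)) {
    stop("infeasible config: more unique triads than exist", call. = FALSE)
  }
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      res <- try_build_triads(W, n_unique, n_duplicates, target, pair_cap,
                              opt_iter)
      if (!is.null(res)) {
        trials <- data.frame(
          trial_index = seq_len(n_trials),
          word1 = word_ids[res$triads[, 1]],
          word2 = word_ids[res$triads[, 2]],
          word3 = word_ids[res$triads[, 3]],
          is_repeat = res$is_repeat,
          repeat_of = res$repeat_of,
          stringsAsFactors = FALSE
        )
        out <- structure(list(trials = trials, word_ids = word_ids,
                              n_words = W),
                         class = "triad_design")
        return(out)
      }
    }
    stop("triad design construction failed after ", max_restarts,
         " restarts; relax the constraints", call. = FALSE)
  })
}

# deficit allocation: how many duplicate appearances each word needs
alloc_deficits <- function(W, n_dup) {
  tot <- 3L * n_dup
  base <- tot %/% W
  extra <- tot %% W
  d <- rep(base, W)
  if (extra > 0) d[sample.int(W, extra)] <- base + 1L
  d
}

try_build_triads <- function(W, n_unique, n_dup, target, pair_cap, opt_iter) {
  d <- alloc_deficits(W, n_dup)
  quota <- target - d                      # unique-stage per-word counts
  if (any(quota < 0) || sum(quota) != 3 * n_unique) return(NULL)
  cnt <- integer(W)
  pm <- matrix(0L, W, W)                   # pair multiplicity, both triangles
  seen <- new.env(hash = TRUE, parent = emptyenv())
  triads <- matrix(0L, n_unique, 3)

  tkey <- function(tr) {
    tr <- sort.int(tr)
    as.character(((tr[1] - 1) * W + tr[2] - 1) * W + tr[3])
  }
  add_triad <- function(tr, sign) {
    i <- tr[1]; j <- tr[2]; k <- tr[3]
    pm[i, j] <<- pm[j, i] <<- pm[i, j] + sign
    pm[i, k] <<- pm[k, i] <<- pm[i, k] + sign
    pm[j, k] <<- pm[k, j] <<- pm[j, k] + sign
    cnt[tr] <<- cnt[tr] + sign
    if (sign > 0) seen[[tkey(tr)]] <- TRUE else rm(list = tkey(tr),
                                                   envir = seen)
  }
  pair_ok <- function(tr) {
    pm[tr[1], tr[2]] < pair_cap && pm[tr[1], tr[3]] < pair_cap &&
      pm[tr[2], tr[3]] < pair_cap
  }
  is_new <- function(tr) is.null(seen[[tkey(tr)]])

  sample_triad <- function() {
    rem <- quota - cnt
    elig <- which(rem > 0)
    if (length(elig) < 3) return(NULL)
    best <- NULL; best_new <- -1L
    for (try in 1:40) {
      w <- rem[elig] + 0.01
      tr <- elig[sample.int(length(elig), 3, prob = w)]
      if (!is_new(tr) || !pair_ok(tr)) next
      nnew <- (pm[tr[1], tr[2]] == 0L) + (pm[tr[1], tr[3]] == 0L) +
        (pm[tr[2], tr[3]] == 0L)
      if (nnew > best_new) { best <- tr; best_new <- nnew }
      if (best_new == 3L) break
    }
    best
  }

  for (t in seq_len(n_unique)) {
    tr <- sample_triad()
    if (is.null(tr)) return(NULL)
    triads[t, ] <- sort.int(tr)
    add_triad(tr, 1L)
  }
  if (!all(cnt == quota)) return(NULL)

  # replacement pass: swap words between two triads (preserving per-word
  # counts) to reduce the number of pairs occurring in exactly one triad
  ut <- upper.tri(pm)
  n_singleton <- function() sum(pm[ut] == 1L)
  cur <- n_singleton()
  stall <- 0L
  for (it in seq_len(opt_iter)) {
    if (cur == 0 || stall >= 300L) break
    stall <- stall + 1L
    singles <- which(ut & pm == 1L, arr.ind = TRUE)
    sp <- singles[sample.int(nrow(singles), 1), ]
    lo <- sp[1]; hi <- sp[2]
    row <- which(rowSums(triads == lo | triads == hi) == 2L)[1]
    old <- triads[row, ]
    keep <- old[old != lo & old != hi]
    # candidate third word z, and a companion triad containing z but not
    # keep in which z is swapped back to keep
    z_cand <- shuffle(setdiff(seq_len(W), old))
    z_cand <- z_cand[seq_len(min(10L, length(z_cand)))]
    done <- FALSE
    for (z in z_cand) {
      repl <- c(lo, hi, z)
      comp_rows <- which(rowSums(triads == z) == 1L &
                           rowSums(triads == keep) == 0L &
                           rowSums(triads == lo) + rowSums(triads == hi) <
                           2L)
      comp_rows <- setdiff(comp_rows, row)
      if (length(comp_rows) == 0) next
      for (comp in shuffle(comp_rows)[seq_len(min(3L, length(comp_rows)))]) {
        old2 <- triads[comp, ]
        new2 <- old2
        new2[new2 == z] <- keep
        add_triad(old, -1L); add_triad(old2, -1L)
        if (is_new(repl) && is_new(new2) && pair_ok(repl) &&
              pair_ok(new2)) {
          add_triad(repl, 1L); add_triad(new2, 1L)
          nxt <- n_singleton()
          if (nxt < cur) {
            triads[row, ] <- sort.int(repl)
            triads[comp, ] <- sort.int(new2)
            cur <- nxt
            stall <- 0L
            done <- TRUE
          } else {
            add_triad(repl, -1L); add_triad(new2, -1L)
            add_triad(old, 1L); add_triad(old2, 1L)
          }
        } else {
          add_triad(old, 1L); add_triad(old2, 1L)
        }
        if (done) break
      }
      if (done) break
    }
  }

  # duplicate selection: 'd' appearances per word, each duplicate an existing
  # unique triad repeated once
  dup_rows <- select_duplicates(triads, d, n_dup)
  if (is.null(dup_rows)) return(NULL)

  all_triads <- rbind(triads, triads[dup_rows, , drop = FALSE])
  list(triads = all_triads,
       is_repeat = c(rep(FALSE, n_unique), rep(TRUE, n_dup)),
       repeat_of = c(rep(NA_integer_, n_unique), as.integer(dup_rows)))
}

select_duplicates <- function(triads, d, n_dup) {
  if (n_dup == 0) return(integer(0))
  n_unique <- nrow(triads)
  for (rs in 1:400) {
    rem <- d
    chosen <- integer(0)
    ok <- TRUE
    for (s in seq_len(n_dup)) {
      score <- rem[triads[, 1]] + rem[triads[, 2]] + rem[triads[, 3]]
      feas <- rem[triads[, 1]] > 0 & rem[triads[, 2]] > 0 &
        rem[triads[, 3]] > 0
      feas[chosen] <- FALSE
      if (!any(feas)) { ok <- FALSE; break }
      cand <- which(feas & score == max(score[feas]))
      pick <- cand[sample.int(length(cand), 1)]
      chosen <- c(chosen, pick)
      rem[triads[pick, ]] <- rem[triads[pick, ]] - 1L
    }
    if (ok && all(rem == 0)) return(chosen)
  }
  NULL
}

#' @export
print.triad_design <- function(x, ...) {
  st <- design_stats(x)
  cat("Triad design:", nrow(x$trials), "presented trials (",
      sum(x$trials$is_repeat), "duplicates ) over", x$n_words, "words\n")
  cat("Per-word presentations:", paste(range(st$word_counts), collapse = "-"),
      "| max pair multiplicity:", max(st$pair_mult$multiplicity),
      "| singleton pairs:", st$n_singleton_pairs, "\n")
  invisible(x)
}
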