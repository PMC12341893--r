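#' Build the pairwise-judgement design
#'
#' Selects unique word pairs stratified by quadrant relation — pairs sharing
#' both dimensions (same quadrant), sharing exactly one of valence /
#' concreteness, or sharing neither — such that every word occurs in the same
#' number of unique pairs. With 8 words per class this yields the canonical
#' composition 64 same-quadrant + 128 share-one + 64 share-none = 256 pairs,
#' 16 per word. Each unique pair is then presented twice per task with
#' opposite instructions ("concrete"/"abstract" for the concreteness task,
#' "positive"/"negative" for the valence task), distributed over blocks that
#' never contain the same pair twice and never show a word more than
#' `word_block_cap` times.
#'
#' @param ws A `word_set` data frame (equal class sizes required).
#' @param n_blocks Blocks per task (default 16).
#' @param word_block_cap Maximum occurrences of a word within a block
#'   (default 5).
#' @param seed Integer seed.
#' @param max_restarts Retry budget for the block assignment search.
#' @return A `pair_design` object: list with `unique_pairs` (data frame
#'   `word_a`, `word_b`, `pair_type`), `trials` (data frame `task`,
#'   `trial_index`, `block`, `word_left`, `word_right`, `instruction`,
#'   `pair_type`) and `word_ids`.
#' @examples
#' ws <- synthesize_word_set(seed = 1)
#' d <- build_pair_design(ws, seed = 2)
#' nrow(d$unique_pairs)  # 256
#' @export
build_pair_design <- function(ws, n_blocks = 16, word_block_cap = 5,
                              seed = NULL, max_restarts = 200) {
  stopifnot(is.data.frame(ws))
  cls <- split(ws$word_id, ws$word_class)
  if (length(cls) != 4 || length(unique(lengths(cls))) != 1) {
    stop("pair design needs four equally sized word classes", call. = FALSE)
  }
  m <- lengths(cls)[[1]]
  with_seed(seed, {
    up <- build_unique_pairs(cls, m)
    if ((2L * nrow(up)) %% n_blocks != 0) {
      stop("infeasible config: trials per task (", 2L * nrow(up),
           ") not divisible by n_blocks", call. = FALSE)
    }
    trials <- rbind(
      assign_blocks(up, task = "concreteness",
                    instructions = c("concrete", "abstract"),
                    n_blocks, word_block_cap, max_restarts),
      assign_blocks(up, task = "valence",
                    instructions = c("positive", "negative"),
                    n_blocks, word_block_cap, max_restarts)
    )
    structure(list(unique_pairs = up, trials = trials, word_ids = ws$word_id),
              class = "pair_design")
  })
}

quadrant_relation <- function(class_a, class_b) {
  if (class_a == class_b) return("same_quadrant")
  a <- strsplit(class_a, "_")[[1]]
  b <- strsplit(class_b, "_")[[1]]
  if (a[1] == b[1] || a[2] == b[2]) "share_one_dimension" else "share_none"
}

build_unique_pairs <- function(cls, m) {
  qs <- names(cls)
  rows <- list()
  d_within <- min(4L, m - 1L)
  if ((m * d_within) %% 2L == 1L) d_within <- d_within - 1L
  d_between <- min(4L, m)
  for (q in qs) {
    e <- regular_graph_edges(m, d_within)
    if (nrow(e) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        word_a = cls[[q]][e[, 1]], word_b = cls[[q]][e[, 2]],
        pair_type = "same_quadrant", stringsAsFactors = FALSE)
    }
  }
  combos <- list(
    c("abstract_positive", "abstract_negative"),
    c("concrete_positive", "concrete_negative"),
    c("abstract_positive", "concrete_positive"),
    c("abstract_negative", "concrete_negative"),
    c("abstract_positive", "concrete_negative"),
    c("abstract_negative", "concrete_positive")
  )
  for (cb in combos) {
    e <- bipartite_regular_edges(m, d_between)
    rows[[length(rows) + 1]] <- data.frame(
      word_a = cls[[cb[1]]][e[, 1]], word_b = cls[[cb[2]]][e[, 2]],
      pair_type = quadrant_relation(cb[1], cb[2]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# random d-regular simple graph on n vertices (configuration model + retries)
regular_graph_edges <- function(n, d) {
  if (d <= 0) return(matrix(integer(0), 0, 2))
  if (d == n - 1) {
    e <- t(utils::combn(n, 2))
    return(e)
  }
  for (rs in 1:500) {
    stubs <- sample(rep(seq_len(n), each = d))
    e <- matrix(stubs, ncol = 2, byrow = TRUE)
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    if (any(lo == hi)) next
    if (anyDuplicated(paste(lo, hi))) next
    return(cbind(lo, hi))
  }
  stop("could not build a ", d, "-regular graph on ", n, " vertices",
       call. = FALSE)
}

# random d-regular bipartite graph: d disjoint perfect matchings built as a
# random d x n Latin rectangle (each row a permutation avoiding the columns
# of earlier rows)
bipartite_regular_edges <- function(n, d) {
  rect <- matrix(0L, d, n)
  for (row in seq_len(d)) {
    placed <- FALSE
    for (rs in 1:10000) {
      p <- sample.int(n)
      if (row == 1 ||
            all(colSums(rect[seq_len(row - 1), , drop = FALSE] ==
                          rep(p, each = row - 1)) == 0)) {
        rect[row, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not build a ", d, "-regular bipartite graph",
           call. = FALSE)
    }
  }
  do.call(rbind, lapply(seq_len(d), function(i) cbind(seq_len(n), rect[i, ])))
}

assign_blocks <- function(up, task, instructions, n_blocks, cap,
                          max_restarts) {
  n_pairs <- nrow(up)
  n_trials <- 2L * n_pairs
  block_size <- n_trials %/% n_blocks
  trial_pairs <- rep(seq_len(n_pairs), 2L)
  trial_instr <- rep(instructions, each = n_pairs)
  for (rs in seq_len(max_restarts)) {
    ord <- sample.int(n_trials)
    block_of <- integer(n_trials)
    bsize <- integer(n_blocks)
    wload <- matrix(0L, n_blocks, length(unique(c(up$word_a, up$word_b))),
                    dimnames = list(NULL, unique(c(up$word_a, up$word_b))))
    pair_in_block <- matrix(FALSE, n_blocks, n_pairs)
    ok <- TRUE
    for (t in ord) {
      p <- trial_pairs[t]
      wa <- up$word_a[p]; wb <- up$word_b[p]
      feas <- which(bsize < block_size & !pair_in_block[, p] &
                      wload[, wa] < cap & wload[, wb] < cap)
      if (length(feas) == 0) { ok <- FALSE; break }
      # fill the emptiest feasible block to keep the end-game unconstrained
      b <- feas[which.min(bsize[feas])]
      block_of[t] <- b
      bsize[b] <- bsize[b] + 1L
      wload[b, wa] <- wload[b, wa] + 1L
      wload[b, wb] <- wload[b, wb] + 1L
      pair_in_block[b, p] <- TRUE
    }
    if (!ok) next
    ordr <- order(block_of, sample.int(n_trials))
    flip <- runif(n_trials) < 0.5
    left <- ifelse(flip, up$word_a[trial_pairs], up$word_b[trial_pairs])
    right <- ifelse(flip, up$word_b[trial_pairs], up$word_a[trial_pairs])
    df <- data.frame(
      task = task,
      trial_index = seq_len(n_trials),
      block = block_of[ordr],
      word_left = left[ordr],
      word_right = right[ordr],
      instruction = trial_instr[ordr],
      pair_type = up$pair_type[trial_pairs[ordr]],
      stringsAsFactors = FALSE
    )
    return(df)
  }
  stop("block assignment failed: could not satisfy the no-repeat-pair and ",
       "per-word block-load constraints in ", max_restarts, " restarts",
       call. = FALSE)
}

#' Summary statistics and constraint checks for a design
#'
#' Recomputes the counts a valid design must satisfy: per-word presentation
#' counts, pair multiplicities over unique triads and the singleton-pair
#' count (triad designs); per-word unique-pair memberships, per-block word
#' loads and within-block pair repeats (pair designs). Violations of the
#' design's declared constraints are listed explicitly.
#'
#' @param d A `triad_design` or `pair_design`.
#' @return A list of count tables plus a character vector `violations`
#'   (empty when the design is valid).
#' @export
design_stats <- function(d) UseMethod("design_stats")

#' @export
design_stats.triad_design <- function(d) {
  tr <- d$trials
  words <- d$word_ids
  all_w <- c(tr$word1, tr$word2, tr$word3)
  word_counts <- table(factor(all_w, levels = words))
  uniq <- tr[!tr$is_repeat, ]
  pk <- c(paste(pmin(uniq$word1, uniq$word2), pmax(uniq$word1, uniq$word2)),
          paste(pmin(uniq$word1, uniq$word3), pmax(uniq$word1, uniq$word3)),
          paste(pmin(uniq$word2, uniq$word3), pmax(uniq$word2, uniq$word3)))
  if (length(pk) > 0) {
    pair_mult <- as.data.frame(table(pk), stringsAsFactors = FALSE)
    names(pair_mult) <- c("pair", "multiplicity")
  } else {
    pair_mult <- data.frame(pair = character(0),
                            multiplicity = integer(0))
  }
  viol <- character(0)
  if (nrow(tr) > 0 && length(unique(word_counts)) != 1) {
    viol <- c(viol, "unequal per-word presentation counts")
  }
  if (any(tr$word1 == tr$word2 | tr$word1 == tr$word3 |
            tr$word2 == tr$word3)) {
    viol <- c(viol, "triad with repeated word")
  }
  list(word_counts = word_counts,
       pair_mult = pair_mult,
       n_singleton_pairs = sum(pair_mult$multiplicity == 1),
       n_trials = nrow(tr),
       n_duplicates = sum(tr$is_repeat),
       violations = viol)
}

#' @export
design_stats.pair_design <- function(d) {
  up <- d$unique_pairs
  words <- d$word_ids
  membership <- table(factor(c(up$word_a, up$word_b), levels = words))
  viol <- character(0)
  if (nrow(up) > 0 && length(unique(membership)) != 1) {
    viol <- c(viol, "unequal per-word unique-pair membership")
  }
  pk <- paste(pmin(up$word_a, up$word_b), pmax(up$word_a, up$word_b))
  if (anyDuplicated(pk)) viol <- c(viol, "duplicated unique pair")
  block_load <- NULL
  for (tk in unique(d$trials$task)) {
    tt <- d$trials[d$trials$task == tk, ]
    bk <- paste(tk, tt$block,
                pmin(tt$word_left, tt$word_right),
                pmax(tt$word_left, tt$word_right))
    if (anyDuplicated(bk)) viol <- c(viol, paste0(tk, ": pair repeated ",
                                                  "within a block"))
    load <- tapply(c(tt$word_left, tt$word_right),
                   list(rep(tt$block, 2),
                        factor(c(tt$word_left, tt$word_right),
                               levels = words)),
                   length)
    load[is.na(load)] <- 0
    block_load <- max(block_load %||% 0, max(load))
  }
  list(pair_membership = membership,
       type_counts = table(up$pair_type),
       n_unique_pairs = nrow(up),
       max_block_word_load = block_load,
       violations = viol)
}

#' Randomize trial presentation order
#'
#' Returns a permutation of trial rows for one participant. Triad designs:
#' a full shuffle re-drawn until no duplicate trial is adjacent to its
#' original. Pair designs: block order and within-block order are shuffled
#' independently per task, preserving block contiguity.
#'
#' @param d A `triad_design` or `pair_design`.
#' @param seed Integer seed.
#' @return An integer permutation of `seq_len(nrow(d$trials))`.
#' @export
randomize_presentation <- function(d, seed = NULL) {
  UseMethod("randomize_presentation")
}

#' @export
randomize_presentation.triad_design <- function(d, seed = NULL) {
  with_seed(seed, {
    n <- nrow(d$trials)
    rep_of <- d$trials$repeat_of
    for (try in 1:1000) {
      p <- sample.int(n)
      pos <- match(seq_len(n), p)
      bad <- FALSE
      for (i in which(d$trials$is_repeat)) {
        if (abs(pos[i] - pos[rep_of[i]]) <= 1) { bad <- TRUE; break }
      }
      if (!bad) return(p)
    }
    p
  })
}

#' @export
randomize_presentation.pair_design <- function(d, seed = NULL) {
  with_seed(seed, {
    tr <- d$trials
    out <- integer(0)
    for (tk in unique(tr$task)) {
      rows <- which(tr$task == tk)
      blocks <- tr$block[rows]
      for (b in shuffle(unique(blocks))) {
        brows <- rows[blocks == b]
        out <- c(out, shuffle(brows))
      }
    }
    out
  })
}

#' @export
print.pair_design <- function(x, ...) {
  st <- design_stats(x)
  cat("Pair design:", st$n_unique_pairs, "unique pairs (",
      paste(names(st$type_counts), st$type_counts, collapse = ", "),
      ")\n")
  cat(nrow(x$trials), "trials over", length(unique(x$trials$block)),
      "blocks per task; max word load per block:",
      st$max_block_word_load, "\n")
  invisible(x)
}
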