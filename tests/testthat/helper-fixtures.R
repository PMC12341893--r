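# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    val <- switch(
      name,
      ws = synthesize_word_set(seed = 1),
      td = build_triad_design(fx("ws"), seed = 2),
      pd = build_pair_design(fx("ws"), seed = 3),
      lc_control = make_latent_config(fx("ws"), "control_like", seed = 4),
      lc_sv = make_latent_config(fx("ws"), "sv_like", seed = 5),
      resp_control = cohort_triads(fx("lc_control"), "control_like", 3,
                                   100),
      resp_sv = cohort_triads(fx("lc_sv"), "sv_like", 1.5, 200),
      stop("unknown fixture: ", name)
    )
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# ten simulated odd-one-out responders sharing one latent configuration
cohort_triads <- function(lc, group, delta, seed0, n = 10) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_triad_responses(
      lc, fx("td"),
      participant_profile(group = group, delta = delta, lapse = 0.02),
      seed = seed0 + i,
      participant_id = sprintf("%s%02d", substr(group, 1, 2), i))
  }))
}

# reduced MCMC settings for unit tests (not the analysis defaults)
quick_cfg <- function(warmup = 150, iter = 300, n_samples = 50) {
  bmds_config(warmup = warmup, iter = iter, n_samples = n_samples)
}

# tiny word table with hand-set norms (2 words per class) for exact checks
toy_words <- function() {
  df <- data.frame(
    word_id = sprintf("t%02d", 1:8),
    concreteness = c(2.0, 2.2, 1.9, 2.1, 4.3, 4.5, 4.2, 4.6),
    valence = c(5.0, 5.4, 2.5, 2.8, 5.1, 5.5, 2.6, 3.0),
    arousal = c(4.1, 4.6, 4.3, 4.8, 4.2, 4.4, 4.7, 4.5),
    dominance = c(4.2, 4.7, 4.1, 4.4, 4.6, 4.3, 4.8, 4.0),
    aoa = c(8.1, 9.0, 7.5, 8.6, 7.9, 8.3, 9.2, 7.2),
    log10_frequency = c(2.5, 2.8, 2.2, 2.6, 2.4, 2.9, 2.1, 2.7),
    orth_nd = c(2, 1, 4, 0, 3, 2, 5, 1),
    length = c(6, 7, 5, 8, 6, 7, 9, 5),
    prevalence = c(0.99, 0.985, 0.995, 0.99, 0.98, 0.99, 0.985, 1.0),
    stringsAsFactors = FALSE
  )
  df$word_class <- classify_word(df$concreteness, df$valence,
                                 df$log10_frequency, df$prevalence)
  class(df) <- c("word_set", "data.frame")
  df
}

# minimal bmds-classed object for method-level tests
fake_fit <- function(samples, word_ids = NULL, aligned = TRUE) {
  ns <- dim(samples)[1]
  word_ids <- word_ids %||% dimnames(samples)[[2]] %||%
    sprintf("w%02d", seq_len(dim(samples)[2]))
  structure(list(samples = samples,
                 delta = matrix(1, ns, 1, dimnames = list(NULL, "p1")),
                 posterior_mean = apply(samples, c(2, 3), mean),
                 word_ids = word_ids, participant_ids = "p1",
                 n_trials = 0L, aligned = aligned,
                 alignment = if (aligned) "mean_template" else "none",
                 diagnostics = list(accept_coord = NA, accept_delta = NA,
                                    rhat_dist = NA, converged = TRUE),
                 config = bmds_config(), seed = NULL),
            class = "bmds")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
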