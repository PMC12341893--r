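#' Configuration of a full synthetic study run
#'
#' Bundles every stage's settings: cohort sizes (defaults mirror a study
#' with 77 analysable controls and 10 patients), the word-set size, design
#' parameters, the MCMC configuration, the spatial-randomness settings and
#' an optional output directory.
#'
#' @param seed Master seed; every stage derives its own child seed from it.
#' @param n_control,n_sv Cohort sizes.
#' @param per_class Words per quadrant class (default 8).
#' @param n_trials,n_duplicates Triad-design sizes (defaults 192 and 24).
#' @param n_blocks Pair-design blocks per task.
#' @param bmds A [bmds_config()]; reduce `warmup` / `iter` for quick runs.
#' @param n_random Null configurations per spatial-randomness evaluation.
#' @param fit_patients Also fit each patient separately (slower).
#' @param out_dir Directory for CSV/JSON artefacts, or `NULL` to skip
#'   writing.
#' @export
study_config <- function(seed = 1, n_control = 77, n_sv = 10, per_class = 8,
                         n_trials = 192, n_duplicates = 24, n_blocks = 16,
                         bmds = bmds_config(), n_random = 10000,
                         fit_patients = FALSE, out_dir = NULL) {
  list(seed = seed, n_control = n_control, n_sv = n_sv,
       per_class = per_class, n_trials = n_trials,
       n_duplicates = n_duplicates, n_blocks = n_blocks, bmds = bmds,
       n_random = n_random, fit_patients = fit_patients, out_dir = out_dir)
}

#' Run the full synthetic study end to end
#'
#' Generates a word set, builds both designs, simulates a control-like and an
#' sv-like cohort, computes data-quality consistency, fits the pooled
#' Bayesian MDS per group (samples aligned to the generator's ground-truth
#' configuration, the recovery-study convention), interprets the dimensions
#' by norm regressions, computes spatial-randomness distributions and their
#' KS comparison, builds relative scales with Kendall agreement,
#' Crawford-Howell single-case tests against the control distribution, and
#' Procrustes mappings with per-stimulus error ANOVA for flagged patients.
#' All stages are deterministic given `cfg$seed`.
#'
#' @param cfg A [study_config()].
#' @return A list bundle with elements `word_set`, `designs`, `cohort`,
#'   `qc`, `fits`, `interpretation`, `randomness`, `scales`, and `session`
#'   (seeds and stage timings).
#' @export
run_study <- function(cfg = study_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  ws <- synthesize_word_set(per_class = cfg$per_class,
                            seed = derive_seed(cfg$seed, 1))
  tick("word_set")
  td <- build_triad_design(ws, n_trials = cfg$n_trials,
                           n_duplicates = cfg$n_duplicates,
                           seed = derive_seed(cfg$seed, 2))
  pd <- build_pair_design(ws, n_blocks = cfg$n_blocks,
                          seed = derive_seed(cfg$seed, 3))
  tick("designs")
  gc_ <- generator_config(n_control = cfg$n_control, n_sv = cfg$n_sv)
  cohort <- simulate_cohort(ws, td, pd, gc_, seed = derive_seed(cfg$seed, 4))
  tick("cohort")
  qc <- cohort_consistency(cohort$responses, td, pd)
  tick("qc")

  resp <- cohort$responses
  fits <- list()
  interp <- list()
  rand <- list()
  for (g in c("control_like", "sv_like")) {
    rs <- resp[resp$group == g & resp$task == "triad", , drop = FALSE]
    fits[[g]] <- bmds(rs, cfg$bmds, seed = derive_seed(cfg$seed, 5),
                      word_ids = ws$word_id, align = "reference",
                      reference = cohort$truth[[g]]$coords)
    # the 8-predictor norm regression needs enough words for residual df
    if (nrow(ws) >= 10) {
      interp[[g]] <- interpret_dimensions(fits[[g]], ws)
    }
    rand[[g]] <- randomness_over_samples(fits[[g]], n_random = cfg$n_random,
                                         seed = derive_seed(cfg$seed, 6))
  }
  ks <- compare_R_distributions(rand$control_like, rand$sv_like)
  tick("bmds")

  patient_fits <- NULL
  if (isTRUE(cfg$fit_patients)) {
    sv_ids <- unique(resp$participant_id[resp$group == "sv_like"])
    patient_fits <- lapply(setNames(sv_ids, sv_ids), function(id) {
      interpret_patient(resp, id, ws, cfg$bmds,
                        seed = derive_seed(cfg$seed, 100 + match(id, sv_ids)),
                        reference = cohort$truth$sv_like$coords)
    })
    tick("patients")
  }

  scales <- analyze_scales(resp, pd, ws)
  tick("scales")

  bundle <- list(word_set = ws,
                 designs = list(triads = td, pairs = pd),
                 cohort = cohort, qc = qc, fits = fits,
                 interpretation = interp,
                 randomness = c(rand, list(ks = ks)),
                 patient_fits = patient_fits,
                 scales = scales,
                 session = list(seed = cfg$seed, timings = timings))
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir, cfg)
  bundle
}

# per-participant relative scales, Kendall agreement, single-case tests and
# Procrustes errors; patients with significantly high SS get the class ANOVA
analyze_scales <- function(resp, pd, ws, alpha = 0.05) {
  ids <- unique(resp$participant_id)
  groups <- resp$group[match(ids, resp$participant_id)]
  rows <- list()
  pr_by_id <- list()
  for (i in seq_along(ids)) {
    rs <- resp[resp$participant_id == ids[i], , drop = FALSE]
    sc_c <- build_relative_scale(rs, pd, "concreteness")
    sc_v <- build_relative_scale(rs, pd, "valence")
    kc <- kendall_vs_ratings(sc_c, ws)
    kv <- kendall_vs_ratings(sc_v, ws)
    pr <- combine_and_procrustes(sc_v, sc_c, ws)
    pr_by_id[[ids[i]]] <- pr
    rows[[i]] <- data.frame(participant_id = ids[i], group = groups[i],
                            tau_concreteness = kc$tau, tau_valence = kv$tau,
                            procrustes_ss = pr$ss, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  hc <- tab[tab$group == "control_like", ]
  sv <- tab[tab$group == "sv_like", ]
  single_case <- NULL
  anovas <- list()
  if (nrow(hc) >= 2 && nrow(sv) >= 1) {
    single_case <- do.call(rbind, lapply(seq_len(nrow(sv)), function(j) {
      id <- sv$participant_id[j]
      ch_c <- crawford_howell(sv$tau_concreteness[j], hc$tau_concreteness)
      ch_v <- crawford_howell(sv$tau_valence[j], hc$tau_valence)
      ch_ss <- crawford_howell(sv$procrustes_ss[j], hc$procrustes_ss,
                               alternative = "greater")
      if (ch_ss$p < alpha) {
        anovas[[id]] <<- stimulus_error_anova(pr_by_id[[id]])
      }
      data.frame(participant_id = id,
                 t_tau_conc = ch_c$t, p_tau_conc = ch_c$p,
                 t_tau_val = ch_v$t, p_tau_val = ch_v$p,
                 t_ss = ch_ss$t, p_ss = ch_ss$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(table = tab,
       hc_mean_tau = c(concreteness = mean(hc$tau_concreteness),
                       valence = mean(hc$tau_valence)),
       single_case = single_case,
       stimulus_anovas = anovas)
}

write_bundle <- function(bundle, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_word_set(bundle$word_set, fp("word_set.csv"))
  write_triad_design(bundle$designs$triads, fp("triad_design.csv"))
  write_pair_design(bundle$designs$pairs, fp("pair_design.csv"))
  write_responses(bundle$cohort$responses, fp("responses.csv"))
  write.csv(bundle$cohort$participants, fp("participants.csv"),
            row.names = FALSE)
  write.csv(bundle$qc, fp("qc.csv"), row.names = FALSE)
  for (g in names(bundle$fits)) {
    write_posterior(bundle$fits[[g]], fp(paste0("posterior_", g, ".csv")))
    write_delta_draws(bundle$fits[[g]], fp(paste0("delta_", g, ".csv")))
    if (!is.null(bundle$interpretation[[g]])) {
      write.csv(bundle$interpretation[[g]]$posterior_mean,
                fp(paste0("regression_", g, ".csv")), row.names = FALSE)
      write.csv(as.data.frame(bundle$interpretation[[g]]$samples),
                fp(paste0("regression_samples_", g, ".csv")),
                row.names = FALSE)
    }
    write.csv(data.frame(sample_index =
                           seq_along(bundle$randomness[[g]]$R),
                         R = bundle$randomness[[g]]$R),
              fp(paste0("randomness_", g, ".csv")), row.names = FALSE)
  }
  write.csv(bundle$scales$table, fp("scales.csv"), row.names = FALSE)
  if (!is.null(bundle$scales$single_case)) {
    write.csv(bundle$scales$single_case, fp("single_case.csv"),
              row.names = FALSE)
  }
  summary <- list(
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    randomness = list(
      control_like = list(mean = bundle$randomness$control_like$mean,
                          sd = bundle$randomness$control_like$sd),
      sv_like = list(mean = bundle$randomness$sv_like$mean,
                     sd = bundle$randomness$sv_like$sd),
      ks = bundle$randomness$ks),
    hc_mean_tau = as.list(bundle$scales$hc_mean_tau),
    diagnostics = lapply(bundle$fits, function(f) f$diagnostics),
    timings = as.list(bundle$session$timings))
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}
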