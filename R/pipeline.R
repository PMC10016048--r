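# Cohort-level configuration, synthetic cohort generation and the end-to-end
# pipeline: simulate -> behavioral scoring -> d' classification -> gait
# variability -> ERP averaging -> cluster permutation statistics -> scalar
# statistics -> combined FDR. Every task constant (240-trial blocks, 13%
# NoGo, 1,017-ms SOA, 183-ms RT gate, 0.1-m prominence, 100-sample cycles,
# epoch windows and baselines, 5,000 permutations, q = 0.05) is a named
# default here, not a magic number inside the stage code.

#' Default cohort configuration
#'
#' The defaults encode the stated experimental world: 26 participants (14
#' improver-like, 12 non-improver-like), 7 blocks of 240 trials per motor
#' condition at 13% NoGo and 1,017-ms onset asynchrony, group RT and d'-rate
#' parameters chosen to match the reported group means, gait jitter ordered
#' DT < ST and improvers < non-improvers, and walking-related ERP amplitude
#' effects injected only in the improver-like group (frontocentral positive
#' deltas in the N2 and premovement/error windows, centroparietal negative
#' delta in the P3 window).
#'
#' @return nested list of configuration defaults
#' @export
default_config <- function() {
  list(
    cohort = list(n_imp = 14, n_nimp = 12),
    task = list(blocks_per_condition = 7, trials_per_block = 240,
                nogo_fraction = 0.13, soa_ms = 1017, stim_duration_ms = 67,
                min_rt_ms = 183),
    behavior = list(
      imp = list(
        sitting = list(hit_rate = 0.95, fa_rate = 0.35,
                       rt_mean_ms = 360, rt_sd_ms = 54),
        walking = list(hit_rate = 0.97, fa_rate = 0.18,
                       rt_mean_ms = 372, rt_sd_ms = 41)),
      nimp = list(
        sitting = list(hit_rate = 0.95, fa_rate = 0.30,
                       rt_mean_ms = 407, rt_sd_ms = 64),
        walking = list(hit_rate = 0.95, fa_rate = 0.30,
                       rt_mean_ms = 411, rt_sd_ms = 47)),
      rt_floor_ms = 100,
      # the group rt_sd_ms values above are across-participant dispersions;
      # trial-to-trial RT scatter and participant-level rate/RT random
      # effects are configured here
      within_rt_sd_ms = 80, rt_cond_cor = 0.85, participant_logit_sd = 0.25),
    gait = list(duration_s = 60, stride_period_s = 1.1,
                sample_rate_hz = 360,
                min_prominence_m = 0.1, n_resample = 100, k_sd = 5,
                jitter_m = list(imp = list(st = 0.012, dt = 0.010),
                                nimp = list(st = 0.014, dt = 0.012)),
                participant_log_sd = 0.25),
    eeg = list(n_epochs = 60, sample_rate_hz = 512,
               noise = list(sd_uv = 8, exponent = 1, lambda = 0.5),
               effects = list(
                 imp = list(
                   correct_rejection = list(
                     list(electrodes = c("FCz", "Fz", "FC1", "FC2", "Cz"),
                          window_ms = c(200, 350), delta_uv = 2.5),
                     list(electrodes = c("CPz", "Pz", "CP1", "CP2", "P1"),
                          window_ms = c(350, 600), delta_uv = -2.5)),
                   false_alarm = list(
                     list(electrodes = c("FCz", "Fz", "FC1", "FC2", "Cz"),
                          window_ms = c(-210, 100), delta_uv = 2.5))),
                 nimp = list(correct_rejection = list(),
                             false_alarm = list()))),
    cluster = list(n_perm = 5000, alpha = 0.05, max_dist = 0.45,
                   wcm_weight = 1),
    stats = list(q_fdr = 0.05, alpha_classify = 0.05)
  )
}

#' Validate and normalize a configuration
#'
#' Fills defaults recursively and rejects unknown keys and out-of-range
#' values. `config` may be a nested list or a path to a YAML file; an empty
#' file or NULL yields the full default configuration.
#'
#' @param config nested list, YAML file path, or NULL
#' @return normalized configuration list
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_mobidt("config", paste("config file not found:", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  merge_into <- function(def, user, path = "") {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      stop_mobidt("config", paste0("unknown config key(s): ",
                                   paste0(path, unknown, collapse = ", ")))
    for (nm in names(user)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_into(def[[nm]], user[[nm]] %||% list(),
                                paste0(path, nm, "."))
      } else def[[nm]] <- user[[nm]]
    }
    def
  }
  cfg <- merge_into(default_config(), config)
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$cohort$n_imp + cfg$cohort$n_nimp >= 2, "cohort must have >= 2 participants")
  chk(cfg$task$nogo_fraction > 0 && cfg$task$nogo_fraction < 1,
      "nogo_fraction must be in (0, 1)")
  chk(cfg$task$soa_ms > cfg$task$stim_duration_ms,
      "soa_ms must exceed stim_duration_ms")
  chk(cfg$task$min_rt_ms > 0, "min_rt_ms must be positive")
  for (g in c("imp", "nimp")) for (cond in c("sitting", "walking")) {
    b <- cfg$behavior[[g]][[cond]]
    chk(b$hit_rate >= 0 && b$hit_rate <= 1 && b$fa_rate >= 0 && b$fa_rate <= 1,
        paste(g, cond, "rates must lie in [0, 1]"))
    chk(b$rt_mean_ms > 0 && b$rt_sd_ms >= 0, paste(g, cond, "RT params invalid"))
  }
  chk(cfg$gait$min_prominence_m > 0, "min_prominence_m must be positive")
  chk(cfg$gait$n_resample >= 2, "n_resample must be >= 2")
  chk(cfg$cluster$n_perm >= 1, "n_perm must be positive")
  chk(cfg$stats$q_fdr > 0 && cfg$stats$q_fdr < 1, "q_fdr must be in (0, 1)")
  if (length(errs))
    stop_mobidt("config", paste("invalid config:", paste(errs, collapse = "; ")))
  cfg
}

#' Simulate one participant's behavioral stream (all blocks, both conditions)
#'
#' Participant-level random effects: a speed factor z (correlated across
#' motor conditions with `rt_cond_cor`) shifts the mean RT by z times the
#' across-participant group SD; hit- and false-alarm-rate logit offsets are
#' shared across conditions so they cancel in the walking-minus-sitting d'
#' difference. Trial-to-trial RT scatter uses `within_rt_sd_ms`.
#' @noRd
sim_participant_behavior <- function(cfg, group, pid) {
  task <- cfg$task
  rho <- cfg$behavior$rt_cond_cor
  z_sit <- rnorm(1)
  z_walk <- rho * z_sit + sqrt(1 - rho^2) * rnorm(1)
  z_rt <- c(sitting = z_sit, walking = z_walk)
  hit_off <- rnorm(1, 0, cfg$behavior$participant_logit_sd)
  fa_off <- rnorm(1, 0, cfg$behavior$participant_logit_sd)
  blocks <- list()
  bid <- 0L
  for (cond in c("sitting", "walking")) {
    pars <- cfg$behavior[[group]][[cond]]
    pars$rt_mean_ms <- pars$rt_mean_ms + z_rt[[cond]] * pars$rt_sd_ms
    pars$rt_sd_ms <- cfg$behavior$within_rt_sd_ms
    pars$hit_rate <- stats::plogis(stats::qlogis(pars$hit_rate) + hit_off)
    pars$fa_rate <- stats::plogis(stats::qlogis(pars$fa_rate) + fa_off)
    pars$rt_floor_ms <- cfg$behavior$rt_floor_ms
    for (b in seq_len(task$blocks_per_condition)) {
      bid <- bid + 1L
      tr <- gen_trial_sequence(task$trials_per_block, task$nogo_fraction,
                               task$soa_ms, block_id = bid,
                               motor_condition = cond)
      blocks[[bid]] <- gen_responses(tr, pars)
    }
  }
  trials <- do.call(rbind, blocks)
  trials$participant_id <- pid
  trials
}

#' Simulate a full synthetic cohort
#'
#' Generates, per participant: the Go/NoGo event stream (both motor
#' conditions), single-task and dual-task gait traces for both feet, and the
#' four ERP epoch sets (correct rejection / false alarm x sitting / walking),
#' with group-dependent effects injected into the walking sets of
#' improver-like participants.
#'
#' @param config configuration (see [validate_config()])
#' @param seed RNG seed for the whole cohort (fixed seed = byte-identical
#'   output)
#' @return list of class `sim_cohort`: `participants` (list with `id`,
#'   `group_true`, `trials`, `gait` (st/dt x left/right), `epochs` (4
#'   conditions)), `config`, `montage`
#' @export
simulate_cohort <- function(config = NULL, seed = 1) {
  cfg <- validate_config(config)
  montage <- montage_biosemi64()
  with_seed(seed, {
    groups <- c(rep("imp", cfg$cohort$n_imp), rep("nimp", cfg$cohort$n_nimp))
    participants <- lapply(seq_along(groups), function(i) {
      g <- groups[i]
      pid <- sprintf("P%02d", i)
      trials <- sim_participant_behavior(cfg, g, pid)
      gait <- list()
      gait_factor <- exp(rnorm(1, 0, cfg$gait$participant_log_sd))
      for (load in c("st", "dt")) {
        jit <- gait_factor * cfg$gait$jitter_m[[g]][[load]]
        gait[[load]] <- list(
          left = gen_gait_trace(cfg$gait$duration_s, cfg$gait$stride_period_s,
                                jit, sample_rate_hz = cfg$gait$sample_rate_hz,
                                foot = "left"),
          right = gen_gait_trace(cfg$gait$duration_s, cfg$gait$stride_period_s,
                                 jit, sample_rate_hz = cfg$gait$sample_rate_hz,
                                 foot = "right"))
      }
      epochs <- list()
      for (cond in c("correct_rejection", "false_alarm")) {
        lock <- if (cond == "correct_rejection") "stimulus_onset" else "response_onset"
        for (motor in c("sitting", "walking")) {
          eff <- if (motor == "walking") cfg$eeg$effects[[g]][[cond]] else NULL
          if (length(eff) == 0) eff <- NULL
          epochs[[paste(cond, motor, sep = ".")]] <-
            gen_epoch_set(default_templates(cond), cfg$eeg$n_epochs,
                          effect_map = eff, noise = cfg$eeg$noise,
                          lock = lock,
                          condition = paste(cond, motor, sep = "."),
                          sample_rate_hz = cfg$eeg$sample_rate_hz,
                          montage = montage)
        }
      }
      list(id = pid, group_true = g, trials = trials, gait = gait,
           epochs = epochs)
    })
    structure(list(participants = participants, config = cfg,
                   montage = montage, seed = seed),
              class = "sim_cohort")
  })
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Stages: behavioral scoring and d' per condition; improver classification
#' from the cohort's walking-minus-sitting d' distribution; gait variability
#' (pooled mean DTW) per cognitive load; epoch rejection and condition
#' averaging; cluster-based permutation tests of walking-minus-sitting ERP
#' differences for the whole cohort and per classified group; scalar tests
#' (normality-gated paired test on d', paired t on RT, Wilcoxon on mean DTW,
#' independent t on average d', two mixed ANOVAs, post-hoc within-group
#' paired t on DTW); combined two-stage FDR over the assembled p-value set.
#' Participants whose streams fail a stage are quarantined with a log entry,
#' not fatal.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()]
#' @param seed seed for the permutation tests
#' @param n_perm override for the permutation count (NULL = config value)
#' @return list of class `pipeline_report`: `behavior`, `classification`,
#'   `gait`, `cluster_results`, `scalar_results`, `fdr`, `quarantined`,
#'   `manifest`
#' @export
run_pipeline <- function(cohort, seed = 1, n_perm = NULL) {
  cfg <- cohort$config
  n_perm <- n_perm %||% cfg$cluster$n_perm
  quarantined <- character(0)
  note <- function(id, why) {
    quarantined <<- c(quarantined, paste0(id, ": ", why))
    message("quarantined ", id, ": ", why)
  }
  # --- behavior ---
  behavior <- list()
  for (p in cohort$participants) {
    res <- tryCatch(behavioral_summary(p$trials, p$id, cfg$task$min_rt_ms),
                    mobidt_error = function(e) {
                      note(p$id, conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) behavior[[p$id]] <- res
  }
  btab <- do.call(rbind, behavior)
  rownames(btab) <- NULL
  wide <- merge(btab[btab$motor_condition == "sitting",
                     c("participant_id", "dprime", "mean_go_rt_ms")],
                btab[btab$motor_condition == "walking",
                     c("participant_id", "dprime", "mean_go_rt_ms")],
                by = "participant_id", suffixes = c("_sitting", "_walking"))
  wide$delta_dprime <- wide$dprime_walking - wide$dprime_sitting
  wide$avg_dprime <- (wide$dprime_walking + wide$dprime_sitting) / 2
  # --- classification ---
  wide$group <- vapply(wide$delta_dprime, function(d)
    as.character(classify_improver(d, wide$delta_dprime,
                                   cfg$stats$alpha_classify)), "")
  # --- gait ---
  gait_rows <- list()
  for (p in cohort$participants) {
    for (load in c("st", "dt")) {
      row <- tryCatch(
        gait_summary(p$gait[[load]]$left, p$gait[[load]]$right,
                     cfg$gait$min_prominence_m, cfg$gait$n_resample,
                     cfg$gait$k_sd),
        mobidt_error = function(e) {
          note(p$id, paste0("gait/", load, ": ", conditionMessage(e)))
          NULL
        })
      if (!is.null(row)) {
        row$participant_id <- p$id
        row$cognitive_load <- toupper(load)
        gait_rows[[paste(p$id, load)]] <- row
      }
    }
  }
  gtab <- do.call(rbind, gait_rows)
  rownames(gtab) <- NULL
  # --- ERP averaging (with epoch rejection) ---
  erps <- list()
  for (p in cohort$participants) {
    pw <- list()
    ok <- TRUE
    for (nm in names(p$epochs)) {
      w <- tryCatch(average_erp(reject_epochs(p$epochs[[nm]])$kept),
                    mobidt_error = function(e) {
                      note(p$id, paste0("eeg/", nm, ": ", conditionMessage(e)))
                      NULL
                    })
      if (is.null(w)) ok <- FALSE else pw[[nm]] <- w
    }
    if (ok) erps[[p$id]] <- pw
  }
  # --- cluster permutation tests ---
  adjacency <- build_adjacency(cohort$montage, cfg$cluster$max_dist)
  id_by_group <- split(wide$participant_id, wide$group)
  analyses <- list(cohort = wide$participant_id,
                   IMP = id_by_group$IMP, nIMP = id_by_group$nIMP)
  cluster_results <- list()
  ck <- 0L
  for (ga in names(analyses)) {
    ids <- intersect(analyses[[ga]], names(erps))
    if (length(ids) < 5) next
    for (cond in c("correct_rejection", "false_alarm")) {
      sit <- lapply(ids, function(id) erps[[id]][[paste0(cond, ".sitting")]])
      walk <- lapply(ids, function(id) erps[[id]][[paste0(cond, ".walking")]])
      ck <- ck + 1L
      cluster_results[[paste(ga, cond, sep = ".")]] <-
        cluster_permutation_test(diff_waves(sit, walk), adjacency,
                                 n_perm = n_perm, alpha = cfg$cluster$alpha,
                                 seed = seed + ck,
                                 wcm_weight = cfg$cluster$wcm_weight)
    }
  }
  # --- scalar statistics ---
  scalar <- list()
  gate <- normality_gate(wide$delta_dprime)
  scalar$dprime_walk_vs_sit <- if (gate == "parametric")
    paired_t(wide$dprime_walking, wide$dprime_sitting)
  else wilcoxon_signed_rank(wide$dprime_walking, wide$dprime_sitting)
  gate_rt <- normality_gate(wide$mean_go_rt_ms_walking - wide$mean_go_rt_ms_sitting)
  scalar$rt_walk_vs_sit <- if (gate_rt == "parametric")
    paired_t(wide$mean_go_rt_ms_walking, wide$mean_go_rt_ms_sitting)
  else wilcoxon_signed_rank(wide$mean_go_rt_ms_walking, wide$mean_go_rt_ms_sitting)
  gwide <- merge(gtab[gtab$cognitive_load == "ST",
                      c("participant_id", "mean_dtw_m")],
                 gtab[gtab$cognitive_load == "DT",
                      c("participant_id", "mean_dtw_m")],
                 by = "participant_id", suffixes = c("_st", "_dt"))
  gate_dtw <- normality_gate(gwide$mean_dtw_m_dt - gwide$mean_dtw_m_st)
  scalar$dtw_st_vs_dt <- if (gate_dtw == "parametric")
    paired_t(gwide$mean_dtw_m_st, gwide$mean_dtw_m_dt)
  else wilcoxon_signed_rank(gwide$mean_dtw_m_st, gwide$mean_dtw_m_dt)
  two_groups <- length(unique(wide$group)) == 2 && all(table(wide$group) >= 2)
  if (two_groups) {
    imp <- wide[wide$group == "IMP", ]
    nimp <- wide[wide$group == "nIMP", ]
    scalar$avg_dprime_imp_vs_nimp <- independent_t(imp$avg_dprime, nimp$avg_dprime)
    a_rt <- anova_2x2_mixed(wide$group,
                            cbind(wide$mean_go_rt_ms_sitting,
                                  wide$mean_go_rt_ms_walking))
    scalar$rt_anova_group <- a_rt$group
    scalar$rt_anova_load <- a_rt$within
    scalar$rt_anova_interaction <- a_rt$interaction
    gmerged <- merge(gwide, wide[, c("participant_id", "group")],
                     by = "participant_id")
    if (all(table(gmerged$group) >= 2)) {
      a_dtw <- anova_2x2_mixed(gmerged$group,
                               cbind(gmerged$mean_dtw_m_st,
                                     gmerged$mean_dtw_m_dt))
      scalar$dtw_anova_group <- a_dtw$group
      scalar$dtw_anova_load <- a_dtw$within
      scalar$dtw_anova_interaction <- a_dtw$interaction
      for (g in c("IMP", "nIMP")) {
        gg <- gmerged[gmerged$group == g, ]
        if (nrow(gg) >= 2)
          scalar[[paste0("dtw_posthoc_", g)]] <-
            paired_t(gg$mean_dtw_m_st, gg$mean_dtw_m_dt)
      }
    }
  }
  # --- combined FDR ---
  pset <- aggregate_pvalues_for_fdr(scalar, cluster_results)
  fdr <- bky_fdr(pset$p, cfg$stats$q_fdr)
  pset$significant <- fdr$reject
  manifest <- list(seed = seed, n_perm = n_perm,
                   n_participants = length(cohort$participants),
                   n_quarantined = length(quarantined),
                   config = cfg, timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(behavior = btab, cohort_table = wide,
                 classification = table(wide$group),
                 gait = gtab, cluster_results = cluster_results,
                 scalar_results = scalar, fdr_set = pset,
                 fdr = fdr, quarantined = quarantined, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  participants:", x$manifest$n_participants,
      "(quarantined:", x$manifest$n_quarantined, ")\n")
  cat("  classification:", paste(names(x$classification),
                                 x$classification, collapse = ", "), "\n")
  cat("  scalar tests:", length(x$scalar_results),
      "| EEG comparisons:", length(x$cluster_results), "\n")
  cat("  FDR set size:", nrow(x$fdr_set), "| critical p:",
      format(x$fdr$critical_p, digits = 3), "\n")
  invisible(x)
}
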