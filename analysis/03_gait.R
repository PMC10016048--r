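# Step 3 -- stride-to-stride gait variability.
#
# For each participant and cognitive load (single-task vs dual-task
# walking): heel strikes from prominent Z-position maxima, gait cycles
# between consecutive same-foot strikes, kurtosis-based outlier rejection
# pooled across feet, resampling to 100 points, and the pooled mean DTW
# distance between consecutive cycles.

source("analysis/00_common.R")

cohort <- get_cohort()
cfg <- cohort$config$gait

rows <- list()
for (p in cohort$participants) {
  for (load in c("st", "dt")) {
    g <- gait_summary(p$gait[[load]]$left, p$gait[[load]]$right,
                      cfg$min_prominence_m, cfg$n_resample, cfg$k_sd)
    g$participant_id <- p$id
    g$cognitive_load <- toupper(load)
    rows[[paste(p$id, load)]] <- g
  }
}
gtab <- do.call(rbind, rows)
rownames(gtab) <- NULL
write.csv(gtab, "results/gait_summary.csv", row.names = FALSE)

agg <- tapply(gtab$mean_dtw_m, gtab$cognitive_load, function(v)
  sprintf("%.2f +/- %.2f m", mean(v), sd(v)))
cat("mean DTW distance ST:", agg[["ST"]], " DT:", agg[["DT"]], "\n")
cat("wrote results/gait_summary.csv\n")
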