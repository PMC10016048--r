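# Step 2 -- score the Go/NoGo task and classify improvers.
#
# Per participant and motor condition: hit / false-alarm counts and rates,
# the d' sensitivity index (183-ms response gate, log-linear edge
# correction), and mean Go RT. Participants whose walking-minus-sitting d'
# difference exceeds the cohort-null 95% bound are labeled IMP.

source("analysis/00_common.R")

cohort <- get_cohort()
cfg <- cohort$config

rows <- lapply(cohort$participants, function(p)
  behavioral_summary(p$trials, p$id, cfg$task$min_rt_ms))
btab <- do.call(rbind, rows)
write.csv(btab, "results/behavior_summary.csv", row.names = FALSE)

wide <- merge(btab[btab$motor_condition == "sitting",
                   c("participant_id", "dprime", "mean_go_rt_ms")],
              btab[btab$motor_condition == "walking",
                   c("participant_id", "dprime", "mean_go_rt_ms")],
              by = "participant_id", suffixes = c("_sitting", "_walking"))
wide$delta_dprime <- wide$dprime_walking - wide$dprime_sitting
wide$group <- vapply(wide$delta_dprime, function(d)
  as.character(classify_improver(d, wide$delta_dprime)), "")
write.csv(wide, "results/cohort_table.csv", row.names = FALSE)

thr <- attr(classify_improver(0, wide$delta_dprime), "threshold")
cat(sprintf("d' sitting %.2f +/- %.2f, walking %.2f +/- %.2f\n",
            mean(wide$dprime_sitting), sd(wide$dprime_sitting),
            mean(wide$dprime_walking), sd(wide$dprime_walking)))
cat(sprintf("classification threshold (1.96 x cohort SD): %.3f\n", thr))
print(table(wide$group))
cat("wrote results/behavior_summary.csv, results/cohort_table.csv\n")
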