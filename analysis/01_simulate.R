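# Step 1 -- generate the synthetic cohort.
#
# The default world: 26 young adults (14 improver-like, 12 non-improver-like),
# 7 blocks of 240 Go/NoGo trials per motor condition (13% NoGo, 1,017-ms
# onset asynchrony), 3D heel-marker traces for single- and dual-task
# treadmill walking, and four ERP epoch sets per participant (correct
# rejection / false alarm x sitting / walking) with walking-related amplitude
# effects injected only in the improver-like group.

source("analysis/00_common.R")

cohort <- get_cohort()

cat("participants:", length(cohort$participants), "\n")
truth <- table(vapply(cohort$participants, `[[`, "", "group_true"))
print(truth)

# export one participant's streams as examples of the interchange formats
p1 <- cohort$participants[[1]]
write_events_csv(head(p1$trials, 240), "results/example_events_block1.csv")
tr <- p1$gait$st$left
short <- list(foot = tr$foot, sample_rate_hz = tr$sample_rate_hz,
              t = tr$t[1:1800], xyz = tr$xyz[1:1800, ])
class(short) <- "gait_trace"
write_gait_csv(short, "results/example_gait_left_st_5s.csv")

cat("wrote results/example_events_block1.csv and results/example_gait_left_st_5s.csv\n")
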