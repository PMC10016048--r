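# Step 4 -- ERP preprocessing and spatiotemporal cluster statistics.
#
# Per participant and condition: artifact-based epoch rejection and
# averaging into ERPs. Then, for the whole cohort and for the classified
# IMP/nIMP groups, cluster-based permutation tests (5,000 sign-flip
# permutations, weighted cluster mass) on the walking-minus-sitting
# difference waveforms of correct-rejection and response-locked false-alarm
# trials.

source("analysis/00_common.R")

cohort <- get_cohort()
cfg <- cohort$config
wide <- read.csv("results/cohort_table.csv")   # from 02_behavior.R

erps <- list()
rej_frac <- c()
for (p in cohort$participants) {
  pw <- list()
  for (nm in names(p$epochs)) {
    r <- reject_epochs(p$epochs[[nm]])
    rej_frac <- c(rej_frac, length(r$rejected) / dim(p$epochs[[nm]]$data)[1])
    pw[[nm]] <- average_erp(r$kept)
  }
  erps[[p$id]] <- pw
}
cat(sprintf("epoch rejection: %.1f%% of epochs on average\n",
            100 * mean(rej_frac)))

adjacency <- build_adjacency(cohort$montage, cfg$cluster$max_dist)
cat(sprintf("electrode graph: mean degree %.1f at max_dist %.2f\n",
            adjacency$mean_degree, adjacency$max_dist))

groups <- list(cohort = wide$participant_id,
               IMP = wide$participant_id[wide$group == "IMP"],
               nIMP = wide$participant_id[wide$group == "nIMP"])
k <- 0L
for (ga in names(groups)) {
  ids <- intersect(groups[[ga]], names(erps))
  if (length(ids) < 5) {
    cat(ga, ": fewer than 5 participants, skipped\n")
    next
  }
  for (cond in c("correct_rejection", "false_alarm")) {
    sit <- lapply(ids, function(id) erps[[id]][[paste0(cond, ".sitting")]])
    walk <- lapply(ids, function(id) erps[[id]][[paste0(cond, ".walking")]])
    k <- k + 1L
    res <- cluster_permutation_test(diff_waves(sit, walk), adjacency,
                                    n_perm = cfg$cluster$n_perm,
                                    alpha = cfg$cluster$alpha,
                                    seed = analysis_seed + k)
    out <- sprintf("results/clusters_%s_%s.json", ga, cond)
    write_cluster_json(res, out)
    write.csv(res$t_map, sprintf("results/tmap_%s_%s.csv", ga, cond),
              row.names = FALSE)
    cat(sprintf("%s / %s: %d cluster(s), min p = %s\n", ga, cond,
                length(res$clusters), format(min_cluster_p(res), digits = 3)))
  }
}
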