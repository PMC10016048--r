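# Shared setup for the analysis drivers: simulate (or reload) the default
# synthetic cohort. The cohort is cached under scratch/ so the numbered
# scripts can be run in sequence without regenerating it each time.

library(mobidt)

analysis_seed <- as.integer(Sys.getenv("MOBIDT_SEED", "1"))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_cohort <- function(seed = analysis_seed) {
  cache <- file.path("scratch", sprintf("cohort_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating default synthetic cohort (seed ", seed, ") ...")
  cohort <- simulate_cohort(seed = seed)
  saveRDS(cohort, cache)
  cohort
}
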