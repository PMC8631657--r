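# Shared settings for the analysis scripts. The cohort mirrors the study
# design (stage counts 11/14/15/10, four technical replicate tubes per
# subject) on a reduced 32 x 200 acquisition grid so the whole workflow
# runs on a laptop; every script regenerates the cohort deterministically
# from the same seed.

library(breathfaims)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

COHORT_SEED <- 2024L
SPLIT_SEED <- 11L
CLASSIFIER_SEED <- 5L

study_config <- function() {
  cohort_config(n_per_stage = c(11L, 14L, 15L, 10L),
                n_technical_replicates = 4L,
                cf_points = 32L, time_points = 200L,
                seed = COHORT_SEED)
}

# crop/embedding settings scaled to the reduced grid
TERMINAL_POINTS <- 10L
EMBED_LENGTH <- 64L
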