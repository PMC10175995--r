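# Shared configuration for the analysis drivers 01-05.
#
# The workflow analyses a synthetic twin cohort at desk scale: 120 subjects
# (18 MZ pairs, 10 DZ pairs, 40 siblings in groups of 2-3, 24 singletons),
# 10 networks, 2 sessions of 400 time-points at TR = 0.72 s, with directed
# ring couplings whose strengths carry heritability h2 = 0.4. All stages
# write plain-text tables under results/.

library(gcherit)

MASTER_SEED <- 20260901L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")

cohort_sim_config <- function() {
  sim_config(n_mz_pairs = 18, n_dz_pairs = 10,
             sib_sizes = sib_sizes_for(40), n_singletons = 24,
             n_networks = 10, n_sessions = 2, n_timepoints = 400,
             h2 = 0.4, c2 = 0,
             seed = child_seed(MASTER_SEED, "simulate"))
}

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
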