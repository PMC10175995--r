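#!/usr/bin/env Rscript
# Simulate the synthetic twin cohort: pedigree, demographics, latent ACE
# coupling traits, and BOLD-like network time-series written as one TSV per
# subject-session plus a manifest.

source("analysis/00_config.R")

cfg <- cohort_sim_config()
pc <- simulate_pedigree(cfg)
cat("Simulated cohort:", nrow(pc$ped), "subjects in",
    length(unique(pc$ped$famid)), "families\n")
print(table(pc$ped$group))

traits <- simulate_ace_traits(pc$ped, cfg)
cat("Latent traits:", ncol(traits), "directed connections, true h2 =",
    unique(attr(traits, "h2")), "\n")

nts <- generate_bold(pc$ped, traits, cfg)

write_pedigree(pc$ped, file.path(DATA_DIR, "pedigree.csv"))
write.csv(pc$cov, file.path(DATA_DIR, "covariates.csv"), row.names = FALSE,
          quote = FALSE)
write.csv(data.frame(key = colnames(traits), true_h2 = attr(traits, "h2")),
          file.path(DATA_DIR, "true_traits_h2.csv"), row.names = FALSE,
          quote = FALSE)
manifest <- write_timeseries(nts, file.path(DATA_DIR, "timeseries"))
cat("Wrote time-series manifest:", manifest, "\n")
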