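#!/usr/bin/env Rscript
# Per-connection heritability in each cohort: covariate adjustment, inverse
# normal transform, AE variance-component fit, boundary-corrected LRT, and
# FDR across all directed connections.

source("analysis/00_config.R")

ped <- read_pedigree(file.path(DATA_DIR, "pedigree.csv"))
cov <- read_covariates(file.path(DATA_DIR, "covariates.csv"))
ids <- list(
  discovery = readLines(file.path(RESULTS, "cohort_discovery_ids.txt")),
  replication = readLines(file.path(RESULTS, "cohort_replication_ids.txt")))

gdir <- file.path(RESULTS, "gc")
gcs <- lapply(list.files(gdir, full.names = TRUE), function(f) {
  as.matrix(read.csv(f, skip = 1, row.names = 1, check.names = FALSE))
})
names(gcs) <- sub("^gc_(.*)\\.csv$", "\\1", list.files(gdir))
traits <- gc_trait_table(gcs)

for (coh in names(ids)) {
  tr <- traits[intersect(rownames(traits), ids[[coh]]), , drop = FALSE]
  scan <- heritability_scan(tr, ped, cov, model = "AE", alpha = 0.05)
  write.csv(scan, file.path(RESULTS, paste0("heritability_", coh, ".csv")),
            row.names = FALSE, quote = FALSE)
  cat(sprintf("%s: %d subjects, %d connections, %d significant (FDR 0.05), mean h2 of significant = %.2f\n",
              coh, nrow(tr), nrow(scan), sum(scan$significant, na.rm = TRUE),
              mean(scan$h2[which(scan$significant)])))
}
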