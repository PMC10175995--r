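#!/usr/bin/env Rscript
# Discovery/replication overlap of significant heritable connections, and a
# check of estimated h2 against the generator's ground truth.

source("analysis/00_config.R")

scans <- lapply(c(discovery = "discovery", replication = "replication"),
                function(coh) read.csv(
                  file.path(RESULTS, paste0("heritability_", coh, ".csv"))))

repl <- replication_overlap(scans$discovery, scans$replication)
write.csv(repl, file.path(RESULTS, "replication.csv"), row.names = FALSE,
          quote = FALSE)
print(repl)

truth <- read.csv(file.path(DATA_DIR, "true_traits_h2.csv"))
key <- paste0(scans$discovery$source, "->", scans$discovery$target)
merged <- data.frame(key = key, h2_discovery = scans$discovery$h2,
                     h2_replication = scans$replication$h2,
                     true_h2 = truth$true_h2[match(key, truth$key)])
write.csv(merged, file.path(RESULTS, "h2_vs_truth.csv"), row.names = FALSE,
          quote = FALSE)
cat(sprintf("mean estimated h2: discovery %.3f, replication %.3f (true latent h2 = %.2f;\nconnectivity estimation noise dilutes the realized trait heritability)\n",
            mean(merged$h2_discovery, na.rm = TRUE),
            mean(merged$h2_replication, na.rm = TRUE),
            mean(merged$true_h2)))
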