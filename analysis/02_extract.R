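#!/usr/bin/env Rscript
# Stage 2: run the CSD extraction scheme on the simulated run and compare
# every emitted reading with its planted ground truth.

suppressPackageStartupMessages(library(csdtools))

scans <- read_spectra("results/scans_synthA.tsv", "tabular")
idt <- read_id_table("results/id_table_synthA.tsv")
truth <- read_csd_table("results/csd_truth.tsv")

csd <- extract_run(scans, idt, extraction_config(), verbose = TRUE)
write_csd_table(csd, "results/csd_synthA.tsv")

key <- match(csd$sequence, truth$sequence)
tv <- vapply(seq_len(nrow(csd)), function(i) {
  total_variation(as.numeric(csd[i, paste0("p", 1:5)]),
                  as.numeric(truth[key[i], paste0("p", 1:5)]))
}, numeric(1))
cat(sprintf("readings: %d/%d peptides\n", nrow(csd), nrow(idt)))
cat(sprintf("extraction error vs ground truth: median TV %.4f, 95th pct %.4f, %.1f%% under 2%%\n",
            median(tv), quantile(tv, 0.95), 100 * mean(tv < 0.02)))
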