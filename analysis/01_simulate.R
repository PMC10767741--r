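#!/usr/bin/env Rscript
# Stage 1: build the synthetic study population and render a reference
# MS1 run. Writes the scan table, identification table and ground-truth
# CSDs under results/.
#
# The planted model and run configuration are the package defaults: 500
# tryptic-like peptides (700-4600 Da, fully observable in the 300-1800
# m/z window), 40 scans per peptide, log-normal intensity noise sd 0.2
# per charge state, 5% chimera injection.

suppressPackageStartupMessages(library(csdtools))

dir.create("results", showWarnings = FALSE)
model <- ground_truth_model()
peptides <- sample_peptides(500, seed = 1, model = model)
cfg <- run_sim_config(seed = 2)
run <- simulate_run(peptides, model, cfg, run_id = "synthA")

write_scan_table(run$scans, "results/scans_synthA.tsv")
write.table(run$id_table, "results/id_table_synthA.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
truth <- ground_truth_csd_table(peptides, model, run_id = "truth")
write_csd_table(truth, "results/csd_truth.tsv")

cat(sprintf("peptides: %d, mass %.0f-%.0f Da, basic sites %d-%d\n",
            length(peptides), min(truth$mass), max(truth$mass),
            min(truth$basic_sites), max(truth$basic_sites)))
cat(sprintf("rendered %d MS1 peaks in %d scans -> results/scans_synthA.tsv\n",
            nrow(run$scans), length(unique(run$scans$scan_id))))
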