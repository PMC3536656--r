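#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a planted-signal log2 expression
# matrix over the 2-sex x 2-genotype x 4-stage x 3-replicate design, the
# matching design/annotation/truth tables, and a NanoString-style count
# table with planted reference instability. All downstream drivers read
# these files, so the whole workflow is reproducible from this script.

library(cagptools)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_probesets = 2000, seed = 1)
sim <- simulate_expression(cfg)
write_expression_matrix(sim$matrix, file.path(out, "expression_log2.tsv"))
write_sample_design(sim$design, file.path(out, "sample_design.tsv"))
write_result_table(sim$annotation, file.path(out, "annotation.tsv"))
write_result_table(sim$truth, file.path(out, "truth_labels.tsv"))

cat(sprintf("expression: %d probesets x %d samples\n",
            nrow(sim$matrix), ncol(sim$matrix)))
print(table(sim$truth$class))
cat(sprintf("attenuated in dko: %d of %d non-null probesets\n",
            sum(sim$truth$attenuated), sum(sim$truth$class != "null")))

ns <- simulate_nanostring(n_endogenous = 60, n_reference_candidates = 8,
                          n_unstable = 2, instability_sd = 1.0, seed = 1)
write_nanostring_counts(ns$counts, file.path(out, "nanostring_counts.csv"))
write_result_table(ns$truth, file.path(out, "nanostring_truth.tsv"))
write_result_table(ns$samples, file.path(out, "nanostring_size_factors.tsv"))
cat(sprintf("nanostring: %d probes x %d samples (2 planted unstable references)\n",
            length(unique(ns$counts$probe_id)),
            length(unique(ns$counts$sample_id))))
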