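#!/usr/bin/env Rscript
# NanoString count processing: positive-control QC, negative-control
# background correction, geNorm reference ranking (recovering the two
# planted unstable candidates), geometric-mean normalization, and the
# per-gene sources-of-variation ANOVA over stage, genotype and sex.

library(cagptools)

dat <- "results/data"
out <- "results/nanostring"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_nanostring_counts(file.path(dat, "nanostring_counts.csv"))
truth <- read.delim(file.path(dat, "nanostring_truth.tsv"),
                    stringsAsFactors = FALSE)
design <- read_sample_design(file.path(dat, "sample_design.tsv"))

qc <- positive_control_qc(counts)
cat(sprintf("positive-control ratio (max/min sample average): %.3f -> %s\n",
            qc$pos_ratio, if (qc$pass) "PASS (< 3)" else "FAIL (>= 3)"))
write_result_table(qc$sample_means, file.path(out, "qc_positive_means.tsv"))

corrected <- background_correct(counts)
write_result_table(corrected$background, file.path(out, "background_model.tsv"))
cat(sprintf("background thresholds (mean + 2 SD of negatives): %.1f - %.1f\n",
            min(corrected$background$threshold),
            max(corrected$background$threshold)))

g <- genorm_rank(corrected)
write_result_table(g$exclusion, file.path(out, "genorm_exclusion.tsv"))
unstable <- truth$probe_id[truth$probe_class == "reference_candidate" &
                             truth$unstable %in% TRUE]
cat("geNorm exclusion order (first = least stable):",
    paste(g$ranking, collapse = " "), "\n")
cat("planted unstable candidates:", paste(sort(unstable), collapse = " "),
    "-> excluded first:", setequal(g$ranking[1:2], unstable), "\n")

refs <- select_references(g, 6)
norm <- reference_normalize(corrected, refs)
write_nanostring_counts(
  transform(norm$counts, count = signif(count, 10)),
  file.path(out, "normalized_counts.csv"))
write_result_table(norm$factors, file.path(out, "normalization_factors.tsv"))
cat("selected references:", paste(refs, collapse = " "), "\n")

a <- anova_sources(norm, design)
write_result_table(a, file.path(out, "anova_sources.tsv"))
mean_frac <- tapply(a$frac_ss, a$term, mean)
mean_frac <- sort(mean_frac[setdiff(names(mean_frac), "residual")],
                  decreasing = TRUE)
cat("mean share of per-gene variance by factor (endogenous probes):\n")
for (nm in names(mean_frac)) cat(sprintf("  %-9s %.3f\n", nm, mean_frac[nm]))
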