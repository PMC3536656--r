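#!/usr/bin/env Rscript
# Differential expression at E11.5: the four pairwise comparisons, each
# varying exactly one factor (sex within a genotype, genotype within a
# sex), using the moderated t with the three-part retention rule
# (intensity above the global median, |FC| >= 1.5, BH q <= 0.01).
# Also writes the sample similarity matrices used for array QC.

library(cagptools)

dat <- "results/data"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- read_expression_matrix(file.path(dat, "expression_log2.tsv"))
design <- read_sample_design(file.path(dat, "sample_design.tsv"))

floor_val <- global_median(m)
cat(sprintf("global median intensity (filter floor): %.6f\n", floor_val))
filt <- de_filter_config(fc_threshold = 1.5, alpha = 0.01,
                         intensity_floor = floor_val)

contrasts <- list(
  sex_control = list(a = list(sex = "XX", genotype = "control", stage = "E11.5"),
                     b = list(sex = "XY", genotype = "control", stage = "E11.5")),
  sex_dko     = list(a = list(sex = "XX", genotype = "dko", stage = "E11.5"),
                     b = list(sex = "XY", genotype = "dko", stage = "E11.5")),
  genotype_xx = list(a = list(sex = "XX", genotype = "control", stage = "E11.5"),
                     b = list(sex = "XX", genotype = "dko", stage = "E11.5")),
  genotype_xy = list(a = list(sex = "XY", genotype = "control", stage = "E11.5"),
                     b = list(sex = "XY", genotype = "dko", stage = "E11.5"))
)

affected <- character(0)
for (nm in names(contrasts)) {
  tab <- run_contrast(m, design, contrasts[[nm]]$a, contrasts[[nm]]$b, filt)
  write_result_table(tab, file.path(out, paste0("de_", nm, ".tsv")))
  up <- sum(tab$is_de & tab$direction %in% "up")
  dn <- sum(tab$is_de & tab$direction %in% "down")
  mod <- attr(tab, "moderation")
  cat(sprintf("%-12s %4d DE (%d up / %d down)  d0 = %s, s0^2 = %.4f\n",
              nm, up + dn, up, dn, format(mod$d0, digits = 4), mod$s02))
  if (grepl("^genotype", nm)) {
    affected <- union(affected, tab$probeset_id[tab$is_de])
  }
}
cat(sprintf("probesets affected in mutants (either sex): %d\n", length(affected)))

# array QC: correlation and Kullback-Leibler similarity between samples
e115 <- design$sample_id[design$stage == "E11.5"]
write_result_table(
  as.data.frame(sample_similarity(m[, e115], "correlation")),
  file.path(out, "sample_correlation_E11.5.tsv"))
write_result_table(
  as.data.frame(sample_similarity(m[, e115], "kl")),
  file.path(out, "sample_kl_E11.5.tsv"))
cat("wrote sample similarity matrices (correlation, symmetrized KL)\n")
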