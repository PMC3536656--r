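#' Run the expression analysis end to end
#'
#' Assembles the study's expression arm on one matrix/design pair:
#'
#' 1. Four pairwise contrasts at `de_stage`, each varying exactly one
#'    factor: sex within controls, sex within mutants, genotype within
#'    XX, genotype within XY.
#' 2. Core-program construction: later-vs-earlier stage contrasts
#'    (`cagp_stages`) in each sex under the control genotype; probesets
#'    up-regulated in both sexes form the core adreno-gonadal program
#'    (CAGP), collapsed to genes with contradictory-gene removal
#'    adjudicated against each sex's time contrast (a gene removed in
#'    either is removed).
#' 3. Mutant-affected set: probesets down-regulated (dko vs control) in
#'    either sex at `de_stage`, collapsed per contrast and unioned.
#' 4. Dimorphic classification from the control sex contrasts at stages
#'    at or after `onset_stage`, mapped to genes (probesets claimed by
#'    both directions are assigned to neither).
#' 5. Overlap report: program sizes, intersections and percentages,
#'    including the externally supplied primed set when given.
#'
#' The run is deterministic (no randomness), so identical inputs give
#' byte-identical outputs.
#'
#' @param matrix probesets x samples log2 matrix.
#' @param design sample design data.frame.
#' @param annotation probeset annotation (probeset_id, gene_id, ...).
#' @param filters a [de_filter_config()]; an `"auto"` floor resolves to
#'   the [global_median()] of `matrix`.
#' @param cagp_stages length-2 character vector, earlier then later
#'   stage, for the core-program step (default E10.5 vs E11.5).
#' @param de_stage stage of the four-way pairwise comparisons.
#' @param onset_stage first stage of dimorphic classification.
#' @param primed optional gene-level [gene_program()] with the external
#'   primed-gene set.
#' @param out_dir optional directory; when given, all DE tables,
#'   programs (GMT), the overlap report and a run log are written there.
#' @return list with elements `de` (named list of flagged DE tables),
#'   `cagp` (probeset- and gene-level programs), `dko_down` (idem),
#'   `dimorphic` (male/female programs and gene-level union), `report`
#'   (overlap data.frame), `intensity_floor`, `log` (character).
#' @export
run_pipeline <- function(matrix, design, annotation,
                         filters = de_filter_config(),
                         cagp_stages = c("E10.5", "E11.5"),
                         de_stage = "E11.5",
                         onset_stage = "E12.5",
                         primed = NULL,
                         out_dir = NULL) {
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    invisible(msg)
  }
  if (identical(filters$intensity_floor, "auto")) {
    filters$intensity_floor <- global_median(matrix)
  }
  note("intensity floor: %.6f", filters$intensity_floor)
  note("matrix: %d probesets x %d samples", nrow(matrix), ncol(matrix))

  cond <- function(sex = NULL, genotype = NULL, stage = NULL) {
    Filter(Negate(is.null), list(sex = sex, genotype = genotype, stage = stage))
  }
  run1 <- function(a, b) run_contrast(matrix, design, a, b, filters)

  de <- list(
    sex_control = run1(cond("XX", "control", de_stage), cond("XY", "control", de_stage)),
    sex_dko     = run1(cond("XX", "dko", de_stage),     cond("XY", "dko", de_stage)),
    genotype_xx = run1(cond("XX", "control", de_stage), cond("XX", "dko", de_stage)),
    genotype_xy = run1(cond("XY", "control", de_stage), cond("XY", "dko", de_stage)),
    time_xx = run1(cond("XX", "control", cagp_stages[1]),
                   cond("XX", "control", cagp_stages[2])),
    time_xy = run1(cond("XY", "control", cagp_stages[1]),
                   cond("XY", "control", cagp_stages[2]))
  )
  for (nm in names(de)) {
    note("contrast %s: %d is_de (%d up, %d down)", nm, sum(de[[nm]]$is_de),
         sum(de[[nm]]$is_de & de[[nm]]$direction %in% "up"),
         sum(de[[nm]]$is_de & de[[nm]]$direction %in% "down"))
  }

  # core adreno-gonadal program
  cagp_ps <- build_upregulated_program(de$time_xx, de$time_xy, "CAGP")
  cagp_xx <- collapse_to_genes(cagp_ps, de$time_xx, annotation)
  cagp_xy <- collapse_to_genes(cagp_ps, de$time_xy, annotation)
  removed <- union(cagp_xx$removed_contradictory, cagp_xy$removed_contradictory)
  cagp_gene <- gene_program(
    "CAGP", setdiff(intersect(cagp_xx$members, cagp_xy$members), removed),
    level = "gene",
    provenance = paste("up-regulated", cagp_stages[1], "->", cagp_stages[2],
                       "in both sexes (control); contradictory genes removed",
                       "against each sex's time contrast"),
    removed_contradictory = removed)
  note("CAGP: %d probesets -> %d genes (%d contradictory removed)",
       length(cagp_ps$members), length(cagp_gene$members), length(removed))

  # probesets down in mutants in either sex
  down_ids <- function(tab) tab$probeset_id[tab$is_de & tab$direction %in% "down"]
  dko_down_ps <- gene_program(
    "dko_down", union(down_ids(de$genotype_xx), down_ids(de$genotype_xy)),
    level = "probeset",
    provenance = paste("is_de down (dko vs control) at", de_stage,
                       "in XX or XY"))
  dd_xx <- collapse_to_genes(
    gene_program("dko_down", down_ids(de$genotype_xx), "probeset"),
    de$genotype_xx, annotation)
  dd_xy <- collapse_to_genes(
    gene_program("dko_down", down_ids(de$genotype_xy), "probeset"),
    de$genotype_xy, annotation)
  dd_removed <- union(dd_xx$removed_contradictory, dd_xy$removed_contradictory)
  dko_down_gene <- gene_program(
    "dko_down", setdiff(union(dd_xx$members, dd_xy$members), dd_removed),
    level = "gene", provenance = dko_down_ps$provenance,
    removed_contradictory = dd_removed)
  note("dko-down: %d probesets -> %d genes", length(dko_down_ps$members),
       length(dko_down_gene$members))

  # dimorphic classification on the control sex contrast, stages >= onset
  dim_stages <- unique(design$stage[stage_index(design$stage) >= stage_index(onset_stage)])
  stage_tabs <- lapply(dim_stages, function(st) {
    run1(cond("XX", "control", st), cond("XY", "control", st))
  })
  names(stage_tabs) <- dim_stages
  dim_ps <- classify_dimorphic(stage_tabs, onset_stage)
  ann_gene <- function(ids) {
    unique(annotation$gene_id[match(ids, annotation$probeset_id)])
  }
  male_g <- setdiff(ann_gene(dim_ps$male$members), NA)
  female_g <- setdiff(ann_gene(dim_ps$female$members), NA)
  both <- intersect(male_g, female_g)  # claimed by both directions: neither
  dimorphic_gene <- gene_program(
    "dimorphic", setdiff(union(male_g, female_g), both), level = "gene",
    provenance = paste("sex-dimorphic (either direction) at stages >=",
                       onset_stage, "; genes claimed by both directions dropped"))
  note("dimorphic: %d male + %d female probesets -> %d genes",
       length(dim_ps$male$members), length(dim_ps$female$members),
       length(dimorphic_gene$members))

  # overlap report on the gene universe of the platform
  universe <- unique(annotation$gene_id)
  universe <- universe[!is.na(universe)]
  dim_cagp <- intersect(cagp_gene$members, dimorphic_gene$members)
  rows <- list()
  add_row <- function(quantity, n, denom_name = NA, denom = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, n = n, denominator = denom_name,
      n_denominator = denom,
      percent = if (!is.na(denom) && denom > 0) 100 * n / denom else NA_real_,
      stringsAsFactors = FALSE)
  }
  add_row("cagp_probesets", length(cagp_ps$members))
  add_row("cagp_genes", length(cagp_gene$members))
  add_row("dko_down_probesets", length(dko_down_ps$members))
  add_row("dko_down_genes", length(dko_down_gene$members))
  add_row("cagp_and_dko_down",
          length(intersect(cagp_gene$members, dko_down_gene$members)),
          "cagp_genes", length(cagp_gene$members))
  add_row("dimorphic_cagp", length(dim_cagp),
          "cagp_genes", length(cagp_gene$members))
  add_row("dimorphic_cagp_and_dko_down",
          length(intersect(dim_cagp, dko_down_gene$members)),
          "dimorphic_cagp", length(dim_cagp))
  if (!is.null(primed)) {
    if (primed$level != "gene") stop("primed program must be gene level")
    add_row("primed_genes", length(primed$members))
    add_row("primed_and_dko_down",
            length(intersect(primed$members, dko_down_gene$members)),
            "primed_genes", length(primed$members))
  }
  report <- do.call(rbind, rows)

  result <- list(de = de, cagp = list(probeset = cagp_ps, gene = cagp_gene),
                 dko_down = list(probeset = dko_down_ps, gene = dko_down_gene),
                 dimorphic = list(male = dim_ps$male, female = dim_ps$female,
                                  gene = dimorphic_gene),
                 report = report, intensity_floor = filters$intensity_floor,
                 universe = universe, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(de)) {
      write_result_table(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
    }
    write_gene_sets(list(cagp_gene, dko_down_gene, dimorphic_gene),
                    file.path(out_dir, "programs.gmt"))
    write_result_table(report, file.path(out_dir, "overlap_report.tsv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' Recovery of a planted set by a detected member list
#'
#' Sensitivity (fraction of planted positives recovered) and realized
#' false-discovery proportion (fraction of detected members that are
#' not planted positives).
#'
#' @param detected character vector of detected ids.
#' @param planted character vector of planted positive ids.
#' @return list with n_detected, n_planted, n_true, sensitivity, fdp.
#' @export
evaluate_recovery <- function(detected, planted) {
  detected <- unique(detected)
  planted <- unique(planted)
  tp <- length(intersect(detected, planted))
  list(
    n_detected = length(detected),
    n_planted = length(planted),
    n_true = tp,
    sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
    fdp = if (length(detected)) 1 - tp / length(detected) else 0
  )
}
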