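#' Construct a gene program object
#'
#' A named set of probeset- or gene-level identifiers with provenance.
#'
#' @param name program name.
#' @param members character vector of member ids (deduplicated,
#'   insertion order kept).
#' @param level "probeset" or "gene".
#' @param provenance free-text rule description.
#' @param removed_contradictory ids removed by the contradictory-probeset
#'   rule (gene level only); must be disjoint from members.
#' @return list of class `"gene_program"`.
#' @export
gene_program <- function(name, members, level = c("probeset", "gene"),
                         provenance = "", removed_contradictory = character()) {
  level <- match.arg(level)
  members <- unique(as.character(members))
  removed_contradictory <- unique(as.character(removed_contradictory))
  if (length(intersect(members, removed_contradictory))) {
    stop("members and removed_contradictory must be disjoint")
  }
  structure(list(name = name, level = level, members = members,
                 provenance = provenance,
                 removed_contradictory = removed_contradictory),
            class = "gene_program")
}

#' @export
print.gene_program <- function(x, ...) {
  cat(sprintf("gene program \"%s\" (%s level): %d members", x$name, x$level,
              length(x$members)))
  if (length(x$removed_contradictory)) {
    cat(sprintf(", %d removed as contradictory", length(x$removed_contradictory)))
  }
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

.check_flagged <- function(table, arg) {
  if (!all(c("is_de", "direction") %in% names(table))) {
    stop(arg, " lacks filter flags; run apply_de_filters() first")
  }
}

#' Probesets up-regulated in both of two contrasts
#'
#' Builds the core-program candidate set: probesets flagged
#' differentially expressed with direction "up" in *both* supplied
#' tables (typically the XX and XY later-vs-earlier stage contrasts).
#'
#' @param de_xx,de_xy flagged DE tables over the same probeset universe.
#' @param name program name (default "CAGP").
#' @return a probeset-level [gene_program()].
#' @export
build_upregulated_program <- function(de_xx, de_xy, name = "CAGP") {
  .check_flagged(de_xx, "de_xx")
  .check_flagged(de_xy, "de_xy")
  if (!setequal(de_xx$probeset_id, de_xy$probeset_id)) {
    stop("the two DE tables cover different probeset universes")
  }
  de_xy <- de_xy[match(de_xx$probeset_id, de_xy$probeset_id), ]
  up_both <- de_xx$is_de & de_xx$direction %in% "up" &
    de_xy$is_de & de_xy$direction %in% "up"
  gene_program(
    name, de_xx$probeset_id[up_both], level = "probeset",
    provenance = paste("probesets is_de and up in both contrasts;",
                       "universe of", nrow(de_xx), "probesets")
  )
}

#' Classify probesets as male- or female-dimorphic
#'
#' Given per-stage DE tables for the sex contrast (condition A = XX,
#' condition B = XY, so positive log2_fc means higher in XY), a probeset
#' is male-dimorphic when it is significantly XY-up at one or more
#' stages at or after the onset stage and never significantly XX-up at
#' any such stage; female-dimorphic symmetrically. Probesets significant
#' in both directions at different stages are assigned to neither.
#'
#' @param stage_tables named list of flagged DE tables, names are stages.
#' @param onset_stage first stage considered (default "E12.5").
#' @return list with elements `male` and `female`, each a
#'   probeset-level [gene_program()].
#' @export
classify_dimorphic <- function(stage_tables, onset_stage = "E12.5") {
  if (is.null(names(stage_tables)) || any(!nzchar(names(stage_tables)))) {
    stop("stage_tables must be a named list (names = stages)")
  }
  onset_i <- stage_index(onset_stage)
  keep <- stage_index(names(stage_tables)) >= onset_i
  if (!any(keep)) stop("no stage tables at or after onset stage ", onset_stage)
  tabs <- stage_tables[keep]
  for (nm in names(tabs)) .check_flagged(tabs[[nm]], nm)
  ids <- tabs[[1]]$probeset_id
  for (nm in names(tabs)) {
    if (!setequal(tabs[[nm]]$probeset_id, ids)) {
      stop("stage table ", nm, " covers a different probeset universe")
    }
  }
  male_any <- female_any <- setNames(rep(FALSE, length(ids)), ids)
  for (tab in tabs) {
    tab <- tab[match(ids, tab$probeset_id), ]
    male_any <- male_any | (tab$is_de & tab$direction %in% "up")
    female_any <- female_any | (tab$is_de & tab$direction %in% "down")
  }
  stages_used <- paste(names(tabs), collapse = ", ")
  list(
    male = gene_program(
      "dimorphic_male", ids[male_any & !female_any], level = "probeset",
      provenance = paste("XY-up is_de at >=1 stage in {", stages_used,
                         "} and never XX-up is_de")),
    female = gene_program(
      "dimorphic_female", ids[female_any & !male_any], level = "probeset",
      provenance = paste("XX-up is_de at >=1 stage in {", stages_used,
                         "} and never XY-up is_de"))
  )
}

#' Collapse a probeset-level program to genes
#'
#' A gene enters the collapsed program when at least one of its
#' annotated probesets is a program member and the gene's probesets are
#' not contradictory in the reference DE table. The contradiction rule
#' is significance-based: a gene is contradictory when its annotated
#' probesets include significantly up- *and* significantly
#' down-regulated members in `full_de`; such genes are listed in
#' `removed_contradictory`. Unannotated member probesets are dropped and
#' counted in the provenance.
#'
#' @param program a probeset-level [gene_program()].
#' @param full_de the flagged DE table over the full probeset universe
#'   used to adjudicate contradictions.
#' @param annotation data.frame with columns probeset_id, gene_id.
#' @return a gene-level [gene_program()].
#' @export
collapse_to_genes <- function(program, full_de, annotation) {
  stopifnot(inherits(program, "gene_program"))
  if (program$level != "probeset") stop("program must be at probeset level")
  .check_flagged(full_de, "full_de")
  if (anyDuplicated(annotation$probeset_id)) {
    stop("annotation maps some probeset to more than one gene")
  }
  ann <- annotation[, c("probeset_id", "gene_id")]
  member_gene <- ann$gene_id[match(program$members, ann$probeset_id)]
  n_unannotated <- sum(is.na(member_gene))
  candidate_genes <- unique(member_gene[!is.na(member_gene)])

  de <- full_de[full_de$is_de & !is.na(full_de$direction), ]
  de_gene <- ann$gene_id[match(de$probeset_id, ann$probeset_id)]
  updn <- split(de$direction, de_gene)
  contradictory <- names(updn)[vapply(updn, function(d) length(unique(d)) > 1,
                                      logical(1))]
  removed <- intersect(candidate_genes, contradictory)
  members <- setdiff(candidate_genes, contradictory)
  gene_program(
    program$name, members, level = "gene",
    provenance = paste0(
      program$provenance,
      "; collapsed from ", length(program$members), " member probesets (",
      n_unannotated, " unannotated, dropped); significance-based ",
      "contradiction rule removed ", length(removed), " gene(s)"),
    removed_contradictory = removed
  )
}

#' Hypergeometric overlap of two programs
#'
#' Counts the intersection of two same-level programs against a finite
#' universe and reports expected overlap and hypergeometric tail
#' probabilities: `p_over = P(X >= n_observed)` and
#' `p_under = P(X <= n_observed)` for
#' `X ~ Hypergeometric(n_universe, n_A, n_B)`.
#'
#' @param program_a,program_b [gene_program()]s of the same level, or
#'   plain character vectors of ids.
#' @param universe character vector of all ids in the universe.
#' @return list of class `"overlap_result"` with n_universe, n_a, n_b,
#'   n_observed, n_expected, p_over, p_under, percent_of_a.
#' @export
overlap_programs <- function(program_a, program_b, universe) {
  a <- if (inherits(program_a, "gene_program")) program_a$members else unique(program_a)
  b <- if (inherits(program_b, "gene_program")) program_b$members else unique(program_b)
  universe <- unique(universe)
  out_a <- setdiff(a, universe)
  out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    stop("members outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  }
  n <- length(universe)
  na <- length(a); nb <- length(b)
  obs <- length(intersect(a, b))
  structure(list(
    n_universe = n, n_a = na, n_b = nb, n_observed = obs,
    n_expected = na * nb / n,
    p_over = phyper(obs - 1, nb, n - nb, na, lower.tail = FALSE),
    p_under = phyper(obs, nb, n - nb, na),
    percent_of_a = if (na > 0) 100 * obs / na else NA_real_
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d observed (%.2f expected) | A = %d, B = %d, universe = %d\n",
    x$n_observed, x$n_expected, x$n_a, x$n_b, x$n_universe))
  cat(sprintf("  p_over = %.3g, p_under = %.3g, %.1f%% of A\n",
              x$p_over, x$p_under, x$percent_of_a))
  invisible(x)
}

#' Percentage of a set covered by an overlap
#'
#' @param n_observed overlap count (0..n_total).
#' @param n_total denominator (> 0).
#' @param rounding "none" (default) or "nearest" integer.
#' @return `100 * n_observed / n_total`, optionally rounded.
#' @export
percent_overlap <- function(n_observed, n_total, rounding = c("none", "nearest")) {
  rounding <- match.arg(rounding)
  if (n_total <= 0) stop("n_total must be positive")
  if (n_observed < 0 || n_observed > n_total) {
    stop("n_observed must lie in [0, n_total]")
  }
  pct <- 100 * n_observed / n_total
  if (rounding == "nearest") round(pct) else pct
}

#' Cluster expression profiles
#'
#' Euclidean K-means (best of `nstart` seeded restarts by total
#' within-cluster sum of squares) on optionally row-standardized
#' profiles; agglomerative complete-linkage clustering is available as
#' an alternative. Deterministic under a fixed seed.
#'
#' @param matrix probesets x samples numeric matrix.
#' @param k number of clusters (1..nrow).
#' @param seed integer RNG seed.
#' @param standardize center and scale each row first (constant rows
#'   become all-zero profiles).
#' @param method "kmeans" or "complete" (complete-linkage hierarchical,
#'   cut at k).
#' @param nstart random restarts for K-means.
#' @return list with `cluster` (named integer vector), `centers`
#'   (k x samples matrix), `method`, and `tot_withinss` (kmeans only).
#' @export
kmeans_profiles <- function(matrix, k, seed = 1, standardize = FALSE,
                            method = c("kmeans", "complete"), nstart = 10) {
  method <- match.arg(method)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(matrix)) stop("k exceeds the number of probesets")
  x <- matrix
  if (standardize) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, sd)
    sdv[sdv == 0] <- 1
    x <- (x - mu) / sdv
  }
  if (method == "kmeans") {
    set.seed(seed)
    fit <- kmeans(x, centers = k, nstart = nstart, iter.max = 100)
    cl <- setNames(fit$cluster, rownames(x))
    centers <- fit$centers
    tot <- fit$tot.withinss
  } else {
    cl <- stats::cutree(hclust(dist(x), method = "complete"), k = k)
    cl <- setNames(as.integer(cl), rownames(x))
    centers <- do.call(rbind, lapply(split(seq_along(cl), cl), function(i) {
      colMeans(x[i, , drop = FALSE])
    }))
    tot <- NA_real_
  }
  list(cluster = cl, centers = centers, method = method, tot_withinss = tot)
}

# gene -> term long table from a probeset annotation with a
# semicolon-separated `terms` column; terms are unioned over probesets.
.gene_terms <- function(annotation) {
  if (!"terms" %in% names(annotation)) {
    stop("annotation has no 'terms' column")
  }
  keep <- !is.na(annotation$gene_id) & !is.na(annotation$terms) &
    nzchar(annotation$terms)
  ann <- annotation[keep, ]
  terms <- strsplit(ann$terms, "[;,]")
  long <- data.frame(
    gene_id = rep(ann$gene_id, lengths(terms)),
    term = trimws(unlist(terms)),
    stringsAsFactors = FALSE
  )
  unique(long[nzchar(long$term), ])
}

#' Term over- and under-representation in a gene set
#'
#' For every annotation term present in the universe, compares the
#' observed member count with the hypergeometric expectation
#' `|members| * K / N` (K = universe genes carrying the term) and
#' reports both tail probabilities with BH adjustment across terms,
#' separately for over- and under-representation.
#'
#' @param members character vector of member gene ids (subset of
#'   universe).
#' @param universe character vector of universe gene ids.
#' @param annotation probeset annotation data.frame with gene_id and a
#'   semicolon-separated `terms` column (terms are unioned per gene).
#' @return data.frame: term, n_with_term, n_observed, n_expected,
#'   p_over, p_under, q_over, q_under; one row per term, ordered by
#'   p_over.
#' @export
term_enrichment <- function(members, universe, annotation) {
  universe <- unique(universe)
  members <- unique(members)
  if (length(universe) == 0) stop("empty universe")
  if (length(setdiff(members, universe))) {
    stop("members must be a subset of the universe")
  }
  gt <- .gene_terms(annotation)
  gt <- gt[gt$gene_id %in% universe, ]
  if (nrow(gt) == 0) stop("no terms annotate the universe")
  n <- length(universe)
  na <- length(members)
  term_univ <- split(gt$gene_id, gt$term)
  res <- do.call(rbind, lapply(names(term_univ), function(tm) {
    k <- length(unique(term_univ[[tm]]))
    obs <- length(intersect(members, term_univ[[tm]]))
    data.frame(
      term = tm, n_with_term = k, n_observed = obs,
      n_expected = na * k / n,
      p_over = phyper(obs - 1, k, n - k, na, lower.tail = FALSE),
      p_under = phyper(obs, k, n - k, na),
      stringsAsFactors = FALSE
    )
  }))
  res$q_over <- bh_adjust(res$p_over)
  res$q_under <- bh_adjust(res$p_under)
  res[order(res$p_over, res$term), ]
}
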