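.ns_classes <- c("endogenous", "reference_candidate", "negative", "positive")

#' Validate a NanoString count table
#'
#' Checks the long-format count table: required columns, known probe
#' classes, non-negative integer counts, at most one record per
#' (probe, sample) pair, and at least 2 negative and 2 positive probes
#' per sample.
#'
#' @param counts data.frame with columns probe_id, probe_class,
#'   sample_id, count.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_nanostring_counts <- function(counts) {
  need <- c("probe_id", "probe_class", "sample_id", "count")
  if (!all(need %in% names(counts))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  bad_class <- setdiff(unique(counts$probe_class), .ns_classes)
  if (length(bad_class)) {
    stop("unknown probe_class value(s): ", paste(bad_class, collapse = ", "))
  }
  if (any(!is.finite(counts$count)) || any(counts$count < 0)) {
    stop("counts must be non-negative")
  }
  if (anyDuplicated(counts[, c("probe_id", "sample_id")])) {
    stop("duplicated (probe, sample) records")
  }
  per_sample <- split(counts$probe_class, counts$sample_id)
  for (s in names(per_sample)) {
    if (sum(per_sample[[s]] == "negative") < 2 ||
        sum(per_sample[[s]] == "positive") < 2) {
      stop("sample ", s, " has fewer than 2 negative or positive probes")
    }
  }
  counts
}

# long table -> probes x samples matrix for one or more classes
.ns_matrix <- function(counts, classes = .ns_classes) {
  sub <- counts[counts$probe_class %in% classes, ]
  probes <- unique(sub$probe_id)
  samples <- unique(counts$sample_id)
  m <- matrix(NA_real_, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(sub$probe_id, probes), match(sub$sample_id, samples))] <- sub$count
  if (anyNA(m)) stop("missing (probe, sample) combinations for classes: ",
                     paste(classes, collapse = ", "))
  m
}

#' Background-correct NanoString counts
#'
#' Per sample, the background threshold is the mean plus two standard
#' deviations (sample SD, n-1 denominator) of the negative-control
#' counts; the threshold is subtracted from every raw count and any
#' result below 1 is fixed to 1. Negative probes are dropped from the
#' corrected output.
#'
#' @param counts long count table (see [validate_nanostring_counts()]).
#' @return list of class `"ns_background"` with `counts` (corrected long
#'   table, negatives removed, `count` now numeric) and `background`
#'   (per-sample data.frame: sample_id, neg_mean, neg_sd, threshold).
#' @export
background_correct <- function(counts) {
  counts <- validate_nanostring_counts(counts)
  neg <- counts[counts$probe_class == "negative", ]
  by_sample <- split(neg$count, neg$sample_id)
  bg <- data.frame(
    sample_id = names(by_sample),
    neg_mean = vapply(by_sample, mean, 0),
    neg_sd = vapply(by_sample, sd, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bg$threshold <- bg$neg_mean + 2 * bg$neg_sd
  out <- counts[counts$probe_class != "negative", ]
  thr <- bg$threshold[match(out$sample_id, bg$sample_id)]
  out$count <- pmax(out$count - thr, 1)
  structure(list(counts = out, background = bg), class = "ns_background")
}

#' Positive-control quality assessment
#'
#' Per-sample mean of the positive-control raw counts; the run passes QC
#' when the ratio of the highest to the lowest per-sample average is
#' below 3. QC uses raw (pre-background) counts.
#'
#' @param counts long count table.
#' @return list of class `"ns_qc"`: `sample_means` (data.frame),
#'   `pos_ratio`, `pass`.
#' @export
positive_control_qc <- function(counts) {
  counts <- validate_nanostring_counts(counts)
  pos <- counts[counts$probe_class == "positive", ]
  by_sample <- split(pos$count, pos$sample_id)
  means <- vapply(by_sample, mean, 0)
  if (any(means == 0)) {
    stop("zero positive-control average in sample(s): ",
         paste(names(means)[means == 0], collapse = ", "))
  }
  ratio <- max(means) / min(means)
  structure(list(
    sample_means = data.frame(sample_id = names(means), pos_mean = unname(means),
                              stringsAsFactors = FALSE),
    pos_ratio = ratio,
    pass = ratio < 3
  ), class = "ns_qc")
}

# mean over other candidates of the SD across samples of pairwise
# log2 ratios; x is candidates x samples, log2-transformed outside
.genorm_m <- function(l2) {
  n <- nrow(l2)
  vapply(seq_len(n), function(j) {
    mean(vapply(setdiff(seq_len(n), j), function(k) sd(l2[j, ] - l2[k, ]), 0))
  }, 0)
}

#' geNorm stability ranking of reference candidates
#'
#' Computes each candidate's stability value M (the mean, over all other
#' candidates, of the standard deviation across samples of their
#' pairwise log2 count ratios) and iteratively excludes the
#' least-stable candidate, recomputing M each round, down to a final
#' pair. Ties on M, including the final pair, are resolved by probe id
#' order (the lexicographically later id is excluded first). The
#' original pairwise-variation statistics `V(k/k+1)` between successive
#' normalization factors are computed and reported for reference but do
#' not drive selection.
#'
#' @param x candidates x samples numeric matrix of background-corrected
#'   counts (all > 0), or an `"ns_background"` / long count table from
#'   which the `reference_candidate` class is taken.
#' @return list of class `"genorm_result"`: `stability` (data.frame
#'   probe_id, m with the initial all-candidate M values), `exclusion`
#'   (data.frame step, probe_id, m_at_removal), `ranking` (ids from
#'   first excluded to the final pair) and `pairwise_variation`.
#' @export
genorm_rank <- function(x) {
  if (inherits(x, "ns_background")) x <- x$counts
  if (is.data.frame(x)) x <- .ns_matrix(x, "reference_candidate")
  if (nrow(x) < 3) stop("geNorm needs at least 3 candidates")
  if (ncol(x) < 2) stop("geNorm needs at least 2 samples")
  if (any(x <= 0)) {
    stop("zero or negative counts among candidates; background-correct first")
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  l2 <- log2(x)

  m0 <- .genorm_m(l2)
  stability <- data.frame(probe_id = rownames(x), m = m0,
                          stringsAsFactors = FALSE)

  remaining <- rownames(x)
  steps <- list()
  step <- 0L
  while (length(remaining) > 2) {
    m <- .genorm_m(l2[remaining, , drop = FALSE])
    worst <- max(m)
    # ties resolved by probe id order: later id excluded first
    drop_id <- max(remaining[m == worst])
    step <- step + 1L
    steps[[step]] <- data.frame(step = step, probe_id = drop_id,
                                m_at_removal = worst, stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, drop_id)
  }
  m_final <- .genorm_m(l2[remaining, , drop = FALSE])
  for (i in order(remaining)) {
    step <- step + 1L
    steps[[step]] <- data.frame(step = step, probe_id = remaining[i],
                                m_at_removal = m_final[i],
                                stringsAsFactors = FALSE)
  }
  exclusion <- do.call(rbind, steps)

  # V(k/k+1): sd across samples of log2(NF_k / NF_{k+1}), NF_k being the
  # per-sample geometric mean of the k most stable candidates
  rank_best_last <- exclusion$probe_id
  n <- length(rank_best_last)
  pv <- c()
  if (n >= 3) {
    for (k in 2:(n - 1)) {
      top_k <- rank_best_last[(n - k + 1):n]
      top_k1 <- rank_best_last[(n - k):n]
      nf_k <- colMeans(l2[top_k, , drop = FALSE])
      nf_k1 <- colMeans(l2[top_k1, , drop = FALSE])
      pv[sprintf("V%d/%d", k, k + 1)] <- sd(nf_k - nf_k1)
    }
  }

  structure(list(stability = stability, exclusion = exclusion,
                 ranking = rank_best_last, pairwise_variation = pv),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm ranking (first excluded -> most stable):\n  ",
      paste(x$ranking, collapse = " < "), "\n")
  invisible(x)
}

#' Select the k most stable reference genes
#'
#' The k candidates surviving longest in the geNorm exclusion order
#' (the study fixed k = 6).
#'
#' @param result a [genorm_rank()] result.
#' @param k number of references to keep.
#' @return character vector of probe ids, most stable last.
#' @export
select_references <- function(result, k = 6) {
  stopifnot(inherits(result, "genorm_result"))
  n <- length(result$ranking)
  if (k > n) stop("k exceeds the number of candidates")
  result$ranking[(n - k + 1):n]
}

#' Normalize counts by the geometric mean of reference genes
#'
#' Per sample, computes the geometric mean of the (background-corrected)
#' reference counts and rescales every count by `mean(g) / g_s`, where
#' the rescale constant is the arithmetic mean across samples of the
#' per-sample geometric means; afterwards the reference geometric mean
#' is identical in every sample and the output stays on a count-like
#' scale. Invariant to global per-sample scaling of all counts.
#'
#' @param corrected long corrected count table or an `"ns_background"`
#'   result.
#' @param references character vector of reference probe ids; each must
#'   be present in every sample with count >= 1.
#' @return list of class `"ns_normalized"`: `counts` (long table) and
#'   `factors` (sample_id, geo_mean, scale).
#' @export
reference_normalize <- function(corrected, references) {
  if (inherits(corrected, "ns_background")) corrected <- corrected$counts
  samples <- unique(corrected$sample_id)
  ref <- corrected[corrected$probe_id %in% references, ]
  have <- table(ref$sample_id)
  if (length(setdiff(references, unique(ref$probe_id))) > 0 ||
      any(!(samples %in% names(have))) ||
      any(have[samples] < length(references))) {
    stop("some reference probes are missing in some samples")
  }
  if (any(ref$count < 1)) stop("reference counts below 1; background-correct first")
  g <- vapply(split(ref$count, ref$sample_id)[samples], geometric_mean, 0)
  rescale <- mean(g)
  factors <- data.frame(sample_id = samples, geo_mean = unname(g),
                        scale = rescale / unname(g), stringsAsFactors = FALSE)
  out <- corrected
  out$count <- out$count * factors$scale[match(out$sample_id, factors$sample_id)]
  structure(list(counts = out, factors = factors), class = "ns_normalized")
}

#' Per-gene sources-of-variation ANOVA
#'
#' Fits, for every gene, a main-effects ANOVA of log2 normalized counts
#' on developmental stage (time), genotype and sex, and decomposes the
#' total sum of squares. Sums of squares are sequential (type I) in the
#' order stage, genotype, sex; on balanced designs all SS types
#' coincide and component plus residual SS equal the total SS. A factor
#' with a single level in the design is dropped with a warning.
#'
#' @param values genes x samples numeric matrix of log2 values, or an
#'   `"ns_normalized"` result (its endogenous probes are log2-ed).
#' @param design sample design with columns sample_id, stage, genotype,
#'   sex.
#' @param log2_transform log2 the values first (applied when a
#'   normalized-count object is given; counts are floored at 1).
#' @return long data.frame: probe_id, term (stage/genotype/sex/
#'   residual), df, ss, frac_ss (share of total SS), statistic, p_value.
#' @export
anova_sources <- function(values, design, log2_transform = inherits(values, "ns_normalized")) {
  if (inherits(values, "ns_normalized")) {
    values <- .ns_matrix(values$counts, "endogenous")
  }
  if (log2_transform) values <- log2(pmax(values, 1))
  idx <- match(colnames(values), design$sample_id)
  if (anyNA(idx)) stop("samples missing from design: ",
                       paste(colnames(values)[is.na(idx)], collapse = ", "))
  d <- design[idx, ]
  factors <- c("stage", "genotype", "sex")
  levels_n <- vapply(factors, function(f) length(unique(d[[f]])), 0L)
  if (any(levels_n < 2)) {
    warning("dropping single-level factor(s): ",
            paste(factors[levels_n < 2], collapse = ", "))
    factors <- factors[levels_n >= 2]
  }
  if (length(factors) == 0) stop("no factor with at least 2 levels")
  fml <- stats::as.formula(paste("y ~", paste(factors, collapse = " + ")))
  dat <- data.frame(lapply(d[factors], factor))
  res <- lapply(rownames(values), function(g) {
    dat$y <- values[g, ]
    a <- anova(lm(fml, data = dat))
    ss <- a[["Sum Sq"]]
    tot <- sum(ss)
    data.frame(
      probe_id = g,
      term = c(factors, "residual"),
      df = a[["Df"]],
      ss = ss,
      frac_ss = if (tot > 0) ss / tot else rep(NA_real_, length(ss)),
      statistic = a[["F value"]],
      p_value = a[["Pr(>F)"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
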