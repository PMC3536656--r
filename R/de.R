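#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) onto the common distribution of
#' cross-sample row-rank means, the usual stand-in when probe-level
#' summarization has already been done elsewhere. Wraps
#' [limma::normalizeQuantiles()] with tie averaging; row and column
#' identifiers are preserved and the operation is idempotent.
#'
#' @param matrix numeric matrix, probesets x samples; no missing values.
#' @return matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stop("input must be a numeric matrix")
  if (ncol(matrix) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(matrix) || any(!is.finite(matrix))) stop("matrix contains missing or non-finite values")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Global median intensity of an expression matrix
#'
#' The median over all matrix entries; for an even entry count the mean
#' of the two middle order statistics. This is the dataset-wide
#' intensity floor of the differential-expression filter (the study's
#' own datasets have global medians 6.295062 and 4.109341; these are
#' dataset-specific constants, not defaults).
#'
#' @param matrix numeric matrix.
#' @return a single number.
#' @export
global_median <- function(matrix) {
  if (length(matrix) == 0) stop("empty matrix has no median")
  median(as.numeric(matrix))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' Direct summation of `sum(p * log(p / q))` with the conventions
#' `0 * log(0/q) = 0` and `p > 0, q = 0 -> Inf`. Natural log.
#'
#' @param p,q non-negative vectors of equal length summing to 1.
#' @return a single number (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("p and q must each sum to 1")
  }
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Symmetrized Kullback-Leibler divergence
#'
#' `0.5 * (KL(p || q) + KL(q || p))`.
#' @inheritParams kl_divergence
#' @export
symmetric_kl <- function(p, q) 0.5 * (kl_divergence(p, q) + kl_divergence(q, p))

#' Sample-to-sample similarity matrix
#'
#' Pairwise Pearson correlation of sample columns, or a symmetrized
#' Kullback-Leibler divergence between per-sample intensity histograms
#' on a shared equal-width bin grid over the pooled value range. Empty
#' histogram bins receive a Laplace-style pseudocount so divergences
#' stay finite; the two-distribution primitive without smoothing is
#' [kl_divergence()]. A constant sample has no defined correlation: its
#' entries are `NA` and a warning names the sample.
#'
#' @param matrix probesets x samples numeric matrix, >= 2 samples.
#' @param method "correlation" or "kl".
#' @param bins number of shared histogram bins (kl only).
#' @param pseudocount smoothing count added to every bin (kl only).
#' @return symmetric samples x samples matrix; diagonal 1 for
#'   correlation, 0 for kl.
#' @export
sample_similarity <- function(matrix, method = c("correlation", "kl"),
                              bins = 64, pseudocount = 0.5) {
  method <- match.arg(method)
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  if (method == "correlation") {
    sds <- apply(matrix, 2, sd)
    if (any(sds == 0)) {
      warning("correlation undefined for constant sample(s): ",
              paste(colnames(matrix)[sds == 0], collapse = ", "))
    }
    out <- suppressWarnings(cor(matrix))
    diag(out)[sds > 0] <- 1
    return(out)
  }
  rng <- range(matrix)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  prob <- apply(matrix, 2, function(x) {
    h <- hist(x, breaks = breaks, plot = FALSE)$counts + pseudocount
    h / sum(h)
  })
  n <- ncol(matrix)
  out <- base::matrix(0, n, n, dimnames = list(colnames(matrix), colnames(matrix)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- symmetric_kl(prob[, i], prob[, j])
    }
  }
  out
}

# Select samples matching every field of a condition spec, e.g.
# list(sex = "XX", genotype = "control", stage = "E11.5").
.match_condition <- function(design, condition) {
  keep <- rep(TRUE, nrow(design))
  for (f in names(condition)) {
    if (!f %in% names(design)) stop("unknown design field: ", f)
    keep <- keep & design[[f]] %in% condition[[f]]
  }
  design$sample_id[keep]
}

.condition_label <- function(condition) {
  paste(sprintf("%s=%s", names(condition),
                vapply(condition, paste, "", collapse = "/")), collapse = ",")
}

#' Per-probeset summaries for a two-condition comparison
#'
#' Computes per-probeset condition means, the two-group pooled residual
#' variance and its degrees of freedom `n_A + n_B - 2`. Conditions are
#' named lists of design-field values; each must select at least two
#' replicate samples.
#'
#' @param matrix probesets x samples log2 matrix.
#' @param design sample design data.frame (sample_id, sex, genotype,
#'   stage, replicate).
#' @param condition_a,condition_b named lists selecting the two sample
#'   groups, e.g. `list(sex = "XX", genotype = "control", stage = "E11.5")`.
#' @return data.frame with columns probeset_id, n_a, n_b, mean_a,
#'   mean_b, log2_fc (= mean_b - mean_a), s2 (pooled variance), df.
#' @export
condition_summaries <- function(matrix, design, condition_a, condition_b) {
  sa <- .match_condition(design, condition_a)
  sb <- .match_condition(design, condition_b)
  if (length(sa) < 2) stop("condition A (", .condition_label(condition_a),
                           ") has fewer than 2 replicates")
  if (length(sb) < 2) stop("condition B (", .condition_label(condition_b),
                           ") has fewer than 2 replicates")
  missing <- setdiff(c(sa, sb), colnames(matrix))
  if (length(missing)) stop("samples absent from matrix: ",
                            paste(missing, collapse = ", "))
  xa <- matrix[, sa, drop = FALSE]
  xb <- matrix[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  data.frame(
    probeset_id = rownames(matrix),
    n_a = na, n_b = nb,
    mean_a = ma, mean_b = mb,
    log2_fc = mb - ma,
    s2 = (ssa + ssb) / df,
    df = df,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Invert the trigamma function by monotone bisection. trigamma is
# strictly decreasing on (0, Inf) with range (0, Inf).
.trigamma_inverse <- function(y, cap = 1e8, rel_tol = 1e-8) {
  if (y <= trigamma(cap)) return(Inf)
  lo <- 1e-8
  hi <- cap
  while ((hi - lo) > rel_tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Fits the scaled inverse chi-square prior of the moderated t-statistic
#' by moment matching on the log residual variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))`
#' (inverted by monotone bisection) and the prior variance is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the trigamma
#' equation has no positive solution (log-variance scatter no larger
#' than sampling noise) `d0` is reported as `Inf` and `s0^2` is the
#' arithmetic mean of the variances (the scale of the limiting
#' point-mass prior, under which each `s2_g` is an unbiased draw).
#' Zero variances are excluded from the moment fit and counted.
#'
#' @param s2 per-probeset residual variances.
#' @param df their degrees of freedom (recycled if scalar).
#' @return list of class `"moderation_params"` with `d0`, `s02`,
#'   `n_used`, `n_zero`.
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  if (all(s2 == 0)) stop("all residual variances are zero; moderation undefined")
  ok <- is.finite(s2) & s2 > 0 & df > 0
  n_zero <- sum(s2 == 0)
  if (sum(ok) < 2) stop("need at least 2 positive residual variances")
  d <- df[ok]
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    half_d0 <- .trigamma_inverse(evar)
  } else {
    half_d0 <- Inf
  }
  if (is.finite(half_d0)) {
    d0 <- 2 * half_d0
    s02 <- exp(emean + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  structure(list(d0 = d0, s02 = s02, n_used = sum(ok), n_zero = n_zero),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat("moderation parameters: d0 =", format(x$d0), " s0^2 =", format(x$s02),
      "\n  fitted on", x$n_used, "variances (", x$n_zero, "zero, excluded )\n")
  invisible(x)
}

#' Moderated two-condition t-test
#'
#' Shrinks each probeset's pooled variance toward the prior,
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and tests
#' `mean_b - mean_a` with `t = log2_fc / sqrt(s2_post * (1/n_a + 1/n_b))`
#' against a t distribution on `d0 + df` degrees of freedom (a normal
#' reference when `d0` is unbounded). `d0 = 0` is accepted and
#' reproduces the ordinary pooled two-sample t-test exactly. BH-adjusted
#' q-values are attached; filter flags are set by [apply_de_filters()].
#'
#' @param summaries output of [condition_summaries()].
#' @param params a `"moderation_params"` object (or list with `d0`, `s02`).
#' @return the summaries data.frame extended with s2_post, t, p_value,
#'   q_value.
#' @export
moderated_contrast_test <- function(summaries, params) {
  need <- c("mean_a", "mean_b", "log2_fc", "s2", "df", "n_a", "n_b")
  if (!all(need %in% names(summaries))) {
    stop("summaries must contain: ", paste(need, collapse = ", "))
  }
  if (any(summaries$n_a < 2) || any(summaries$n_b < 2)) {
    stop("each condition needs at least 2 replicates")
  }
  d0 <- params$d0
  s02 <- params$s02
  if (d0 < 0) stop("d0 must be non-negative")
  if (s02 <= 0) stop("s0^2 must be positive")
  s2_post <- if (is.infinite(d0)) {
    rep(s02, nrow(summaries))
  } else {
    (d0 * s02 + summaries$df * summaries$s2) / (d0 + summaries$df)
  }
  se <- sqrt(s2_post * (1 / summaries$n_a + 1 / summaries$n_b))
  t <- ifelse(se > 0, summaries$log2_fc / se,
              ifelse(summaries$log2_fc == 0, 0,
                     sign(summaries$log2_fc) * Inf))
  df_total <- d0 + summaries$df
  p <- 2 * pt(-abs(t), df = df_total)
  out <- summaries
  out$s2_post <- s2_post
  out$t <- t
  out$p_value <- p
  out$q_value <- bh_adjust(p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`,
#' returned in input order (delegates to [stats::p.adjust()] after
#' validating the inputs).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential-expression filter configuration
#'
#' The study's three-part retention rule: intensity strictly above a
#' global-median floor in at least one condition mean, absolute fold
#' change of at least `fc_threshold` (applied as
#' `|log2_fc| >= log2(fc_threshold)`), and BH-adjusted p at most `alpha`.
#'
#' @param fc_threshold fold-change ratio threshold (>= 1; default 1.5).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param intensity_floor log2 intensity floor, or `"auto"` to use the
#'   [global_median()] of the matrix at filtering time.
#' @return list of class `"de_filter_config"`.
#' @export
de_filter_config <- function(fc_threshold = 1.5, alpha = 0.01,
                             intensity_floor = "auto") {
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!identical(intensity_floor, "auto") && !is.numeric(intensity_floor)) {
    stop("intensity_floor must be numeric or \"auto\"")
  }
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 intensity_floor = intensity_floor),
            class = "de_filter_config")
}

#' Apply the three-part differential-expression filter
#'
#' Sets `passes_intensity` (max of the two condition means strictly
#' above the floor), `passes_fc` (`|log2_fc| >= log2(fc_threshold)`,
#' boundary inclusive), `passes_p` (`q_value <= alpha`), their
#' conjunction `is_de`, and `direction` ("up"/"down" by the sign of
#' log2_fc, `NA` at exactly zero).
#'
#' @param table output of [moderated_contrast_test()] (q_values present).
#' @param filters a [de_filter_config()]; `"auto"` floors are not
#'   resolvable here and must be replaced by a number first.
#' @return the table with flag columns added.
#' @export
apply_de_filters <- function(table, filters) {
  if (!"q_value" %in% names(table)) stop("q_values missing; run the test first")
  floor_val <- filters$intensity_floor
  if (identical(floor_val, "auto")) {
    stop("intensity_floor \"auto\" must be resolved to a number ",
         "(global_median of the source matrix) before filtering")
  }
  out <- table
  out$passes_intensity <- pmax(table$mean_a, table$mean_b) > floor_val
  out$passes_fc <- abs(table$log2_fc) >= log2(filters$fc_threshold)
  out$passes_p <- table$q_value <= filters$alpha
  out$is_de <- out$passes_intensity & out$passes_fc & out$passes_p
  out$direction <- ifelse(table$log2_fc > 0, "up",
                          ifelse(table$log2_fc < 0, "down", NA_character_))
  attr(out, "filters") <- filters
  out
}

#' Run one complete two-condition differential-expression contrast
#'
#' Convenience wrapper: condition summaries, moderation estimated from
#' this comparison's own variances, moderated test, BH adjustment and
#' the three-part filter. An `"auto"` intensity floor resolves to the
#' global median of the supplied matrix.
#'
#' @inheritParams condition_summaries
#' @param filters a [de_filter_config()].
#' @param params optional pre-computed moderation parameters; estimated
#'   from the data when `NULL`.
#' @return flagged DE table (one row per probeset).
#' @export
run_contrast <- function(matrix, design, condition_a, condition_b,
                         filters = de_filter_config(), params = NULL) {
  summ <- condition_summaries(matrix, design, condition_a, condition_b)
  if (is.null(params)) params <- estimate_moderation(summ$s2, summ$df)
  tab <- moderated_contrast_test(summ, params)
  if (identical(filters$intensity_floor, "auto")) {
    filters$intensity_floor <- global_median(matrix)
  }
  tab <- apply_de_filters(tab, filters)
  attr(tab, "moderation") <- params
  attr(tab, "conditions") <- list(a = condition_a, b = condition_b)
  tab
}
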