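#' Simulation configuration for planted-signal expression data
#'
#' Defines the synthetic study: a two-sex (XX/XY), two-genotype
#' (control/dko) design over an ordered stage list with a fixed number of
#' replicates per condition, and planted gene classes on the log2 scale.
#'
#' Gene classes and their planted effects (control genotype):
#' \describe{
#'   \item{null}{baseline expression only.}
#'   \item{cagp}{up-regulated by `effect_size` from the second stage
#'     onward in both sexes (the core-program step between the first two
#'     stages); a fraction `cagp_dimorphic_fraction` additionally gains a
#'     sex effect from `dimorphic_onset` ("future dimorphic" genes).}
#'   \item{dimorphic_male / dimorphic_female}{a sex effect of
#'     `effect_size` (XY-up or XX-up) from `dimorphic_onset` onward,
#'     nothing earlier.}
#'   \item{primed}{elevated by `effect_size` in both sexes at all stages
#'     (equal in XX and XY before sex determination), plus a sex effect
#'     from `dimorphic_onset`.}
#' }
#' In the dko genotype, a fraction `dko_attenuation` of non-null genes is
#' "attenuated": all planted effects are removed so their means revert to
#' baseline (effect removal, not sign flip). Baselines for non-null genes
#' are drawn from the upper half of the baseline distribution
#' (`baseline_mean + |N(0, baseline_sd)|`): gene programs are defined
#' over expressed, above-median transcripts, so planted program genes
#' live in the detectable range.
#'
#' @param n_probesets total number of probesets.
#' @param prop_cagp,prop_dimorphic_male,prop_dimorphic_female,prop_primed
#'   fractions of genes in each planted class; the remainder is null.
#' @param cagp_dimorphic_fraction fraction of cagp genes that also become
#'   sexually dimorphic after the onset stage (split evenly male/female).
#' @param dko_attenuation fraction of non-null genes whose effects are
#'   suppressed in the dko genotype.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param effect_size planted log2 fold change (default `log2(2)`).
#' @param noise_sd residual log2 SD per measurement.
#' @param replicates replicates per (sex, genotype, stage) condition.
#' @param stages ordered character vector of developmental stages.
#' @param dimorphic_onset stage at which sex effects begin.
#' @param prop_multi_probeset fraction of genes carrying two probesets.
#' @param prop_contradictory fraction of multi-probeset non-null genes
#'   whose second probeset has all planted effects negated, to exercise
#'   the contradictory-probeset collapse rule.
#' @param seed integer RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_probesets = 2000,
                       prop_cagp = 0.15,
                       prop_dimorphic_male = 0.05,
                       prop_dimorphic_female = 0.05,
                       prop_primed = 0.05,
                       cagp_dimorphic_fraction = 0.5,
                       dko_attenuation = 0.30,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       effect_size = log2(2),
                       noise_sd = 0.25,
                       replicates = 3,
                       stages = c("E10.5", "E11.5", "E12.5", "E13.5"),
                       dimorphic_onset = "E12.5",
                       prop_multi_probeset = 0,
                       prop_contradictory = 0,
                       seed = 1) {
  props <- c(prop_cagp, prop_dimorphic_male, prop_dimorphic_female, prop_primed)
  if (any(props < 0) || sum(props) > 1) {
    stop("class proportions must be non-negative and sum to at most 1")
  }
  if (effect_size <= 0) stop("effect_size must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (replicates < 2) stop("at least 2 replicates per condition are required")
  if (length(stages) < 2) stop("at least two stages are required")
  stage_index(stages)  # validates the vocabulary
  if (!dimorphic_onset %in% stages) stop("dimorphic_onset must be one of the stages")
  if (dko_attenuation < 0 || dko_attenuation > 1) stop("dko_attenuation must be in [0, 1]")
  if (cagp_dimorphic_fraction < 0 || cagp_dimorphic_fraction > 1) {
    stop("cagp_dimorphic_fraction must be in [0, 1]")
  }
  structure(list(
    n_probesets = as.integer(n_probesets),
    prop_cagp = prop_cagp,
    prop_dimorphic_male = prop_dimorphic_male,
    prop_dimorphic_female = prop_dimorphic_female,
    prop_primed = prop_primed,
    cagp_dimorphic_fraction = cagp_dimorphic_fraction,
    dko_attenuation = dko_attenuation,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    effect_size = effect_size,
    noise_sd = noise_sd,
    replicates = as.integer(replicates),
    stages = stages,
    dimorphic_onset = dimorphic_onset,
    prop_multi_probeset = prop_multi_probeset,
    prop_contradictory = prop_contradictory,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build a full factorial sample design
#'
#' @param sexes,genotypes,stages factor levels.
#' @param replicates replicates per condition.
#' @return a data.frame with columns sample_id, sex, genotype, stage,
#'   replicate; one row per sample.
#' @export
make_sample_design <- function(sexes = c("XX", "XY"),
                               genotypes = c("control", "dko"),
                               stages = c("E10.5", "E11.5", "E12.5", "E13.5"),
                               replicates = 3) {
  g <- expand.grid(replicate = seq_len(replicates), sex = sexes,
                   genotype = genotypes, stage = stages,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sex", "genotype", "stage", "replicate")]
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$sex, g$genotype, g$stage, g$replicate)
  rownames(g) <- NULL
  g[, c("sample_id", "sex", "genotype", "stage", "replicate")]
}

# Planted mean for one probeset in one condition. `sgn` is -1 for
# contradictory probesets (effects negated, baseline untouched).
.planted_effect <- function(class, future_dimorphic, dim_direction,
                            sex, stage_i, onset_i, effect_size) {
  eff <- 0
  if (class == "cagp") {
    if (stage_i >= 2) eff <- eff + effect_size
    if (future_dimorphic && stage_i >= onset_i) {
      if ((dim_direction == "male" && sex == "XY") ||
          (dim_direction == "female" && sex == "XX")) {
        eff <- eff + effect_size
      }
    }
  } else if (class == "dimorphic_male") {
    if (stage_i >= onset_i && sex == "XY") eff <- eff + effect_size
  } else if (class == "dimorphic_female") {
    if (stage_i >= onset_i && sex == "XX") eff <- eff + effect_size
  } else if (class == "primed") {
    eff <- eff + effect_size
    if (stage_i >= onset_i) {
      if ((dim_direction == "male" && sex == "XY") ||
          (dim_direction == "female" && sex == "XX")) {
        eff <- eff + effect_size
      }
    }
  }
  eff
}

#' Simulate a planted-signal log2 expression matrix
#'
#' Generates a probesets x samples log2 intensity matrix over the full
#' (sex x genotype x stage x replicate) design of the configuration,
#' together with the sample design, a probeset-to-gene annotation and
#' per-probeset ground-truth labels. With `noise_sd = 0` every realized
#' condition mean equals its planted value exactly; identical seeds give
#' bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `"sim_expression"` with elements `matrix`
#'   (numeric matrix, probesets x samples), `design` (data.frame),
#'   `annotation` (data.frame: probeset_id, gene_id, gene_symbol, terms),
#'   `truth` (data.frame of planted labels and effects) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_ps <- config$n_probesets
  n_genes <- as.integer(round(n_ps / (1 + config$prop_multi_probeset)))
  n_multi <- n_ps - n_genes
  gene_id <- sprintf("gene%05d", seq_len(n_genes))

  n_cagp <- floor(config$prop_cagp * n_genes)
  n_dm <- floor(config$prop_dimorphic_male * n_genes)
  n_df <- floor(config$prop_dimorphic_female * n_genes)
  n_pr <- floor(config$prop_primed * n_genes)
  class <- rep("null", n_genes)
  class[seq_len(n_cagp)] <- "cagp"
  class[n_cagp + seq_len(n_dm)] <- "dimorphic_male"
  class[n_cagp + n_dm + seq_len(n_df)] <- "dimorphic_female"
  class[n_cagp + n_dm + n_df + seq_len(n_pr)] <- "primed"

  future_dimorphic <- rep(FALSE, n_genes)
  n_fd <- floor(config$cagp_dimorphic_fraction * n_cagp)
  future_dimorphic[seq_len(n_fd)] <- TRUE

  dim_direction <- rep(NA_character_, n_genes)
  if (n_fd > 0) dim_direction[seq_len(n_fd)] <- rep_len(c("male", "female"), n_fd)
  dim_direction[class == "dimorphic_male"] <- "male"
  dim_direction[class == "dimorphic_female"] <- "female"
  is_primed <- class == "primed"
  dim_direction[is_primed] <- sample(c("male", "female"), sum(is_primed), replace = TRUE)

  nonnull <- which(class != "null")
  attenuated <- rep(FALSE, n_genes)
  n_att <- floor(config$dko_attenuation * length(nonnull))
  if (n_att > 0) attenuated[sample(nonnull, n_att)] <- TRUE

  baseline <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  baseline[nonnull] <- config$baseline_mean +
    abs(rnorm(length(nonnull), 0, config$baseline_sd))

  # Probeset layout: every gene gets one probeset; a random subset gets a
  # second, and a sub-fraction of multi-probeset non-null genes carries a
  # sign-flipped (contradictory) second probeset.
  multi_genes <- if (n_multi > 0) sort(sample(n_genes, n_multi)) else integer(0)
  ps_gene <- c(seq_len(n_genes), multi_genes)
  ps_sgn <- rep(1, length(ps_gene))
  if (n_multi > 0) {
    second <- n_genes + seq_len(n_multi)
    multi_nonnull <- second[class[multi_genes] != "null"]
    n_contra <- floor(config$prop_contradictory * length(multi_nonnull))
    if (n_contra > 0) ps_sgn[sample(multi_nonnull, n_contra)] <- -1
  }
  ord <- order(ps_gene, -ps_sgn)
  ps_gene <- ps_gene[ord]
  ps_sgn <- ps_sgn[ord]
  dup <- duplicated(ps_gene)
  probeset_id <- sprintf("ps%05d_%s", ps_gene, ifelse(dup, "b", "a"))

  design <- make_sample_design(stages = config$stages,
                               replicates = config$replicates)
  onset_i <- stage_index(config$dimorphic_onset)
  stage_i <- match(design$stage, config$stages)  # 1 = first stage
  # planted effects are keyed on position within the configured stage
  # list, onset on the global vocabulary; map onset into list position
  onset_pos <- match(config$dimorphic_onset, config$stages)

  n_total_ps <- length(ps_gene)
  mu <- matrix(0, n_total_ps, nrow(design),
               dimnames = list(probeset_id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    sx <- design$sex[s]
    gt <- design$genotype[s]
    st <- stage_i[s]
    for (p in seq_len(n_total_ps)) {
      g <- ps_gene[p]
      if (gt == "dko" && attenuated[g]) {
        mu[p, s] <- baseline[g]
      } else {
        eff <- .planted_effect(class[g], future_dimorphic[g], dim_direction[g],
                               sx, st, onset_pos, config$effect_size)
        mu[p, s] <- baseline[g] + ps_sgn[p] * eff
      }
    }
  }
  mat <- mu
  if (config$noise_sd > 0) {
    mat <- mu + matrix(rnorm(length(mu), 0, config$noise_sd), nrow(mu))
    dimnames(mat) <- dimnames(mu)
  }

  # simple class-linked + random term annotation for enrichment testing
  term_pool <- sprintf("T_rand%02d", 1:10)
  terms <- paste(paste0("T_", class), sample(term_pool, n_genes, replace = TRUE),
                 sep = ";")

  annotation <- data.frame(
    probeset_id = probeset_id,
    gene_id = gene_id[ps_gene],
    gene_symbol = toupper(gene_id[ps_gene]),
    terms = terms[ps_gene],
    stringsAsFactors = FALSE
  )

  elev <- ifelse(class %in% c("cagp", "primed"), config$effect_size, 0)
  truth <- data.frame(
    probeset_id = probeset_id,
    gene_id = gene_id[ps_gene],
    class = class[ps_gene],
    contradictory = ps_sgn < 0,
    future_dimorphic = future_dimorphic[ps_gene],
    dim_direction = dim_direction[ps_gene],
    attenuated = attenuated[ps_gene],
    baseline = baseline[ps_gene],
    # log2 step between the first two stages (both sexes, control)
    effect_stage = ps_sgn * ifelse(class[ps_gene] == "cagp", config$effect_size, 0),
    # signed sex effect from the onset stage (positive = XY-up)
    effect_sex = ps_sgn * ifelse(
      !is.na(dim_direction[ps_gene]),
      ifelse(dim_direction[ps_gene] == "male", config$effect_size,
             -config$effect_size),
      0),
    # dko minus control at the second stage (shared by both sexes)
    effect_genotype = ps_sgn * ifelse(attenuated[ps_gene], -elev[ps_gene], 0),
    stringsAsFactors = FALSE
  )

  structure(list(matrix = mat, design = design, annotation = annotation,
                 truth = truth, config = config),
            class = "sim_expression")
}

#' Simulate NanoString-style barcode counts with planted structure
#'
#' Emulates an nCounter run over the supplied sample design: negative
#' probes carry background only, positive probes form a fixed spike
#' ladder independent of sample content (they report lane efficiency,
#' not RNA amount, so they do not scale with the content size factor),
#' reference candidates are proportional to a per-sample size factor
#' with optional extra log-normal instability for a planted subset, and
#' endogenous probes carry planted stage/genotype/sex effects on top of
#' the size factor. Counts are negative binomial around the scaled means
#' with additive Poisson background; `dispersion = 0` switches to fully
#' deterministic counts `round(mu + background_mean)` so zero-noise
#' properties hold exactly.
#'
#' @param n_endogenous,n_reference_candidates,n_negative,n_positive
#'   probe counts per class (at least 2 negatives and 2 positives).
#' @param design sample design (default [make_sample_design()]).
#' @param size_factor_range c(lo, hi); per-sample content size factors
#'   are drawn log-uniformly on this interval.
#' @param background_mean Poisson mean of the additive background.
#' @param n_unstable number of reference candidates given extra
#'   instability; `instability_sd` is its per-measurement log2 SD.
#' @param instability_sd log2 SD of the planted reference instability.
#' @param dispersion negative-binomial dispersion (variance
#'   mu + dispersion * mu^2); 0 means deterministic counts.
#' @param frac_stage,frac_genotype,frac_sex fractions of endogenous
#'   probes carrying each planted factor effect.
#' @param effect_log2 magnitude of the planted log2 effects (the stage
#'   effect is a per-stage-step slope of half this magnitude).
#' @param seed integer RNG seed.
#' @return list of class `"sim_nanostring"` with `counts` (long
#'   data.frame: probe_id, probe_class, sample_id, count), `truth`
#'   (per-probe planted parameters), `samples` (per-sample size
#'   factors) and the call parameters.
#' @export
simulate_nanostring <- function(n_endogenous = 60,
                                n_reference_candidates = 8,
                                n_negative = 6,
                                n_positive = 6,
                                design = make_sample_design(),
                                size_factor_range = c(0.5, 2),
                                background_mean = 20,
                                n_unstable = 0,
                                instability_sd = 0,
                                dispersion = 0.1,
                                frac_stage = 0.4,
                                frac_genotype = 0.3,
                                frac_sex = 0.2,
                                effect_log2 = 1,
                                seed = 1) {
  if (n_negative < 2 || n_positive < 2) {
    stop("at least 2 negative and 2 positive probes are required")
  }
  if (any(size_factor_range <= 0)) stop("size factors must be positive")
  if (n_unstable > n_reference_candidates) {
    stop("n_unstable cannot exceed the number of reference candidates")
  }
  set.seed(seed)
  n_s <- nrow(design)
  sample_id <- design$sample_id

  sf <- if (size_factor_range[1] == size_factor_range[2]) {
    rep(size_factor_range[1], n_s)
  } else {
    exp(runif(n_s, log(size_factor_range[1]), log(size_factor_range[2])))
  }

  stage_pos <- match(design$stage, unique(design$stage)) - 1L
  is_dko <- design$genotype == "dko"
  is_xy <- design$sex == "XY"

  probes <- list()
  mus <- list()

  if (n_negative > 0) {
    ids <- sprintf("NEG_%02d", seq_len(n_negative))
    probes$negative <- data.frame(probe_id = ids, probe_class = "negative",
                                  stringsAsFactors = FALSE)
    mus$negative <- matrix(0, n_negative, n_s, dimnames = list(ids, sample_id))
  }
  pos_levels <- 2^seq(4, by = 2, length.out = n_positive)
  ids <- sprintf("POS_%02d", seq_len(n_positive))
  probes$positive <- data.frame(probe_id = ids, probe_class = "positive",
                                stringsAsFactors = FALSE)
  mus$positive <- matrix(pos_levels, n_positive, n_s,
                         dimnames = list(ids, sample_id))

  ref_ids <- sprintf("REF_%02d", seq_len(n_reference_candidates))
  ref_abund <- 2^rnorm(n_reference_candidates, 10, 1)
  unstable <- rep(FALSE, n_reference_candidates)
  if (n_unstable > 0) unstable[sample(n_reference_candidates, n_unstable)] <- TRUE
  ref_mu <- outer(ref_abund, sf)
  if (instability_sd > 0 && any(unstable)) {
    jitter <- matrix(0, n_reference_candidates, n_s)
    jitter[unstable, ] <- rnorm(sum(unstable) * n_s, 0, instability_sd)
    ref_mu <- ref_mu * 2^jitter
  }
  dimnames(ref_mu) <- list(ref_ids, sample_id)
  probes$reference <- data.frame(probe_id = ref_ids,
                                 probe_class = "reference_candidate",
                                 stringsAsFactors = FALSE)
  mus$reference <- ref_mu

  end_ids <- sprintf("END_%03d", seq_len(n_endogenous))
  end_abund <- 2^rnorm(n_endogenous, 8, 1.5)
  has_stage <- runif(n_endogenous) < frac_stage
  has_geno <- runif(n_endogenous) < frac_genotype
  has_sex <- runif(n_endogenous) < frac_sex
  stage_slope <- ifelse(has_stage, sample(c(-1, 1), n_endogenous, TRUE) *
                          effect_log2 / 2, 0)
  geno_fc <- ifelse(has_geno, sample(c(-1, 1), n_endogenous, TRUE) * effect_log2, 0)
  sex_fc <- ifelse(has_sex, sample(c(-1, 1), n_endogenous, TRUE) * effect_log2, 0)
  log2eff <- outer(stage_slope, stage_pos) +
    outer(geno_fc, as.numeric(is_dko)) +
    outer(sex_fc, as.numeric(is_xy))
  end_mu <- (end_abund * 2^log2eff) * rep(sf, each = n_endogenous)
  dimnames(end_mu) <- list(end_ids, sample_id)
  probes$endogenous <- data.frame(probe_id = end_ids, probe_class = "endogenous",
                                  stringsAsFactors = FALSE)
  mus$endogenous <- end_mu

  probe_tab <- do.call(rbind, probes)
  mu <- do.call(rbind, mus)

  if (dispersion == 0) {
    counts <- round(mu + background_mean)
  } else {
    # biological probes are overdispersed; positive spike-ins are purely
    # technical and behave near-Poisson, keeping the max/min QC ratio of
    # the per-sample positive averages tight as in a passing run
    counts <- matrix(
      rnbinom(length(mu), size = 1 / dispersion, mu = mu) +
        rpois(length(mu), background_mean),
      nrow(mu), dimnames = dimnames(mu))
    pos_rows <- which(probe_tab$probe_class == "positive")
    counts[pos_rows, ] <- rpois(length(pos_rows) * ncol(mu), mu[pos_rows, ]) +
      rpois(length(pos_rows) * ncol(mu), background_mean)
  }

  long <- data.frame(
    probe_id = rep(rownames(counts), times = ncol(counts)),
    probe_class = rep(probe_tab$probe_class, times = ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    count = as.integer(as.vector(counts)),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    probe_id = probe_tab$probe_id,
    probe_class = probe_tab$probe_class,
    abundance = c(rep(NA_real_, n_negative), pos_levels, ref_abund, end_abund),
    unstable = c(rep(NA, n_negative + n_positive), unstable,
                 rep(NA, n_endogenous)),
    stage_slope_log2 = c(rep(NA_real_, n_negative + n_positive +
                               n_reference_candidates), stage_slope),
    genotype_log2fc = c(rep(NA_real_, n_negative + n_positive +
                              n_reference_candidates), geno_fc),
    sex_log2fc = c(rep(NA_real_, n_negative + n_positive +
                         n_reference_candidates), sex_fc),
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL

  structure(list(
    counts = long,
    truth = truth,
    samples = data.frame(sample_id = sample_id, size_factor = sf,
                         stringsAsFactors = FALSE),
    design = design,
    background_mean = background_mean,
    dispersion = dispersion,
    seed = seed
  ), class = "sim_nanostring")
}
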