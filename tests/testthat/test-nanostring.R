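# small hand-built count table: 3 negatives {2,4,6}, 2 positives, one
# reference trio and one endogenous probe over 2 samples
toy_counts <- function() {
  expand_counts <- function(sample_id, neg, pos, ref, endo) {
    data.frame(
      probe_id = c(paste0("NEG_", 1:3), paste0("POS_", 1:2),
                   paste0("REF_", 1:3), "END_1"),
      probe_class = c(rep("negative", 3), rep("positive", 2),
                      rep("reference_candidate", 3), "endogenous"),
      sample_id = sample_id,
      count = c(neg, pos, ref, endo),
      stringsAsFactors = FALSE)
  }
  rbind(
    expand_counts("s1", c(2, 4, 6), c(100, 200), c(10, 18, 10), 10),
    expand_counts("s2", c(2, 4, 6), c(100, 200), c(12, 20, 24), 5)
  )
}

test_that("background correction subtracts mean + 2 SD and floors at 1", {
  out <- background_correct(toy_counts())
  bg <- out$background
  expect_equal(bg$neg_mean, c(4, 4))
  expect_equal(bg$neg_sd, c(2, 2))
  expect_equal(bg$threshold, c(8, 8))
  cor1 <- out$counts[out$counts$sample_id == "s1", ]
  expect_equal(cor1$count[cor1$probe_id == "END_1"], 2)   # 10 - 8
  expect_equal(cor1$count[cor1$probe_id == "REF_1"], 2)
  s2 <- out$counts[out$counts$sample_id == "s2", ]
  expect_equal(s2$count[s2$probe_id == "END_1"], 1)       # 5 - 8 -> clipped
  expect_false("negative" %in% out$counts$probe_class)
  expect_true(all(out$counts$count >= 1))

  # all-zero negatives: threshold 0, corrected = max(raw, 1)
  z <- toy_counts()
  z$count[z$probe_class == "negative"] <- 0
  zo <- background_correct(z)
  expect_equal(zo$background$threshold, c(0, 0))
  expect_equal(zo$counts$count,
               pmax(z$count[z$probe_class != "negative"], 1))

  bad <- toy_counts()
  bad <- bad[!(bad$sample_id == "s2" & bad$probe_id %in% c("NEG_1", "NEG_2")), ]
  expect_error(background_correct(bad), "s2")
})

test_that("positive-control QC computes the max/min average ratio", {
  qc <- positive_control_qc(toy_counts())
  expect_equal(qc$pos_ratio, 1)
  expect_true(qc$pass)

  x <- toy_counts()
  x$count[x$probe_class == "positive" & x$sample_id == "s2"] <- c(300, 200)
  qc2 <- positive_control_qc(x)
  expect_equal(qc2$pos_ratio, 250 / 150)
  expect_true(qc2$pass)
  x$count[x$probe_class == "positive" & x$sample_id == "s2"] <- c(500, 700)
  qc3 <- positive_control_qc(x)
  expect_equal(qc3$pos_ratio, 4)
  expect_false(qc3$pass)
  x$count[x$probe_class == "positive" & x$sample_id == "s1"] <- 0
  expect_error(positive_control_qc(x), "s1")
})

test_that("geNorm M and exclusion order match the all-pairs brute force", {
  # 3-candidate toy, hand-enumerable pairwise ratio SDs
  x <- matrix(c(2, 4, 4, 8, 2, 16), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  g <- genorm_rank(x)
  expect_equal(setNames(g$stability$m, g$stability$probe_id),
               oracle_genorm_m(x))
  # A and B are exactly proportional; C varies against both
  expect_equal(g$ranking, c("C", "A", "B"))
  expect_equal(select_references(g, 2), c("A", "B"))
  expect_error(select_references(g, 4), "exceeds")

  # perfectly proportional candidates: all M = 0
  prop <- outer(c(2, 5, 9), c(1, 3, 7))
  dimnames(prop) <- list(c("A", "B", "C"), c("s1", "s2", "s3"))
  expect_true(all(genorm_rank(prop)$stability$m < 1e-12))

  # duplicating a candidate cannot raise the duplicated pair's M
  set.seed(12)
  y <- matrix(2^rnorm(4 * 5, 8, 1), 4, 5,
              dimnames = list(LETTERS[1:4], paste0("s", 1:5)))
  y2 <- rbind(y, E = y["A", ])
  mA <- oracle_genorm_m(y)["A"]
  m2 <- genorm_rank(y2)$stability
  expect_lte(m2$m[m2$probe_id == "A"], mA)

  expect_error(genorm_rank(y[1:2, ]), "3 candidates")
  y0 <- y; y0[1, 1] <- 0
  expect_error(genorm_rank(y0), "background-correct")

  # randomized equivalence with the independent brute-force implementation
  set.seed(99)
  for (i in 1:100) {
    nc <- sample(3:8, 1); ns <- sample(2:6, 1)
    z <- matrix(2^rnorm(nc * ns, 8, 1), nc, ns,
                dimnames = list(paste0("c", seq_len(nc)), paste0("s", seq_len(ns))))
    gr <- genorm_rank(z)
    expect_equal(setNames(gr$stability$m, gr$stability$probe_id),
                 oracle_genorm_m(z[order(rownames(z)), ]))
    expect_equal(gr$ranking, oracle_genorm_order(z))
  }
})

test_that("reference normalization equalizes reference geometric means", {
  # 2 samples with reference geometric means 100 and 200: rescale to 150
  df <- data.frame(
    probe_id = rep(c("R1", "R2", "T1"), 2),
    probe_class = rep(c("reference_candidate", "reference_candidate",
                        "endogenous"), 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    count = c(50, 200, 10, 100, 400, 20),
    stringsAsFactors = FALSE)
  out <- reference_normalize(df, c("R1", "R2"))
  t1 <- out$counts[out$counts$probe_id == "T1", ]
  expect_equal(t1$count, c(15, 15))
  g <- vapply(split(out$counts[out$counts$probe_id %in% c("R1", "R2"), "count"],
                    out$counts$sample_id[out$counts$probe_id %in% c("R1", "R2")]),
              function(v) exp(mean(log(v))), 0)
  expect_equal(unname(g), c(150, 150))

  # already-normalized input passes through unchanged
  same <- df; same$count <- c(50, 200, 10, 50, 200, 20)
  out2 <- reference_normalize(same, c("R1", "R2"))
  expect_equal(out2$counts$count, same$count)

  # per-sample scaling cancels up to the single global rescale constant:
  # every normalized value changes by the same factor, so all within- and
  # cross-sample comparisons are preserved
  scaled <- df
  scaled$count[scaled$sample_id == "s2"] <- scaled$count[scaled$sample_id == "s2"] * 2
  out3 <- reference_normalize(scaled, c("R1", "R2"))
  ratio <- out3$counts$count / out$counts$count
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)

  expect_error(reference_normalize(df[-1, ], c("R1", "R2")), "missing")
})

test_that("sources-of-variation ANOVA decomposes balanced designs exactly", {
  design <- make_sample_design(stages = c("E10.5", "E11.5"), replicates = 2)
  y <- numeric(nrow(design))
  # additive construction: stage +4, genotype +2, sex +1, no noise
  y <- 4 * (design$stage == "E11.5") + 2 * (design$genotype == "dko") +
    1 * (design$sex == "XY")
  m <- rbind(g1 = y)
  colnames(m) <- design$sample_id
  a <- suppressWarnings(anova_sources(m, design, log2_transform = FALSE))
  ss <- setNames(a$ss, a$term)
  # per-factor SS = n/4 * effect^2 on a balanced 2x2x2 with n samples
  n <- nrow(design)
  expect_equal(unname(ss["stage"]), n / 4 * 16)
  expect_equal(unname(ss["genotype"]), n / 4 * 4)
  expect_equal(unname(ss["sex"]), n / 4 * 1)
  expect_equal(unname(ss["residual"]), 0)
  expect_equal(unname(ss[c("stage", "genotype", "sex")] / ss["stage"] * 16),
               c(16, 4, 1))

  # single-factor signal: that factor takes all of the model SS
  y2 <- 3 * (design$stage == "E11.5")
  m2 <- rbind(g1 = y2); colnames(m2) <- design$sample_id
  a2 <- suppressWarnings(anova_sources(m2, design, log2_transform = FALSE))
  expect_equal(a2$frac_ss[a2$term == "stage"], 1)
  expect_equal(a2$ss[a2$term %in% c("genotype", "sex")], c(0, 0))

  # SS conservation with noise, near machine precision
  set.seed(21)
  m3 <- matrix(rnorm(3 * n, 8), 3, n,
               dimnames = list(paste0("g", 1:3), design$sample_id))
  a3 <- anova_sources(m3, design, log2_transform = FALSE)
  for (g in paste0("g", 1:3)) {
    sub <- a3[a3$probe_id == g, ]
    tot <- sum((m3[g, ] - mean(m3[g, ]))^2)
    expect_equal(sum(sub$ss), tot, tolerance = 1e-13)
    expect_equal(sum(sub$frac_ss), 1, tolerance = 1e-13)
  }

  # single-level factor is dropped with a warning
  d1 <- design[design$sex == "XX", ]
  m4 <- m3[, d1$sample_id]
  expect_warning(a4 <- anova_sources(m4, d1, log2_transform = FALSE), "sex")
  expect_false("sex" %in% a4$term)
})

test_that("normalized endogenous means recover planted count ratios", {
  # planted genotype effects survive the full chain within 10%
  err <- numeric(10)
  for (i in 1:10) {
    ns <- simulate_nanostring(n_endogenous = 30, size_factor_range = c(0.5, 2),
                              frac_stage = 0, frac_sex = 0,
                              frac_genotype = 1, effect_log2 = 1,
                              background_mean = 5, seed = 200 + i)
    corrected <- background_correct(ns$counts)
    g <- genorm_rank(corrected)
    norm <- reference_normalize(corrected, select_references(g, 6))
    m <- with(norm$counts[norm$counts$probe_class == "endogenous", ],
              tapply(count, list(probe_id, sample_id), mean))
    dko <- ns$design$sample_id[ns$design$genotype == "dko"]
    ctrl <- ns$design$sample_id[ns$design$genotype == "control"]
    ratio <- rowMeans(m[, dko]) / rowMeans(m[, ctrl])
    planted <- 2^ns$truth$genotype_log2fc[ns$truth$probe_class == "endogenous"]
    strong <- ns$truth$abundance[ns$truth$probe_class == "endogenous"] > 100
    err[i] <- median(abs(log2(ratio[strong]) - log2(planted[strong])))
  }
  expect_lt(mean(err), log2(1.1))
})
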