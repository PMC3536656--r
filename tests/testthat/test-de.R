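test_that("quantile normalization maps samples onto shared rank means", {
  x <- matrix(c(1, 3, 2, 6), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- quantile_normalize(x)
  expect_equal(unname(out[, "s1"]), c(1.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(1.5, 4.5))
  expect_identical(dimnames(out), dimnames(x))

  set.seed(10)
  y <- matrix(rnorm(200), 40, 5, dimnames = list(paste0("p", 1:40), paste0("s", 1:5)))
  qn <- quantile_normalize(y)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(quantile_normalize(qn), qn)  # idempotent

  expect_error(quantile_normalize(y[, 1, drop = FALSE]), "2 samples")
})

test_that("global median follows the even-count mean-of-middle-pair convention", {
  expect_equal(global_median(matrix(5, 3, 3)), 5)
  expect_equal(global_median(matrix(1:5, 1)), 3)
  expect_equal(global_median(matrix(c(1, 2, 3, 10), 2)), 2.5)
  expect_error(global_median(matrix(numeric(0), 0, 0)), "empty")
})

test_that("sample similarity matches hand-computed correlation and KL values", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(1, 2, 3))
  rc <- sample_similarity(x, "correlation")
  expect_equal(rc["s1", "s2"], 1)
  expect_equal(rc["s1", "s3"], 1)
  expect_true(isSymmetric(rc))

  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  hand <- 0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  expect_equal(symmetric_kl(p, q), hand)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)

  dup <- cbind(s1 = rnorm(50), s2 = rnorm(50))
  dup <- cbind(dup, s3 = dup[, "s1"])
  kl <- sample_similarity(dup, "kl")
  expect_equal(kl["s1", "s3"], 0)
  expect_equal(diag(kl), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(kl["s1", "s2"] > 0)

  const <- cbind(s1 = rep(1, 5), s2 = rnorm(5))
  expect_warning(rc2 <- sample_similarity(const, "correlation"), "constant")
  expect_true(is.na(rc2["s1", "s2"]))
})

test_that("condition summaries pool variances by hand-checkable arithmetic", {
  design <- data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    sex = c("XX", "XX", "XX", "XY", "XY", "XY"),
    genotype = "control", stage = "E11.5", replicate = c(1:3, 1:3),
    stringsAsFactors = FALSE)
  m <- rbind(p1 = c(4, 4, 4, 6, 6, 6), p2 = c(1, 3, 2, 2, 6, 4))
  colnames(m) <- design$sample_id
  s <- condition_summaries(m, design, list(sex = "XX"), list(sex = "XY"))
  expect_equal(s$mean_a, c(4, 2))
  expect_equal(s$mean_b, c(6, 4))
  expect_equal(s$s2, c(0, (2 + 8) / 4))
  expect_equal(s$df, c(4L, 4L))

  # two replicates per group: s2 = (2 + 8) / 2 = 5, df = 2
  d2 <- design[c(1, 2, 4, 5), ]
  m2 <- rbind(p1 = c(1, 3, 2, 6)); colnames(m2) <- d2$sample_id
  s2 <- condition_summaries(m2, d2, list(sex = "XX"), list(sex = "XY"))
  expect_equal(s2$mean_a, 2); expect_equal(s2$mean_b, 4)
  expect_equal(s2$s2, 5); expect_equal(s2$df, 2L)

  # replicate order is immaterial
  perm <- design[c(3, 1, 2, 6, 5, 4), ]
  expect_equal(condition_summaries(m, perm, list(sex = "XX"), list(sex = "XY")), s)

  expect_error(
    condition_summaries(m, design[-(1:2), ], list(sex = "XX"), list(sex = "XY")),
    "condition A")
})

test_that("moderation hyperparameters recover planted prior df and scale", {
  set.seed(2024)
  d0 <- 4; s02 <- 1; dg <- 4; n <- 5000
  true_var <- s02 * d0 / stats::rchisq(n, d0)
  s2 <- true_var * stats::rchisq(n, dg) / dg
  fit <- estimate_moderation(s2, dg)
  expect_lt(abs(fit$d0 - d0) / d0, 0.20)
  expect_lt(abs(fit$s02 - s02) / s02, 0.10)
  # independent cross-check against the reference empirical-Bayes fitter
  ref <- limma::fitFDist(s2, dg)
  expect_equal(fit$d0, ref$df2, tolerance = 1e-6)
  expect_equal(fit$s02, ref$scale, tolerance = 1e-6)
})

test_that("moderation edge cases follow the moment equations", {
  # no dispersion of variances: unbounded d0, scale equals the common value
  fit <- estimate_moderation(rep(2.5, 200), 4)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s02, 2.5)
  # scatter below sampling noise also yields an unbounded prior
  expect_identical(estimate_moderation(c(1, 2), 4)$d0, Inf)
  # wide scatter: finite root matching an independent root-finder
  s2 <- rep(c(1, 10), 50)
  fit2 <- estimate_moderation(s2, 4)
  e <- log(s2) - digamma(2) + log(2)
  y <- var(e) - trigamma(2)
  expect_gt(y, 0)
  expect_equal(fit2$d0, oracle_trigamma_root(y), tolerance = 1e-6)
  # zero variances are excluded and counted; all-zero is an error
  fit3 <- estimate_moderation(c(0, 0, rep(c(1, 10), 50)), 4)
  expect_equal(fit3$n_zero, 2)
  expect_equal(fit3$d0, fit2$d0)
  expect_error(estimate_moderation(c(0, 0), 4), "zero")
})

test_that("moderated t matches the hand-evaluated formula and its limits", {
  summ <- data.frame(probeset_id = "p1", n_a = 3, n_b = 3, mean_a = 2,
                     mean_b = 4, log2_fc = 2, s2 = 1, df = 4,
                     stringsAsFactors = FALSE)
  out <- moderated_contrast_test(summ, list(d0 = 4, s02 = 1))
  expect_equal(out$s2_post, 1)
  expect_equal(out$t, 2 / sqrt(2 / 3))
  expect_equal(out$p_value, 2 * pt(-2 / sqrt(2 / 3), df = 8))

  # null contrast: t = 0, p = 1
  null_s <- transform(summ, mean_b = 2, log2_fc = 0)
  out0 <- moderated_contrast_test(null_s, list(d0 = 4, s02 = 1))
  expect_equal(out0$t, 0); expect_equal(out0$p_value, 1)

  set.seed(5)
  many <- data.frame(probeset_id = paste0("p", 1:50), n_a = 3, n_b = 4,
                     mean_a = rnorm(50), mean_b = rnorm(50),
                     s2 = stats::rchisq(50, 4) / 4, df = 5,
                     stringsAsFactors = FALSE)
  many$log2_fc <- many$mean_b - many$mean_a
  # d0 = 0: exactly the ordinary pooled t-test
  plain <- moderated_contrast_test(many, list(d0 = 0, s02 = 1))
  ref <- oracle_pooled_t(many$mean_a, many$mean_b, many$s2, 3, 4)
  expect_equal(plain$t, ref$t)
  expect_equal(plain$p_value, ref$p)
  # d0 -> Inf: z-statistic on the prior scale
  big <- moderated_contrast_test(many, list(d0 = 1e6, s02 = 2))
  z <- many$log2_fc / sqrt(2 * (1 / 3 + 1 / 4))
  expect_lt(max(abs(big$t - z) / abs(z)), 1e-3)
  inf <- moderated_contrast_test(many, list(d0 = Inf, s02 = 2))
  expect_equal(inf$t, z)
  expect_equal(inf$p_value, 2 * pnorm(-abs(z)))
})

test_that("swapping condition labels negates the statistic and keeps p", {
  cfg <- sim_config(n_probesets = 100, seed = 8)
  sim <- simulate_expression(cfg)
  a <- list(sex = "XX", genotype = "control", stage = "E10.5")
  b <- list(sex = "XX", genotype = "control", stage = "E11.5")
  s_ab <- condition_summaries(sim$matrix, sim$design, a, b)
  s_ba <- condition_summaries(sim$matrix, sim$design, b, a)
  prm <- estimate_moderation(s_ab$s2, s_ab$df)
  t_ab <- moderated_contrast_test(s_ab, prm)
  t_ba <- moderated_contrast_test(s_ba, prm)
  expect_equal(t_ba$log2_fc, -t_ab$log2_fc)
  expect_equal(t_ba$t, -t_ab$t)
  expect_equal(t_ba$p_value, t_ab$p_value)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.005, 0.01, 0.04, 0.03)), c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(77)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("the three-part filter realizes the exhaustive flag truth table", {
  floor_val <- 6
  filt <- de_filter_config(fc_threshold = 1.5, alpha = 0.01,
                           intensity_floor = floor_val)
  # rows spanning all 8 combinations of (intensity, fc, p)
  tab <- data.frame(
    probeset_id = paste0("p", 1:8),
    n_a = 3, n_b = 3,
    mean_a = c(7, 7, 7, 7, 5, 5, 5, 5),
    mean_b = c(8, 8, 7.1, 7.1, 5.8, 5.8, 5.1, 5.1),
    s2 = 0.1, df = 4, s2_post = 0.1, t = 1,
    p_value = c(.001, .5, .001, .5, .001, .5, .001, .5),
    q_value = c(.001, .5, .001, .5, .001, .5, .001, .5),
    stringsAsFactors = FALSE)
  tab$log2_fc <- tab$mean_b - tab$mean_a
  out <- apply_de_filters(tab, filt)
  expect_equal(out$passes_intensity, rep(c(TRUE, FALSE), each = 4))
  expect_equal(out$passes_fc, rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(out$passes_p, rep(c(TRUE, FALSE), 4))
  expect_equal(out$is_de, c(TRUE, rep(FALSE, 7)))

  # FC boundary is inclusive: an anti-log fold change of exactly 1.5 passes
  b <- tab[1, ]; b$mean_b <- b$mean_a + log2(1.5); b$log2_fc <- log2(1.5)
  expect_true(apply_de_filters(b, filt)$passes_fc)
  # intensity floor is strict: means equal to the floor fail
  b2 <- tab[1, ]; b2$mean_a <- floor_val; b2$mean_b <- floor_val
  b2$log2_fc <- 0
  expect_false(apply_de_filters(b2, filt)$passes_intensity)
  expect_error(apply_de_filters(tab, de_filter_config()), "auto")
})

test_that("realized false-discovery proportion stays controlled on null-rich data", {
  # planted effects at 4x the residual SD, alpha = 0.01, 20 seeded runs
  fdp <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(n_probesets = 400, noise_sd = 0.25, seed = 100 + i)
    sim <- simulate_expression(cfg)
    tab <- run_contrast(sim$matrix, sim$design,
                        list(sex = "XX", genotype = "control", stage = "E10.5"),
                        list(sex = "XX", genotype = "control", stage = "E11.5"))
    called <- tab$probeset_id[tab$is_de & tab$direction %in% "up"]
    truth <- sim$truth$probeset_id[sim$truth$effect_stage > 0]
    fdp[i] <- evaluate_recovery(called, truth)$fdp
  }
  expect_lte(mean(fdp), 0.05)
})
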