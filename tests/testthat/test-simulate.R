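small_cfg <- function(seed = 101, ...) {
  sim_config(n_genes = 600, seed = seed,
             tissues = c("testis", "midgut", "head", "ovary"),
             proteins = c(H1 = "silencing", H3.3A = "activation"), ...)
}

test_that("identical configs give byte-identical studies", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$truth, s2$truth)
  expect_identical(unclass(s1$atlas), unclass(s2$atlas))
  expect_identical(s1$timecourse$values, s2$timecourse$values)
  expect_identical(s1$binding$scores, s2$binding$scores)
  s3 <- simulate_study(small_cfg(seed = 102))
  expect_false(identical(unclass(s1$atlas), unclass(s3$atlas)))
})

test_that("truth and generated tables share one gene set, in order", {
  s <- simulate_study(small_cfg())
  expect_identical(s$truth$gene_id, s$catalog$gene_id)
  expect_identical(rownames(s$atlas), s$catalog$gene_id)
  expect_identical(rownames(s$timecourse$values), s$catalog$gene_id)
  expect_identical(rownames(s$binding$scores), s$catalog$gene_id)
})

test_that("per-table substreams are independent of one another", {
  cfg <- small_cfg()
  ct <- generate_catalog(cfg)
  a1 <- generate_atlas(ct$catalog, ct$truth, cfg)
  invisible(generate_binding(ct$catalog, ct$truth, cfg))  # consume RNG elsewhere
  a2 <- generate_atlas(ct$catalog, ct$truth, cfg)
  expect_identical(unclass(a1), unclass(a2))
})

test_that("X depletion of high-bias genes follows the configured multiplier", {
  # null case: no depletion leaves high-bias genes at the genomic X share
  cfg1 <- sim_config(n_genes = 20000, x_highbias_depletion = 1, seed = 7)
  t1 <- generate_catalog(cfg1)$truth
  x_high <- mean(t1$arm[t1$high_bias] == "X")
  n_high <- sum(t1$high_bias)
  expect_lt(abs(x_high - 0.17), 4 * sqrt(0.17 * 0.83 / n_high))

  # boundary: full depletion puts no high-bias genes on the X
  cfg0 <- sim_config(n_genes = 5000, x_highbias_depletion = 0, seed = 7)
  t0 <- generate_catalog(cfg0)$truth
  expect_equal(sum(t0$arm[t0$high_bias] == "X"), 0)
  expect_gt(sum(t0$arm == "X"), 0)

  # halving: X share among high-bias genes is half the configured share
  cfg5 <- sim_config(n_genes = 40000, x_highbias_depletion = 0.5, seed = 7)
  t5 <- generate_catalog(cfg5)$truth
  x5 <- mean(t5$arm[t5$high_bias] == "X")
  expect_lt(abs(x5 - 0.085), 4 * sqrt(0.085 * 0.915 / sum(t5$high_bias)))
})

test_that("noiseless atlas reproduces planted ratios exactly", {
  cfg <- small_cfg(noise_cv = 0)
  ct <- generate_catalog(cfg)
  atl <- generate_atlas(ct$catalog, ct$truth, cfg)
  bt <- bias_table(atl, "testis", epsilon = 0)
  planted <- ct$truth$bias_tissue == "testis" & !is.na(ct$truth$bias_tissue)
  expect_equal(bt$min_ratio[planted], ct$truth$bias_factor[planted])
  others <- is.na(ct$truth$bias_tissue)
  expect_true(all(bt$min_ratio[others] == 1))

  cfg_null <- small_cfg(noise_cv = 0, bias_fraction_per_tissue = 0)
  ctn <- generate_catalog(cfg_null)
  atln <- generate_atlas(ctn$catalog, ctn$truth, cfg_null)
  expect_true(all(bias_table(atln, "testis", epsilon = 0)$min_ratio == 1))
})

test_that("noisy recovery of a planted factor matches a Monte-Carlo oracle", {
  # oracle: simulate the construction directly -- min over the panel of
  # ratios of two lognormal noise draws, scaled by the planted factor
  sdl <- sqrt(log(1 + 0.2^2))
  n_panel <- length(DEFAULT_TISSUES) - 1
  set.seed(5150)
  oracle <- replicate(4000, 10 * exp(rnorm(1, 0, sdl) -
                                       max(rnorm(n_panel, 0, sdl))))
  band <- quantile(oracle, c(0.005, 0.995))

  cfg <- sim_config(n_genes = 800, noise_cv = 0.2, seed = 202,
                    bias_fraction_per_tissue = 0.07,
                    bias_strata = list(breaks = c(10, 10 + 1e-9),
                                       weights = 1),
                    x_highbias_depletion = 1)
  ct <- generate_catalog(cfg)
  atl <- generate_atlas(ct$catalog, ct$truth, cfg)
  planted <- which(ct$truth$bias_tissue == "testis")
  expect_gt(length(planted), 40)
  med <- median(bias_table(atl, "testis", epsilon = 0)$min_ratio[planted])
  expect_gt(med, median(oracle) * 0.85)
  expect_lt(med, median(oracle) * 1.15)
  expect_true(med > band[1] && med < band[2])
})

test_that("time-course construction is exact without noise", {
  cfg <- small_cfg(noise_cv = 0)
  ct <- generate_catalog(cfg)
  tc <- generate_timecourse(ct$catalog, ct$truth, cfg)
  lg <- log2(tc$values)
  day <- tc$samples$day
  for (g in which(ct$truth$activated)[1:5]) {
    fc <- lg[g, ] - lg[g, day == 4][1]
    expect_equal(unname(fc), ct$truth$slope[g] * (day - 4))
  }
  flat <- which(!ct$truth$activated)[1:5]
  expect_true(all(apply(lg[flat, ], 1, function(r) diff(range(r))) == 0))

  cfg0 <- small_cfg(noise_cv = 0, activation_fraction = 0)
  ct0 <- generate_catalog(cfg0)
  tc0 <- generate_timecourse(ct0$catalog, ct0$truth, cfg0)
  expect_true(all(tc0$values == tc0$values[, 1]))
})

test_that("binding scores carry the planted correlation structure", {
  cfg <- sim_config(n_genes = 5000, seed = 303, x_attenuation = 1,
                    binding_rho_silencing = 0.4,
                    binding_rho_activation = -0.4,
                    proteins = c(H1 = "silencing", H3.3A = "activation"))
  ct <- generate_catalog(cfg)
  bp <- generate_binding(ct$catalog, ct$truth, cfg)
  z <- scale(ct$truth$upregulation)[, 1]
  expect_lt(abs(cor(bp$scores[, "H1"], z) - 0.4), 0.05)
  expect_lt(abs(cor(bp$scores[, "H3.3A"], z) + 0.4), 0.05)

  # with full attenuation, X-linked genes decorrelate
  cfg0 <- sim_config(n_genes = 5000, seed = 303, x_attenuation = 0,
                     proteins = c(H1 = "silencing"))
  ct0 <- generate_catalog(cfg0)
  bp0 <- generate_binding(ct0$catalog, ct0$truth, cfg0)
  isx <- ct0$truth$arm == "X"
  z0 <- scale(ct0$truth$upregulation)[, 1]
  expect_lt(abs(cor(bp0$scores[isx, "H1"], z0[isx])),
            4 / sqrt(sum(isx)))

  # rho = 0 stays inside the null sampling band
  cfgn <- sim_config(n_genes = 5000, seed = 303,
                     binding_rho_silencing = 0,
                     proteins = c(H1 = "silencing"))
  ctn <- generate_catalog(cfgn)
  bpn <- generate_binding(ctn$catalog, ctn$truth, cfgn)
  zn <- scale(ctn$truth$upregulation)[, 1]
  expect_lt(abs(cor(bpn$scores[, "H1"], zn)), 3 / sqrt(5000))

  # per-protein thresholds sit at the configured quantile
  expect_equal(unname(bp$thresholds["H1"]),
               unname(quantile(bp$scores[, "H1"], 0.75)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(arm_proportions = c(X = 0.5, `2L` = 0.5)),
               "every arm")
  expect_error(sim_config(x_highbias_depletion = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(bias_fraction_per_tissue = 0.2), "exceeds 1")
  expect_error(sim_config(binding_rho_silencing = 1), "correlations")
})
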