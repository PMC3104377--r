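test_that("quantile normalization removes scale differences between arrays", {
  set.seed(71)
  base <- rlnorm(300, 5, 1)
  vals <- cbind(s1 = base, s2 = base * 3.7, s3 = base, s4 = base * 0.2)
  rownames(vals) <- paste0("g", 1:300)
  meta <- data.frame(sample = colnames(vals), day = c(4, 4, 7, 7),
                     stage = "feeding", replicate = c(1, 2, 1, 2))
  tc <- suppressWarnings(time_course(vals, meta))
  norm <- normalize_arrays(tc)
  expect_true(norm$log2)
  # scalar multiples become identical columns
  expect_equal(norm$values[, "s2"], norm$values[, "s1"])
  expect_equal(norm$values[, "s4"], norm$values[, "s1"])
  expect_equal(diff(range(colMeans(norm$values))), 0, tolerance = 1e-10)
  expect_error(normalize_arrays(norm), "already")

  # columns already identical in distribution are only log2 transformed
  perm <- cbind(s1 = base, s2 = sample(base), s3 = base, s4 = rev(base))
  rownames(perm) <- rownames(vals)
  tcp <- suppressWarnings(time_course(perm, meta))
  normp <- normalize_arrays(tcp)
  expect_equal(normp$values[, "s1"], log2(perm[, "s1"]),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("moderated t degenerates to the ordinary t and to a z statistic", {
  set.seed(81)
  s2 <- rchisq(200, 4) / 4
  # d0 = 0: posterior equals the gene-wise variance
  m0 <- moderate_variances(s2, 4, d0 = 0, s02 = 1)
  expect_equal(m0$s2_post, s2)
  # d0 = Inf: posterior collapses onto the prior
  mi <- moderate_variances(s2, 4, d0 = Inf, s02 = 1.3)
  expect_equal(mi$s2_post, rep(1.3, 200))
  # estimated prior interpolates and shrinks toward the mean
  me <- moderate_variances(s2, 4)
  expect_true(me$d0 > 0)
  expect_true(all(me$s2_post > pmin(s2, me$s02) - 1e-12 &
                  me$s2_post < pmax(s2, me$s02) + 1e-12))
})

test_that("moment matching recovers a known variance prior", {
  set.seed(82)
  d <- 4; d0_true <- 8; s02_true <- 0.5
  sigma2 <- s02_true * d0_true / rchisq(20000, d0_true)
  s2 <- sigma2 * rchisq(20000, d) / d
  est <- moderate_variances(s2, d)
  expect_lt(abs(est$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(est$s02 - s02_true) / s02_true, 0.1)
})

test_that("fold changes and tests behave on constructed genes", {
  set.seed(91)
  n <- 100
  ref <- matrix(rnorm(n * 3, 8, 0.3), n, 3)
  later <- matrix(rnorm(n * 3, 8, 0.3), n, 3)
  # gene 1: identical replicate values at both timepoints
  ref[1, ] <- later[1, ] <- 8
  tc <- two_point_tc(ref, later)
  fc <- fold_change_vs_earliest(tc)
  expect_equal(unname(fc$lfc["g1", 1]), 0)
  expect_equal(unname(fc$t["g1", 1]), 0)
  expect_equal(unname(fc$p["g1", 1]), 1)
  expect_equal(fc$reference, "d4f")
  expect_equal(fc$q[, 1], bh_fdr(fc$p[, 1]))

  # antisymmetry: swapping the two timepoints negates the fold changes
  tc_rev <- two_point_tc(later, ref)
  fc_rev <- fold_change_vs_earliest(tc_rev)
  expect_equal(fc_rev$lfc[, 1], -fc$lfc[, 1])
})

test_that("noiseless planted trajectories give exact fold changes", {
  cfg <- sim_config(n_genes = 300, noise_cv = 0, seed = 55,
                    tissues = c("testis", "midgut"),
                    proteins = c(H1 = "silencing"))
  ct <- generate_catalog(cfg)
  tc <- generate_timecourse(ct$catalog, ct$truth, cfg)
  lg <- suppressWarnings(time_course(log2(tc$values), tc$samples, log2 = TRUE))
  fc <- fold_change_vs_earliest(lg, shrink = FALSE)
  act <- which(ct$truth$activated)
  for (g in act[1:3])
    expect_equal(unname(fc$lfc[g, "d10w"]), ct$truth$slope[g] * 6)
})

test_that("moderated t agrees with an independent moderated-t implementation", {
  cfg <- sim_config(n_genes = 400, seed = 77, tissues = c("testis", "head"),
                    proteins = c(H1 = "silencing"))
  ct <- generate_catalog(cfg)
  tc <- normalize_arrays(generate_timecourse(ct$catalog, ct$truth, cfg))
  fc <- fold_change_vs_earliest(tc)
  cond <- paste0("d", tc$samples$day, substr(tc$samples$stage, 1, 1))
  design <- stats::model.matrix(~ 0 + factor(cond, levels = unique(cond)))
  colnames(design) <- unique(cond)
  fit <- limma::lmFit(tc$values, design)
  cm <- limma::makeContrasts(contrasts = "d10w - d4f", levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  # same fold changes; the shrinkage estimators differ (moment matching
  # here, marginal-likelihood fit there) so t statistics agree in rank
  expect_equal(unname(fc$lfc[, "d10w"]), unname(eb$coefficients[, 1]),
               tolerance = 1e-8)
  expect_gt(cor(fc$t[, "d10w"], eb$t[, 1], method = "spearman"), 0.95)
})

test_that("upregulated_set applies the q and direction rules", {
  set.seed(92)
  n <- 60
  ref <- matrix(rnorm(n * 3, 8, 0.2), n, 3)
  later <- ref + rnorm(n * 3, 0, 0.2)
  later[1, ] <- ref[1, ] + 4   # strongly up
  later[2, ] <- ref[2, ] - 4   # strongly down: must be excluded
  fc <- fold_change_vs_earliest(two_point_tc(ref, later))
  up <- upregulated_set(fc, 0.1)
  expect_true("g1" %in% up)
  expect_false("g2" %in% up)
  expect_true(all(fc$q[setdiff(rownames(fc$q), up), 1] >= 0.1 |
                  fc$lfc[setdiff(rownames(fc$q), up), 1] <= 0))
  # all q at 1 gives an empty set
  fc_null <- fc
  fc_null$q[] <- 1
  expect_equal(length(upregulated_set(fc_null)), 0)
})

test_that("X-versus-autosome profile is antisymmetric and detects planted shifts", {
  cfg <- sim_config(n_genes = 1200, seed = 31, activation_fraction = 0,
                    tissues = c("testis", "head"),
                    proteins = c(H1 = "silencing"))
  ct <- generate_catalog(cfg)
  tc <- normalize_arrays(generate_timecourse(ct$catalog, ct$truth, cfg))
  prof <- x_vs_autosome_profile(tc, ct$catalog)
  expect_equal(nrow(prof), 6)
  # null: group medians agree within sampling noise (~3.5 sigma of the
  # median difference for ~200 X genes at log2 spread 1.7)
  expect_true(all(abs(prof$median_diff) < 0.6))

  # swapping the group labels negates the median difference
  swapped <- ct$catalog
  swapped$arm <- ifelse(swapped$arm == "X", "2L", "X")
  prof_sw <- x_vs_autosome_profile(tc, gene_catalog(swapped$gene_id,
                                                    swapped$arm))
  expect_equal(prof_sw$median_diff, -prof$median_diff)
  expect_equal(prof_sw$p, prof$p)

  # a planted two-fold X down-regulation at one timepoint is detected
  vals <- tc$values
  isx <- ct$catalog$arm[match(rownames(vals), ct$catalog$gene_id)] == "X"
  d10 <- tc$samples$day == 10
  vals[isx, d10] <- vals[isx, d10] - 1
  tc2 <- suppressWarnings(time_course(vals, tc$samples, log2 = TRUE))
  prof2 <- x_vs_autosome_profile(tc2, ct$catalog)
  expect_lt(prof2$p[prof2$condition == "d10w"], 0.01)
  expect_lt(prof2$median_diff[prof2$condition == "d10w"], -0.5)
})

test_that("qPCR relative quantification follows 2^-ddCt", {
  qt <- qpcr_table(data.frame(
    gene_id = rep(c("Sdic", "ocn"), each = 3),
    sample_id = rep(c("pupae", "d5", "d7"), 2),
    ct_target = c(30, 27, 26, 28, 28, 29),
    ct_reference = c(20, 20, 19, 20, 21, 21)))
  rel <- qpcr_relative(qt, "pupae")
  expect_equal(rel$rel_expression[rel$sample_id == "pupae"], c(1, 1))
  # Sdic at d7: dCt = 7 vs 10 at reference; ddCt = -3 -> 8-fold
  expect_equal(rel$rel_expression[rel$gene_id == "Sdic" &
                                  rel$sample_id == "d7"], 8)
  # shifting target and control Ct together leaves values unchanged
  qt2 <- qt; qt2$ct_target <- qt2$ct_target + 1
  qt2$ct_reference <- qt2$ct_reference + 1
  expect_equal(qpcr_relative(qt2, "pupae")$rel_expression,
               rel$rel_expression)
  qt3 <- qpcr_table(data.frame(gene_id = "a", sample_id = "d5",
                               ct_target = 30, ct_reference = 20))
  expect_error(qpcr_relative(qt3, "pupae"), "reference sample")
})
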