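test_that("allele classes follow the private-variant definitions", {
  # rows: hom-unique alt SNP; het singleton; shared het in two samples;
  # hom-unique indel; hom alt in two samples
  gt <- rbind(c("1/1", "0/0", "0/0"),
              c("0/1", "0/0", "0/0"),
              c("0/1", "0/1", "0/0"),
              c("1/1", "0/0", "0/0"),
              c("1/1", "1/1", "0/0"))
  al <- c(rep(list(c("A", "T")), 3), list(c("A", "AT")), list(c("A", "T")))
  vt <- toy_vt(gt, alleles = al)
  cls <- classify_private_alleles(vt)
  expect_equal(cls$class,
               c("PRIVATE_DOUBLETON", "SINGLETON", "NON_PRIVATE",
                 "PRIVATE_INDEL", "NON_PRIVATE"))
  expect_equal(cls$carrier[1], "S1")
  expect_equal(cls$carrier[2], "S1")
  expect_true(is.na(cls$carrier[3]))
})

test_that("proportions, denominators and duplicate behaviour", {
  # 3 PVs over 1000 valid calls -> 0.3%; shared alleles at sites 4 and 5
  # keep the three columns distinct without adding private variants
  n <- 1000
  gt <- cbind(c(rep("1/1", 3), rep("0/0", n - 3)), rep("0/0", n),
              rep("0/0", n))
  gt[4, c(1, 2)] <- "1/1"
  gt[5, c(1, 3)] <- "1/1"
  vt <- toy_vt(gt, depths = matrix(10L, n, 3))
  pv <- pv_proportions(vt, min_dp = 2)
  expect_equal(pv$per_setting$n_pv, c(3L, 0L, 0L))
  expect_equal(pv$per_setting$pv_pct[1], 0.3)
  # an exact duplicate wipes out both copies' PVs (and warns)
  gt2 <- cbind(gt, gt[, 1])
  vt2 <- toy_vt(gt2, depths = matrix(10L, n, 4))
  expect_warning(pv2 <- pv_proportions(vt2, min_dp = 2), "duplicate")
  expect_equal(pv2$per_setting$n_pv, rep(0L, 4))
})

test_that("PV conservation and order invariance", {
  b <- simulate_nuclear(sim_config(
    seed = 21, n_wild = 8, n_landrace = 10, n_cultivar = 5, n_sites = 1000,
    dom_specific_sites = 60, region_site_base = 8, pv_rate_base = 2,
    diag_sites = 20, duplicate_pairs = 0))
  vt <- b$vt
  cls <- classify_private_alleles(vt, check_duplicates = FALSE)
  n_private <- sum(cls$class %in% c("PRIVATE_DOUBLETON", "PRIVATE_INDEL"))
  pv <- pv_proportions(vt, min_dp = 1)
  expect_equal(sum(pv$per_setting$n_pv), n_private)
  # permutation of site and sample order leaves proportions unchanged
  perm_s <- sample(n_samples(vt))
  vt_p <- vt_subset(vt, samples = perm_s)
  pv_p <- pv_proportions(vt_p, min_dp = 1)
  expect_equal(
    pv_p$summary$mean_pv_pct[match(vt$samples, pv_p$summary$sample)],
    pv$summary$mean_pv_pct)
})

test_that("correlation matches a direct evaluation of the t transform", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 6.1, 0.3, 2.8)
  y <- c(2.0, 3.1, 2.9, 4.8, 5.2, 5.9, 1.1, 2.0)
  out <- pv_correlate(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t_manual <- r_manual * sqrt((n - 2) / (1 - r_manual^2))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = n - 2)
  expect_equal(out$r, r_manual, tolerance = 1e-12)
  expect_equal(out$p, p_manual, tolerance = 1e-12)
  expect_equal(pv_correlate(1:10, 2 * (1:10))$r, 1)
  expect_true(is.na(pv_correlate(rep(1, 5), 1:5)$r))
})

test_that("z-scores use the sample sd", {
  expect_equal(group_zscore(2, c(1, 2, 3)), 0)
  ref <- c(4, 8, 6, 2)
  expect_equal(group_zscore(mean(ref) + stats::sd(ref), ref), 1)
  expect_equal(group_zscore(5, c(1, 2, 3)), 3)
  expect_true(is.na(group_zscore(5, c(2, 2, 2))))
})

test_that("Thompson Tau flags gross outliers and stops on tight clusters", {
  vals <- c(rep(1, 9), 100)
  expect_equal(thompson_tau_outliers(vals), 10L)
  expect_equal(thompson_tau_outliers(rep(3, 8)), integer(0))
  # after removing the flagged point the remainder is clean
  rest <- vals[-10]
  expect_equal(thompson_tau_outliers(rest), integer(0))
  # direct evaluation of the tau rule for n = 10
  n <- 10; s <- stats::sd(vals); dev <- abs(vals - mean(vals))
  tv <- stats::qt(1 - 0.025, n - 2)
  tau <- tv * (n - 1) / (sqrt(n) * sqrt(n - 2 + tv^2))
  expect_true(max(dev) > tau * s)
})

test_that("regional summary validates inputs and recovers the gradient", {
  b <- simulate_nuclear(sim_config(seed = 31))
  keep <- setdiff(b$vt$samples, b$truth$duplicates$copy)
  vt <- vt_subset(b$vt, samples = keep)
  pv <- pv_proportions(vt)
  dmeta <- b$meta[b$meta$status %in% c("landrace", "cultivar") &
                    b$meta$sample %in% keep, ]
  theta <- regional_theta_from_genotypes(vt, dmeta)
  rs <- regional_summary(pv, dmeta, theta)
  expect_gt(rs$correlation$r, 0.9)
  expect_error(regional_summary(pv, dmeta, theta[-1]), "absent")
  two <- dmeta[dmeta$region %in% names(theta)[1:2], ]
  expect_error(regional_summary(pv, two, theta), ">= 3 regions")
})
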