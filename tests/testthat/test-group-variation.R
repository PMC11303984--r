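toy_meta <- function(samples, status) {
  tibble::tibble(sample = samples, status = status,
                 region = "r", country = "c")
}

test_that("venn partition matches a brute-force per-site check", {
  # 10 sites, hand-assigned: cultivars S1-S2, landraces S3-S4, wild S5-S6
  gt <- rbind(
    c("0/1", "0/0", "0/0", "0/0", "0/0", "0/0"),  # cultivar only
    c("0/0", "0/0", "1/1", "0/0", "0/0", "0/0"),  # landrace only
    c("0/0", "0/0", "0/0", "0/0", "0/1", "0/0"),  # wild only
    c("0/1", "0/0", "1/1", "0/0", "0/0", "0/0"),  # cult & land
    c("0/1", "0/0", "0/0", "0/0", "1/1", "0/0"),  # cult & wild
    c("0/0", "0/0", "0/1", "0/0", "0/1", "0/0"),  # land & wild
    c("0/1", "0/0", "0/1", "0/0", "0/1", "0/0"),  # all three
    c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),  # monomorphic
    c("./.", "./.", "0/1", "0/0", "./.", "./."),  # landrace only (missing)
    c("1/1", "1/1", "1/1", "1/1", "1/1", "1/1"))  # monomorphic alt
  vt <- toy_vt(gt)
  meta <- toy_meta(paste0("S", 1:6),
                   rep(c("cultivar", "landrace", "wild"), each = 2))
  vp <- venn_partition(vt, meta)
  cnt <- function(region) vp$counts$n_sites[vp$counts$region == region]
  expect_equal(cnt("cultivar"), 1L)
  expect_equal(cnt("landrace"), 2L)
  expect_equal(cnt("wild"), 1L)
  expect_equal(cnt("cultivar&landrace"), 1L)
  expect_equal(cnt("cultivar&wild"), 1L)
  expect_equal(cnt("landrace&wild"), 1L)
  expect_equal(cnt("cultivar&landrace&wild"), 1L)
  expect_equal(sum(vp$counts$n_sites),
               length(unique(unlist(vp$sets))))
  # 3 of the 4 wild-variable sites appear in the domesticated union
  expect_equal(vp$wild_carried_over, 3 / 4)
  expect_error(venn_partition(vt, meta[meta$status != "wild", ]), "wild")
})

test_that("venn counts are invariant to sample and site order", {
  b <- simulate_nuclear(sim_config(
    seed = 41, n_wild = 6, n_landrace = 6, n_cultivar = 4, n_sites = 500,
    dom_specific_sites = 40, region_site_base = 5, pv_rate_base = 1,
    diag_sites = 10, duplicate_pairs = 0))
  v1 <- venn_partition(b$vt, b$meta)
  perm <- sample(n_samples(b$vt))
  v2 <- venn_partition(vt_subset(b$vt, samples = perm), b$meta)
  expect_equal(v1$counts, v2$counts)
})

test_that("clustering test input validation and planted-block detection", {
  b <- simulate_nuclear(sim_config(
    seed = 43, n_wild = 8, n_landrace = 10, n_cultivar = 6, n_sites = 4000,
    dom_specific_sites = 300, dom_block_frac = 0.5, pv_rate_base = 1,
    region_site_base = 10, diag_sites = 20, duplicate_pairs = 0))
  vt <- b$vt
  # planted block sites that realised as variable (a low-frequency draw
  # can leave a planted site monomorphic)
  blocks <- intersect(match(b$truth$dom_block_sites, vt$sites$id),
                      which(erodiv:::site_variable(vt)))
  expect_error(specific_snp_clustering(vt, blocks[1]), "at least 2")
  out <- specific_snp_clustering(vt, blocks, n_draws = 999, seed = 7)
  expect_lte(out$p, 0.01)
  expect_lt(out$observed, out$null_mean)
  # alternative statistic runs too
  out2 <- specific_snp_clustering(vt, blocks, n_draws = 99, seed = 7,
                                  statistic = "gap")
  expect_lte(out2$p, 0.05)
})

test_that("diagnostic sites use strict frequency inequalities", {
  # 20 domesticated + 20 wild haploid-coded samples
  dom_gt <- function(n_alt, n = 20) c(rep("1/1", n_alt), rep("0/0", n - n_alt))
  wild_gt <- function(n_alt, n = 20) c(rep("1/1", n_alt), rep("0/0", n - n_alt))
  gt <- rbind(c(dom_gt(20), wild_gt(2)),    # dom 1.00, wild 0.10 -> in
              c(dom_gt(19), wild_gt(2)),    # dom 0.95 exactly -> out
              c(dom_gt(20), wild_gt(5)),    # wild 0.25 exactly -> out
              c(dom_gt(20), wild_gt(6)))    # wild 0.30 -> out
  vt <- toy_vt(gt, samples = c(sprintf("d%02d", 1:20), sprintf("w%02d", 1:20)))
  meta <- toy_meta(vt$samples, c(rep("landrace", 20), rep("wild", 20)))
  ds <- diagnostic_sites(vt, meta)
  expect_equal(ds$site, 1L)
  expect_equal(ds$allele, 1L)
  expect_equal(ds$dom_freq, 1)
  expect_equal(ds$wild_freq, 0.1)
})

test_that("domestication scores count carriers over informative sites", {
  b <- simulate_nuclear(sim_config(seed = 47, exact_truth = TRUE,
                                   n_wild = 15, n_landrace = 20,
                                   n_cultivar = 8, n_sites = 3000,
                                   pv_rate_base = 0, duplicate_pairs = 0,
                                   n_ancient = 0, diag_sites = 200))
  ds <- diagnostic_sites(b$vt, b$meta)
  # planted diagnostic sites are recovered except where wild sampling
  # noise pushes the observed wild frequency over the threshold
  planted <- match(b$truth$diagnostic_sites, b$vt$sites$id)
  expect_gte(mean(planted %in% ds$site), 0.8)
  sc <- domestication_score(b$vt, ds[ds$site %in% planted, ])
  dom <- b$meta$sample[b$meta$status %in% c("landrace", "cultivar")]
  wild <- b$meta$sample[b$meta$status == "wild"]
  expect_true(all(sc$score[sc$sample %in% dom] >=
                    max(sc$score[sc$sample %in% wild])))
  expect_equal(mean(sc$score[sc$sample %in% dom]), 1)
  # wild score close to the planted diagnostic wild frequency
  expect_lt(abs(mean(sc$score[sc$sample %in% wild]) - 0.1), 0.05)
  # sample missing at every diagnostic site -> NA
  vt2 <- b$vt
  vt2$A[ds$site, 1] <- NA_integer_
  vt2$B[ds$site, 1] <- NA_integer_
  sc2 <- domestication_score(vt2, ds, samples = vt2$samples[1])
  expect_true(is.na(sc2$score))
})

test_that("genotype PCA separates planted clusters and is exact for duplicates", {
  b <- simulate_nuclear(sim_config(
    seed = 53, n_wild = 15, n_landrace = 15, n_cultivar = 10,
    n_sites = 2000, dom_specific_sites = 200, region_site_base = 10,
    pv_rate_base = 1, diag_sites = 100, duplicate_pairs = 0,
    n_ancient = 0))
  # append an exact copy of L001
  vt <- b$vt
  j0 <- match("L001", vt$samples)
  vt$A <- cbind(vt$A, L001_dup = vt$A[, j0])
  vt$B <- cbind(vt$B, L001_dup = vt$B[, j0])
  vt$DP <- cbind(vt$DP, L001_dup = vt$DP[, j0])
  vt$samples <- colnames(vt$A)
  b$vt <- vt
  p <- genotype_pca(b$vt, k = 4)
  expect_true(all(p$var_frac >= 0))
  expect_lte(sum(p$var_frac), 1 + 1e-9)
  sc <- p$scores
  st <- b$meta$status[match(sc$sample, b$meta$sample)]
  wild_pc1 <- sc$PC1[which(st == "wild")]
  dom_pc1 <- sc$PC1[which(st %in% c("landrace", "cultivar"))]
  # >= 95% of wild/domesticated pairs land on opposite sides of PC1
  frac_sep <- mean(outer(wild_pc1, dom_pc1, function(a, b) sign(a) != sign(b)))
  expect_gte(frac_sep, 0.95)
  # exact duplicates get identical coordinates
  i <- match("L001", sc$sample); j <- match("L001_dup", sc$sample)
  expect_equal(unlist(sc[i, -1]), unlist(sc[j, -1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(genotype_pca(b$vt, k = 10000), "exceeds")
})
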