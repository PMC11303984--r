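test_that("read_vcf decodes genotypes, missing calls and depths", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sA", "sB"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:12\t1/1:8",
    "chr1\t200\t.\tG\tC,GAT\t.\tPASS\t.\tGT:DP\t./.:3\t0/2:5",
    "chr1\t300\t.\tT\tTA\t.\tPASS\t.\tGT\t0/0\t1/."
  ), path)
  vt <- read_vcf(path)
  expect_equal(dim(vt$A), c(3L, 2L))
  expect_equal(vt$alleles[[2]], c("G", "C", "GAT"))
  expect_equal(vt$sites$site_kind, c("SNP", "INDEL", "INDEL"))
  # unphased decoding
  expect_equal(vt$A[1, ], c(sA = 0L, sB = 1L))
  expect_equal(vt$B[1, ], c(sA = 1L, sB = 1L))
  # ./. and half-call 1/. are missing; multiallelic kept multistate
  expect_true(is.na(vt$A[2, "sA"]))
  expect_equal(vt$B[2, "sB"], 2L)
  expect_true(is.na(vt$A[3, "sB"]))
  # record without DP -> unknown depth
  expect_true(all(is.na(vt$DP[3, ])))
  expect_equal(vt$DP[1, ], c(sA = 12L, sB = 8L))
})

test_that("read_vcf rejects sample ids absent from metadata", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sA", "sX"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1"), path)
  meta <- tibble::tibble(sample = c("sA", "sB"), status = "wild",
                         region = "r", country = "c")
  expect_error(read_vcf(path, meta), "sX")
})

test_that("depth masking follows minDP and unknown-depth policy", {
  dp <- matrix(c(2L, 3L, NA, 10L), 2, 2)
  vt <- toy_vt(matrix(c("1/1", "0/1", "0/0", "1/1"), 2, 2), depths = dp)
  m3 <- mask_low_depth(vt, 3)
  expect_true(is.na(m3$A[1, 1]))      # depth 2 < 3 -> masked
  expect_equal(unname(m3$A[2, 1]), 0L)  # depth 3 retained
  expect_equal(unname(m3$A[1, 2]), 0L)  # unknown depth passes by default
  expect_true(is.na(mask_low_depth(vt, 3, strict = TRUE)$A[1, 2]))
  # all depths >= 1: masking at 1 is the identity
  vt2 <- toy_vt(matrix("1/1", 2, 2), depths = matrix(1L, 2, 2))
  expect_identical(mask_low_depth(vt2, 1)$A, vt2$A)
})

test_that("missingness is non-decreasing across a minDP sweep", {
  set.seed(7)
  b <- simulate_nuclear(sim_config(
    seed = 7, n_wild = 5, n_landrace = 8, n_cultivar = 3, n_sites = 500,
    dom_specific_sites = 30, region_site_base = 5, pv_rate_base = 1,
    diag_sites = 10, duplicate_pairs = 0))
  prev <- rep(0, n_samples(b$vt))
  for (d in 2:5) {
    cur <- colMeans(is.na(mask_low_depth(b$vt, d)$A))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("site filters apply the >missingness and >=het rules strictly", {
  # 6 of 10 genotypes missing -> removed; exactly 50% retained
  gt_row <- function(n_miss, n_het, n = 10) {
    c(rep("./.", n_miss), rep("0/1", n_het), rep("0/0", n - n_miss - n_het))
  }
  gt <- rbind(gt_row(6, 0), gt_row(5, 0), gt_row(0, 1))
  vt <- toy_vt(gt)
  out <- filter_sites(vt, filter_config(max_het_proportion = 0.5))
  expect_equal(out$sites$pos, vt$sites$pos[2:3])
  rep <- site_filter_report(out)
  expect_equal(rep$n_sites[rep$rule == "missingness"], 1L)

  # het boundary: 1 het of 20 non-missing (5.0%) removed,
  # 1 of 21 (4.76%) retained
  gt2 <- rbind(c(rep("0/0", 19), "0/1", "./."),
               c(rep("0/0", 20), "0/1"))
  vt2 <- toy_vt(gt2)
  out2 <- filter_sites(vt2)
  expect_equal(out2$sites$pos, vt2$sites$pos[2])

  # zero non-missing calls -> removed under missingness, no div-by-zero
  vt3 <- toy_vt(rbind(rep("./.", 4), rep("0/0", 4)))
  expect_equal(n_sites(filter_sites(vt3)), 1L)
})

test_that("filter_sites is idempotent", {
  set.seed(3)
  b <- simulate_nuclear(sim_config(
    seed = 3, n_wild = 6, n_landrace = 6, n_cultivar = 4, n_sites = 400,
    residual_het = 0.1, modern_missingness = 0.3, dom_specific_sites = 20,
    region_site_base = 5, pv_rate_base = 0, diag_sites = 10,
    duplicate_pairs = 0))
  once <- filter_sites(b$vt)
  twice <- filter_sites(once)
  expect_equal(once$sites, twice$sites)
  expect_identical(once$A, twice$A)
  expect_equal(site_filter_report(twice)$n_sites[1:2], c(0L, 0L))
})

test_that("write -> read round-trip preserves the table exactly", {
  set.seed(5)
  b <- simulate_nuclear(sim_config(
    seed = 5, n_wild = 4, n_landrace = 6, n_cultivar = 3, n_sites = 300,
    dom_specific_sites = 20, region_site_base = 4, pv_rate_base = 1,
    diag_sites = 10, duplicate_pairs = 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(b$vt, path)
  back <- expect_no_warning(read_vcf(path))
  expect_identical(unname(back$A), unname(b$vt$A))
  expect_identical(unname(back$B), unname(b$vt$B))
  expect_identical(unname(back$DP), unname(b$vt$DP))
  expect_equal(back$alleles, b$vt$alleles)
  expect_equal(back$sites$pos, b$vt$sites$pos)
  expect_equal(back$samples, b$vt$samples)
})

test_that("metadata reader validates columns, statuses and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample = c("a", "b"), status = c("wild", "landrace"),
    region = "r", country = "c"), path)
  expect_equal(nrow(read_sample_meta(path)), 2L)
  readr::write_tsv(tibble::tibble(
    sample = c("a", "b"), status = c("wild", "weedy"),
    region = "r", country = "c"), path)
  expect_error(read_sample_meta(path), "weedy")
})
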