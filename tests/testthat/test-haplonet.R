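test_that("scored-site extraction enforces the minor-count rule", {
  aln <- rbind(
    s1 = c("A", "A", "A", "-", "A"),
    s2 = c("A", "G", "A", "A", "C"),
    s3 = c("A", "G", "T", "A", "N"),
    s4 = c("A", "A", "T", "A", "A"))
  h <- extract_scored_sites(aln)
  # col1 monomorphic; col2 minor G x2 kept; col3 minor T x2 kept;
  # col4 varies only by gap -> monomorphic among valid; col5 minor C x1
  expect_equal(h$positions, c(2L, 3L))
  expect_equal(dim(h$states), c(4L, 2L))
  expect_warning(extract_scored_sites(matrix("A", 3, 4,
    dimnames = list(1:3, NULL))), "no scored")
})

test_that("haplotype calling: exact match, unique partial, ambiguous partial", {
  st <- rbind(a1 = c("A", "A", "A", "A"), a2 = c("A", "A", "A", "A"),
              b1 = c("T", "T", "A", "A"), b2 = c("T", "T", "A", "A"),
              c1 = c("T", "A", "T", "A"),
              p_uniq = c("A", NA, NA, "A"),
              p_ambi = c("T", NA, NA, "A"),
              p_deep = c(NA, NA, NA, "A"))
  h <- structure(list(states = st, positions = 1:4,
                      samples = rownames(st)),
                 class = "haplotype_alignment")
  out <- call_haplotypes(h, max_missing = 0.6)
  expect_equal(unname(out$haplotype[c("a1", "a2")]), rep("H1", 2))
  # p_uniq only compatible with the A-haplotype
  expect_equal(unname(out$haplotype["p_uniq"]), "H1")
  # p_ambi compatible with both T-haplotypes -> unassigned
  expect_true(is.na(out$haplotype["p_ambi"]))
  # too much missing data -> unassigned even though compatible with all
  expect_true(is.na(out$haplotype["p_deep"]))
  expect_equal(out$haplotype_table$n[1], 3L)  # a1, a2, p_uniq
})

test_that("a 31/116-missing vector still assigns to its one compatible haplotype", {
  cp <- simulate_chloroplast(seed = 5, alignment_length = 600,
                             minor_distance = 16)
  h <- extract_scored_sites(cp$aln)
  hap <- call_haplotypes(h)
  # every planted sample gets called and multiplicities match the truth
  expect_false(anyNA(hap$haplotype))
  # now mask ~27% of scored positions of one minor-group sample, chosen
  # where all minor-group haplotypes agree, so the partial vector stays
  # uniquely compatible with its own (deeply diverged) haplotype
  st <- h$states
  victim <- cp$truth$sample[cp$truth$haplogroup == "B"][1]
  b_seq <- do.call(rbind, strsplit(
    cp$hap_def$sequence[cp$hap_def$haplogroup == "B"], ""))
  b_scored <- b_seq[, h$positions, drop = FALSE]
  agree <- which(apply(b_scored, 2, function(z) length(unique(z)) == 1))
  P <- ncol(st)
  st[victim, agree[seq_len(round(0.27 * P))]] <- NA
  h2 <- structure(list(states = st, positions = h$positions,
                       samples = h$samples), class = "haplotype_alignment")
  hap2 <- call_haplotypes(h2)
  expect_equal(unname(hap2$haplotype[victim]),
               unname(hap$haplotype[victim]))
})

test_that("median-joining solves the textbook cases", {
  # two haplotypes at distance k -> single edge of weight k
  net2 <- mj_network(rbind(x = c("A", "A", "A"), y = c("T", "T", "A")))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 2)
  # {000, 110, 101}: median 100 added, three weight-1 edges, length 3
  net3 <- mj_network(binary_haps(c(0L, 3L, 5L), 3))
  expect_equal(sum(net3$nodes$type == "median"), 1L)
  med <- net3$states[net3$nodes$name[net3$nodes$type == "median"], ]
  expect_equal(unname(med), c("1", "0", "0"))
  expect_equal(net3$total_length, 3)
  expect_true(all(net3$edges$weight == 1))
  # observed-centre star: no medians needed
  star <- binary_haps(c(0L, 1L, 2L, 4L, 8L), 4)
  net4 <- mj_network(star)
  expect_equal(sum(net4$nodes$type == "median"), 0L)
  expect_equal(net4$total_length, 4)
  # incomplete vectors are rejected
  bad <- rbind(c("A", NA), c("T", "T"))
  expect_error(mj_network(bad), "complete")
})

test_that("network keeps all observed haplotypes and stays connected", {
  set.seed(2)
  for (rep in 1:5) {
    nh <- sample(3:6, 1); nc <- sample(4:6, 1)
    haps <- binary_haps(sample(0:(2^nc - 1), nh), nc)
    net <- mj_network(haps)
    expect_true(all(rownames(haps) %in% net$nodes$name))
    g <- as_igraph(net)
    expect_equal(igraph::components(g)$no, 1L)
    # spanning length never exceeds the observed-only MST
    expect_lte(net$total_length,
               prim_weight(outer(seq_len(nh), seq_len(nh), Vectorize(
                 function(i, j) sum(haps[i, ] != haps[j, ])))))
  }
})

test_that("haplogroup assignment minimises network path length", {
  # chain: A - m - B where B sits 15 steps away
  haps <- rbind(A = rep("A", 16),
                near = c("T", rep("A", 15)),
                B = rep("T", 16))
  net <- mj_network(haps)
  hg <- assign_haplogroups(net, c(grpA = "A", grpB = "B"))
  expect_equal(hg$haplogroup[hg$haplotype == "near"], "grpA")
  expect_equal(hg$haplogroup[hg$haplotype == "A"], "grpA")
  expect_equal(hg$distance[hg$haplotype == "near"], 1)
  # equidistant node is unresolved
  haps2 <- rbind(L = c("A", "A"), mid = c("A", "T"), R = c("T", "T"))
  hg2 <- assign_haplogroups(mj_network(haps2), c(a = "L", b = "R"))
  expect_true(is.na(hg2$haplogroup[hg2$haplotype == "mid"]))
})

test_that("divergence dating follows T = (d/L) / (2 mu)", {
  expect_equal(divergence_time(0, 100, 1e-9), 0)
  expect_equal(divergence_time(2, 10000, 1e-9), 1e5)
  expect_equal(divergence_time(3, 1000, 2e-9),
               divergence_time(3, 1000, 1e-9) / 2)
  expect_error(divergence_time(1, 100, 0), "mu")
})

test_that("exclusion masks drop 0-based half-open intervals", {
  aln <- matrix(rep(c("A", "C", "G", "T"), each = 3), 3, 4,
                dimnames = list(1:3, NULL))
  out <- apply_exclusion_mask(aln, tibble::tibble(start = 1, end = 3))
  expect_equal(attr(out, "positions"), c(1L, 4L))
  expect_equal(out[1, ], c("A", "T"))
})
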