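# Small in-code fixtures and independent oracles used across the suite.

# build a variant_table from a genotype string matrix like "0/1", "./.",
# depth matrix optional
toy_vt <- function(gt, depths = NULL, chrom = NULL, pos = NULL,
                   alleles = NULL, samples = NULL) {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(alleles)) alleles <- rep(list(c("A", "T")), ns)
  if (is.null(depths)) depths <- matrix(NA_integer_, ns, ncol(gt))
  parse1 <- function(s) {
    p <- strsplit(s, "/", fixed = TRUE)[[1]]
    suppressWarnings(as.integer(p))
  }
  A <- B <- matrix(NA_integer_, ns, ncol(gt))
  for (i in seq_len(ns)) for (j in seq_len(ncol(gt))) {
    ab <- parse1(gt[i, j])
    A[i, j] <- ab[1]; B[i, j] <- ab[2]
  }
  kind <- vapply(alleles, function(a)
    if (any(nchar(a) != nchar(a[1]))) "INDEL" else "SNP", character(1))
  variant_table(
    sites = tibble::tibble(chrom = chrom, pos = pos, site_kind = kind),
    alleles = alleles, A = A, B = B, DP = depths, samples = samples)
}

# naive per-pair IBS: loop over pairs and sites, best order-free slot
# matching
naive_ibs <- function(vt) {
  ns <- n_samples(vt)
  vals <- matrix(NA_real_, ns, ns)
  comp <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    shares <- comparable <- 0
    for (s in seq_len(n_sites(vt))) {
      a1 <- vt$A[s, i]; b1 <- vt$B[s, i]
      a2 <- vt$A[s, j]; b2 <- vt$B[s, j]
      if (anyNA(c(a1, b1, a2, b2))) next
      comparable <- comparable + 1
      m1 <- (a1 == a2) + (b1 == b2)
      m2 <- (a1 == b2) + (b1 == a2)
      shares <- shares + max(m1, m2) / 2
    }
    comp[i, j] <- comparable
    vals[i, j] <- if (comparable > 0) shares / comparable else NA_real_
  }
  list(values = vals, comparable = comp)
}

# brute-force per-site nucleotide diversity: enumerate all sequence pairs
# at every site with >= 2 valid bases
brute_pi <- function(m) {
  m <- as_alignment(m)
  tot <- 0; included <- 0
  for (s in seq_len(ncol(m))) {
    v <- m[, s]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    included <- included + 1
    diffs <- 0; pairs <- 0
    for (i in seq_len(length(v) - 1)) for (j in (i + 1):length(v)) {
      pairs <- pairs + 1
      if (v[i] != v[j]) diffs <- diffs + 1
    }
    tot <- tot + diffs / pairs
  }
  if (included == 0) return(NA_real_)
  tot / included
}

# -- exhaustive Steiner oracle for small binary haplotype sets ----------

popcount6 <- vapply(0:63, function(x) sum(bitwAnd(x, 2^(0:5)) > 0), numeric(1))

prim_weight <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  w <- 0
  for (s in seq_len(n - 1)) {
    cand <- which(!intree)
    i <- cand[which.min(mind[cand])]
    w <- w + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, d[i, ])
  }
  w
}

# minimum spanning length achievable by augmenting the observed binary
# vectors with up to max_add Steiner points, by exhaustive enumeration
steiner_optimum <- function(obs_int, nchar, max_add = 3) {
  allv <- 0:(2^nchar - 1)
  D <- outer(allv, allv, function(a, b) popcount6[bitwXor(a, b) + 1])
  best <- prim_weight(D[obs_int + 1, obs_int + 1, drop = FALSE])
  cands <- setdiff(allv, obs_int)
  if (max_add >= 1) for (m in seq_len(max_add)) {
    cmb <- utils::combn(cands, m)
    for (c in seq_len(ncol(cmb))) {
      idx <- c(obs_int, cmb[, c]) + 1
      w <- prim_weight(D[idx, idx, drop = FALSE])
      if (w < best) best <- w
    }
  }
  best
}

# integer-coded binary haplotypes -> character state matrix for mj_network
binary_haps <- function(ints, nchar) {
  m <- t(vapply(ints, function(x)
    as.integer(bitwAnd(x, 2^(0:(nchar - 1))) > 0), integer(nchar)))
  matrix(as.character(m), nrow = length(ints),
         dimnames = list(paste0("h", seq_along(ints)), NULL))
}

# write a minimal VCF text fixture
write_toy_vcf <- function(lines, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##contig=<ID=chr1>")
  writeLines(c(header, lines), path)
  path
}
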