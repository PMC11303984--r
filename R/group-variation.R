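# variable sites within a sample subset: >= 2 distinct alleles among
# non-missing calls (a het carries both of its alleles)
group_variable_sites <- function(x, ids) {
  site_variable(vt_subset(x, samples = ids))
}

#' Partition variable sites among cultivars, landraces and wild barley
#'
#' A site is "variable in a group" when at least two distinct alleles
#' occur among the group's non-missing calls. Returns the per-group
#' variable-site sets, the seven intersection-region counts, and the
#' fraction of wild-variable sites also variable in the domesticated
#' union (the share of wild diversity carried over).
#'
#' @param x a `variant_table`.
#' @param meta metadata tibble with `sample` and `status`; the three
#'   groups are `cultivar`, `landrace`, `wild` (all must be non-empty).
#' @return An object of class `venn_partition`: list with `sets` (named
#'   list of site-id vectors), `counts` (tibble of the 7 regions),
#'   `wild_carried_over` (fraction).
#' @export
venn_partition <- function(x, meta) {
  groups <- c("cultivar", "landrace", "wild")
  ids <- lapply(groups, function(g) meta$sample[meta$status == g &
                                                  meta$sample %in% x$samples])
  names(ids) <- groups
  empty <- groups[lengths(ids) == 0]
  if (length(empty) > 0)
    stop("empty group(s): ", paste(empty, collapse = ", "))
  memb <- vapply(ids, function(s) group_variable_sites(x, s),
                 logical(n_sites(x)))
  sets <- lapply(groups, function(g) x$sites$id[memb[, g]])
  names(sets) <- groups
  combos <- expand.grid(cultivar = c(TRUE, FALSE), landrace = c(TRUE, FALSE),
                        wild = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  counts <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    inside <- rep(TRUE, n_sites(x))
    for (g in groups) inside <- inside &
        (if (combos[i, g]) memb[, g] else !memb[, g])
    tibble::tibble(
      region = paste(groups[unlist(combos[i, ])], collapse = "&"),
      n_sites = sum(inside & rowSums(memb) > 0))
  })
  dom <- memb[, "cultivar"] | memb[, "landrace"]
  structure(list(
    sets = sets, counts = counts,
    wild_carried_over = if (sum(memb[, "wild"]) > 0)
      sum(memb[, "wild"] & dom) / sum(memb[, "wild"]) else NA_real_
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  print(x$counts)
  cat(sprintf("wild diversity carried over to domesticated: %.1f%%\n",
              100 * x$wild_carried_over))
  invisible(x)
}

#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) x$counts

#' Permutation test for physical clustering of group-specific SNPs
#'
#' Observed statistic: the mean nearest-neighbour base-pair distance
#' among the specific sites, computed within chromosomes (chromosomes
#' with fewer than two specific sites contribute nothing). The null
#' distribution comes from `n_draws` uniform random subsets of equal
#' size drawn from all variable sites; the empirical p-value is
#' `(1 + #[null <= observed]) / (n_draws + 1)` (one-sided: are the
#' specific sites closer together than random ones?).
#'
#' @param x a `variant_table`.
#' @param specific integer site row indices (or site ids) of the
#'   group-specific SNPs; must be a subset of the variable sites, with at
#'   least 2 elements.
#' @param n_draws number of random draws; default 999.
#' @param seed RNG seed for the draws.
#' @param statistic `"nn"` (nearest-neighbour, default) or `"gap"` (mean
#'   adjacent gap).
#' @return A tibble with `observed`, `null_mean`, `null_sd`, `p`,
#'   `n_draws`, `seed`; the null values are in attribute `"null"`.
#' @export
specific_snp_clustering <- function(x, specific, n_draws = 999, seed = 1,
                                    statistic = c("nn", "gap")) {
  statistic <- match.arg(statistic)
  if (is.character(specific)) specific <- match(specific, x$sites$id)
  stopifnot(!anyNA(specific))
  if (length(specific) < 2)
    stop("need at least 2 specific sites")
  universe <- which(site_variable(x))
  if (!all(specific %in% universe))
    stop("specific sites must be a subset of the variable sites")
  chrom <- x$sites$chrom
  pos <- x$sites$pos
  stat_of <- function(idx) {
    vals <- unlist(lapply(split(pos[idx], chrom[idx]), function(p) {
      if (length(p) < 2) return(NULL)
      p <- sort(p)
      gaps <- diff(p)
      if (statistic == "gap") gaps
      else pmin(c(gaps, Inf), c(Inf, gaps))   # per-site nearest neighbour
    }))
    if (length(vals) == 0)
      stop("no chromosome has >= 2 sites in the subset")
    mean(vals)
  }
  observed <- stat_of(specific)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i)
    stat_of(sample(universe, length(specific))), numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- (1 + sum(null <= observed)) / (n_draws + 1)
  out <- tibble::tibble(observed = observed, null_mean = mean(null),
                        null_sd = stats::sd(null), p = p,
                        n_draws = n_draws, seed = seed)
  attr(out, "null") <- null
  out
}

#' Diagnostic domestication sites
#'
#' Sites where some allele has frequency strictly above `hi` among
#' domesticated samples (landraces + cultivars) and strictly below `lo`
#' among wild samples, over non-missing calls per group. Hybrid/feral
#' and ancient samples belong to neither frequency group.
#'
#' @param x a `variant_table`.
#' @param meta metadata tibble with `sample` and `status`.
#' @param hi domesticated-frequency threshold (strict >); default 0.95.
#' @param lo wild-frequency threshold (strict <); default 0.25.
#' @return A tibble with `site`, `chrom`, `pos`, `allele` (0-based index
#'   of the domesticated variant) and the two frequencies; thresholds in
#'   attribute `"thresholds"`.
#' @export
diagnostic_sites <- function(x, meta, hi = 0.95, lo = 0.25) {
  dom_ids <- meta$sample[meta$status %in% domesticated_statuses() &
                           meta$sample %in% x$samples]
  wild_ids <- meta$sample[meta$status == "wild" & meta$sample %in% x$samples]
  if (length(dom_ids) == 0 || length(wild_ids) == 0)
    stop("both the domesticated and the wild group must be non-empty")
  allele_freq <- function(ids, k) {
    sub <- vt_subset(x, samples = ids)
    occ <- (sub$A == k) + (sub$B == k)
    cnt <- rowSums(occ, na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(sub$A))
    ifelse(tot > 0, cnt / tot, NA_real_)
  }
  out <- list()
  for (k in 0:(max(lengths(x$alleles)) - 1L)) {
    fd <- allele_freq(dom_ids, k)
    fw <- allele_freq(wild_ids, k)
    hit <- which(!is.na(fd) & !is.na(fw) & fd > hi & fw < lo &
                   lengths(x$alleles) > k)
    if (length(hit) > 0)
      out[[length(out) + 1]] <- tibble::tibble(
        site = hit, chrom = x$sites$chrom[hit], pos = x$sites$pos[hit],
        allele = k, dom_freq = fd[hit], wild_freq = fw[hit])
  }
  res <- if (length(out) > 0) dplyr::arrange(dplyr::bind_rows(out),
                                             .data$site, .data$allele)
         else tibble::tibble(site = integer(), chrom = character(),
                             pos = integer(), allele = integer(),
                             dom_freq = numeric(), wild_freq = numeric())
  attr(res, "thresholds") <- c(hi = hi, lo = lo)
  res
}

#' Domestication score of samples at diagnostic sites
#'
#' Fraction of diagnostic sites, non-missing in the sample, where the
#' sample carries at least one copy of the domesticated variant (or two
#' copies with `hom_only = TRUE`).
#'
#' @param x a `variant_table`.
#' @param sites tibble from [diagnostic_sites()].
#' @param samples sample ids to score; default all.
#' @param hom_only require homozygous carriage; default `FALSE`.
#' @return A tibble with `sample`, `n_informative`, `score` (`NA` when a
#'   sample is missing at every diagnostic site).
#' @export
domestication_score <- function(x, sites, samples = NULL,
                                hom_only = FALSE) {
  if (nrow(sites) == 0) stop("no diagnostic sites supplied")
  if (is.null(samples)) samples <- x$samples
  A <- x$A[sites$site, samples, drop = FALSE]
  B <- x$B[sites$site, samples, drop = FALSE]
  occ <- (A == sites$allele) + (B == sites$allele)
  carries <- if (hom_only) occ == 2 else occ > 0
  informative <- colSums(!is.na(A))
  score <- ifelse(informative > 0,
                  colSums(carries, na.rm = TRUE) / informative, NA_real_)
  tibble::tibble(sample = samples, n_informative = as.integer(informative),
                 score = unname(score))
}

#' Genotype principal component analysis
#'
#' Samples are encoded as 0/1/2 alternate-allele dosages (multistate
#' sites use the most frequent non-reference allele), columns are
#' mean-centred, missing entries imputed to the column mean, and (by
#' default) scaled by `sqrt(p(1-p))` with `p` the allele frequency
#' (Patterson normalisation). Scores are the top-k left singular vectors
#' scaled by their singular values.
#'
#' @param x a `variant_table` with >= 2 samples and >= 1 variable site.
#' @param k number of components; default `min(10, n_samples - 1)`.
#' @param scale `"patterson"` (default) or `"none"`.
#' @return An object of class `genotype_pca`: `scores` tibble (sample,
#'   PC1..PCk) and `var_frac` (fraction of total variance per PC).
#' @export
genotype_pca <- function(x, k = NULL, scale = c("patterson", "none")) {
  scale <- match.arg(scale)
  stopifnot(n_samples(x) >= 2)
  if (is.null(k)) k <- min(10L, n_samples(x) - 1L)
  variable <- which(site_variable(x))
  if (length(variable) == 0) stop("no variable sites")
  if (k > min(n_samples(x), length(variable)))
    stop("k exceeds min(samples, variable sites)")
  sub <- vt_subset(x, sites = variable)
  # dosage of the most frequent non-reference allele per site
  max_alt <- max(lengths(sub$alleles)) - 1L
  best_cnt <- rep(-1, n_sites(sub))
  dose <- matrix(0, n_sites(sub), n_samples(sub))
  for (kk in seq_len(max_alt)) {
    occ <- (sub$A == kk) + (sub$B == kk)
    cnt <- rowSums(occ, na.rm = TRUE)
    upd <- cnt > best_cnt
    if (any(upd)) {
      dose[upd, ] <- occ[upd, , drop = FALSE]
      best_cnt[upd] <- cnt[upd]
    }
  }
  G <- t(dose)                       # samples x sites, NA = missing
  mu <- colMeans(G, na.rm = TRUE)
  G <- sweep(G, 2, mu)
  G[is.na(G)] <- 0                   # impute to column mean (0 after centring)
  if (scale == "patterson") {
    p <- mu / 2
    sdv <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    G <- sweep(G, 2, sdv, "/")
  }
  sv <- svd(G, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = tibble::as_tibble(cbind(tibble::tibble(sample = x$samples),
                                     as.data.frame(scores))),
    var_frac = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    k = k, scale = scale, n_sites_used = length(variable)
  ), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca> ", nrow(x$scores), " samples, ", x$n_sites_used,
      " sites, ", x$k, " components\n", sep = "")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy genotype_pca
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' @method glance genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(k = x$k, n_sites = x$n_sites_used,
                 var_frac_pc1 = x$var_frac[1],
                 var_frac_total = sum(x$var_frac))
}

#' Plot the first two genotype principal components
#'
#' @param object a `genotype_pca`.
#' @param meta optional metadata with `sample` and `status` for colour.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot genotype_pca
#' @export
autoplot.genotype_pca <- function(object, meta = NULL, ...) {
  d <- object$scores
  if (!is.null(meta))
    d <- dplyr::left_join(d, meta[, c("sample", "status")], by = "sample")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])) +
    ggplot2::theme_minimal()
  if (!is.null(meta)) p + ggplot2::geom_point(ggplot2::aes(colour = .data$status))
  else p + ggplot2::geom_point()
}
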