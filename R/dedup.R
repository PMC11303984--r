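#' Identity-by-state similarity matrix
#'
#' For every sample pair, IBS is the mean over mutually non-missing sites
#' of the per-site share of allele slots identical by state (0, 0.5 or 1
#' for diploid genotypes, order-free), with flat weighting: every
#' comparable site weighs 1 regardless of allele frequency. A pair with
#' zero comparable sites gets `NA` with a warning.
#'
#' The per-site share equals the multiset intersection of the two
#' genotypes' alleles divided by 2, which allows the whole matrix to be
#' accumulated from per-allele dosage cross-products instead of a loop
#' over pairs.
#'
#' @param x a `variant_table` with at least two samples.
#' @return An object of class `ibs_matrix`: list with `values` (symmetric
#'   similarity matrix, diagonal 1), `comparable` (counts of mutually
#'   non-missing sites) and `samples`.
#' @export
ibs_matrix <- function(x) {
  stopifnot(n_samples(x) >= 2)
  V <- 1 - is.na(x$A)              # valid-call indicator
  storage.mode(V) <- "double"
  comparable <- crossprod(V)
  max_allele <- max(lengths(x$alleles)) - 1L
  # sum over alleles k of |dose_k(i) - dose_k(j)| restricted to mutually
  # valid sites; |d| = d^2 except for the (0,2) case which contributes 2
  # instead of 4
  S <- matrix(0, n_samples(x), n_samples(x))
  for (k in 0:max_allele) {
    Dk <- (x$A == k) + (x$B == k)
    Dk[is.na(Dk)] <- 0
    storage.mode(Dk) <- "double"
    D2 <- Dk^2
    sq <- crossprod(D2, V)
    S <- S + sq + t(sq) - 2 * crossprod(Dk)
    Z <- V * (Dk == 0)
    Tw <- (Dk == 2) * 1
    zt <- crossprod(Z, Tw)
    S <- S - 2 * (zt + t(zt))
  }
  values <- ifelse(comparable > 0, 1 - S / (4 * comparable), NA_real_)
  diag(values) <- 1
  dimnames(values) <- dimnames(comparable) <- list(x$samples, x$samples)
  if (any(comparable[upper.tri(comparable)] == 0))
    warning("sample pair(s) with zero comparable sites; IBS undefined for them")
  structure(list(values = values, comparable = comparable,
                 samples = x$samples),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  cat("<ibs_matrix> ", length(x$samples), " samples; IBS range ",
      sprintf("%.3f-%.3f", min(x$values, na.rm = TRUE),
              max(x$values[upper.tri(x$values)], na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' @method tidy ibs_matrix
#' @export
tidy.ibs_matrix <- function(x, ...) {
  ut <- upper.tri(x$values)
  tibble::tibble(
    sample1 = rownames(x$values)[row(x$values)[ut]],
    sample2 = colnames(x$values)[col(x$values)[ut]],
    ibs = x$values[ut],
    comparable_sites = x$comparable[ut]
  )
}

#' Find groups of duplicated accessions
#'
#' Duplicate groups are the connected components of the graph with an
#' edge between samples whose IBS similarity exceeds `threshold`
#' (transitive grouping). Singleton components are omitted; undefined
#' (NA) similarities contribute no edge.
#'
#' @param m an [ibs_matrix()].
#' @param threshold IBS similarity above which two samples are considered
#'   duplicates; default 0.985.
#' @return A list of character vectors of sample ids (each of length >= 2),
#'   sorted within and between groups.
#' @export
find_duplicate_groups <- function(m, threshold = 0.985) {
  ut <- which(upper.tri(m$values) & !is.na(m$values) & m$values > threshold,
              arr.ind = TRUE)
  if (nrow(ut) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = m$samples[ut[, 1]], to = m$samples[ut[, 2]]),
    directed = FALSE, vertices = data.frame(name = m$samples))
  comp <- igraph::components(g)
  grp <- split(m$samples, comp$membership)
  grp <- grp[lengths(grp) >= 2]
  grp <- lapply(grp, sort)
  unname(grp[order(vapply(grp, `[`, character(1), 1))])
}

#' Prune duplicate groups down to one representative
#'
#' Within each duplicate group the sample with the lowest genotype
#' missingness is retained; ties are broken by the lexicographically
#' smallest sample id.
#'
#' @param groups list of duplicate groups ([find_duplicate_groups()]).
#' @param missingness named numeric vector (or tibble with `sample` and
#'   `missingness` columns, e.g. from [sample_missingness()]) covering all
#'   grouped samples.
#' @return A list with `retained` and `dropped` character vectors
#'   (`retained` contains one id per group; samples outside any group are
#'   not listed).
#' @export
prune_duplicates <- function(groups, missingness) {
  if (is.data.frame(missingness))
    missingness <- stats::setNames(missingness$missingness, missingness$sample)
  retained <- character(0); dropped <- character(0)
  for (g in groups) {
    miss <- missingness[g]
    if (anyNA(miss)) stop("missingness unknown for sample(s): ",
                          paste(g[is.na(miss)], collapse = ", "))
    keep <- sort(g[miss == min(miss)])[1]
    retained <- c(retained, keep)
    dropped <- c(dropped, setdiff(g, keep))
  }
  list(retained = retained, dropped = dropped)
}

#' Drop duplicated samples from a variant table
#'
#' Convenience wrapper: computes IBS, finds duplicate groups at
#' `threshold`, prunes each group by missingness and returns the reduced
#' table.
#'
#' @inheritParams ibs_matrix
#' @inheritParams find_duplicate_groups
#' @return A `variant_table` without the dropped duplicates; the dedup
#'   decision is attached as attribute `"dedup"`.
#' @export
drop_duplicate_samples <- function(x, threshold = 0.985) {
  m <- ibs_matrix(x)
  groups <- find_duplicate_groups(m, threshold)
  pr <- prune_duplicates(groups, sample_missingness(x))
  out <- vt_subset(x, samples = setdiff(x$samples, pr$dropped))
  attr(out, "dedup") <- list(groups = groups, retained = pr$retained,
                             dropped = pr$dropped, threshold = threshold)
  out
}
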