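#' Genotype table for multi-sample variant data
#'
#' A `variant_table` holds a sites-by-samples diploid genotype matrix
#' together with per-genotype sequencing depths and per-site allele
#' definitions. Genotypes are stored as two integer matrices of 0-based
#' allele indices (`A`, `B`, with `A <= B` so unphased genotypes are
#' order-free); `NA` marks a missing call. Depths are integers with `NA`
#' meaning unknown. Multiallelic sites are kept multistate, never split.
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based), `id`,
#'   `site_kind` (`"SNP"` or `"INDEL"`).
#' @param alleles list of character vectors, reference allele first.
#' @param A,B integer matrices (sites x samples) of allele indices, `NA`
#'   for missing calls.
#' @param DP integer matrix of per-genotype depths, `NA` for unknown.
#' @param samples character vector of sample ids (unique).
#' @param validate check and normalise genotype encoding (unordered
#'   pairs, half-calls, allele-index bounds); internal callers that
#'   already guarantee a normalised encoding may pass `FALSE`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, alleles, A, B, DP, samples,
                          validate = TRUE) {
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos", "site_kind") %in% names(sites)),
    length(alleles) == nrow(sites),
    is.matrix(A), is.matrix(B),
    all(dim(A) == c(nrow(sites), length(samples))),
    all(dim(B) == dim(A)), all(dim(DP) == dim(A)),
    !anyDuplicated(samples)
  )
  if (!"id" %in% names(sites)) sites$id <- paste0(sites$chrom, ":", sites$pos)
  if (validate) {
    # unordered genotypes: normalise so A <= B
    swap <- !is.na(A) & !is.na(B) & A > B
    if (any(swap)) {
      tmp <- A[swap]; A[swap] <- B[swap]; B[swap] <- tmp
    }
    # half-calls are treated as missing
    half <- xor(is.na(A), is.na(B))
    if (any(half)) { A[half] <- NA_integer_; B[half] <- NA_integer_ }
    nall <- lengths(alleles)
    hi <- suppressWarnings(max(B, na.rm = TRUE))
    if (is.finite(hi) && hi >= min(nall)) {
      bad <- which(!is.na(B) & B >= nall[row(B)])
      if (length(bad) > 0)
        stop("genotype allele index exceeds allele count at site row ",
             row(B)[bad[1]])
    }
  }
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    alleles <- alleles[ord]
    A <- A[ord, , drop = FALSE]; B <- B[ord, , drop = FALSE]
    DP <- DP[ord, , drop = FALSE]
  }
  colnames(A) <- colnames(B) <- colnames(DP) <- samples
  structure(
    list(sites = tibble::as_tibble(sites), alleles = alleles,
         A = A, B = B, DP = DP, samples = samples),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", n_sites(x), " sites x ", n_samples(x), " samples\n",
      sep = "")
  kinds <- table(x$sites$site_kind)
  cat("  ", paste(names(kinds), kinds, sep = ": ", collapse = ", "), "\n",
      sep = "")
  cat("  missing calls: ",
      sprintf("%.1f%%", 100 * mean(is.na(x$A))), "\n", sep = "")
  invisible(x)
}

#' @rdname variant_table
#' @param x a `variant_table`.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname variant_table
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a variant table by sites and/or samples
#'
#' @param x a `variant_table`.
#' @param sites integer or logical index over site rows.
#' @param samples character, integer or logical index over samples.
#' @return A `variant_table`.
#' @export
vt_subset <- function(x, sites = NULL, samples = NULL) {
  if (!is.null(sites)) {
    x$sites <- x$sites[sites, , drop = FALSE]
    x$alleles <- x$alleles[sites]
    x$A <- x$A[sites, , drop = FALSE]
    x$B <- x$B[sites, , drop = FALSE]
    x$DP <- x$DP[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    x$A <- x$A[, samples, drop = FALSE]
    x$B <- x$B[, samples, drop = FALSE]
    x$DP <- x$DP[, samples, drop = FALSE]
    x$samples <- colnames(x$A)
  }
  x
}

#' Per-sample missingness of a variant table
#'
#' Fraction of sites with a missing genotype call, per sample.
#'
#' @param x a `variant_table`.
#' @return A tibble with columns `sample` and `missingness`.
#' @export
sample_missingness <- function(x) {
  tibble::tibble(sample = x$samples, missingness = colMeans(is.na(x$A)))
}

# exact-duplicate genotype columns, located via two weighted checksums
# (candidates verified exactly)
duplicate_column_pairs <- function(x) {
  A <- x$A; B <- x$B
  na <- is.na(A)
  w1 <- seq_len(nrow(A)) %% 97 + 1
  w2 <- seq_len(nrow(A)) %% 89 + 3
  cs <- rbind(colSums((A + 2L) * w1, na.rm = TRUE),
              colSums((B + 2L) * w2, na.rm = TRUE),
              colSums(na * w1))
  key <- apply(cs, 2, paste, collapse = "|")
  cand <- which(key %in% key[duplicated(key)])
  out <- NULL
  if (length(cand) > 1) {
    for (i in cand) for (j in cand) if (i < j && key[i] == key[j] &&
        identical(A[, i], A[, j]) && identical(B[, i], B[, j]))
      out <- rbind(out, c(i, j))
  }
  out
}

has_duplicate_columns <- function(x) !is.null(duplicate_column_pairs(x))

# per-site counts used by several filters
site_call_stats <- function(x) {
  nonmiss <- rowSums(!is.na(x$A))
  het <- rowSums(x$A != x$B, na.rm = TRUE)
  tibble::tibble(
    nonmiss = nonmiss,
    missing_frac = 1 - nonmiss / n_samples(x),
    het = het,
    het_frac = ifelse(nonmiss > 0, het / nonmiss, NA_real_)
  )
}

#' Read a sample metadata table
#'
#' Expects a TSV with header columns `sample`, `status`, `region`,
#' `country`. `status` must be one of wild, landrace, cultivar, ancient,
#' hybrid/feral.
#'
#' @param path path to a tab-separated file.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "status", "region", "country")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  ok <- c("wild", "landrace", "cultivar", "ancient", "hybrid/feral")
  bad <- setdiff(unique(meta$status), ok)
  if (length(bad) > 0)
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop("duplicated sample ids in metadata")
  meta
}

# the domesticated statuses used throughout (hybrid/feral belongs to neither
# the wild nor the domesticated reference group)
domesticated_statuses <- function() c("landrace", "cultivar")
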