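#' Coerce sequences to an alignment matrix
#'
#' Accepts a character matrix (sequences x positions), a named character
#' vector of equal-length strings, or a list of single characters.
#' Everything other than A/C/G/T (case-insensitive) — gaps, N, IUPAC
#' ambiguities — is treated as missing.
#'
#' @param x sequences in any of the accepted forms.
#' @return An upper-case character matrix with `NA` at non-ACGT positions.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) m <- toupper(x)
  else {
    x <- unlist(x)
    lens <- nchar(x)
    if (length(unique(lens)) != 1)
      stop("aligned sequences must have equal lengths")
    m <- toupper(do.call(rbind, strsplit(x, "", fixed = TRUE)))
    rownames(m) <- names(x)
  }
  m[!m %in% c("A", "C", "G", "T")] <- NA_character_
  m
}

#' Read a FASTA alignment as a character matrix
#'
#' @param path path to an (uncompressed or gzipped) FASTA file of
#'   equal-length aligned sequences.
#' @return A character matrix via [as_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  as_alignment(seqs)
}

# per-site counts of the four bases; rows = sites
site_base_counts <- function(m) {
  vapply(c("A", "C", "G", "T"),
         function(b) colSums(m == b, na.rm = TRUE),
         numeric(ncol(m)))
}

#' Nucleotide diversity (pi) with pairwise deletion
#'
#' Per-site nucleotide diversity under the NumNuc = 2 convention: a site
#' is included iff at least two sequences carry an unambiguous base
#' there; its contribution is the mean pairwise difference among the
#' valid bases, and pi is the average contribution over included sites.
#'
#' @param x an alignment (see [as_alignment()]); >= 2 sequences.
#' @return Per-site pi, with attributes `L` (included sites) and `n`.
#' @export
nucleotide_diversity_pi <- function(x) {
  m <- as_alignment(x)
  if (nrow(m) < 2) stop("pi needs >= 2 sequences")
  cnt <- site_base_counts(m)
  n <- rowSums(cnt)
  keep <- n >= 2
  if (!any(keep)) return(structure(NA_real_, L = 0L, n = nrow(m)))
  pairs <- n[keep] * (n[keep] - 1) / 2
  same <- rowSums(cnt[keep, , drop = FALSE] *
                    (cnt[keep, , drop = FALSE] - 1) / 2)
  pi_site <- (pairs - same) / pairs
  structure(sum(pi_site) / sum(keep), L = sum(keep), n = nrow(m))
}

#' Watterson's Theta per site
#'
#' `Theta = S / (a * L)` where S counts included segregating sites
#' (>= 2 valid bases and >= 2 states among them), `a` is the harmonic
#' number over `n - 1` for `n` sequences, and `L` the included site
#' count.
#'
#' @param x an alignment; >= 2 sequences.
#' @return Per-site Theta, with attributes `S`, `L`, `n`.
#' @export
watterson_theta <- function(x) {
  m <- as_alignment(x)
  n_seq <- nrow(m)
  if (n_seq < 2) stop("Watterson's Theta needs >= 2 sequences")
  cnt <- site_base_counts(m)
  n <- rowSums(cnt)
  keep <- n >= 2
  states <- rowSums(cnt > 0)
  S <- sum(keep & states >= 2)
  L <- sum(keep)
  a <- sum(1 / seq_len(n_seq - 1))
  structure(if (L > 0) S / (a * L) else NA_real_, S = S, L = L, n = n_seq)
}

#' Haplotype diversity
#'
#' `H = N/(N-1) * (1 - sum(x_i^2))` where `x_i` is the frequency of
#' haplotype i and N the sample size.
#'
#' @param counts named (or unnamed) vector of haplotype counts; N >= 2.
#' @return H in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) stop("haplotype diversity needs N >= 2")
  N / (N - 1) * (1 - sum((counts / N)^2))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles (here: haplotypes counted as
#' alleles) in a subsample of size `g` drawn without replacement:
#' `A(g) = sum_a [1 - C(N - N_a, g) / C(N, g)]`.
#'
#' @param counts vector of haplotype counts.
#' @param g rarefaction size, `1 <= g <= N`.
#' @return A(g).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("rarefaction size g must be in [1, N]")
  miss <- ifelse(N - counts < g, 0,
                 exp(lchoose(N - counts, g) - lchoose(N, g)))
  sum(1 - miss)
}

#' Per-group diversity table
#'
#' Computes N, segregating sites, per-site pi and Theta from the
#' alignment for each group, plus haplotype diversity and rarefied
#' allelic richness from haplotype assignments when given.
#'
#' @param x an alignment; rows must be named with sample ids.
#' @param groups named character vector mapping sample id to group label.
#' @param haplotypes optional named character vector mapping sample id to
#'   haplotype label (`NA` = unassigned, dropped from H and A(g)).
#' @param g rarefaction size; default: the smallest group's N.
#' @return A tibble with one row per group.
#' @export
diversity_summary <- function(x, groups, haplotypes = NULL, g = NULL) {
  m <- as_alignment(x)
  stopifnot(!is.null(rownames(m)), all(names(groups) %in% rownames(m)))
  labs <- unique(groups)
  if (is.null(g)) g <- min(table(groups))
  purrr::map_dfr(labs, function(lab) {
    ids <- names(groups)[groups == lab]
    sub <- m[ids, , drop = FALSE]
    pi <- if (length(ids) >= 2) nucleotide_diversity_pi(sub) else NA_real_
    th <- if (length(ids) >= 2) watterson_theta(sub) else NA_real_
    row <- tibble::tibble(
      group = lab, n = length(ids),
      segregating_sites = if (length(ids) >= 2) attr(th, "S") else NA_integer_,
      pi = as.numeric(pi), theta = as.numeric(th),
      haplotype_diversity = NA_real_, allelic_richness = NA_real_
    )
    if (!is.null(haplotypes)) {
      h <- haplotypes[ids]
      h <- h[!is.na(h)]
      if (length(h) >= 2) {
        tab <- table(h)
        row$haplotype_diversity <- haplotype_diversity(tab)
        if (g <= sum(tab)) row$allelic_richness <- allelic_richness(tab, g)
      }
    }
    row
  })
}
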