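#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file (plain or bgzipped) with vcfR and decodes it into
#' the internal genotype model. Genotypes are decoded unphased; `./.` and
#' half-calls (e.g. `1/.`) become missing; a record without a DP FORMAT
#' field gets unknown depth for all its genotypes. Multiallelic records
#' are kept multistate. A site is flagged INDEL iff any allele length
#' differs from the reference allele length.
#'
#' @param path path to the VCF file.
#' @param meta optional sample metadata tibble (see [read_sample_meta()]);
#'   if given, the VCF sample ids must all be present in `meta$sample`.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  samples <- colnames(v@gt)[-1]
  if (!is.null(meta)) {
    unknown <- setdiff(samples, meta$sample)
    if (length(unknown) > 0)
      stop("VCF sample id(s) not found in metadata: ",
           paste(unknown, collapse = ", "))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alleles <- purrr::map2(ref, alt, function(r, a) {
    if (is.na(a) || a == "." || a == "") r else c(r, strsplit(a, ",", fixed = TRUE)[[1]])
  })
  kind <- vapply(alleles, function(al)
    if (any(nchar(al) != nchar(al[1]))) "INDEL" else "SNP", character(1))
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos)) stop("malformed POS field at record line ", which(is.na(pos))[1])

  gt <- vcfR::extract.gt(v, element = "GT")
  # decode via a lookup over the (small) set of distinct genotype strings
  decode_gt <- function(codes) {
    a <- b <- rep(NA_integer_, length(codes))
    valid <- !is.na(codes) & grepl("^[0-9]+[/|][0-9]+$", codes)
    if (any(valid)) {
      parts <- strsplit(codes[valid], "[/|]")
      a[valid] <- as.integer(vapply(parts, `[`, character(1), 1))
      b[valid] <- as.integer(vapply(parts, `[`, character(1), 2))
    }
    list(a = a, b = b)
  }
  codes <- unique(as.vector(gt))
  dec <- decode_gt(codes)
  idx <- match(gt, codes)
  A <- matrix(dec$a[idx], nrow = nrow(gt), dimnames = dimnames(gt))
  B <- matrix(dec$b[idx], nrow = nrow(gt), dimnames = dimnames(gt))

  has_dp <- grepl("(^|:)DP(:|$)", v@gt[, "FORMAT"])
  DP <- matrix(NA_integer_, nrow = nrow(A), ncol = ncol(A))
  if (any(has_dp)) {
    dp <- suppressWarnings(
      apply(vcfR::extract.gt(v, element = "DP"), 2, as.integer))
    dp <- matrix(dp, nrow = nrow(A))
    DP[has_dp, ] <- dp[has_dp, ]
  }

  variant_table(
    sites = tibble::tibble(chrom = fix[, "CHROM"], pos = pos,
                           id = paste0(fix[, "CHROM"], ":", pos),
                           site_kind = kind),
    alleles = alleles, A = A, B = B, DP = DP, samples = samples
  )
}

#' Write a variant table as a VCF file
#'
#' Emits a minimal, deterministic VCF 4.2 text file with GT:DP genotype
#' fields. Unknown depths are written as `.`; missing genotypes as `./.`.
#'
#' @param x a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  ref <- vapply(x$alleles, `[`, character(1), 1)
  alt <- vapply(x$alleles, function(a)
    if (length(a) > 1) paste(a[-1], collapse = ",") else ".", character(1))
  gt <- matrix(paste0(ifelse(is.na(x$A), ".", x$A), "/",
                      ifelse(is.na(x$B), ".", x$B), ":",
                      ifelse(is.na(x$DP), ".", x$DP)),
               nrow = n_sites(x))
  body <- paste(x$sites$chrom, x$sites$pos, x$sites$id, ref, alt,
                ".", "PASS", ".", "GT:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##contig=<ID=", unique(x$sites$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Mask genotype calls below a depth threshold
#'
#' Sets genotypes with per-genotype depth below `min_depth` to missing
#' (the minDP genotype-calling regime). Unknown depth passes by default;
#' set `strict = TRUE` to mask unknown depths as well.
#'
#' @param x a `variant_table`.
#' @param min_depth integer >= 1.
#' @param strict if `TRUE`, unknown depths are masked too.
#' @return A `variant_table` with low-depth calls set to missing.
#' @export
mask_low_depth <- function(x, min_depth, strict = FALSE) {
  stopifnot(min_depth >= 1)
  drop <- if (strict) is.na(x$DP) | x$DP < min_depth
          else !is.na(x$DP) & x$DP < min_depth
  x$A[drop] <- NA_integer_
  x$B[drop] <- NA_integer_
  x
}

#' Site-filter configuration
#'
#' Holds the site-level quality thresholds: sites with more than
#' `max_site_missingness` missing calls are removed, as are sites whose
#' heterozygous fraction among non-missing calls is at least
#' `max_het_proportion` (in a predominantly selfing species a high het
#' fraction indicates read-mapping artefacts rather than true
#' heterozygosity). `min_depth` is the default minDP for masking.
#'
#' @param max_site_missingness fraction in (0, 1]; default 0.5.
#' @param max_het_proportion fraction in (0, 1]; default 0.05.
#' @param min_depth integer >= 1; default 3.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_site_missingness = 0.5,
                          max_het_proportion = 0.05,
                          min_depth = 3) {
  stopifnot(max_site_missingness > 0, max_site_missingness <= 1,
            max_het_proportion > 0, max_het_proportion <= 1,
            min_depth >= 1)
  structure(list(max_site_missingness = max_site_missingness,
                 max_het_proportion = max_het_proportion,
                 min_depth = min_depth),
            class = "filter_config")
}

#' Remove sites failing missingness or heterozygosity filters
#'
#' A site is removed iff its missing fraction exceeds
#' `max_site_missingness` (strictly) OR its het fraction among non-missing
#' calls reaches `max_het_proportion` (>=). A site with zero non-missing
#' calls is removed under the missingness rule. The removal report is
#' attached as attribute `"removal_report"` (see [site_filter_report()]).
#'
#' @param x a `variant_table` (non-empty).
#' @param cfg a [filter_config()].
#' @return The filtered `variant_table`, with a removal report attached.
#' @export
filter_sites <- function(x, cfg = filter_config()) {
  stopifnot(n_sites(x) > 0)
  st <- site_call_stats(x)
  drop_miss <- st$missing_frac > cfg$max_site_missingness
  drop_het <- !drop_miss & !is.na(st$het_frac) &
    st$het_frac >= cfg$max_het_proportion
  keep <- !(drop_miss | drop_het)
  out <- vt_subset(x, sites = keep)
  attr(out, "removal_report") <- tibble::tibble(
    rule = c("missingness", "heterozygosity", "retained"),
    threshold = c(cfg$max_site_missingness, cfg$max_het_proportion, NA),
    n_sites = c(sum(drop_miss), sum(drop_het), sum(keep))
  )
  out
}

#' Removal report of the last site filtering
#'
#' @param x a `variant_table` returned by [filter_sites()].
#' @return A tibble with per-rule removal counts.
#' @export
site_filter_report <- function(x) {
  rep <- attr(x, "removal_report")
  if (is.null(rep)) stop("no removal report attached; run filter_sites() first")
  rep
}
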