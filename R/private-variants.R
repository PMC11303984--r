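#' Classify alleles as singletons, private variants or shared
#'
#' For every non-reference allele at every site, counts its occurrences
#' over non-missing genotypes and assigns one of:
#' * `SINGLETON` — observed once, i.e. one heterozygous carrier (excluded
#'   from private variants);
#' * `PRIVATE_DOUBLETON` — observed exactly twice, both copies in one
#'   homozygous sample, at a SNP site;
#' * `PRIVATE_INDEL` — carried by exactly one sample, homozygous, at an
#'   INDEL site;
#' * `NON_PRIVATE` — anything else (including unobserved alternate
#'   alleles).
#'
#' Duplicated accessions should be pruned first: a duplicated sample has
#' no true private variants. With `check_duplicates = TRUE` a warning is
#' issued if identical genotype columns survive.
#'
#' @param x a `variant_table`.
#' @param check_duplicates warn when exact-duplicate genotype columns are
#'   present (default `TRUE`).
#' @return A tibble with columns `site` (row index), `chrom`, `pos`,
#'   `allele` (index, 1 = first alternate), `count`, `class`, `carrier`
#'   (sample id for singletons and private variants, else `NA`).
#' @export
classify_private_alleles <- function(x, check_duplicates = TRUE) {
  if (check_duplicates && has_duplicate_columns(x))
    warning("exact-duplicate genotype columns present; ",
            "their private-variant counts will be 0 (prune duplicates first)")
  max_alt <- max(lengths(x$alleles)) - 1L
  is_indel <- x$sites$site_kind == "INDEL"
  out <- vector("list", max_alt)
  for (k in seq_len(max_alt)) {
    has_k <- lengths(x$alleles) > k
    occ <- (x$A == k) + (x$B == k)
    occ[is.na(occ)] <- 0L
    count <- rowSums(occ)
    carriers <- rowSums(occ > 0)
    hom <- rowSums(occ == 2)
    cls <- rep("NON_PRIVATE", n_sites(x))
    cls[count == 1] <- "SINGLETON"
    pv_snp <- count == 2 & carriers == 1 & hom == 1 & !is_indel
    pv_ind <- carriers == 1 & hom == 1 & is_indel
    cls[pv_snp] <- "PRIVATE_DOUBLETON"
    cls[pv_ind] <- "PRIVATE_INDEL"
    carrier <- rep(NA_character_, n_sites(x))
    single <- count >= 1 & carriers == 1
    if (any(single))
      carrier[single] <- x$samples[max.col(occ[single, , drop = FALSE],
                                           ties.method = "first")]
    keep <- which(has_k)
    out[[k]] <- tibble::tibble(
      site = keep, chrom = x$sites$chrom[keep], pos = x$sites$pos[keep],
      allele = k, count = count[keep], class = cls[keep],
      carrier = carrier[keep]
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$site, .data$allele)
}

#' Per-sample private-variant proportions across minDP settings
#'
#' The central per-sample uniqueness statistic: for each minDP setting,
#' genotypes below the depth threshold are masked, alleles are
#' re-classified on the masked table, and each sample's private-variant
#' proportion is 100 x (private doubleton SNPs + private homozygous
#' indels) / its non-missing genotype calls over all retained sites.
#' The report carries the per-setting counts and the mean and standard
#' deviation of the proportion across settings.
#'
#' @param x a `variant_table` (duplicates pruned).
#' @param min_dp integer vector of minDP settings; default `2:5`.
#' @param strict_depth passed to [mask_low_depth()].
#' @return An object of class `pv_report`; see [tidy.pv_report()] and
#'   [glance.pv_report()].
#' @export
pv_proportions <- function(x, min_dp = 2:5, strict_depth = FALSE) {
  stopifnot(length(min_dp) >= 1, all(min_dp >= 1))
  if (has_duplicate_columns(x))
    warning("exact-duplicate genotype columns present; ",
            "their private-variant counts will be 0 (prune duplicates first)")
  is_indel <- x$sites$site_kind == "INDEL"
  max_alt <- max(lengths(x$alleles)) - 1L
  n_samp <- n_samples(x)
  per <- purrr::map(min_dp, function(d) {
    m <- mask_low_depth(x, d, strict = strict_depth)
    n_sg <- n_dbl <- n_ind <- integer(n_samp)
    for (k in seq_len(max_alt)) {
      occ <- (m$A == k) + (m$B == k)
      occ[is.na(occ)] <- 0L
      count <- rowSums(occ)
      carriers <- rowSums(occ > 0)
      hom <- rowSums(occ == 2)
      tab_by_carrier <- function(rows) {
        if (length(rows) == 0) return(integer(n_samp))
        ci <- max.col(occ[rows, , drop = FALSE], ties.method = "first")
        tabulate(ci, nbins = n_samp)
      }
      n_sg <- n_sg + tab_by_carrier(which(count == 1))
      n_dbl <- n_dbl + tab_by_carrier(
        which(count == 2 & carriers == 1 & hom == 1 & !is_indel))
      n_ind <- n_ind + tab_by_carrier(
        which(carriers == 1 & hom == 1 & is_indel))
    }
    tibble::tibble(
      sample = x$samples,
      min_dp = d,
      n_singleton = n_sg,
      n_private_doubleton = n_dbl,
      n_private_indel = n_ind,
      n_valid = as.integer(colSums(!is.na(m$A)))
    )
  })
  per <- dplyr::bind_rows(per) |>
    dplyr::mutate(
      n_pv = .data$n_private_doubleton + .data$n_private_indel,
      pv_pct = ifelse(.data$n_valid > 0, 100 * .data$n_pv / .data$n_valid,
                      NA_real_)
    )
  summ <- per |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      mean_pv_pct = mean(.data$pv_pct),
      sd_pv_pct = stats::sd(.data$pv_pct),
      undefined = anyNA(.data$pv_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$sample, x$samples))
  if (any(summ$undefined))
    warning("sample(s) with zero valid calls at some minDP: ",
            paste(summ$sample[summ$undefined], collapse = ", "))
  structure(list(per_setting = per, summary = summ, min_dp = min_dp),
            class = "pv_report")
}

#' @export
print.pv_report <- function(x, ...) {
  cat("<pv_report> ", nrow(x$summary), " samples, minDP {",
      paste(x$min_dp, collapse = ","), "}\n", sep = "")
  print(x$summary, n = 5)
  invisible(x)
}

#' Tidy a private-variant report
#'
#' @param x a `pv_report`.
#' @param ... unused.
#' @return The long per-setting tibble (one row per sample x minDP).
#' @method tidy pv_report
#' @export
tidy.pv_report <- function(x, ...) x$per_setting

#' One-row summary of a private-variant report
#'
#' @param x a `pv_report`.
#' @param ... unused.
#' @return A tibble with sample count, settings and the grand mean/max of
#'   the per-sample mean PV proportions.
#' @method glance pv_report
#' @export
glance.pv_report <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$summary),
    n_settings = length(x$min_dp),
    mean_pv_pct = mean(x$summary$mean_pv_pct, na.rm = TRUE),
    max_pv_pct = max(x$summary$mean_pv_pct, na.rm = TRUE)
  )
}

#' Plot private-variant proportions against sample missingness
#'
#' Scatter of the per-sample mean PV proportion (error bars: sd across
#' minDP settings) against genotype missingness, optionally coloured by
#' status.
#'
#' @param object a `pv_report`.
#' @param missingness tibble from [sample_missingness()].
#' @param meta optional metadata tibble with `sample` and `status`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pv_report
#' @export
autoplot.pv_report <- function(object, missingness, meta = NULL, ...) {
  d <- dplyr::left_join(object$summary, missingness, by = "sample")
  if (!is.null(meta))
    d <- dplyr::left_join(d, meta[, c("sample", "status")], by = "sample")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$missingness,
                                       y = .data$mean_pv_pct)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_pv_pct - .data$sd_pv_pct,
      ymax = .data$mean_pv_pct + .data$sd_pv_pct), width = 0, alpha = 0.4) +
    ggplot2::labs(x = "genotype missingness",
                  y = "private variants (% of valid calls)") +
    ggplot2::theme_minimal()
  if (!is.null(meta))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$status))
  else p + ggplot2::geom_point()
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return A tibble with `r`, `p` (two-sided), `n`. `r` is `NA` when
#'   either vector has zero variance.
#' @export
pv_correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' z-score of a value against a reference group
#'
#' `z = (value - mean(reference)) / sd(reference)` with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param value a number.
#' @param reference numeric vector, length >= 2 with positive sd.
#' @return The z-score; `NA` if the reference sd is zero.
#' @export
group_zscore <- function(value, reference) {
  stopifnot(length(reference) >= 2)
  s <- stats::sd(reference)
  if (is.na(s) || s == 0) return(NA_real_)
  (value - mean(reference)) / s
}

#' Modified Thompson Tau outlier detection
#'
#' Iteratively flags the most extreme point: with n values, mean m and
#' sample sd s, the rejection threshold is
#' `tau = t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))` where
#' `t = qt(1 - alpha/2, n - 2)`. The point with the largest `|x - m|` is
#' an outlier iff `|x - m| > tau * s`; it is removed and the test is
#' repeated until no point is flagged.
#'
#' @param values numeric vector, length >= 3.
#' @param ids optional identifiers (defaults to indices).
#' @param alpha significance level; default 0.05.
#' @return The ids of flagged outliers (possibly empty), in flagging order.
#' @export
thompson_tau_outliers <- function(values, ids = NULL, alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (is.null(ids)) ids <- seq_along(values)
  stopifnot(length(ids) == length(values))
  flagged <- ids[0]
  repeat {
    n <- length(values)
    if (n < 3) break
    s <- stats::sd(values)
    if (is.na(s) || s == 0) break
    dev <- abs(values - mean(values))
    i <- which.max(dev)
    tval <- stats::qt(1 - alpha / 2, df = n - 2)
    tau <- tval * (n - 1) / (sqrt(n) * sqrt(n - 2 + tval^2))
    if (dev[i] > tau * s) {
      flagged <- c(flagged, ids[i])
      values <- values[-i]; ids <- ids[-i]
    } else break
  }
  flagged
}

#' Regional summary of private-variant proportions
#'
#' Averages the per-sample mean PV proportion by geographic region and
#' correlates the regional means with regional diversity (Watterson's
#' Theta), the oversampling/undersampling diagnostic.
#'
#' @param report a `pv_report`.
#' @param meta metadata tibble with `sample` and `region`; only samples
#'   present in `meta` contribute (subset it to the domesticated group
#'   beforehand if desired).
#' @param theta_by_region named numeric vector mapping region to Theta.
#' @return A list with `regions` (tibble: region, n, mean_pv_pct, theta)
#'   and `correlation` (tibble from [pv_correlate()]).
#' @export
regional_summary <- function(report, meta, theta_by_region) {
  d <- dplyr::inner_join(report$summary,
                         meta[, c("sample", "region")], by = "sample")
  regions <- d |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pv_pct = mean(.data$mean_pv_pct, na.rm = TRUE),
                     .groups = "drop")
  missing <- setdiff(regions$region, names(theta_by_region))
  if (length(missing) > 0)
    stop("region(s) absent from theta mapping: ",
         paste(missing, collapse = ", "))
  if (nrow(regions) < 3)
    stop("need >= 3 regions for the regional correlation, got ",
         nrow(regions))
  regions$theta <- unname(theta_by_region[regions$region])
  list(regions = regions,
       correlation = pv_correlate(regions$mean_pv_pct, regions$theta))
}

#' Watterson-style Theta from a genotype matrix, per region
#'
#' Counts sites segregating among the region's samples (>= 2 distinct
#' alleles over non-missing calls, het counting both alleles) and scales
#' by the harmonic number of the sample count and the total site count:
#' `theta = S / (a_{n-1} * L)`.
#'
#' @param x a `variant_table`.
#' @param meta metadata tibble with `sample` and `region`.
#' @return A named numeric vector of per-region theta values.
#' @export
regional_theta_from_genotypes <- function(x, meta) {
  meta <- meta[meta$sample %in% x$samples, ]
  regions <- unique(meta$region)
  out <- stats::setNames(numeric(length(regions)), regions)
  for (r in regions) {
    ids <- meta$sample[meta$region == r]
    if (length(ids) < 2) { out[r] <- NA_real_; next }
    sub <- vt_subset(x, samples = ids)
    seg <- sum(site_variable(sub))
    a <- sum(1 / seq_len(length(ids) - 1))
    out[r] <- seg / (a * n_sites(sub))
  }
  out
}

# logical vector: site has >= 2 distinct alleles among non-missing calls
site_variable <- function(x) {
  cols <- c(lapply(seq_len(ncol(x$A)), function(j) x$A[, j]),
            lapply(seq_len(ncol(x$B)), function(j) x$B[, j]))
  lo <- do.call(pmin, c(cols, list(na.rm = TRUE)))
  hi <- do.call(pmax, c(cols, list(na.rm = TRUE)))
  !is.na(lo) & hi > lo
}
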