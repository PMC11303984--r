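#' Run the nuclear private-variant pipeline
#'
#' Ordered stages: read VCF -> site filters (missingness, het fraction)
#' -> IBS duplicate pruning -> minDP sweep of private-variant
#' proportions -> z-scores of every sample against the domesticated and
#' wild reference groups -> Thompson Tau outliers within the
#' domesticated group -> regional summary with the PV/Theta correlation.
#' All reports are plain TSV/JSON so every stage is independently
#' re-runnable; the run is deterministic for fixed inputs.
#'
#' @param vcf path to the input VCF.
#' @param meta path to the metadata TSV, or a metadata tibble.
#' @param out_dir report directory (created).
#' @param cfg a [filter_config()].
#' @param dedup_threshold IBS duplicate threshold; default 0.985.
#' @param min_dp minDP sweep; default `2:5`.
#' @param tau_alpha Thompson Tau significance level; default 0.05.
#' @return Invisibly, a list with the main result objects (`vt`,
#'   `pv`, `zscores`, `outliers`, `regional`).
#' @export
run_pv_pipeline <- function(vcf, meta, out_dir,
                            cfg = filter_config(),
                            dedup_threshold = 0.985,
                            min_dp = 2:5,
                            tau_alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[pv] ", ...)
  if (is.character(meta)) meta <- read_sample_meta(meta)

  log_stage("read: ", vcf)
  vt <- read_vcf(vcf, meta)
  log_stage("read ", n_sites(vt), " sites x ", n_samples(vt), " samples")

  vt <- filter_sites(vt, cfg)
  rep_rm <- site_filter_report(vt)
  readr::write_tsv(rep_rm, file.path(out_dir, "site_filter_report.tsv"))
  log_stage("site filters kept ", n_sites(vt), " sites")

  ibs <- ibs_matrix(vt)
  utils::write.table(round(ibs$values, 6),
                     file.path(out_dir, "ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  groups <- find_duplicate_groups(ibs, dedup_threshold)
  pruned <- prune_duplicates(groups, sample_missingness(vt))
  group_tbl <- purrr::imap_dfr(groups, function(g, i)
    tibble::tibble(group_id = i, sample = g,
                   retained = g %in% pruned$retained))
  if (nrow(group_tbl) == 0)
    group_tbl <- tibble::tibble(group_id = integer(), sample = character(),
                                retained = logical())
  readr::write_tsv(group_tbl, file.path(out_dir, "duplicate_groups.tsv"))
  vt <- vt_subset(vt, samples = setdiff(vt$samples, pruned$dropped))
  log_stage("dedup dropped ", length(pruned$dropped), " sample(s)")

  pv <- pv_proportions(vt, min_dp = min_dp)
  miss <- sample_missingness(vt)
  dom_ids <- meta$sample[meta$status %in% domesticated_statuses()]
  wild_ids <- meta$sample[meta$status == "wild"]
  dom_vals <- pv$summary$mean_pv_pct[pv$summary$sample %in% dom_ids]
  wild_vals <- pv$summary$mean_pv_pct[pv$summary$sample %in% wild_ids]
  zs <- pv$summary |>
    dplyr::left_join(miss, by = "sample") |>
    dplyr::left_join(meta[, c("sample", "status", "region")], by = "sample") |>
    dplyr::mutate(
      z_vs_domesticated = vapply(.data$mean_pv_pct, group_zscore,
                                 numeric(1), reference = dom_vals),
      z_vs_wild = vapply(.data$mean_pv_pct, group_zscore,
                         numeric(1), reference = wild_vals))
  # ancient samples are evaluated within the domesticated pool, as they
  # sit inside the domesticated cluster
  pool_ids <- meta$sample[meta$status %in%
                            c(domesticated_statuses(), "ancient")]
  dom_now <- zs[zs$sample %in% pool_ids & !zs$undefined, ]
  outliers <- thompson_tau_outliers(dom_now$mean_pv_pct, dom_now$sample,
                                    alpha = tau_alpha)
  zs$tau_outlier <- zs$sample %in% outliers
  per <- tidyr::pivot_wider(
    pv$per_setting[, c("sample", "min_dp", "n_pv", "pv_pct")],
    names_from = "min_dp", values_from = c("n_pv", "pv_pct"),
    names_prefix = "minDP")
  readr::write_tsv(dplyr::left_join(zs, per, by = "sample"),
                   file.path(out_dir, "pv_report.tsv"))
  log_stage("tau outliers (domesticated): ",
            if (length(outliers) > 0) paste(outliers, collapse = ", ")
            else "none")

  regional <- NULL
  dom_meta <- meta[meta$sample %in% dom_ids & meta$sample %in% vt$samples, ]
  if (length(unique(dom_meta$region)) >= 3) {
    theta <- regional_theta_from_genotypes(vt, dom_meta)
    regional <- regional_summary(pv, dom_meta, theta)
    readr::write_tsv(regional$regions, file.path(out_dir, "pv_regional.tsv"))
  } else log_stage("fewer than 3 domesticated regions; regional stage skipped")

  summary <- list(
    n_sites = n_sites(vt), n_samples = n_samples(vt),
    dropped_duplicates = pruned$dropped,
    tau_outliers = outliers,
    min_dp = min_dp,
    regional_r = if (!is.null(regional)) regional$correlation$r else NULL,
    regional_p = if (!is.null(regional)) regional$correlation$p else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(vt = vt, pv = pv, zscores = zs, outliers = outliers,
                 regional = regional))
}

#' Run the chloroplast haplotype-network pipeline
#'
#' Ordered stages: read FASTA alignment -> optional BED exclusion mask
#' -> scored segregating sites -> haplotype calling -> median-joining
#' network -> haplogroup assignment from seeds -> per-group diversity
#' table.
#'
#' @param fasta path to the aligned FASTA.
#' @param out_dir report directory.
#' @param mask optional BED-like exclusion file or tibble
#'   (see [apply_exclusion_mask()]).
#' @param seeds optional named vector label -> haplotype id, or a
#'   two-column TSV path (label, haplotype); when absent the haplogroup
#'   stage is skipped with a warning.
#' @param groups optional named vector sample -> group for the diversity
#'   table.
#' @param max_missing passed to [call_haplotypes()].
#' @param epsilon passed to [mj_network()].
#' @return Invisibly, a list with `haplotypes`, `network`, `haplogroups`,
#'   `diversity`.
#' @export
run_cp_pipeline <- function(fasta, out_dir, mask = NULL, seeds = NULL,
                            groups = NULL, max_missing = 0.5, epsilon = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[cp] ", ...)
  aln <- read_fasta_alignment(fasta)
  log_stage("alignment: ", nrow(aln), " sequences x ", ncol(aln), " columns")
  if (!is.null(mask)) aln <- apply_exclusion_mask(aln, mask)
  h <- extract_scored_sites(aln)
  log_stage("scored segregating sites: ", ncol(h$states))
  hap <- NULL; net <- NULL; hg <- NULL; div <- NULL
  if (ncol(h$states) > 0) {
    hap <- call_haplotypes(h, max_missing = max_missing)
    readr::write_tsv(
      tibble::tibble(sample = hap$samples, haplotype = unname(hap$haplotype)),
      file.path(out_dir, "haplotypes.tsv"))
    readr::write_tsv(hap$haplotype_table,
                     file.path(out_dir, "haplotype_table.tsv"))
    if (nrow(hap$hap_states) >= 2) {
      net <- mj_network(hap, epsilon = epsilon)
      readr::write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
      igraph::write_graph(as_igraph(net),
                          file.path(out_dir, "network.gml"), format = "gml")
      if (!is.null(seeds)) {
        if (is.character(seeds) && length(seeds) == 1 && file.exists(seeds)) {
          s <- utils::read.table(seeds, sep = "\t", header = TRUE)
          seeds <- stats::setNames(s[[2]], s[[1]])
        }
        hg <- assign_haplogroups(net, seeds)
        readr::write_tsv(hg, file.path(out_dir, "haplogroups.tsv"))
      } else warning("no haplogroup seeds supplied; haplogroup stage skipped")
    }
  }
  if (!is.null(groups)) {
    haplos <- if (!is.null(hap)) hap$haplotype else NULL
    div <- diversity_summary(aln, groups, haplotypes = haplos)
    readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))
  }
  invisible(list(haplotypes = hap, network = net, haplogroups = hg,
                 diversity = div))
}
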