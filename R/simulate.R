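#' Configuration for the cohort simulator
#'
#' Defines the statistical structure of a simulated wild/domesticated/
#' ancient study: a high-diversity wild allele pool, a bottlenecked
#' domesticated subset with group-specific (partly physically clustered)
#' derived alleles, near-complete homozygosity with a residual
#' heterozygosity rate (selfing), per-region diversity multipliers that
#' create a regional uniqueness/diversity gradient, planted per-sample
#' private variants, an optional low-coverage "ancient" sample carrying
#' eroded variants absent from the extant pool, and exact duplicate
#' accessions.
#'
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @param n_wild,n_landrace,n_cultivar cohort sizes.
#' @param n_sites total variant sites.
#' @param n_chrom,chrom_length genome layout (positions in bp).
#' @param wild_poly_frac fraction of background sites polymorphic in wild.
#' @param bottleneck_retention fraction of wild-polymorphic sites that
#'   stay polymorphic in the domesticated group (< 1 models the
#'   domestication bottleneck).
#' @param residual_het per-call probability of a heterozygous genotype at
#'   sites polymorphic for the sample's group (selfing leaves this low).
#' @param modern_missingness random per-call missingness of modern samples.
#' @param dom_specific_sites count of domesticated-only derived alleles.
#' @param dom_block_frac fraction of those arranged in tight physical
#'   blocks (to exercise the clustering test).
#' @param block_span bp span of one tight block.
#' @param regions named numeric vector of per-region diversity
#'   multipliers for the domesticated samples.
#' @param region_site_base region-restricted polymorphic sites per unit
#'   multiplier.
#' @param pv_rate_base mean planted private variants per domesticated
#'   sample per unit region multiplier (Poisson).
#' @param planted_pv optional named integer vector of exact planted
#'   private-variant counts for designated samples (overrides the
#'   Poisson draw for those samples).
#' @param n_ancient 0 or 1 ancient samples.
#' @param ancient_missingness random per-call missingness of the ancient
#'   sample.
#' @param eroded_frac fraction of `n_sites` planted as eroded variants:
#'   homozygous alleles carried only by the ancient sample (by
#'   construction they become private doubletons).
#' @param duplicate_pairs number of landraces emitted twice (exact
#'   genotype copies, the copy with slightly more missing calls).
#' @param depth_mean_modern,depth_mean_ancient,depth_size negative
#'   binomial depth model (mu, size).
#' @param depth_constant if set, every genotype gets this constant depth
#'   (used for noise-free truth recovery).
#' @param indel_frac fraction of polymorphic sites emitted as indels.
#' @param diag_sites count of domestication-diagnostic sites (alternate
#'   allele fixed in domesticated, rare in wild).
#' @param diag_wild_freq wild frequency of the domesticated variant at
#'   diagnostic sites.
#' @param exact_truth disable all stochastic noise interfering with
#'   planted truth: forces zero residual heterozygosity and missingness,
#'   constant depth, and gives any accidental single-carrier background
#'   allele a second homozygous carrier, so planted private-variant
#'   counts are recovered exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_wild = 40, n_landrace = 80, n_cultivar = 30,
    n_sites = 20000,
    n_chrom = 5, chrom_length = 1e6,
    wild_poly_frac = 0.35,
    bottleneck_retention = 0.4,
    residual_het = 0.01,
    modern_missingness = 0.03,
    dom_specific_sites = 600,
    dom_block_frac = 0.3,
    block_span = 2000,
    regions = c("C Asia" = 2.4, "S Asia" = 2.0, "Turkey+" = 1.6,
                "N Africa" = 1.2, "SE Europe" = 0.8, "C + W Europe" = 0.4),
    region_site_base = 150,
    pv_rate_base = 8,
    planted_pv = NULL,
    n_ancient = 1,
    ancient_missingness = 0.4,
    eroded_frac = 0.005,
    duplicate_pairs = 2,
    depth_mean_modern = 20, depth_mean_ancient = 2, depth_size = 10,
    depth_constant = NULL,
    indel_frac = 0.1,
    diag_sites = 300,
    diag_wild_freq = 0.1,
    exact_truth = FALSE) {
  stopifnot(wild_poly_frac >= 0, wild_poly_frac <= 1,
            bottleneck_retention >= 0, bottleneck_retention <= 1,
            residual_het >= 0, residual_het <= 1,
            eroded_frac >= 0, eroded_frac <= 1,
            n_ancient %in% 0:1)
  if (exact_truth) {
    residual_het <- 0; modern_missingness <- 0
    if (is.null(depth_constant)) depth_constant <- 30L
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a nuclear variant cohort with planted truth
#'
#' Generates the genotype table, sample metadata and truth tables
#' described by a [sim_config()]. Wild samples draw from a
#' high-diversity pool; domesticated samples from a bottlenecked subset
#' plus group-specific derived alleles (a fraction tightly linked in
#' blocks); planted private variants are unique homozygous alleles; the
#' ancient sample carries eroded variants and low sequencing depth;
#' duplicates are exact genotype copies.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_bundle`: `vt` ([variant_table()]), `meta`
#'   (tibble), `truth` (list of truth tables), `config`.
#' @export
simulate_nuclear <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_dom <- cfg$n_landrace + cfg$n_cultivar
  samples <- c(sprintf("W%03d", seq_len(cfg$n_wild)),
               sprintf("L%03d", seq_len(cfg$n_landrace)),
               sprintf("C%03d", seq_len(cfg$n_cultivar)),
               if (cfg$n_ancient > 0) "ANC001")
  status <- c(rep("wild", cfg$n_wild), rep("landrace", cfg$n_landrace),
              rep("cultivar", cfg$n_cultivar),
              rep("ancient", cfg$n_ancient))
  is_dom <- status %in% domesticated_statuses()
  region_names <- names(cfg$regions)
  region <- rep("wild range", length(samples))
  region[is_dom] <- rep(region_names, length.out = n_dom)
  if (cfg$n_ancient > 0) region[length(samples)] <- "Levant (ancient)"
  n_samp <- length(samples)

  # planted private-variant counts per domesticated sample
  mult <- stats::setNames(rep(0, n_samp), samples)
  mult[is_dom] <- cfg$regions[region[is_dom]]
  planted <- stats::setNames(rep(0L, n_samp), samples)
  if (cfg$pv_rate_base > 0)
    planted[is_dom] <- stats::rpois(n_dom, cfg$pv_rate_base * mult[is_dom])
  if (!is.null(cfg$planted_pv)) {
    bad <- setdiff(names(cfg$planted_pv), samples)
    if (length(bad) > 0) stop("planted_pv names unknown: ",
                              paste(bad, collapse = ", "))
    planted[names(cfg$planted_pv)] <- as.integer(cfg$planted_pv)
  }

  # site budget
  n_eroded <- if (cfg$n_ancient > 0) round(cfg$eroded_frac * cfg$n_sites) else 0L
  n_region <- round(cfg$region_site_base * cfg$regions)
  n_planted_total <- sum(planted)
  n_special <- cfg$diag_sites + n_eroded + n_planted_total +
    sum(n_region) + cfg$dom_specific_sites
  n_back <- cfg$n_sites - n_special
  if (n_back < 0)
    stop("infeasible config: planted/special sites (", n_special,
         ") exceed n_sites (", cfg$n_sites, ")")
  n_wild_poly <- round(cfg$wild_poly_frac * n_back)
  n_shared <- round(cfg$bottleneck_retention * n_wild_poly)

  # site categories, then positions
  category <- c(rep("shared", n_shared),
                rep("wild_only", n_wild_poly - n_shared),
                rep("mono", n_back - n_wild_poly),
                rep("diag", cfg$diag_sites),
                rep("eroded", n_eroded),
                rep("region", sum(n_region)),
                rep("dom_specific", cfg$dom_specific_sites),
                rep("planted", n_planted_total))
  region_of_site <- rep(NA_character_, cfg$n_sites)
  region_of_site[category == "region"] <- rep(region_names, n_region)
  carrier_of_site <- rep(NA_character_, cfg$n_sites)
  carrier_of_site[category == "planted"] <- rep(samples, planted)

  n_block <- round(cfg$dom_block_frac * cfg$dom_specific_sites)
  dom_idx <- which(category == "dom_specific")
  block_sites <- dom_idx[seq_len(n_block)]
  chrom <- sample.int(cfg$n_chrom, cfg$n_sites, replace = TRUE)
  pos <- sample.int(cfg$chrom_length, cfg$n_sites, replace = TRUE)
  if (n_block > 0) {
    # tight physical blocks of ~20 sites each on one chromosome
    per_block <- 20L
    n_blocks <- ceiling(n_block / per_block)
    centers <- sample.int(cfg$chrom_length - cfg$block_span, n_blocks)
    bi <- rep(seq_len(n_blocks), each = per_block)[seq_len(n_block)]
    chrom[block_sites] <- sample.int(cfg$n_chrom, n_blocks, replace = TRUE)[bi]
    pos[block_sites] <- centers[bi] +
      sample.int(cfg$block_span, n_block, replace = TRUE)
  }
  # resolve position collisions within a chromosome
  key <- paste(chrom, pos)
  while (anyDuplicated(key) > 0) {
    dup <- duplicated(key)
    pos[dup] <- pos[dup] + 1L
    key <- paste(chrom, pos)
  }
  # sort sites by coordinate up front so the genotype matrices are built
  # in final order
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  category <- category[ord]
  region_of_site <- region_of_site[ord]
  carrier_of_site <- carrier_of_site[ord]
  block_sites <- match(block_sites, ord)
  dom_idx <- match(dom_idx, ord)

  # group allele frequencies
  fw <- fd <- rep(0, cfg$n_sites)
  fw[category == "shared"] <- stats::runif(n_shared, 0.1, 0.9)
  fd[category == "shared"] <- stats::runif(n_shared, 0.1, 0.9)
  fw[category == "wild_only"] <- stats::runif(n_wild_poly - n_shared, 0.1, 0.9)
  fd[category == "dom_specific"] <- stats::runif(cfg$dom_specific_sites, 0.1, 0.6)
  fw[category == "diag"] <- cfg$diag_wild_freq
  fd[category == "diag"] <- 1

  P <- matrix(0, cfg$n_sites, n_samp)
  P[, status == "wild"] <- fw
  P[, is_dom] <- fd
  if (cfg$n_ancient > 0) P[, n_samp] <- fd
  for (r in region_names) {
    rows <- which(region_of_site == r)
    cols <- which(region == r)
    if (length(rows) > 0 && length(cols) > 0) P[rows, cols] <- 0.3
  }

  z <- matrix(stats::rbinom(length(P), 1L, P), nrow = cfg$n_sites)
  A <- z; B <- z
  if (cfg$residual_het > 0) {
    # thinned index sampling: equivalent to a per-call Bernoulli draw
    k <- stats::rbinom(1, length(P), cfg$residual_het)
    idx <- sample.int(length(P), k)
    idx <- idx[P[idx] > 0 & P[idx] < 1]
    A[idx] <- 0L; B[idx] <- 1L
  }
  # planted private variants and eroded ancient variants: unique hom calls
  pl <- which(category == "planted")
  if (length(pl) > 0) {
    ci <- match(carrier_of_site[pl], samples)
    A[cbind(pl, ci)] <- 1L; B[cbind(pl, ci)] <- 1L
  }
  if (n_eroded > 0) {
    er <- which(category == "eroded")
    A[er, n_samp] <- 1L; B[er, n_samp] <- 1L
  }

  # depth and missingness
  if (!is.null(cfg$depth_constant)) {
    DP <- matrix(as.integer(cfg$depth_constant), cfg$n_sites, n_samp)
  } else {
    DP <- matrix(stats::rnbinom(cfg$n_sites * n_samp, size = cfg$depth_size,
                                mu = cfg$depth_mean_modern),
                 nrow = cfg$n_sites)
    if (cfg$n_ancient > 0)
      DP[, n_samp] <- stats::rnbinom(cfg$n_sites, size = cfg$depth_size,
                                     mu = cfg$depth_mean_ancient)
    storage.mode(DP) <- "integer"
  }
  miss_p <- rep(cfg$modern_missingness, n_samp)
  if (cfg$n_ancient > 0) miss_p[n_samp] <- cfg$ancient_missingness
  for (j in which(miss_p > 0)) {
    k <- stats::rbinom(1, cfg$n_sites, miss_p[j])
    idx <- sample.int(cfg$n_sites, k)
    A[idx, j] <- NA_integer_; B[idx, j] <- NA_integer_
  }
  nocall <- DP == 0
  A[nocall] <- NA_integer_; B[nocall] <- NA_integer_

  if (cfg$exact_truth) {
    # guarantee exact planted truth: give accidental single-carrier
    # background alleles a second homozygous carrier
    occ <- (A == 1L) + (B == 1L); occ[is.na(occ)] <- 0L
    acc <- which(rowSums(occ > 0) == 1 & !category %in% c("planted", "eroded"))
    if (length(acc) > 0) {
      ci <- max.col(occ[acc, , drop = FALSE] > 0, ties.method = "first")
      other <- ifelse(ci == 1L, 2L, 1L)
      A[cbind(acc, other)] <- 1L; B[cbind(acc, other)] <- 1L
    }
  }

  # duplicates: exact copies of the first landraces, with a few extra
  # masked calls so the original is retained at pruning
  dup_from <- character(0)
  if (cfg$duplicate_pairs > 0) {
    dup_from <- sprintf("L%03d", seq_len(cfg$duplicate_pairs))
    for (s in dup_from) {
      j <- match(s, samples)
      a <- A[, j]; b <- B[, j]; d <- DP[, j]
      extra <- stats::runif(cfg$n_sites) < 0.02
      a[extra] <- NA_integer_; b[extra] <- NA_integer_
      A <- cbind(A, a); B <- cbind(B, b); DP <- cbind(DP, d)
      samples <- c(samples, paste0(s, "_dup"))
      status <- c(status, status[j]); region <- c(region, region[j])
    }
  }

  is_indel <- stats::runif(cfg$n_sites) < cfg$indel_frac &
    !category %in% c("mono", "eroded")
  alleles <- rep(list(c("A", "T")), cfg$n_sites)
  alleles[is_indel] <- list(c("A", "AT"))
  vt <- variant_table(
    sites = tibble::tibble(chrom = paste0("chr", chrom), pos = pos,
                           site_kind = ifelse(is_indel, "INDEL", "SNP")),
    alleles = alleles,
    A = A, B = B, DP = DP, samples = samples, validate = FALSE)

  meta <- tibble::tibble(sample = samples, status = status, region = region,
                         country = region) |>
    dplyr::left_join(sample_missingness(vt), by = "sample")

  # site order changed when the table was coordinate-sorted
  site_id <- paste0("chr", chrom, ":", pos)
  truth <- list(
    planted_pv = tibble::tibble(sample = names(planted),
                                n_planted = unname(planted)),
    planted_sites = tibble::tibble(id = site_id[pl],
                                   carrier = carrier_of_site[pl],
                                   indel = is_indel[pl]),
    eroded_sites = site_id[category == "eroded"],
    diagnostic_sites = site_id[category == "diag"],
    dom_block_sites = site_id[block_sites],
    dom_specific_sites = site_id[dom_idx],
    duplicates = tibble::tibble(original = dup_from,
                                copy = paste0(dup_from, "_dup")),
    ancient = if (cfg$n_ancient > 0) "ANC001" else character(0),
    category = tibble::tibble(id = site_id, category = category,
                              region = region_of_site)
  )
  structure(list(vt = vt, meta = meta, truth = truth, config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle> ", n_samples(x$vt), " samples x ", n_sites(x$vt),
      " sites (seed ", x$config$seed, ")\n", sep = "")
  print(table(x$meta$status))
  invisible(x)
}

#' Simulate a chloroplast alignment with a planted haplotype structure
#'
#' Emits an aligned set of sequences with a star-like dominant
#' haplogroup (a centre haplotype with 1-2-substitution satellites) and
#' a deeply diverged minor haplogroup at a configured substitution
#' distance, plus optional ambiguity injection to exercise partial
#' haplotype assignment. Every planted haplotype has multiplicity >= 2
#' so all its substitutions pass the minor-count >= 2 scoring rule.
#'
#' @param seed RNG seed.
#' @param alignment_length total alignment columns.
#' @param major_center_n samples carrying the major centre haplotype.
#' @param major_satellites number of satellite haplotypes (1-2
#'   substitutions from the centre).
#' @param satellite_n samples per satellite haplotype.
#' @param minor_distance substitutions separating the minor haplogroup
#'   centre from the major centre (>= 1).
#' @param minor_center_n,minor_satellites,minor_satellite_n minor
#'   haplogroup sizes.
#' @param ambiguous_samples how many extra samples are emitted as
#'   partial copies of the major centre (a fraction of positions masked
#'   with N).
#' @param ambiguity_frac fraction of positions masked in those samples.
#' @return A list of class `cp_sim`: `aln` (character matrix),
#'   `truth` (tibble sample/haplotype/haplogroup), `hap_def` (tibble of
#'   planted haplotypes), `seed`.
#' @export
simulate_chloroplast <- function(seed = 1L, alignment_length = 3000,
                                 major_center_n = 40, major_satellites = 6,
                                 satellite_n = 4,
                                 minor_distance = 16,
                                 minor_center_n = 6, minor_satellites = 2,
                                 minor_satellite_n = 2,
                                 ambiguous_samples = 0,
                                 ambiguity_frac = 0.3) {
  set.seed(seed)
  n_sub <- minor_distance + 2 * major_satellites + 2 * minor_satellites
  if (n_sub > alignment_length)
    stop("requested substitution distance exceeds the alignment length")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, alignment_length, replace = TRUE)
  sub_pos <- sample.int(alignment_length, n_sub)
  flip <- function(seqv, p) {
    seqv[p] <- vapply(seqv[p], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    seqv
  }
  used <- 0
  take <- function(k) {
    out <- sub_pos[used + seq_len(k)]; used <<- used + k; out
  }
  haps <- list(A1 = ref)
  group <- c(A1 = "A")
  for (i in seq_len(major_satellites)) {
    k <- 1 + (i %% 2)                       # alternate 1- and 2-sub satellites
    haps[[paste0("A", i + 1)]] <- flip(ref, take(k))
    group[paste0("A", i + 1)] <- "A"
  }
  minor_center <- flip(ref, take(minor_distance))
  haps[["B1"]] <- minor_center
  group["B1"] <- "B"
  for (i in seq_len(minor_satellites)) {
    haps[[paste0("B", i + 1)]] <- flip(minor_center, take(2))
    group[paste0("B", i + 1)] <- "B"
  }
  nn <- c(major_center_n, rep(satellite_n, major_satellites),
          minor_center_n, rep(minor_satellite_n, minor_satellites))
  names(nn) <- names(haps)
  sample_hap <- rep(names(haps), nn)
  ids <- sprintf("S%03d", seq_along(sample_hap))
  aln <- do.call(rbind, haps[sample_hap])
  rownames(aln) <- ids
  truth <- tibble::tibble(sample = ids, haplotype = sample_hap,
                          haplogroup = unname(group[sample_hap]))
  if (ambiguous_samples > 0) {
    amb <- do.call(rbind, replicate(ambiguous_samples, ref, simplify = FALSE))
    for (i in seq_len(ambiguous_samples))
      amb[i, sample.int(alignment_length,
                        round(ambiguity_frac * alignment_length))] <- "N"
    amb_ids <- sprintf("P%03d", seq_len(ambiguous_samples))
    rownames(amb) <- amb_ids
    aln <- rbind(aln, amb)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      sample = amb_ids, haplotype = "A1", haplogroup = "A"))
  }
  hap_def <- tibble::tibble(
    haplotype = names(haps), haplogroup = unname(group),
    n = as.integer(nn),
    sequence = vapply(haps, paste, character(1), collapse = ""))
  structure(list(aln = aln, truth = truth, hap_def = hap_def, seed = seed),
            class = "cp_sim")
}

#' Preset erosion scenario
#'
#' The package's reference study condition: 40 wild, 80 landraces, 30
#' cultivars and 20,000 sites; one ancient sample with 40% missingness
#' carrying 0.5% eroded private variants; two duplicate pairs; six
#' regions spanning a diversity gradient; plus a chloroplast alignment
#' with a dominant star-like haplogroup and a deep minor haplogroup.
#'
#' @param seed integer seed driving both simulations.
#' @return A list with `nuclear` (a `sim_bundle`) and `chloroplast`
#'   (a `cp_sim`).
#' @export
scenario_erosion <- function(seed = 1L) {
  list(
    nuclear = simulate_nuclear(sim_config(seed = seed)),
    chloroplast = simulate_chloroplast(seed = seed + 1L)
  )
}

#' Write a simulated bundle to disk
#'
#' Emits the VCF (GT:DP), the metadata TSV, the truth tables and a JSON
#' echo of the configuration; for a full scenario also the chloroplast
#' FASTA and haplotype truth.
#'
#' @param bundle a `sim_bundle` or the list from [scenario_erosion()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$nuclear)) {
    write_sim_bundle(bundle$nuclear, dir)
    cp <- bundle$chloroplast
    writeLines(paste0(">", rownames(cp$aln), "\n",
                      apply(cp$aln, 1, paste, collapse = "")),
               file.path(dir, "chloroplast.fasta"))
    readr::write_tsv(cp$truth, file.path(dir, "truth_chloroplast.tsv"))
    return(invisible(dir))
  }
  write_vcf(bundle$vt, file.path(dir, "variants.vcf"))
  readr::write_tsv(bundle$meta, file.path(dir, "samples.tsv"))
  readr::write_tsv(bundle$truth$planted_pv, file.path(dir, "truth_pv.tsv"))
  readr::write_tsv(bundle$truth$duplicates,
                   file.path(dir, "truth_duplicates.tsv"))
  readr::write_tsv(bundle$truth$category, file.path(dir, "truth_sites.tsv"))
  cfg <- bundle$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "planted_pv")],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
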