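#' Apply a BED-style exclusion mask to an alignment
#'
#' Drops alignment columns falling in the given 0-based half-open
#' intervals (e.g. a chloroplast/mitochondrial paralogous region).
#'
#' @param x an alignment matrix (see [as_alignment()]).
#' @param mask tibble/data frame with columns `start`, `end` (0-based,
#'   half-open, alignment coordinates), or a path to a BED-like TSV with
#'   those columns in positions 2 and 3.
#' @return The alignment without the masked columns; surviving original
#'   column indices are kept in attribute `"positions"`.
#' @export
apply_exclusion_mask <- function(x, mask) {
  m <- as_alignment(x)
  if (is.character(mask)) {
    bed <- utils::read.table(mask, sep = "\t", header = FALSE)
    mask <- tibble::tibble(start = bed[[2]], end = bed[[3]])
  }
  drop <- logical(ncol(m))
  for (i in seq_len(nrow(mask)))
    drop[(mask$start[i] + 1):mask$end[i]] <- TRUE
  out <- m[, !drop, drop = FALSE]
  attr(out, "positions") <- which(!drop)
  out
}

#' Extract reliably scored segregating sites
#'
#' Keeps alignment columns where, among non-missing states, at least two
#' states occur and the minor state is present in at least two samples.
#' Gaps and IUPAC ambiguities count as missing.
#'
#' @param x an alignment matrix or sequences accepted by
#'   [as_alignment()]; rows should be named with sample ids.
#' @param min_minor_count minimum minor-state count; default 2.
#' @return An object of class `haplotype_alignment`: list with `states`
#'   (samples x scored positions, `NA` = missing), `positions` (original
#'   column indices) and `samples`.
#' @export
extract_scored_sites <- function(x, min_minor_count = 2) {
  m <- as_alignment(x)
  pos0 <- attr(m, "positions")
  cnt <- site_base_counts(m)           # sites x 4
  nstates <- rowSums(cnt > 0)
  minor_ok <- apply(cnt, 1, function(z) {
    z <- sort(z[z > 0], decreasing = TRUE)
    length(z) >= 2 && z[2] >= min_minor_count
  })
  keep <- nstates >= 2 & minor_ok
  if (!any(keep))
    warning("no scored segregating sites found")
  structure(
    list(states = m[, keep, drop = FALSE],
         positions = if (is.null(pos0)) which(keep) else pos0[keep],
         samples = rownames(m)),
    class = "haplotype_alignment"
  )
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("<haplotype_alignment> ", length(x$samples), " samples x ",
      ncol(x$states), " scored sites\n", sep = "")
  if (!is.null(x$haplotype))
    cat("  haplotypes called: ",
        length(unique(stats::na.omit(x$haplotype))), " (",
        sum(is.na(x$haplotype)), " unassigned)\n", sep = "")
  invisible(x)
}

#' Call haplotypes on scored sites
#'
#' Complete state vectors define haplotypes (identical vectors share a
#' label, numbered by decreasing multiplicity). A vector with missing
#' entries is assigned to an existing haplotype iff it is compatible at
#' all its non-missing positions with exactly one haplotype; vectors
#' compatible with several, or with missing fraction above `max_missing`,
#' stay unassigned (`NA`).
#'
#' @param h a `haplotype_alignment` from [extract_scored_sites()].
#' @param max_missing maximum tolerated missing fraction for partial
#'   assignment; default 0.5.
#' @return `h` with elements `haplotype` (named per-sample labels) and
#'   `haplotype_table` (tibble: haplotype, n, states matrix rows).
#' @export
call_haplotypes <- function(h, max_missing = 0.5) {
  st <- h$states
  miss_frac <- rowMeans(is.na(st))
  complete <- miss_frac == 0
  if (!any(complete)) stop("no complete state vectors to define haplotypes")
  keys <- apply(st[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(keys), decreasing = TRUE)
  hap_ids <- stats::setNames(paste0("H", seq_along(tab)), names(tab))
  lab <- rep(NA_character_, length(h$samples))
  names(lab) <- h$samples
  lab[complete] <- unname(hap_ids[keys])
  hap_states <- do.call(rbind, strsplit(names(tab), ""))
  rownames(hap_states) <- unname(hap_ids)
  for (i in which(!complete)) {
    if (miss_frac[i] > max_missing) next
    obs <- !is.na(st[i, ])
    if (!any(obs)) next
    compat <- which(colSums(t(hap_states[, obs, drop = FALSE]) !=
                              st[i, obs]) == 0)
    if (length(compat) == 1) lab[i] <- rownames(hap_states)[compat]
  }
  h$haplotype <- lab
  h$haplotype_table <- tibble::tibble(
    haplotype = unname(hap_ids),
    n = as.integer(table(factor(lab, levels = unname(hap_ids)))),
    sequence = names(tab)
  )
  h$hap_states <- hap_states
  h
}

# -- median-joining network ---------------------------------------------

hamming_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# Prim MST weight of a distance matrix
mst_weight <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  w <- 0
  for (step in seq_len(n - 1)) {
    i <- which(!intree)[which.min(mind[!intree])]
    w <- w + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, d[i, ])
  }
  w
}

# epsilon-relaxed minimum spanning network edges: edge (u,v) kept iff
# d(u,v) <= bottleneck(u,v) + epsilon, where bottleneck is the minimax
# path weight (single-linkage merge height)
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  # single-linkage merge heights via Kruskal-style union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  bott <- matrix(Inf, n, n)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)])
  members <- lapply(seq_len(n), identity)
  for (e in ord) {
    i <- ut[e, 1]; j <- ut[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      for (a in members[[ri]]) for (b in members[[rj]])
        bott[a, b] <- bott[b, a] <- d[i, j]
      members[[ri]] <- c(members[[ri]], members[[rj]])
      parent[rj] <- ri
    }
  }
  keep <- which(upper.tri(d) & d <= bott + epsilon, arr.ind = TRUE)
  keep
}

# all majority-consensus medians of a state-vector triple; per-position
# ties branch into all tied states (capped)
triple_medians <- function(m3, cap = 1000) {
  opts <- lapply(seq_len(ncol(m3)), function(p) {
    z <- m3[, p]
    tb <- table(z)
    names(tb)[tb == max(tb)]
  })
  n_comb <- prod(lengths(opts))
  if (n_comb > cap) opts <- lapply(opts, `[`, 1)
  do.call(rbind, lapply(
    seq_len(min(n_comb, cap)) - 1L,
    function(k) {
      vapply(opts, function(o) {
        i <- k %% length(o); k <<- k %/% length(o); o[i + 1]
      }, character(1))
    }))
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network from complete haplotype state
#' vectors: iteratively (1) form the epsilon-relaxed minimum spanning
#' network over current nodes, (2) generate per-position majority median
#' vectors from node triples, (3) add the median that most reduces the
#' network's spanning length, and (4) prune median vectors whose removal
#' does not increase the spanning length; repeated until stable. Edge
#' weights are Hamming distances over the scored positions.
#'
#' @param haps a character state matrix with one row per distinct
#'   haplotype (rownames = labels), or a `haplotype_alignment` after
#'   [call_haplotypes()]; vectors must be complete (no `NA`).
#' @param epsilon non-negative integer relaxation of the minimum
#'   spanning connection; default 0 (most parsimonious network).
#' @param multiplicity optional named counts of samples per haplotype.
#' @param median_cap maximum candidate medians per triple; default 1000.
#' @return An object of class `mj_network`: tibbles `nodes` (name, type,
#'   multiplicity) and `edges` (from, to, weight), the state matrix, the
#'   spanning `total_length`, and `epsilon`.
#' @export
mj_network <- function(haps, epsilon = 0, multiplicity = NULL,
                       median_cap = 1000) {
  if (inherits(haps, "haplotype_alignment")) {
    if (is.null(haps$hap_states))
      stop("run call_haplotypes() before mj_network()")
    multiplicity <- stats::setNames(haps$haplotype_table$n,
                                    haps$haplotype_table$haplotype)
    haps <- haps$hap_states
  }
  stopifnot(is.matrix(haps), nrow(haps) >= 2)
  if (anyNA(haps))
    stop("median-joining needs complete state vectors; resolve or exclude ",
         "incomplete haplotypes first")
  if (is.null(rownames(haps))) rownames(haps) <- paste0("H", seq_len(nrow(haps)))
  haps <- haps[!duplicated(apply(haps, 1, paste, collapse = "")), ,
               drop = FALSE]
  observed <- rownames(haps)
  nodes <- haps
  n_median <- 0L

  spanning <- function(m) mst_weight(hamming_dist(m))
  repeat {
    changed <- FALSE
    d <- hamming_dist(nodes)
    base_len <- mst_weight(d)
    # candidate medians from all node triples
    if (nrow(nodes) < 3) break
    idx <- utils::combn(nrow(nodes), 3)
    seen <- apply(nodes, 1, paste, collapse = "")
    cands <- list()
    for (t in seq_len(ncol(idx))) {
      med <- triple_medians(nodes[idx[, t], , drop = FALSE], cap = median_cap)
      for (r in seq_len(nrow(med))) {
        key <- paste(med[r, ], collapse = "")
        if (!key %in% seen) {
          cands[[key]] <- med[r, ]
          seen <- c(seen, key)
        }
      }
      if (length(cands) >= median_cap) break
    }
    if (length(cands) > 0) {
      gains <- vapply(cands, function(v)
        base_len - spanning(rbind(nodes, v)), numeric(1))
      if (max(gains) > 0) {
        best <- which.max(gains)
        n_median <- n_median + 1L
        v <- matrix(cands[[best]], nrow = 1,
                    dimnames = list(paste0("mv", n_median), NULL))
        nodes <- rbind(nodes, v)
        changed <- TRUE
      }
    }
    # prune obsolete medians
    repeat {
      med_rows <- which(!rownames(nodes) %in% observed)
      if (length(med_rows) == 0) break
      len_now <- spanning(nodes)
      removable <- med_rows[vapply(med_rows, function(r)
        spanning(nodes[-r, , drop = FALSE]) <= len_now, logical(1))]
      if (length(removable) == 0) break
      nodes <- nodes[-removable[1], , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }

  d <- hamming_dist(nodes)
  ek <- msn_edges(d, epsilon)
  mult <- stats::setNames(rep(0L, nrow(nodes)), rownames(nodes))
  if (!is.null(multiplicity))
    mult[names(multiplicity)] <- as.integer(multiplicity)
  else mult[observed] <- 1L
  structure(list(
    nodes = tibble::tibble(
      name = rownames(nodes),
      type = ifelse(rownames(nodes) %in% observed, "observed", "median"),
      multiplicity = unname(mult)),
    edges = tibble::tibble(from = rownames(nodes)[ek[, 1]],
                           to = rownames(nodes)[ek[, 2]],
                           weight = d[ek]),
    states = nodes,
    total_length = mst_weight(d),
    epsilon = epsilon
  ), class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat("<mj_network> ", sum(x$nodes$type == "observed"), " haplotypes + ",
      sum(x$nodes$type == "median"), " median vectors; ",
      nrow(x$edges), " edges; spanning length ", x$total_length,
      " (epsilon ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' @method tidy mj_network
#' @export
tidy.mj_network <- function(x, ...) x$edges

#' @method glance mj_network
#' @export
glance.mj_network <- function(x, ...) {
  tibble::tibble(n_haplotypes = sum(x$nodes$type == "observed"),
                 n_medians = sum(x$nodes$type == "median"),
                 n_edges = nrow(x$edges),
                 total_length = x$total_length,
                 epsilon = x$epsilon)
}

#' Convert a median-joining network to an igraph graph
#'
#' @param x an `mj_network`.
#' @return An undirected weighted igraph object.
#' @export
as_igraph <- function(x) {
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = x$nodes)
}

#' Plot a median-joining network
#'
#' Node area scales with sample multiplicity; median vectors are drawn
#' as small points; edge labels give substitution counts > 1.
#'
#' @param object an `mj_network`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mj_network
#' @export
autoplot.mj_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    dplyr::left_join(nd[, c("name", "x", "y")], by = c(from = "name")) |>
    dplyr::left_join(nd[, c("name", "x", "y")], by = c(to = "name"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed, ggplot2::aes(
      x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_point(data = nd, ggplot2::aes(
      x = .data$x, y = .data$y, size = pmax(.data$multiplicity, 0.5),
      shape = .data$type, colour = .data$type)) +
    ggplot2::geom_text(data = nd[nd$type == "observed", ], ggplot2::aes(
      x = .data$x, y = .data$y, label = .data$name), vjust = -1, size = 3) +
    ggplot2::scale_size_area(max_size = 10, guide = "none") +
    ggplot2::theme_void()
}

#' Assign haplotypes to haplogroups from seed nodes
#'
#' Each observed haplotype gets the label of the seed haplotype with the
#' smallest network path length (sum of edge substitution counts); ties
#' and unreachable nodes stay unresolved (`NA`).
#'
#' @param net an `mj_network`.
#' @param seeds named character vector: haplogroup label -> node name.
#' @return A tibble with `haplotype`, `haplogroup`, `distance`.
#' @export
assign_haplogroups <- function(net, seeds) {
  stopifnot(all(seeds %in% net$nodes$name))
  g <- as_igraph(net)
  obs <- net$nodes$name[net$nodes$type == "observed"]
  dmat <- igraph::distances(g, v = seeds, to = obs,
                            weights = igraph::E(g)$weight)
  lab <- dist <- rep(NA_character_, length(obs))
  dist <- rep(NA_real_, length(obs))
  for (i in seq_along(obs)) {
    dv <- dmat[, i]
    if (all(is.infinite(dv))) {
      warning("haplotype ", obs[i], " unreachable from all seeds")
      next
    }
    best <- which(dv == min(dv))
    dist[i] <- min(dv)
    if (length(best) == 1) lab[i] <- names(seeds)[best]
  }
  tibble::tibble(haplotype = obs, haplogroup = lab, distance = dist)
}

#' Divergence time from substitution counts
#'
#' `T = (d / L) / (2 * mu)` years for `d` substitutions over `L`
#' compared sites and a substitution rate `mu` per site per year.
#'
#' @param d substitution count (>= 0).
#' @param L number of compared sites (> 0).
#' @param mu substitutions per site per year (> 0).
#' @return Divergence time in years.
#' @export
divergence_time <- function(d, L, mu) {
  if (L <= 0) stop("L must be positive")
  if (mu <= 0) stop("substitution rate mu must be positive")
  (d / L) / (2 * mu)
}
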