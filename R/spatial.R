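#' Remove boundaries within 1 Mb of a centromere
#'
#' Boundaries whose midpoint lies strictly within `distance` of a centromere
#' interval (or inside it) are dropped; a midpoint exactly at `distance` is
#' retained. Layouts without centromere annotations pass through unchanged.
#'
#' @param boundaries Boundary table with `chrom` and `midpoint`.
#' @param layout A [genome_layout()].
#' @param distance Exclusion distance in bp (default 1 Mb).
#' @return Filtered boundary table.
#' @export
filter_centromeric <- function(boundaries, layout, distance = 1e6) {
  cen <- layout$centromeres
  if (is.null(cen) || !nrow(boundaries)) return(boundaries)
  keep <- rep(TRUE, nrow(boundaries))
  for (i in seq_len(nrow(cen))) {
    near <- boundaries$chrom == cen$chrom[i] &
      boundaries$midpoint > cen$start[i] - distance &
      boundaries$midpoint < cen$end[i] + distance
    keep <- keep & !near
  }
  boundaries[keep]
}

#' Cluster boundaries along the genome by a gap threshold
#'
#' A single linear sweep per chromosome joins consecutive boundaries whose
#' midpoint gap is at most `gap`; maximal runs with at least two members are
#' clusters, the rest singletons.
#'
#' @param boundaries Boundary table with `chrom`, `midpoint`, `boundary_id`.
#' @param gap Maximum gap between consecutive cluster members in bp
#'   (default 2 Mb).
#' @return List with `clusters` (`cluster_id`, `chrom`, `start`, `end`,
#'   `n_members`, `members`), `singletons` (boundary table rows), and
#'   `summary` (n_clusters, mean/min/max members, fraction of boundaries in
#'   clusters).
#' @export
cluster_boundaries <- function(boundaries, gap = 2e6) {
  b <- data.table::as.data.table(boundaries)
  empty <- data.table::data.table(cluster_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  n_members = integer(), members = character())
  if (!nrow(b)) return(list(clusters = empty, singletons = b,
                            summary = list(n_clusters = 0L, mean_members = NaN,
                                           min_members = NA, max_members = NA,
                                           frac_clustered = NaN)))
  data.table::setorder(b, chrom, midpoint)
  b[, run := cumsum(c(1, diff(midpoint) > gap | chrom[-1] != chrom[-.N])), ]
  grp <- b[, .(chrom = chrom[1], start = min(midpoint), end = max(midpoint),
               n_members = .N, members = paste(boundary_id, collapse = ",")), by = run]
  clusters <- grp[n_members >= 2][, cluster_id := sprintf("cluster%03d", seq_len(.N))]
  singles <- b[run %in% grp[n_members < 2]$run][, run := NULL]
  b[, run := NULL]
  list(clusters = if (nrow(clusters)) clusters[, .(cluster_id, chrom, start, end, n_members, members)] else empty,
       singletons = singles,
       summary = list(n_clusters = nrow(clusters),
                      mean_members = if (nrow(clusters)) mean(clusters$n_members) else NaN,
                      min_members = if (nrow(clusters)) min(clusters$n_members) else NA,
                      max_members = if (nrow(clusters)) max(clusters$n_members) else NA,
                      frac_clustered = sum(clusters$n_members) / nrow(b)))
}

#' Count HDS boundaries per bin of a (4-Mb) bin table
#' @keywords internal
hds_per_bin <- function(bins, boundaries) {
  cnt <- integer(nrow(bins))
  if (nrow(boundaries)) {
    pos <- if ("midpoint" %in% names(boundaries)) boundaries$midpoint else boundaries$pos
    if (is.null(pos)) stop("boundary table needs a midpoint or pos column")
    ids <- bin_id_at(bins, boundaries$chrom,
                     pmin(pos, layout_of(bins)$lengths[boundaries$chrom] - 1))
    tab <- table(ids)
    cnt[as.integer(names(tab)) + 1L] <- as.integer(tab)
  }
  cnt
}

#' Aggregate interchromosomal contacts by HDS-boundary density
#'
#' Each bin of the trans bin table is assigned its HDS-boundary count and a
#' group label (`0`, `1`, `2`, `3+` by default). Counts are normalised to
#' counts-per-million over the sample's total trans count. The default
#' group value is the mean CPM over all interchromosomal bin pairs whose two
#' bins fall in the same group; `mode = "one_sided"` instead averages over
#' pairs with at least one bin in the group.
#'
#' @param trans_map A [contact_map()] of trans contacts on a 4-Mb bin table.
#' @param boundaries HDS boundary table (`chrom`, `midpoint`).
#' @param group_breaks Integer lower edges of the HDS-count groups
#'   (default `c(0, 1, 2, 3)`; the last group is open-ended).
#' @param mode Pair grouping rule.
#' @param condition Optional label carried into the output.
#' @return `data.table`: `group`, `condition`, `mean_cpm`, `n_pairs`,
#'   `n_bins`; attribute `bin_groups` maps bins to groups.
#' @export
trans_aggregate <- function(trans_map, boundaries, group_breaks = c(0, 1, 2, 3),
                            mode = c("same_group", "one_sided"), condition = NA_character_) {
  mode <- match.arg(mode)
  bins <- trans_map$bins
  cnt <- hds_per_bin(bins, boundaries)
  labels <- c(as.character(group_breaks[-length(group_breaks)]),
              paste0(group_breaks[length(group_breaks)], "+"))
  grp <- labels[findInterval(cnt, group_breaks)]
  total <- total_count(trans_map, trans_only = TRUE)
  if (total == 0) stop("trans map has no interchromosomal counts")
  nb <- nrow(bins)
  pairs <- data.table::CJ(a = seq_len(nb), b = seq_len(nb))[a < b]
  pairs <- pairs[bins$chrom[a] != bins$chrom[b]]
  px <- trans_map$pixels
  key <- paste(px$bin1, px$bin2)
  pairs[, count := px$count[match(paste(a - 1L, b - 1L), key)]]
  pairs[is.na(count), count := 0]
  pairs[, cpm := count / total * 1e6]
  pairs[, c("ga", "gb") := .(grp[a], grp[b])]
  if (mode == "same_group") {
    agg <- pairs[ga == gb, .(mean_cpm = mean(cpm), n_pairs = .N), by = .(group = ga)]
  } else {
    long <- data.table::rbindlist(list(pairs[, .(group = ga, cpm)],
                                       pairs[ga != gb, .(group = gb, cpm)]))
    agg <- long[, .(mean_cpm = mean(cpm), n_pairs = .N), by = group]
  }
  agg[, group := factor(group, levels = labels)]
  out <- data.table::data.table(group = factor(labels, levels = labels))
  out <- agg[out, on = "group"]
  out[, condition := condition]
  out[, n_bins := as.integer(table(factor(grp, levels = labels)))]
  data.table::setorder(out, group)
  data.table::setattr(out, "bin_groups",
                      data.table::data.table(bin_id = bins$bin_id, hds_count = cnt, group = grp))
  out[]
}

#' Total-boundary confounder check for trans aggregation groups
#'
#' For each HDS-count group of the trans bin table, summarises the
#' distribution of total (HDS + unaffected) boundary counts per bin, to
#' check that trans enrichment tracks HDS density rather than overall
#' boundary density.
#'
#' @param bins Trans (4-Mb) bin table.
#' @param all_boundaries,hds_boundaries Boundary tables (`chrom`,
#'   `midpoint`).
#' @inheritParams trans_aggregate
#' @return `data.table`: `group`, `n_bins`, `mean_total`, `sd_total`.
#' @export
control_total_boundaries <- function(bins, all_boundaries, hds_boundaries,
                                     group_breaks = c(0, 1, 2, 3)) {
  hds_cnt <- hds_per_bin(bins, hds_boundaries)
  tot_cnt <- hds_per_bin(bins, all_boundaries)
  labels <- c(as.character(group_breaks[-length(group_breaks)]),
              paste0(group_breaks[length(group_breaks)], "+"))
  grp <- factor(labels[findInterval(hds_cnt, group_breaks)], levels = labels)
  data.table::data.table(group = grp, total = tot_cnt)[
    , .(n_bins = .N, mean_total = mean(total), sd_total = stats::sd(total)), by = group][
      order(group)]
}

#' Housekeeping-gene enrichment on boundary clusters
#'
#' The housekeeping set is the intersection of per-tissue top-`top_fraction`
#' expression lists (genes in the top fraction in EVERY tissue). Enrichment
#' compares housekeeping gene density (genes per Mb, midpoint containment)
#' inside cluster spans against the rest of the genome.
#'
#' @param expression Gene-by-tissue table (first column `gene`, remaining
#'   columns numeric expression per tissue; >= 2 tissues).
#' @param genes Gene annotation (`chrom`, `start`, `end`, `name`).
#' @param clusters Cluster span table (`chrom`, `start`, `end`).
#' @param layout A [genome_layout()].
#' @param top_fraction Fraction in (0, 0.5] defining each tissue's top list
#'   (default 0.01).
#' @return List: `enrichment` (density ratio), `n_housekeeping`,
#'   `n_inside`, `cluster_fraction` (of the genome), `housekeeping` (gene
#'   names). Empty intersection yields `enrichment = NA` with a warning.
#' @export
housekeeping_enrichment <- function(expression, genes, clusters, layout,
                                    top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction > 0.5) stop("top_fraction must lie in (0, 0.5]")
  expression <- data.table::as.data.table(expression)
  tissues <- setdiff(names(expression), "gene")
  if (length(tissues) < 2) stop("need >= 2 tissues")
  n_top <- max(1L, floor(top_fraction * nrow(expression)))
  top_lists <- lapply(tissues, function(tt)
    expression$gene[order(-expression[[tt]])][seq_len(n_top)])
  hk <- Reduce(intersect, top_lists)
  if (!length(hk)) {
    warning("empty housekeeping intersection; enrichment undefined")
    return(list(enrichment = NA_real_, n_housekeeping = 0L, n_inside = 0L,
                cluster_fraction = NA_real_, housekeeping = character()))
  }
  genes <- data.table::as.data.table(genes)
  g <- genes[name %in% hk]
  mid <- (g$start + g$end) / 2
  clusters <- data.table::as.data.table(clusters)
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(clusters)))
    inside <- inside | (g$chrom == clusters$chrom[i] &
                        mid >= clusters$start[i] & mid < clusters$end[i])
  span_in <- sum(clusters$end - clusters$start)
  genome <- sum(layout$lengths)
  span_out <- genome - span_in
  dens_in <- sum(inside) / (span_in / 1e6)
  dens_out <- sum(!inside) / (span_out / 1e6)
  list(enrichment = dens_in / dens_out,
       n_housekeeping = length(hk), n_inside = sum(inside),
       cluster_fraction = span_in / genome, housekeeping = hk)
}
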