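#' Bundled demo genome and simulation configurations
#'
#' `demo_config()` is the package's reference study design: two 20-Mb
#' chromosomes binned at 40 kb, centromeres at mid-chromosome, 10 planted
#' TAD boundaries per chromosome with permeabilities in \[0.15, 0.5\], 20%
#' of boundaries HDS (placed as adjacent pairs so they cluster), two
#' replicates per condition, and a treatment/recovery schedule in which the
#' treated condition raises HDS-boundary permeability (weaken = 0.6) and
#' recovery conditions relax it back (0.25, then 0).
#'
#' @param seed Master seed.
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 20 Mb).
#' @param n_boundaries Boundaries per chromosome (default 10).
#' @param hds_pairs Number of adjacent HDS boundary pairs per chromosome
#'   (default 1, i.e. 20% of boundaries HDS).
#' @param ... Passed through to [sim_config()] (e.g. `cis_depth`,
#'   `conditions`).
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1, n_chroms = 2, chrom_length = 20e6,
                        n_boundaries = 10, hds_pairs = 1, ...) {
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  cen <- data.table::data.table(chrom = chroms,
                                start = chrom_length / 2 - 0.2e6,
                                end = chrom_length / 2 + 0.2e6)
  layout <- genome_layout(chroms, rep(chrom_length, n_chroms), centromeres = cen)
  bs <- 40e3
  # base positions avoid chromosome edges and the 1-Mb centromere exclusion zone
  base_frac <- c(0.06, 0.15, 0.24, 0.32, 0.39, 0.58, 0.66, 0.74, 0.82, 0.90)
  stopifnot(n_boundaries <= length(base_frac))
  base <- round(base_frac[seq_len(n_boundaries)] * chrom_length / bs) * bs
  b <- with_stream(derive_seed(seed, "layout"), {
    data.table::rbindlist(lapply(chroms, function(ch) {
      jit <- sample(-2:2, n_boundaries, replace = TRUE) * bs
      hds <- rep(FALSE, n_boundaries)
      # adjacent pairs inside the 2-Mb clustering gap
      for (k in seq_len(hds_pairs)) hds[c(2 * k, 2 * k + 1)] <- TRUE
      data.table::data.table(chrom = ch, pos = base + jit,
                             permeability = round(stats::runif(n_boundaries, 0.15, 0.5), 3),
                             hds = hds)
    }))
  })
  cfg <- sim_config(layout, bin_size = bs, boundaries = b, seed = seed, ...)
  # genes near HDS boundaries transcribe at twice the baseline and respond
  # to treatment with increased pausing
  hds_pos <- cfg$boundaries[cfg$boundaries$hds == TRUE]
  mid <- (cfg$genes$start + cfg$genes$end) / 2
  near <- rep(FALSE, nrow(cfg$genes))
  for (i in seq_len(nrow(hds_pos)))
    near <- near | (cfg$genes$chrom == hds_pos$chrom[i] & abs(mid - hds_pos$pos[i]) <= 3e5)
  if (!length(cfg$paused_genes)) cfg$paused_genes <- cfg$genes$name[near]
  cfg$genes$score[near] <- cfg$genes$score[near] * 2
  cfg
}

#' @describeIn demo_config Compartment-analysis configuration: 500-kb bins,
#'   a planted alternating A/B block pattern (blocks of `block_bins` bins)
#'   with plaid strength `strength`, and no TAD boundaries.
#' @param block_bins Compartment block length in 500-kb bins (default 4).
#' @param strength Plaid strength (default 0.4).
#' @param flip_bins Global bin ids whose planted label is negated (used to
#'   plant differential-compartment signal; default none).
#' @export
compartment_config <- function(seed = 1, n_chroms = 2, chrom_length = 20e6,
                               block_bins = 4, strength = 0.4,
                               flip_bins = integer(), ...) {
  layout <- genome_layout(sprintf("chr%d", seq_len(n_chroms)),
                          rep(chrom_length, n_chroms))
  bs <- 500e3
  bins <- make_bin_table(layout, bs)
  labels <- with_stream(derive_seed(seed, "compartments"), {
    lab <- numeric(nrow(bins))
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      lab[idx] <- ifelse((seq_along(idx) - 1) %/% block_bins %% 2 == 0, 1, -1)
    }
    lab
  })
  labels[flip_bins + 1L] <- -labels[flip_bins + 1L]
  sim_config(layout, bin_size = bs,
             compartments = list(labels = labels, strength = strength),
             tad_boost = 1, seed = seed, ...)
}

#' @describeIn demo_config Trans-aggregation configuration: four 16-Mb
#'   chromosomes at 4-Mb trans bins with a designed HDS-count gradient
#'   (bins carrying 0-3 HDS boundaries) and a hub (cluster) bin set whose
#'   membership fraction rises with HDS count, so group means increase
#'   strictly and the top/bottom ratio equals `trans_enrichment`.
#' @export
trans_demo_config <- function(seed = 1, trans_rate = 5000, trans_enrichment = 2, ...) {
  chroms <- sprintf("chrT%d", 1:4)
  layout <- genome_layout(chroms, rep(16e6, 4))
  # HDS boundaries per 4-Mb bin, by chromosome (columns = bin position)
  counts <- rbind(c(3, 2, 1, 0),
                  c(3, 2, 1, 0),
                  c(2, 1, 0, 0),
                  c(1, 0, 0, 0))
  bs <- 40e3
  b <- data.table::rbindlist(lapply(1:4, function(ci) {
    data.table::rbindlist(lapply(1:4, function(bi) {
      n <- counts[ci, bi]
      if (n == 0) return(NULL)
      pos <- (bi - 1) * 4e6 + seq_len(n) * 1e6
      data.table::data.table(chrom = chroms[ci], pos = pos,
                             permeability = 0.3, hds = TRUE)
    }))
  }))
  # hub set: all 3-HDS bins, the 2-HDS bins of chrT1/chrT2, the 1-HDS bins
  # of chrT1/chrT2 (global 4-Mb bin ids)
  cluster_bins <- c(0L, 4L, 1L, 5L, 2L, 6L)
  sim_config(layout, bin_size = bs, boundaries = b, cluster_bins = cluster_bins,
             trans_rate = trans_rate, trans_enrichment = trans_enrichment,
             seed = seed, ...)
}
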