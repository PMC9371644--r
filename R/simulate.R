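#' Configuration for the synthetic perturbation Hi-C / PRO-seq generator
#'
#' The generator emulates a condensate-perturbation experiment: a genome
#' partitioned into TADs by boundaries of varying permeability, a treatment
#' that transiently weakens a designated (HDS) subset of boundaries and then
#' recovers over a condition schedule, replicate-level Poisson sequencing
#' noise, trans-contact enrichment between designated hub bins, and nascent
#' transcription with a tunable promoter-proximal pause.
#'
#' Effective permeability of an HDS boundary under a condition with
#' weakening factor `w` is `pi + w * (1 - pi)`; unaffected boundaries keep
#' `pi` in every condition.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Cis map bin size in bp (default 40 kb).
#' @param boundaries `data.frame` with columns `chrom`, `pos` (bin-edge
#'   coordinate, multiple of `bin_size`), `permeability` in (0, 1], and
#'   logical `hds`. May be empty (single-TAD genome).
#' @param conditions `data.frame` with columns `condition` (label) and
#'   `weaken` in \[0, 1\]; the first row is the control.
#' @param n_replicates Replicates per condition (default 2).
#' @param alpha Contact distance-decay exponent (> 0).
#' @param tad_boost Multiplicative intra-TAD contact enrichment (>= 1).
#' @param cis_depth Expected total cis contacts per chromosome per replicate.
#' @param compartments Optional `list(labels, strength)`: `labels` is a
#'   +1/-1 vector over the cis bin table (A/B identity) and `strength` in
#'   \[0, 1) scales a plaid multiplier `1 + strength` (same label) vs
#'   `1 - strength` (different label).
#' @param trans_bin_size Trans map bin size in bp (default 4 Mb).
#' @param trans_rate Baseline expected count per trans bin pair.
#' @param trans_enrichment Fold enrichment `epsilon >= 1` applied when both
#'   bins of a trans pair lie in `cluster_bins`; conditions scale it toward 1
#'   as `1 + (epsilon - 1) * (1 - weaken)`.
#' @param cluster_bins Integer global bin ids (at `trans_bin_size`) forming
#'   the trans-interacting hub set.
#' @param genes Optional BED6-like `data.frame` (`chrom`, `start`, `end`,
#'   `name`, `score` = relative expression, `strand`); generated if `NULL`.
#' @param n_genes,gene_length Used when generating genes.
#' @param paused_genes Gene names whose pause fraction responds to treatment.
#' @param f_pause_base,f_pause_treated Pause-window read fraction at
#'   weaken = 0 and weaken = 1; responsive genes interpolate linearly in the
#'   condition's weakening factor.
#' @param pause_up,pause_down Pause window spans \[TSS - pause_up,
#'   TSS + pause_down) in the direction of transcription.
#' @param proseq_reads_per_expr Expected PRO-seq reads per unit expression.
#' @param housekeeping_genes Gene names drawn with high expression in every
#'   tissue of the expression table. When empty, 5% of generated genes are
#'   designated housekeeping, each drawn from inside an HDS-boundary cluster
#'   span with probability `p_hk_in_cluster` and from outside otherwise.
#' @param p_hk_in_cluster Probability a designated housekeeping gene falls
#'   inside an HDS-cluster span (default 0.35).
#' @param n_tissues Number of tissues in the simulated expression table.
#' @param seed Master seed; every per-(condition, replicate) stream is
#'   derived from it, so adding a replicate never perturbs existing ones.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout, bin_size = 40e3,
                       boundaries = NULL,
                       conditions = data.frame(condition = c("control", "treat_5min", "recover_30min", "recover_3h"),
                                               weaken = c(0, 0.6, 0.25, 0)),
                       n_replicates = 2,
                       alpha = 1, tad_boost = 2, cis_depth = 1e6,
                       compartments = NULL,
                       trans_bin_size = 4e6, trans_rate = 500, trans_enrichment = 2,
                       cluster_bins = integer(),
                       genes = NULL, n_genes = 200, gene_length = c(4e3, 10e3),
                       paused_genes = character(),
                       f_pause_base = 0.4, f_pause_treated = 0.7,
                       pause_up = 50, pause_down = 300,
                       proseq_reads_per_expr = 2000,
                       housekeeping_genes = character(), p_hk_in_cluster = 0.35,
                       n_tissues = 54, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  if (alpha <= 0) stop("alpha must be > 0")
  if (tad_boost < 1) stop("tad_boost must be >= 1")
  if (trans_enrichment < 1) stop("trans_enrichment must be >= 1")
  if (is.null(boundaries)) boundaries <- data.table::data.table(
    chrom = character(), pos = numeric(), permeability = numeric(), hds = logical())
  boundaries <- data.table::as.data.table(boundaries)
  if (nrow(boundaries)) {
    if (any(boundaries$permeability <= 0 | boundaries$permeability > 1))
      stop("boundary permeability must lie in (0, 1]")
    if (any(boundaries$pos %% bin_size != 0)) stop("boundary pos must be a multiple of bin_size")
    boundaries[, boundary_id := sprintf("%s:%d", chrom, as.integer(pos))]
    data.table::setorder(boundaries, chrom, pos)
  }
  conditions <- data.table::as.data.table(conditions)
  if (any(conditions$weaken < 0 | conditions$weaken > 1)) stop("weaken must lie in [0, 1]")
  cfg <- structure(list(
    layout = layout, bin_size = bin_size,
    bins = make_bin_table(layout, bin_size),
    boundaries = boundaries, conditions = conditions, n_replicates = n_replicates,
    alpha = alpha, tad_boost = tad_boost, cis_depth = cis_depth,
    compartments = compartments,
    trans_bin_size = trans_bin_size,
    trans_bins = make_bin_table(layout, trans_bin_size),
    trans_rate = trans_rate, trans_enrichment = trans_enrichment,
    cluster_bins = as.integer(cluster_bins),
    genes = genes, paused_genes = paused_genes,
    f_pause_base = f_pause_base, f_pause_treated = f_pause_treated,
    pause_up = pause_up, pause_down = pause_down,
    proseq_reads_per_expr = proseq_reads_per_expr,
    housekeeping_genes = housekeeping_genes, n_tissues = n_tissues,
    seed = as.integer(seed)), class = "sim_config")
  if (is.null(cfg$genes)) {
    cfg$genes <- sim_genes(cfg, n_genes = n_genes, gene_length = gene_length)
    if (!length(cfg$housekeeping_genes))
      cfg$housekeeping_genes <- designate_housekeeping(cfg, p_hk_in_cluster)
  } else {
    cfg$genes <- data.table::as.data.table(genes)
  }
  cfg
}

#' Ground-truth HDS-cluster spans of a config (2-Mb gap sweep)
#' @param config A [sim_config()].
#' @param gap Clustering gap in bp.
#' @return `data.table` of cluster spans (`chrom`, `start`, `end`).
#' @export
truth_cluster_spans <- function(config, gap = 2e6) {
  hds <- config$boundaries[config$boundaries$hds == TRUE]
  if (!nrow(hds)) return(data.table::data.table(chrom = character(),
                                                start = numeric(), end = numeric()))
  hds <- data.table::copy(hds)[, midpoint := pos]
  cluster_boundaries(hds, gap = gap)$clusters[, .(chrom, start, end)]
}

# Pick the housekeeping set: 5% of genes, drawn from inside cluster spans
# with probability p and outside otherwise.
designate_housekeeping <- function(cfg, p) {
  g <- cfg$genes
  n_hk <- max(1L, round(0.05 * nrow(g)))
  spans <- truth_cluster_spans(cfg)
  mid <- (g$start + g$end) / 2
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(spans)))
    inside <- inside | (g$chrom == spans$chrom[i] & mid >= spans$start[i] & mid < spans$end[i])
  with_stream(derive_seed(cfg$seed, "genes_hk"), {
    n_in <- min(stats::rbinom(1, n_hk, p), sum(inside))
    picks <- c(sample(which(inside), n_in),
               sample(which(!inside), n_hk - n_in))
    sort(g$name[picks])
  })
}

# Deterministic 31-bit stream seed from the master seed and labels.
derive_seed <- function(master, ...) {
  labs <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(labs)) h <- (h * 31 + cc) %% 2147483629
  as.integer(h)
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

weaken_of <- function(config, condition) {
  w <- config$conditions$weaken[config$conditions$condition == condition]
  if (!length(w)) stop("unknown condition: ", condition)
  w
}

#' Per-boundary effective permeability under a condition
#' @param config A [sim_config()].
#' @param condition Condition label from the schedule.
#' @return Numeric vector parallel to `config$boundaries`.
#' @export
effective_permeability <- function(config, condition) {
  w <- weaken_of(config, condition)
  b <- config$boundaries
  if (!nrow(b)) return(numeric())
  ifelse(b$hds, b$permeability + w * (1 - b$permeability), b$permeability)
}

#' Noise-free expected cis matrix for one chromosome
#'
#' Expected count for local bins i, j is
#' `D * (1 + |i - j|)^(-alpha) * tad_boost^[same TAD] * prod(pi_eff)` over
#' boundaries strictly between them, with `D` scaled so the upper triangle
#' (incl. diagonal) sums to `cis_depth`; an optional compartment plaid
#' multiplies on top.
#'
#' @inheritParams effective_permeability
#' @param chrom Chromosome name.
#' @return Dense symmetric matrix of expected counts.
#' @export
expected_cis_matrix <- function(config, condition, chrom) {
  ch_query <- chrom
  off <- chrom_offsets(config$bins)[data.table::data.table(chrom = ch_query)]
  if (is.na(off$offset)) stop("unknown chromosome: ", ch_query)
  n <- off$n
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- (1 + d)^(-config$alpha)
  on_ch <- config$boundaries$chrom == ch_query
  b <- config$boundaries[on_ch]
  if (nrow(b)) {
    peff <- effective_permeability(config, condition)[on_ch]
    k <- as.integer(b$pos / config$bin_size)      # boundary between local bins k-1, k (0-based)
    # cumulative log-permeability: boundaries crossed between i < j are those with i < k <= j
    cum <- numeric(n)
    for (bi in seq_along(k)) if (k[bi] >= 1 && k[bi] <= n - 1)
      cum[(k[bi] + 1):n] <- cum[(k[bi] + 1):n] + log(peff[bi])
    e <- e * exp(-abs(outer(cum, cum, "-")))
    tad <- findInterval(seq_len(n) - 1L, sort(k))
    e <- e * config$tad_boost^(outer(tad, tad, "=="))
  } else if (config$tad_boost != 1) {
    e <- e * config$tad_boost      # single TAD: uniform boost
  }
  if (!is.null(config$compartments)) {
    lab <- config$compartments$labels[(off$offset + 1):(off$offset + n)]
    s <- config$compartments$strength
    e <- e * ifelse(outer(lab, lab, "=="), 1 + s, 1 - s)
  }
  e * (config$cis_depth / sum(e[upper.tri(e, diag = TRUE)]))
}

#' Simulate one replicate cis contact map (all chromosomes)
#'
#' Counts are Poisson draws around [expected_cis_matrix()]; the random
#' stream is derived from `(seed, "cis", condition, replicate)` only.
#'
#' @inheritParams effective_permeability
#' @param replicate Replicate index (1-based).
#' @return A [contact_map()] on the config's cis bin table.
#' @export
simulate_cis <- function(config, condition, replicate = 1) {
  mats <- with_stream(derive_seed(config$seed, "cis", condition, replicate), {
    out <- lapply(config$layout$chroms, function(ch) {
      e <- expected_cis_matrix(config, condition, ch)
      n <- nrow(e)
      up <- upper.tri(e, diag = TRUE)
      m <- matrix(0, n, n)
      m[up] <- stats::rpois(sum(up), e[up])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    names(out) <- config$layout$chroms
    out
  })
  map_from_cis_matrices(config$bins, mats)
}

#' Noise-free expected trans matrix for a chromosome pair
#' @inheritParams effective_permeability
#' @param chrom1,chrom2 Distinct chromosome names.
#' @export
expected_trans_matrix <- function(config, condition, chrom1, chrom2) {
  w <- weaken_of(config, condition)
  eps <- 1 + (config$trans_enrichment - 1) * (1 - w)
  offs <- chrom_offsets(config$trans_bins)
  o1 <- offs[data.table::data.table(chrom = chrom1)]
  o2 <- offs[data.table::data.table(chrom = chrom2)]
  in_cluster1 <- (o1$offset + seq_len(o1$n) - 1L) %in% config$cluster_bins
  in_cluster2 <- (o2$offset + seq_len(o2$n) - 1L) %in% config$cluster_bins
  config$trans_rate * eps^outer(in_cluster1, in_cluster2, "&")
}

#' Simulate one replicate trans contact map (all chromosome pairs)
#' @inheritParams simulate_cis
#' @return A [contact_map()] on the config's trans bin table.
#' @export
simulate_trans <- function(config, condition, replicate = 1) {
  chroms <- config$layout$chroms
  if (length(chroms) < 2) stop("trans simulation needs >= 2 chromosomes")
  offs <- chrom_offsets(config$trans_bins)
  px <- with_stream(derive_seed(config$seed, "trans", condition, replicate), {
    data.table::rbindlist(lapply(seq_len(length(chroms) - 1), function(a) {
      data.table::rbindlist(lapply((a + 1):length(chroms), function(b) {
        e <- expected_trans_matrix(config, condition, chroms[a], chroms[b])
        cnt <- matrix(stats::rpois(length(e), e), nrow(e))
        idx <- which(cnt != 0, arr.ind = TRUE)
        oa <- offs[data.table::data.table(chrom = chroms[a])]$offset
        ob <- offs[data.table::data.table(chrom = chroms[b])]$offset
        data.table::data.table(bin1 = oa + idx[, 1] - 1L, bin2 = ob + idx[, 2] - 1L,
                               count = cnt[idx])
      }))
    }))
  })
  contact_map(config$trans_bins, px)
}

#' Generate non-overlapping gene annotations for a config
#'
#' Genes are placed uniformly on a 1-kb lattice, strands alternate randomly,
#' and relative expression is log-normal.
#' @keywords internal
sim_genes <- function(config, n_genes, gene_length) {
  with_stream(derive_seed(config$seed, "genes"), {
    lens <- config$layout$lengths
    per_chrom <- round(n_genes * lens / sum(lens))
    g <- data.table::rbindlist(lapply(seq_along(config$layout$chroms), function(ci) {
      ch <- config$layout$chroms[ci]
      n <- per_chrom[ci]
      glen <- round(stats::runif(n, gene_length[1], gene_length[2]) / 100) * 100
      # partition the chromosome into n slots, one gene centered per slot
      slot <- lens[ci] / n
      start <- round((seq_len(n) - 1) * slot + (slot - glen) * stats::runif(n)) %/% 100 * 100
      data.table::data.table(chrom = ch, start = pmax(0, start),
                             end = pmin(lens[ci], start + glen),
                             strand = sample(c("+", "-"), n, replace = TRUE))
    }))
    g[, name := sprintf("gene%04d", seq_len(.N))]
    g[, score := round(exp(stats::rnorm(.N, 1, 0.6)), 3)]
    g[, .(chrom, start, end, name, score, strand)]
  })
}

pause_window <- function(gene, pause_up, pause_down) {
  if (gene$strand == "+") c(gene$start - pause_up, gene$start + pause_down)
  else c(gene$end - pause_down, gene$end + pause_up)
}

body_window <- function(gene, pause_down) {
  if (gene$strand == "+") c(gene$start + pause_down, gene$end)
  else c(gene$start, gene$end - pause_down)
}

f_pause_of <- function(config, condition) {
  w <- weaken_of(config, condition)
  f <- rep(config$f_pause_base, nrow(config$genes))
  f[config$genes$name %in% config$paused_genes] <-
    config$f_pause_base + (config$f_pause_treated - config$f_pause_base) * w
  f
}

#' Simulate one replicate of stranded PRO-seq coverage
#'
#' Per gene, total reads are Poisson around `score * proseq_reads_per_expr`;
#' a fraction `f_pause` lands uniformly in the TSS-anchored pause window
#' (strand-aware) and the remainder uniformly over the gene body.
#'
#' @inheritParams simulate_cis
#' @return `list(plus = , minus = )` of run-length coverage `data.table`s
#'   (`chrom`, `start`, `end`, `value`).
#' @export
simulate_proseq <- function(config, condition, replicate = 1) {
  g <- config$genes
  fp <- f_pause_of(config, condition)
  with_stream(derive_seed(config$seed, "proseq", condition, replicate), {
    pos_tabs <- list("+" = list(), "-" = list())
    for (i in seq_len(nrow(g))) {
      gene <- g[i]
      total <- stats::rpois(1, gene$score * config$proseq_reads_per_expr)
      if (total == 0) next
      pw <- pause_window(gene, config$pause_up, config$pause_down)
      bw <- body_window(gene, config$pause_down)
      n_pause <- stats::rbinom(1, total, fp[i])
      pos <- c(if (n_pause > 0) floor(stats::runif(n_pause, pw[1], pw[2])),
               if (total - n_pause > 0) floor(stats::runif(total - n_pause, bw[1], bw[2])))
      pos <- pos[pos >= 0 & pos < config$layout$lengths[[gene$chrom]]]
      if (!length(pos)) next
      pos_tabs[[gene$strand]][[length(pos_tabs[[gene$strand]]) + 1L]] <-
        data.table::data.table(chrom = gene$chrom, pos = pos)
    }
    to_runs <- function(lst) {
      if (!length(lst)) return(data.table::data.table(
        chrom = character(), start = numeric(), end = numeric(), value = numeric()))
      cnt <- data.table::rbindlist(lst)[, .N, by = .(chrom, pos)]
      data.table::setorder(cnt, chrom, pos)
      # merge consecutive single-base counts into runs
      n <- nrow(cnt)
      new_run <- c(TRUE, cnt$pos[-1] != cnt$pos[-n] + 1 |
                     cnt$N[-1] != cnt$N[-n] |
                     cnt$chrom[-1] != cnt$chrom[-n])
      idx <- which(new_run)
      last <- c(idx[-1] - 1L, n)
      data.table::data.table(chrom = cnt$chrom[idx], start = cnt$pos[idx],
                             end = cnt$pos[last] + 1, value = as.numeric(cnt$N[idx]))
    }
    list(plus = to_runs(pos_tabs[["+"]]), minus = to_runs(pos_tabs[["-"]]))
  })
}

#' Simulate a gene-by-tissue expression table
#'
#' Log-normal expression; designated housekeeping genes get a high mean in
#' every tissue, other genes a gene-specific mean shared across tissues plus
#' tissue noise.
#'
#' @param config A [sim_config()].
#' @return `data.table` with `gene` and one numeric column per tissue.
#' @export
simulate_expression <- function(config) {
  g <- config$genes
  with_stream(derive_seed(config$seed, "expression"), {
    hk <- g$name %in% config$housekeeping_genes
    mu <- stats::rnorm(nrow(g), 1, 1)
    mu[hk] <- stats::rnorm(sum(hk), 6, 0.25)
    mat <- sapply(seq_len(config$n_tissues), function(t) exp(mu + stats::rnorm(nrow(g), 0, 0.5)))
    out <- data.table::data.table(gene = g$name)
    out[, (sprintf("tissue%02d", seq_len(config$n_tissues))) := data.table::as.data.table(mat)]
    out
  })
}

#' Write the generator's ground truth as TSVs
#'
#' Emits `<dir>/truth_boundaries.tsv` (boundary, permeability, HDS flag) and
#' `<dir>/truth_genes.tsv` (gene, pause fraction per condition).
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(config$boundaries, file.path(dir, "truth_boundaries.tsv"), sep = "\t")
  ft <- data.table::data.table(gene = config$genes$name)
  for (cond in config$conditions$condition) ft[[cond]] <- f_pause_of(config, cond)
  data.table::fwrite(ft, file.path(dir, "truth_genes.tsv"), sep = "\t")
  invisible(dir)
}
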