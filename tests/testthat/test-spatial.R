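mk_bounds <- function(chrom, mid) data.table::data.table(
  boundary_id = sprintf("%s:%d", chrom, as.integer(mid)),
  chrom = chrom, midpoint = mid)

test_that("centromere-proximal boundaries are filtered with a strict 1-Mb rule", {
  lay <- tiny_layout(c(chrA = 20e6),
                     centromeres = data.frame(chrom = "chrA", start = 9.8e6, end = 10.2e6))
  b <- mk_bounds("chrA", c(9.3e6,          # 0.5 Mb from the edge -> removed
                           8.8e6,          # exactly 1 Mb -> retained
                           10e6,           # inside -> removed
                           5e6))
  out <- filter_centromeric(b, lay)
  expect_equal(sort(out$midpoint), c(5e6, 8.8e6))
  # no centromere annotation -> unchanged
  expect_equal(filter_centromeric(b, tiny_layout(c(chrA = 20e6))), b)
})

test_that("the linear sweep matches the documented clustering example", {
  b <- mk_bounds("chrA", c(1, 2, 10, 11, 12) * 1e6)
  res <- cluster_boundaries(b, gap = 2e6)
  expect_equal(res$clusters$n_members, c(2L, 3L))
  expect_equal(res$summary$mean_members, 2.5)
  expect_equal(res$summary$frac_clustered, 1)
  expect_equal(nrow(res$singletons), 0)

  one <- cluster_boundaries(mk_bounds("chrA", 5e6), gap = 2e6)
  expect_equal(one$summary$n_clusters, 0)
  expect_equal(nrow(one$singletons), 1)
})

test_that("sweep clustering equals the transitive-closure oracle on random placements", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(3:25, 1)
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    pos <- round(runif(n, 0, 50e6))
    gap <- runif(1, 0.5e6, 5e6)
    b <- mk_bounds(chrom, pos)
    b <- b[!duplicated(paste(chrom, pos))]
    res <- cluster_boundaries(b, gap = gap)
    # oracle partition
    o <- order(b$chrom, b$midpoint)
    grp_oracle <- cluster_oracle(b$chrom[o], b$midpoint[o], gap)
    sizes_oracle <- sort(as.integer(table(grp_oracle)[table(grp_oracle) >= 2]))
    expect_equal(sort(res$clusters$n_members), sizes_oracle)
    expect_equal(nrow(res$singletons), sum(table(grp_oracle) == 1))
  }
  # gap 0 -> all singletons
  b <- mk_bounds("c1", c(1e6, 2e6, 3e6))
  expect_equal(cluster_boundaries(b, gap = 0)$summary$n_clusters, 0)
})

test_that("trans aggregation is CPM-normalised and grouped correctly", {
  cfg <- trans_demo_config(seed = 2)
  hds <- cfg$boundaries[hds == TRUE]
  tm <- simulate_trans(cfg, "control", 1)
  agg <- trans_aggregate(tm, hds)
  # strictly increasing means with the designed hub gradient
  expect_true(all(diff(agg$mean_cpm) > 0))
  expect_lt(abs(agg$mean_cpm[4] / agg$mean_cpm[1] - 2), 0.15)
  # doubling all counts leaves CPM means unchanged
  tm2 <- contact_map(tm$bins, data.table::copy(tm$pixels)[, count := count * 2])
  agg2 <- trans_aggregate(tm2, hds)
  expect_equal(agg2$mean_cpm, agg$mean_cpm, tolerance = 1e-12)
  # uniform map -> equal group means
  u <- expected_trans_matrix(cfg, "control", "chrT1", "chrT2")
  cfg_u <- cfg; cfg_u$cluster_bins <- integer()
  tm_u <- pool_maps(lapply(1:3, function(r) simulate_trans(cfg_u, "control", r)))
  agg_u <- trans_aggregate(tm_u, hds)
  expect_lt(diff(range(agg_u$mean_cpm)), 0.08 * mean(agg_u$mean_cpm))
  expect_error(trans_aggregate(tm, hds, group_breaks = c(0, 1, 2, 3),
                               mode = "nope"), "arg")
})

test_that("the total-boundary control distinguishes density from HDS identity", {
  cfg <- trans_demo_config(seed = 2)
  hds <- cfg$boundaries[hds == TRUE]
  bins <- cfg$trans_bins
  # HDS = all boundaries -> groups ordered identically by both counts
  ctrl <- control_total_boundaries(bins, cfg$boundaries, hds)
  expect_equal(ctrl$mean_total, c(0, 1, 2, 3))
  # empty HDS set -> one group holding every bin
  ctrl0 <- control_total_boundaries(bins, cfg$boundaries, hds[0])
  expect_equal(ctrl0$n_bins[1], nrow(bins))
})

test_that("housekeeping enrichment follows the density arithmetic and top-list oracle", {
  lay <- tiny_layout(c(chrA = 100e6))
  # 50% of housekeeping genes inside clusters covering 20% of the genome -> 4x
  genes <- data.table::data.table(chrom = "chrA",
                                  start = c(seq(1e6, 19e6, 2e6), seq(21e6, 99e6, 4.5e6)),
                                  name = sprintf("g%02d", 1:28))
  genes[, end := start + 1e5]
  clusters <- data.frame(chrom = "chrA", start = 0, end = 20e6)
  hk <- c(sprintf("g%02d", 1:5), sprintf("g%02d", 24:28))   # 5 inside, 5 outside
  expr <- data.table::data.table(gene = genes$name)
  expr[, t1 := ifelse(gene %in% hk, 100 + seq_len(.N), seq_len(.N))]
  expr[, t2 := ifelse(gene %in% hk, 200 + seq_len(.N), seq_len(.N))]
  res <- housekeeping_enrichment(expr, genes, clusters, lay, top_fraction = 10 / 28)
  expect_equal(sort(res$housekeeping), sort(hk))
  expect_equal(res$cluster_fraction, 0.2)
  expect_equal(res$enrichment, (0.5 / 0.2) / (0.5 / 0.8))

  # per-tissue rescaling leaves the result unchanged
  expr2 <- data.table::copy(expr)[, t1 := t1 * 37][, t2 := t2 / 11]
  expect_equal(housekeeping_enrichment(expr2, genes, clusters, lay, 10 / 28)$enrichment,
               res$enrichment)

  # intersection-of-top-lists equals brute-force set intersection on random tables
  set.seed(31)
  for (rep in 1:20) {
    ng <- 60
    ex <- data.table::data.table(gene = sprintf("r%02d", 1:ng),
                                 a = runif(ng), b = runif(ng), c = runif(ng))
    tf <- 0.2
    res_r <- suppressWarnings(
      housekeeping_enrichment(ex, data.frame(chrom = "chrA", start = 1:ng * 1e6,
                                             end = 1:ng * 1e6 + 1e5,
                                             name = ex$gene),
                              clusters, lay, top_fraction = tf))
    k <- floor(tf * ng)
    brute <- Reduce(intersect, lapply(c("a", "b", "c"), function(cc)
      ex$gene[rank(-ex[[cc]]) <= k]))
    expect_equal(sort(res_r$housekeeping), sort(brute))
  }

  # uniform genes at matched fractions -> enrichment 1
  unif <- data.table::data.table(chrom = "chrA", start = seq(0.5e6, 99.5e6, 5e6))
  unif[, `:=`(end = start + 1e5, name = sprintf("u%02d", seq_len(.N)))]
  # top half alternates along the genome, matching the cluster fraction exactly
  exu <- data.table::data.table(gene = unif$name,
                                a = rep(c(10, 0), 10) + seq_len(20) / 100,
                                b = rep(c(10, 0), 10) + seq_len(20) / 100)
  r_u <- housekeeping_enrichment(exu, unif, clusters, lay, top_fraction = 0.5)
  expect_equal(r_u$enrichment, 1)
  expect_warning(
    housekeeping_enrichment(data.table::data.table(gene = c("x", "y"), a = c(1, 2), b = c(2, 1)),
                            unif, clusters, lay, top_fraction = 0.5),
    "empty")
})
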