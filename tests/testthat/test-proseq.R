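runs <- function(chrom, start, end, value) data.table::data.table(
  chrom = chrom, start = start, end = end, value = value)

test_that("pausing index reproduces direct arithmetic and per-base tallies", {
  # 50 reads over the 350-bp pause window, 100 over a 5,000-bp body
  gene <- data.frame(chrom = "chrA", start = 1000, end = 6300,
                     name = "g1", score = 1, strand = "+")
  cov <- list(plus = runs("chrA", c(950, 1300), c(1300, 6300), c(50 / 350, 100 / 5000)),
              minus = runs(character(), numeric(), numeric(), numeric()))
  pt <- pausing_index(cov, gene)
  expect_equal(pt$pi, (50 / 350) / (100 / 5000))
  expect_equal(pt$pi, 7.142857142857, tolerance = 1e-10)
  expect_equal(pt$pause_count, 50)
  expect_equal(pt$body_count, 100)

  # random fragmented coverage: window counts equal a brute-force per-base tally
  set.seed(13)
  for (rep in 1:10) {
    n <- 40
    st <- sort(sample(0:9950, n))
    cov_r <- runs("chrA", st, st + sample(1:40, n, replace = TRUE), rpois(n, 3))
    a <- sample(0:5000, 1); b <- a + sample(100:4000, 1)
    per_base <- numeric(12000)
    for (i in seq_len(n)) {
      ix <- (cov_r$start[i] + 1):cov_r$end[i]
      per_base[ix] <- per_base[ix] + cov_r$value[i]
    }
    expect_equal(window_count(cov_r, "chrA", a, b), sum(per_base[(a + 1):b]))
    expect_equal(insuldiff:::count_range(insuldiff:::cov_index(cov_r), "chrA", a, b),
                 window_count(cov_r, "chrA", a, b))
  }
})

test_that("pausing index is invariant under strand mirroring", {
  L <- 20000
  gene_p <- data.frame(chrom = "chrA", start = 2000, end = 9000,
                       name = "g", score = 1, strand = "+")
  set.seed(8)
  st <- sort(sample(1500:8900, 60))
  cov_p <- runs("chrA", st, st + 20, rpois(60, 4))
  pi_p <- pausing_index(list(plus = cov_p, minus = cov_p[0]), gene_p)$pi
  # mirror: x -> L - x maps the gene to the minus strand with flipped coverage
  gene_m <- data.frame(chrom = "chrA", start = L - 9000, end = L - 2000,
                       name = "g", score = 1, strand = "-")
  cov_m <- runs("chrA", L - (st + 20), L - st, cov_p$value)
  pi_m <- pausing_index(list(plus = cov_m[0], minus = cov_m), gene_m)$pi
  expect_equal(pi_m, pi_p)
})

test_that("short genes and low body coverage are flagged, not scored", {
  genes <- data.frame(chrom = "chrA", start = c(100, 5000), end = c(900, 15000),
                      name = c("tiny", "quiet"), score = 1, strand = "+")
  cov <- list(plus = runs("chrA", 5000, 5300, 1), minus = runs("chrA", 1, 2, 1)[0])
  pt <- pausing_index(cov, genes)
  expect_equal(pt$reason, c("short_gene", "low_body_reads"))
  expect_true(all(is.na(pt$pi)))
})

test_that("Fisher differential pausing matches hypergeometric enumeration", {
  # oracle: exhaustive hypergeometric enumeration for table [[10, 90], [40, 60]]
  x <- 10; m <- 50; n2 <- 150; k <- 100   # margins of the 2x2 table
  probs <- dhyper(max(0, k - n2):min(m, k), m, n2, k)
  p_oracle <- sum(probs[probs <= dhyper(x, m, n2, k) * (1 + 1e-7)])
  p_fisher <- fisher.test(matrix(c(10, 90, 40, 60), 2))$p.value
  expect_equal(p_fisher, p_oracle, tolerance = 1e-10)

  tab <- function(pc, bc) data.table::data.table(
    gene = "g", strand = "+", pause_count = pc, pause_len = 350,
    body_count = bc, body_len = 5000, pi = NA_real_, reason = "ok")
  # identical counts -> p = 1, unchanged
  dp <- differential_pausing(list(tab(10, 90)), list(tab(10, 90)))
  expect_equal(dp$p, 1)
  expect_equal(dp$class, "unchanged")
  # the hand table above, via the module interface
  dp2 <- differential_pausing(list(tab(10, 90)), list(tab(40, 60)))
  expect_equal(dp2$p, p_oracle, tolerance = 1e-10)
  expect_equal(dp2$class, "more_paused")
  # symmetric swap of conditions gives the mirrored class, same p
  dp3 <- differential_pausing(list(tab(40, 60)), list(tab(10, 90)))
  expect_equal(dp3$p, dp2$p)
  expect_equal(dp3$class, "less_paused")
})

test_that("simulated pause-fraction sweeps recover the multinomial closed form", {
  lay <- tiny_layout(c(chrA = 200e3))
  gene <- data.frame(chrom = "chrA", start = 50e3, end = 60e3,
                     name = "g", score = 10, strand = "+")
  fs <- c(0.1, 0.3, 0.5, 0.7)
  pis <- sapply(fs, function(f) {
    cfg <- sim_config(lay, bin_size = 10e3, genes = gene,
                      conditions = data.frame(condition = "ctrl", weaken = 0),
                      f_pause_base = f, proseq_reads_per_expr = 3000)
    mean(sapply(1:4, function(r)
      pausing_index(simulate_proseq(cfg, "ctrl", r), gene)$pi))
  })
  Lp <- 350; Lb <- 10e3 - 300
  closed <- fs * Lb / ((1 - fs) * Lp)
  expect_true(all(diff(pis) > 0))
  expect_equal(pis, closed, tolerance = 0.05)
})

test_that("boundary-centred profiles localise signal and split by class", {
  b <- data.table::data.table(boundary_id = c("x", "y"), chrom = "chrA",
                              midpoint = c(10e3, 30e3), class = c("HDS", "unaffected"))
  cov <- list(plus = runs("chrA", 9990, 10010, 5), minus = runs("chrA", 1, 2, 1)[0])
  prof <- boundary_transcription(cov, b, flank = 2e3, n_bins = 10)
  expect_equal(dim(prof), c(2, 10))
  expect_true(all(prof[2, ] == 0))
  expect_true(which.max(prof[1, ]) %in% 5:6)
  expect_equal(sum(prof[1, ]) * (4e3 / 10), 20 * 5)
  cls <- profile_by_class(prof, b$class)
  expect_equal(cls["HDS", ], prof[1, ])
})

test_that("region enrichment and boundary-transcript fractions follow the span arithmetic", {
  hds <- data.frame(chrom = "chrA", start = 0, end = 10e6)
  una <- data.frame(chrom = "chrA", start = 20e6, end = 60e6)
  genes <- data.frame(chrom = "chrA",
                      start = c(seq(1e6, 9.1e6, 0.9e6), seq(21e6, 59e6, 2e6)),
                      end = c(seq(1e6, 9.1e6, 0.9e6), seq(21e6, 59e6, 2e6)) + 1e4)
  res <- deregulated_boundary_enrichment(genes, hds, una)
  expect_equal(res$n_hds, 10); expect_equal(res$n_unaffected, 20)
  expect_equal(res$enrichment, (10 / 10) / (20 / 40))
  # swapping labels inverts the ratio
  swapped <- deregulated_boundary_enrichment(genes, una, hds)
  expect_equal(swapped$enrichment, 1 / res$enrichment)

  tr <- data.frame(chrom = "chrA", start = c(1e6, 2e6, 25e6, 80e6), end = c(1e6, 2e6, 25e6, 80e6) + 100)
  all_regions <- rbind(hds, una)
  expect_equal(fraction_boundary_transcripts(tr, hds, all_regions), 2 / 3)
  expect_equal(fraction_boundary_transcripts(tr, hds[0, ], all_regions), 0)
  expect_equal(fraction_boundary_transcripts(tr[1:2, ], hds, all_regions), 1)
})
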