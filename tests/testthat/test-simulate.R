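small_cfg <- function(...) {
  lay <- tiny_layout(c(chrA = 2e6, chrB = 2e6))
  sim_config(lay, bin_size = 50e3,
             boundaries = data.frame(chrom = "chrA", pos = 1e6,
                                     permeability = 0.4, hds = TRUE),
             conditions = data.frame(condition = c("ctrl", "hd"), weaken = c(0, 0.5)),
             cis_depth = 2e4, n_genes = 10, ...)
}

test_that("expected cis counts follow decay, TAD boost and boundary permeability", {
  lay <- tiny_layout(c(chrA = 2e6))
  # permeability 1 everywhere and no boost: pure distance decay
  cfg <- sim_config(lay, bin_size = 50e3,
                    boundaries = data.frame(chrom = "chrA", pos = 1e6, permeability = 1, hds = FALSE),
                    conditions = data.frame(condition = "ctrl", weaken = 0),
                    tad_boost = 1, alpha = 1.3, cis_depth = 1e4)
  e <- expected_cis_matrix(cfg, "ctrl", "chrA")
  d <- abs(outer(1:40, 1:40, "-"))
  expect_equal(e / e[1, 1], (1 + d)^(-1.3), tolerance = 1e-12)

  # permeability ~0 kills all cross-boundary contacts
  cfg0 <- sim_config(lay, bin_size = 50e3,
                     boundaries = data.frame(chrom = "chrA", pos = 1e6, permeability = 1e-12, hds = FALSE),
                     conditions = data.frame(condition = "ctrl", weaken = 0), cis_depth = 1e4)
  e0 <- expected_cis_matrix(cfg0, "ctrl", "chrA")
  expect_true(all(e0[1:20, 21:40] < 1e-6))
  expect_true(all(e0[1:20, 1:20] > 0))

  # effective permeability under weakening
  cfg2 <- small_cfg()
  expect_equal(effective_permeability(cfg2, "ctrl"), 0.4)
  expect_equal(effective_permeability(cfg2, "hd"), 0.4 + 0.5 * 0.6)

  expect_error(sim_config(lay, alpha = -1), "alpha")
})

test_that("Poisson sampling is unbiased for the expected matrix", {
  cfg <- small_cfg()
  e <- expected_cis_matrix(cfg, "ctrl", "chrA")
  reps <- 200
  acc <- matrix(0, nrow(e), ncol(e))
  for (r in seq_len(reps)) acc <- acc + cis_matrix(simulate_cis(cfg, "ctrl", r), "chrA")
  mbar <- acc / reps
  se <- sqrt(e / reps)
  idx <- e > 0.5
  z <- (mbar[idx] - e[idx]) / se[idx]
  # all within 5 se, >= 99% within 3 se (Monte-Carlo against the closed form)
  expect_lt(max(abs(z)), 5)
  expect_gt(mean(abs(z) < 3), 0.99)
  # total depth within Poisson fluctuation of the configured value
  tot <- insuldiff:::total_count(simulate_cis(cfg, "ctrl", 1))
  expect_lt(abs(tot - 2 * cfg$cis_depth), 6 * sqrt(2 * cfg$cis_depth))
})

test_that("simulation streams are deterministic and replicate-independent", {
  cfg <- small_cfg()
  expect_equal(simulate_cis(cfg, "ctrl", 1), simulate_cis(cfg, "ctrl", 1))
  expect_false(identical(simulate_cis(cfg, "ctrl", 1)$pixels,
                         simulate_cis(cfg, "ctrl", 2)$pixels))
  expect_false(identical(simulate_cis(cfg, "ctrl", 1)$pixels,
                         simulate_cis(cfg, "hd", 1)$pixels))
  p1 <- simulate_proseq(cfg, "ctrl", 1)
  expect_equal(p1, simulate_proseq(cfg, "ctrl", 1))
  expect_equal(simulate_expression(cfg), simulate_expression(cfg))
})

test_that("trans maps carry the configured hub enrichment", {
  lay <- tiny_layout(c(chrA = 8e6, chrB = 8e6))
  cfg <- sim_config(lay, bin_size = 40e3, trans_bin_size = 4e6,
                    conditions = data.frame(condition = c("ctrl", "hd"), weaken = c(0, 1)),
                    trans_rate = 300, trans_enrichment = 3,
                    cluster_bins = c(0L, 2L), n_genes = 4)
  e <- expected_trans_matrix(cfg, "ctrl", "chrA", "chrB")
  expect_equal(e[1, 1], 900)   # both bins in the hub set
  expect_equal(e[2, 2], 300)
  # full weakening collapses the enrichment to 1
  e_hd <- expected_trans_matrix(cfg, "hd", "chrA", "chrB")
  expect_equal(unname(e_hd[1, 1]), 300)
  # sampled group means recover the enrichment
  tm <- pool_maps(lapply(1:20, function(r) simulate_trans(cfg, "ctrl", r)))
  m <- trans_matrix(tm, "chrA", "chrB")
  expect_lt(abs(m[1, 1] / m[2, 2] - 3), 0.35)
})

test_that("PRO-seq placement respects strand and pause fraction", {
  lay <- tiny_layout(c(chrA = 100e3))
  genes <- data.frame(chrom = "chrA", start = c(10e3, 60e3), end = c(20e3, 70e3),
                      name = c("gp", "gm"), score = 5, strand = c("+", "-"))
  cfg <- sim_config(lay, bin_size = 10e3, genes = genes,
                    conditions = data.frame(condition = "ctrl", weaken = 0),
                    f_pause_base = 0.6, proseq_reads_per_expr = 4000)
  cov <- simulate_proseq(cfg, "ctrl", 1)
  # plus-strand gene: pause window at the left (TSS) end
  pw_plus <- window_count(cov$plus, "chrA", 10e3 - 50, 10e3 + 300)
  total_plus <- window_count(cov$plus, "chrA", 0, 30e3)
  expect_lt(abs(pw_plus / total_plus - 0.6), 0.05)
  # minus-strand gene: pause window upstream in coordinates = right end
  pw_minus <- window_count(cov$minus, "chrA", 70e3 - 300, 70e3 + 50)
  total_minus <- window_count(cov$minus, "chrA", 50e3, 80e3)
  expect_lt(abs(pw_minus / total_minus - 0.6), 0.05)
  # f_pause = 0: flat body, no pause excess
  cfg0 <- sim_config(lay, bin_size = 10e3, genes = genes[1, ],
                     conditions = data.frame(condition = "ctrl", weaken = 0),
                     f_pause_base = 0, proseq_reads_per_expr = 4000)
  cov0 <- simulate_proseq(cfg0, "ctrl", 1)
  # all reads in the body, uniformly: the two body halves have equal density
  expect_equal(window_count(cov0$plus, "chrA", 10e3 - 50, 10.3e3), 0)
  d1 <- window_count(cov0$plus, "chrA", 10.3e3, 15e3) / 4700
  d2 <- window_count(cov0$plus, "chrA", 15e3, 20e3) / 5000
  expect_lt(abs(d1 / d2 - 1), 0.1)
})

test_that("expression tables mark housekeeping genes high in every tissue", {
  cfg <- small_cfg(n_tissues = 8)
  ex <- simulate_expression(cfg)
  hk <- ex$gene %in% cfg$housekeeping_genes
  for (tt in sprintf("tissue%02d", 1:8))
    expect_gt(min(ex[[tt]][hk]), max(ex[[tt]][!hk]) / 10)
  # housekeeping rows dominate on average in all tissues
  mins <- sapply(sprintf("tissue%02d", 1:8), function(tt) min(rank(-ex[[tt]])[hk]))
  expect_true(all(mins <= sum(hk) + 3))
})
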