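test_that("matrix balancing equalises row sums and matches a Sinkhorn oracle", {
  set.seed(42)
  m <- matrix(runif(16, 1, 5), 4); m <- m + t(m)
  res <- balance_matrix(m, min_nnz = 1)
  expect_lt(max(abs(rowSums(res$matrix) - 1)), 1e-5)

  # independent Sinkhorn oracle run to tight convergence
  x <- m
  for (k in 1:10000) x <- x / outer(sqrt(rowSums(x)), sqrt(colSums(x)))
  expect_equal(unname(res$matrix), unname(x), tolerance = 1e-4)

  # a doubly stochastic matrix is a fixed point
  ds <- matrix(0.25, 4, 4)
  expect_equal(balance_matrix(ds, min_nnz = 1)$matrix, ds, tolerance = 1e-6)

  # all-zero row is masked, not balanced
  m0 <- m; m0[2, ] <- 0; m0[, 2] <- 0
  r0 <- balance_matrix(m0, min_nnz = 1)
  expect_true(r0$mask[2])
  expect_lt(max(abs(rowSums(r0$matrix[-2, -2]) - 1)), 1e-5)
  expect_error(balance_matrix(matrix(-1, 2, 2)), "nonnegative")
})

test_that("insulation scores equal the exhaustive enumeration oracle", {
  set.seed(7)
  for (rep in 1:25) {
    m <- random_symmetric(20)
    map <- map_from_dense(m)
    tr <- insulation_score(map, window = 30, balance = FALSE)  # w = 3 bins
    expect_equal(tr$score, insulation_oracle(m, 3))
    expect_equal(tr$valid, !is.na(insulation_oracle(m, 3)))
  }
  # constant matrix scores exactly zero on valid bins
  tr0 <- insulation_score(map_from_dense(matrix(4, 15, 15)), 20, balance = FALSE)
  expect_equal(tr0$score[tr0$valid], rep(0, sum(tr0$valid)))
})

test_that("insulation window preconditions and edge masking hold", {
  m <- random_symmetric(12)
  map <- map_from_dense(m)
  expect_error(insulation_score(map, 25), "multiple")
  expect_error(insulation_score(map, 10), "2 bins")
  expect_warning(insulation_score(map, 60), "masked")   # 2w+1 = 13 > 12 bins
  tr <- insulation_score(map, 30, balance = FALSE)
  expect_false(any(tr$valid[c(1:3, 10:12)]))
})

test_that("a contact-free junction produces a guarded deep minimum", {
  m <- matrix(0, 20, 20)
  m[1:10, 1:10] <- 50; m[11:20, 11:20] <- 50
  tr <- insulation_score(map_from_dense(m), 40, balance = FALSE)
  b <- call_boundaries(tr, prominence_min = 0.1)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin_id, 9)   # leftmost bin of the two-bin plateau (0-based)
  expect_true(is.finite(b$score))
})

test_that("boundary calling finds minima with the stated tie and prominence rules", {
  mk_track <- function(score) {
    n <- length(score)
    data.table::data.table(chrom = "chrA", start = (0:(n - 1)) * 10,
                           end = (1:n) * 10, bin_id = 0:(n - 1),
                           score = score, valid = TRUE)
  }
  expect_equal(nrow(call_boundaries(mk_track(1:10 / 2))), 0)       # monotone
  b <- call_boundaries(mk_track(c(3, 2, 1, 0.2, 1, 2, 3)))
  expect_equal(b$bin_id, 3L)                                       # V shape
  # plateau resolved to leftmost bin
  bp <- call_boundaries(mk_track(c(3, 1, 1, 1, 3)))
  expect_equal(bp$bin_id, 1L)
  # prominence gate
  expect_equal(nrow(call_boundaries(mk_track(c(1, 0.95, 1)), prominence_min = 0.1)), 0)
  expect_equal(nrow(call_boundaries(mk_track(c(1, 0.85, 1)), prominence_min = 0.1)), 1)
})

test_that("cross-sample scoring preserves missingness and the union merge rule", {
  mk_track <- function(score, valid = rep(TRUE, length(score))) {
    n <- length(score)
    data.table::data.table(chrom = "chrA", start = (0:(n - 1)) * 10,
                           end = (1:n) * 10, bin_id = 0:(n - 1),
                           score = score, valid = valid)
  }
  sc <- c(3, 2, 0.5, 2, 3, 2, 1, 2, 3)
  t1 <- mk_track(sc)
  b <- call_boundaries(t1)
  out <- score_boundaries_across_samples(b, list(s1 = t1, s2 = t1))
  expect_equal(out$score_s1, out$score_s2)
  # masked bin in one sample -> NA, never zero
  t2 <- mk_track(sc, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  out2 <- score_boundaries_across_samples(b, list(s1 = t1, s2 = t2))
  expect_true(is.na(out2$score_s2[out2$bin_id == 2]))
  # union mode: calls 1 bin apart merge to the lower-score bin
  ta <- mk_track(c(3, 2, 0.5, 2, 3, 3, 3, 3, 3))
  tb <- mk_track(c(3, 2, 2, 0.8, 3, 3, 3, 3, 3))
  merged <- score_boundaries_across_samples(
    list(a = call_boundaries(ta), b = call_boundaries(tb)),
    list(a = ta, b = tb), mode = "union")
  expect_equal(merged$bin_id, 2L)
})

test_that("weakening a boundary raises its expected insulation score monotonically", {
  lay <- tiny_layout(c(chrA = 4e6))
  scores <- sapply(c(0.1, 0.3, 0.5, 0.8, 1), function(pi_b) {
    cfg <- sim_config(lay, bin_size = 50e3,
                      boundaries = data.frame(chrom = "chrA", pos = 2e6,
                                              permeability = pi_b, hds = FALSE),
                      conditions = data.frame(condition = "ctrl", weaken = 0),
                      cis_depth = 1e5)
    e <- expected_cis_matrix(cfg, "ctrl", "chrA")
    tr <- insulation_score(map_from_dense(e, bin_size = 50e3), 250e3, balance = FALSE)
    tr$score[tr$bin_id == 39]   # bin left of the boundary edge
  })
  expect_true(all(diff(scores) > 0))
})

test_that("shifting planted boundaries shifts called midpoints identically", {
  lay <- tiny_layout(c(chrA = 4e6))
  call_at <- function(pos) {
    cfg <- sim_config(lay, bin_size = 50e3,
                      boundaries = data.frame(chrom = "chrA", pos = pos,
                                              permeability = 0.2, hds = FALSE),
                      conditions = data.frame(condition = "ctrl", weaken = 0),
                      cis_depth = 1e5)
    e <- expected_cis_matrix(cfg, "ctrl", "chrA")
    call_boundaries(insulation_score(map_from_dense(e, bin_size = 50e3), 250e3,
                                     balance = FALSE))$midpoint
  }
  shift <- 10 * 50e3
  expect_equal(call_at(2e6 + shift), call_at(2e6) + shift)
})
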