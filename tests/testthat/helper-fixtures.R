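# Shared fixtures: tiny genomes and dense-matrix contact maps built in code.

tiny_layout <- function(lengths = c(chrA = 100e3), centromeres = NULL) {
  genome_layout(names(lengths), unname(lengths), centromeres = centromeres)
}

# Wrap a dense symmetric matrix as a one-chromosome contact map with 10-bp bins.
map_from_dense <- function(m, bin_size = 10, chrom = "chrA") {
  layout <- genome_layout(chrom, nrow(m) * bin_size)
  bins <- make_bin_table(layout, bin_size)
  insuldiff:::map_from_cis_matrices(bins, stats::setNames(list(m), chrom))
}

random_symmetric <- function(n, lambda = 20) {
  m <- matrix(rpois(n * n, lambda), n)
  (m + t(m))
}

# Independent exhaustive oracle for the insulation score (raw counts, no
# balancing): direct double loop over the crossing square, then the same
# log2 / floor rule as documented.
insulation_oracle <- function(m, w) {
  n <- nrow(m)
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    tot <- 0; cnt <- 0
    for (u in (i - w):(i - 1)) for (v in (i + 1):(i + w)) {
      tot <- tot + m[u, v]; cnt <- cnt + 1
    }
    s[i] <- tot / cnt
  }
  ok <- !is.na(s)
  pos <- s[ok & s > 0]
  floor_val <- if (length(pos)) min(pos) / 2 else 0.5
  s[ok & s == 0] <- floor_val
  out <- rep(NA_real_, n)
  out[ok] <- log2(s[ok] / mean(s[ok]))
  out
}

# Independent Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Closed-form pooled two-sample t-test (the textbook formula).
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(delta = mean(y) - mean(x), t = t,
       p = 2 * pt(-abs(t), nx + ny - 2))
}

# Brute-force transitive-closure clustering oracle: repeatedly merge any two
# groups containing boundaries within the gap, until stable.
cluster_oracle <- function(chrom, pos, gap) {
  grp <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (i == j || grp[i] == grp[j]) next
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= gap) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp[order(chrom, pos)]))
}
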