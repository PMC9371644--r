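#' Iterative proportional fitting (matrix balancing) of a cis matrix
#'
#' Alternately rescales rows and columns (symmetrically) until all unmasked
#' row sums agree to within `tol` (relative). Bins with fewer than `min_nnz`
#' nonzero entries are masked and excluded.
#'
#' @param mat Dense symmetric nonnegative matrix.
#' @param tol Relative row-sum tolerance (default 1e-5).
#' @param max_iter Iteration cap; non-convergence is an error that reports
#'   the iteration count.
#' @param min_nnz Minimum nonzero entries for a bin to stay unmasked.
#' @return List with `matrix` (balanced, masked rows/cols set to `NA`) and
#'   logical `mask` (`TRUE` = bin masked).
#' @export
balance_matrix <- function(mat, tol = 1e-5, max_iter = 1000, min_nnz = 5) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0)) stop("contact matrix must be nonnegative")
  n <- nrow(mat)
  mask <- rowSums(mat > 0) < min_nnz
  m <- mat[!mask, !mask, drop = FALSE]
  if (!nrow(m)) return(list(matrix = matrix(NA_real_, n, n), mask = rep(TRUE, n)))
  bias <- rep(1, nrow(m))
  target <- 1
  for (it in seq_len(max_iter)) {
    rs <- rowSums(m * rep(bias, each = nrow(m))) * bias
    if (max(abs(rs - target) / target) < tol) {
      out <- matrix(NA_real_, n, n)
      out[!mask, !mask] <- m * outer(bias, bias)
      return(list(matrix = out, mask = mask, iterations = it))
    }
    bias <- bias / sqrt(rs / target)
  }
  stop("matrix balancing did not converge after ", max_iter, " iterations")
}

#' Balance every cis matrix of a contact map
#'
#' @param map A [contact_map()] holding cis contacts.
#' @inheritParams balance_matrix
#' @return List keyed by chromosome of [balance_matrix()] results.
#' @export
balance_cis <- function(map, tol = 1e-5, max_iter = 1000, min_nnz = 5) {
  chroms <- unique(map$bins$chrom)
  out <- lapply(chroms, function(ch) balance_matrix(cis_matrix(map, ch),
                                                    tol = tol, max_iter = max_iter,
                                                    min_nnz = min_nnz))
  names(out) <- chroms
  out
}

insulation_chrom <- function(m, valid, w) {
  n <- nrow(m)
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n || !valid[i]) next
    block <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (all(is.na(block))) next
    s[i] <- mean(block, na.rm = TRUE)
  }
  s
}

#' Insulation-score track from a cis contact map
#'
#' For bin i and window of w bins, the raw score is the mean contact count
#' over the w-by-w square of pairs (u, v) with u < i < v, u >= i - w,
#' v <= i + w — the contacts crossing the bin. The reported score is
#' `log2(raw / chromosome-wide mean of raw over valid bins)`. Bins within a
#' window of a chromosome edge, masked bins, and short terminal bins are
#' invalid. A raw score of exactly 0 is floored at half the smallest
#' positive raw score on that chromosome before taking logs.
#'
#' @param map A [contact_map()] of cis contacts.
#' @param window Window in bp; must be a positive multiple of the bin size,
#'   at least 2 bins.
#' @param balance Balance matrices first (default `TRUE`); set `FALSE` to
#'   score raw counts.
#' @param min_nnz Passed to [balance_matrix()].
#' @return `data.table` insulation track: `chrom`, `start`, `end`, `bin_id`,
#'   `score`, `valid`; attribute `window`.
#' @export
insulation_score <- function(map, window, balance = TRUE, min_nnz = 5) {
  bins <- map$bins
  bs <- bin_size_of(bins)
  if (window %% bs != 0 || window < 2 * bs)
    stop("window must be a multiple of the bin size and span >= 2 bins")
  w <- as.integer(window / bs)
  offs <- chrom_offsets(bins)
  track <- data.table::copy(bins)[, `:=`(score = NA_real_, valid = FALSE)]
  for (ch in unique(bins$chrom)) {
    o <- offs[data.table::data.table(chrom = ch)]
    n <- o$n
    if (n < 2 * w + 1) {
      warning("chromosome ", ch, " shorter than 2*window + 1 bins; all bins masked")
      next
    }
    if (balance) {
      bal <- balance_matrix(cis_matrix(map, ch), min_nnz = min_nnz)
      m <- bal$matrix
      valid <- !bal$mask
    } else {
      m <- cis_matrix(map, ch)
      valid <- rep(TRUE, n)
    }
    # short terminal bin is not comparable to full bins
    idx <- (o$offset + 1):(o$offset + n)
    valid <- valid & (bins$end[idx] - bins$start[idx] == bs)
    s <- insulation_chrom(m, valid, w)
    ok <- !is.na(s)
    if (any(ok)) {
      pos_min <- suppressWarnings(min(s[ok & s > 0]))
      if (!is.finite(pos_min)) pos_min <- 1
      s[ok & s == 0] <- pos_min / 2
      sc <- log2(s / mean(s[ok]))
      track[idx[ok], `:=`(score = sc[ok], valid = TRUE)]
    }
  }
  data.table::setattr(track, "window", window)
  track[]
}

# Topographic prominence of a local minimum within one valid segment.
min_prominence <- function(s, i) {
  left <- if (i > 1) rev(s[1:(i - 1)]) else numeric()
  right <- if (i < length(s)) s[(i + 1):length(s)] else numeric()
  side_max <- function(v) {
    below <- which(v < s[i])
    if (length(below)) v <- v[seq_len(below[1] - 1)]
    if (length(v)) max(v) else s[i]
  }
  min(side_max(left), side_max(right)) - s[i]
}

#' Call TAD boundaries at insulation-score minima
#'
#' Local minima (strictly lower than both flanking valid scores; plateaus
#' resolved to their leftmost bin) with topographic prominence at least
#' `prominence_min` are reported, sorted by coordinate. Masked bins split a
#' chromosome into independent segments.
#'
#' @param track An [insulation_score()] track.
#' @param prominence_min Minimum prominence in log2 units (default 0.1).
#' @return `data.table` of boundaries: `boundary_id`, `chrom`, `bin_id`,
#'   `start`, `end`, `midpoint`, `score`, `prominence`.
#' @export
call_boundaries <- function(track, prominence_min = 0.1) {
  empty <- data.table::data.table(boundary_id = character(), chrom = character(),
                                  bin_id = integer(), start = numeric(), end = numeric(),
                                  midpoint = numeric(), score = numeric(), prominence = numeric())
  v <- which(track$valid)
  if (!length(v)) return(empty)
  seg_id <- cumsum(c(1, diff(v) != 1 | diff(track$bin_id[v]) != 1))
  res <- list()
  for (sg in unique(seg_id)) {
    rows <- v[seg_id == sg]
    s <- track$score[rows]
    if (length(s) < 3) next
    for (i in 2:(length(s) - 1)) {
      # plateau: leftmost bin of a flat run that is a minimum wins
      if (s[i] >= s[i - 1]) next
      j <- i
      while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
      if (j == length(s) || s[j + 1] <= s[i]) next
      prom <- min_prominence(s, i)
      if (prom < prominence_min) next
      r <- rows[i]
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = track$chrom[r], bin_id = track$bin_id[r],
        start = track$start[r], end = track$end[r],
        midpoint = (track$start[r] + track$end[r]) / 2,
        score = s[i], prominence = prom)
    }
  }
  if (!length(res)) return(empty)
  out <- data.table::rbindlist(res)
  data.table::setorder(out, chrom, start)
  out[, boundary_id := sprintf("%s:%d", chrom, as.integer(start))]
  data.table::setcolorder(out, "boundary_id")
  out[]
}

#' Annotate a fixed boundary set with insulation scores from many samples
#'
#' Boundaries are taken either from a designated reference sample's calls
#' (`boundaries` argument) or, with `mode = "union"`, from the union of
#' per-sample calls merged within 1 bin (the lower-score bin wins a merge).
#' Each boundary is annotated with every sample's insulation score at its
#' bin; a masked bin yields `NA`, never 0.
#'
#' @param boundaries Boundary table from [call_boundaries()] (reference
#'   mode), or a named list of per-sample boundary tables (union mode).
#' @param tracks Named list of [insulation_score()] tracks, one per sample.
#' @param mode `"reference"` or `"union"`.
#' @return `data.table` with boundary columns plus one `score_<sample>`
#'   column per track.
#' @export
score_boundaries_across_samples <- function(boundaries, tracks, mode = c("reference", "union")) {
  mode <- match.arg(mode)
  if (mode == "union") {
    all_b <- data.table::rbindlist(boundaries, use.names = TRUE)
    data.table::setorder(all_b, chrom, bin_id, score)
    merged <- list()
    for (ch in unique(all_b$chrom)) {
      bb <- all_b[chrom == ch]
      data.table::setorder(bb, bin_id)
      grp <- cumsum(c(1, diff(bb$bin_id) > 1))
      merged[[ch]] <- bb[, .SD[which.min(score)], by = .(grp = grp)][, grp := NULL]
    }
    boundaries <- data.table::rbindlist(merged)
    data.table::setorder(boundaries, chrom, start)
    boundaries <- unique(boundaries, by = "bin_id")
  }
  out <- data.table::copy(boundaries)
  for (smp in names(tracks)) {
    tr <- tracks[[smp]]
    sc <- tr$score[match(out$bin_id, tr$bin_id)]
    sc[!tr$valid[match(out$bin_id, tr$bin_id)]] <- NA_real_
    out[[paste0("score_", smp)]] <- sc
  }
  out
}
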