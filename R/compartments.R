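#' A/B compartment profile from a cis contact map
#'
#' Per chromosome: expected counts are the mean of each diagonal over valid
#' bins; the observed/expected matrix is correlated (Pearson) across valid
#' bins and the leading eigenvector of that correlation matrix is the
#' compartment profile (PC1, unit norm per chromosome). Its global sign is
#' chosen so PC1 correlates positively with a caller-supplied orientation
#' track (e.g. gene density); bins with positive PC1 are labelled A,
#' negative B.
#'
#' @param map A [contact_map()] (typically 500-kb bins).
#' @param orientation Numeric orientation track over the map's bin table.
#' @param min_valid Minimum valid bins per chromosome; chromosomes below it
#'   are skipped with a warning.
#' @return `data.table`: `chrom`, `start`, `end`, `bin_id`, `pc1`, `label`
#'   (`NA` on masked/skipped bins).
#' @export
compartment_pc1 <- function(map, orientation, min_valid = 10) {
  bins <- map$bins
  stopifnot(length(orientation) == nrow(bins))
  out <- data.table::copy(bins)[, `:=`(pc1 = NA_real_, label = NA_character_)]
  offs <- chrom_offsets(bins)
  for (ch in unique(bins$chrom)) {
    o <- offs[data.table::data.table(chrom = ch)]
    m <- cis_matrix(map, ch)
    n <- o$n
    valid <- rowSums(m) > 0
    if (sum(valid) < min_valid) {
      warning("chromosome ", ch, ": fewer than ", min_valid, " valid bins; skipped")
      next
    }
    mv <- m[valid, valid, drop = FALSE]
    d <- abs(outer(which(valid), which(valid), "-"))
    exp_diag <- vapply(0:(n - 1), function(k) {
      v <- mv[d == k]
      if (length(v)) mean(v) else NA_real_
    }, 1)
    oe <- mv / matrix(exp_diag[d + 1], nrow(mv))
    oe[!is.finite(oe)] <- 0
    cc <- suppressWarnings(stats::cor(oe))
    cc[!is.finite(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    pc1 <- eg$vectors[, 1]
    ori <- orientation[(o$offset + 1):(o$offset + n)][valid]
    if (sum(pc1 * ori, na.rm = TRUE) < 0) pc1 <- -pc1
    idx <- (o$offset + 1):(o$offset + n)
    out$pc1[idx[valid]] <- pc1
    out$label[idx[valid]] <- ifelse(pc1 > 0, "A", "B")
  }
  out[]
}

#' Differential compartment calls between two conditions
#'
#' Per-bin Gaussian test of PC1 across replicates (same pooled-t machinery
#' as the boundary analysis), Benjamini-Hochberg FDR; a bin is reported as
#' switched when its mean PC1 changes sign between conditions and
#' `q < fdr`.
#'
#' @param tracks Named list of [compartment_pc1()] tracks, one per sample.
#' @param samples Sample sheet (`sample`, `condition`).
#' @param control,treated Condition labels.
#' @param fdr FDR threshold (default 0.05).
#' @return `data.table` of per-bin results: mean PC1 per condition, `delta`,
#'   `p`, `q`, logical `switched`.
#' @export
differential_compartments <- function(tracks, samples, control, treated, fdr = 0.05) {
  samples <- data.table::as.data.table(samples)
  use <- samples[condition %in% c(control, treated)]
  mat <- sapply(use$sample, function(s) tracks[[s]]$pc1)
  bins <- tracks[[use$sample[1]]][, .(chrom, start, end, bin_id)]
  cond <- factor(use$condition, levels = c(control, treated))
  res <- row_t_test(mat, cond)
  out <- data.table::copy(bins)
  out[, mean_control := rowMeans(mat[, cond == control, drop = FALSE], na.rm = TRUE)]
  out[, mean_treated := rowMeans(mat[, cond == treated, drop = FALSE], na.rm = TRUE)]
  out[, c("delta", "p") := .(res$delta, res$p)]
  ok <- is.finite(out$p)
  out[, q := NA_real_]
  out[ok, q := stats::p.adjust(p, method = "BH")]
  out[, switched := ok & q < fdr & sign(mean_control) != sign(mean_treated) &
        is.finite(mean_control) & is.finite(mean_treated)]
  out[]
}
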