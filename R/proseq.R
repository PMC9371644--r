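#' Total reads in a genomic window of a run-length coverage track
#'
#' @param cov Coverage `data.table` (`chrom`, `start`, `end`, `value`),
#'   value = reads per base.
#' @param chrom Chromosome; `a`, `b`: window, 0-based half-open.
#' @return Read count (value times covered length).
#' @export
window_count <- function(cov, chrom, a, b) {
  cc <- cov[cov$chrom == chrom & cov$end > a & cov$start < b]
  if (!nrow(cc)) return(0)
  sum(cc$value * (pmin(cc$end, b) - pmax(cc$start, a)))
}

# Index a run-length coverage track for O(log n) window queries.
# Runs must be disjoint within a chromosome (as emitted by the simulator
# and by bedGraph convention).
cov_index <- function(cov) {
  cov <- data.table::as.data.table(cov)
  data.table::setorder(cov, chrom, start)
  lapply(split(cov, by = "chrom"), function(cc)
    list(start = cc$start, end = cc$end, value = cc$value,
         disjoint = !is.unsorted(cc$end) && all(cc$start[-1] >= cc$end[-length(cc$end)])))
}

count_range <- function(ix, chrom, a, b) {
  s <- ix[[chrom]]
  if (is.null(s) || !length(s$start)) return(0)
  if (!s$disjoint) {                                     # overlapping runs: linear scan
    r <- which(s$end > a & s$start < b)
    if (!length(r)) return(0)
    return(sum(s$value[r] * (pmin(s$end[r], b) - pmax(s$start[r], a))))
  }
  lo <- findInterval(a, s$end) + 1L                      # first run ending after a
  hi <- findInterval(b, s$start, left.open = TRUE)       # last run starting before b
  if (hi < lo) return(0)
  r <- lo:hi
  sum(s$value[r] * (pmin(s$end[r], b) - pmax(s$start[r], a)))
}

#' Boundary-centred transcription profiles
#'
#' Strand-summed coverage is binned over +/- `flank` around each boundary
#' midpoint into `n_bins` equal bins (reads per bp per bin).
#'
#' @param coverage `list(plus =, minus =)` of coverage tracks.
#' @param boundaries Boundary table with `chrom`, `midpoint` (and
#'   optionally `class` for [profile_by_class()]).
#' @param flank Half-width of the profile window in bp.
#' @param n_bins Number of profile bins (even; default 50).
#' @return Matrix boundaries x bins of read density; rownames =
#'   `boundary_id` when present.
#' @export
boundary_transcription <- function(coverage, boundaries, flank = 2e5, n_bins = 50) {
  ix_p <- cov_index(coverage$plus)
  ix_m <- cov_index(coverage$minus)
  width <- 2 * flank / n_bins
  prof <- matrix(0, nrow(boundaries), n_bins)
  for (i in seq_len(nrow(boundaries))) {
    lo <- boundaries$midpoint[i] - flank
    for (k in seq_len(n_bins)) {
      a <- lo + (k - 1) * width; b <- lo + k * width
      prof[i, k] <- (count_range(ix_p, boundaries$chrom[i], a, b) +
                     count_range(ix_m, boundaries$chrom[i], a, b)) / width
    }
  }
  if ("boundary_id" %in% names(boundaries)) rownames(prof) <- boundaries$boundary_id
  prof
}

#' Mean transcription profile per boundary class
#' @param prof Matrix from [boundary_transcription()].
#' @param class Class label per boundary (e.g. HDS / unaffected).
#' @return Matrix class x bins of mean density.
#' @export
profile_by_class <- function(prof, class) {
  t(sapply(split(seq_along(class), class), function(ix)
    colMeans(prof[ix, , drop = FALSE])))
}

#' Promoter-proximal pausing index per gene
#'
#' PI = (pause-window reads / pause length) / (body reads / body length),
#' with strand-aware windows: pause = \[TSS - pause_up, TSS + pause_down)
#' and body = \[TSS + pause_down, TES) in the direction of transcription.
#' PI is `NA` when the body has fewer than `min_body_reads` reads; genes
#' whose body would be shorter than `min_body_len` are skipped with a
#' reason code.
#'
#' @param coverage `list(plus =, minus =)` coverage tracks; each gene is
#'   quantified on its own strand.
#' @param genes Gene table (`chrom`, `start`, `end`, `name`, `strand`).
#' @param pause_up,pause_down Pause window geometry in bp.
#' @param min_body_reads Minimum body reads for a defined PI (default 10).
#' @param min_body_len Minimum body length in bp (default 1000).
#' @return `data.table`: `gene`, `strand`, `pause_count`, `pause_len`,
#'   `body_count`, `body_len`, `pi`, `reason` (`"ok"`, `"short_gene"`,
#'   `"low_body_reads"`).
#' @export
pausing_index <- function(coverage, genes, pause_up = 50, pause_down = 300,
                          min_body_reads = 10, min_body_len = 1000) {
  genes <- data.table::as.data.table(genes)
  ix <- list("+" = cov_index(coverage$plus), "-" = cov_index(coverage$minus))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    body_len <- (g$end - g$start) - pause_down
    if (body_len < min_body_len)
      return(data.table::data.table(gene = g$name, strand = g$strand,
                                    pause_count = NA_real_, pause_len = NA_real_,
                                    body_count = NA_real_, body_len = NA_real_,
                                    pi = NA_real_, reason = "short_gene"))
    if (g$strand == "+") {
      pw <- c(g$start - pause_up, g$start + pause_down); bw <- c(g$start + pause_down, g$end)
    } else {
      pw <- c(g$end - pause_down, g$end + pause_up); bw <- c(g$start, g$end - pause_down)
    }
    pc <- count_range(ix[[g$strand]], g$chrom, pw[1], pw[2])
    bc <- count_range(ix[[g$strand]], g$chrom, bw[1], bw[2])
    pl <- pw[2] - pw[1]; bl <- bw[2] - bw[1]
    ok <- bc >= min_body_reads
    data.table::data.table(gene = g$name, strand = g$strand,
                           pause_count = pc, pause_len = pl,
                           body_count = bc, body_len = bl,
                           pi = if (ok) (pc / pl) / (bc / bl) else NA_real_,
                           reason = if (ok) "ok" else "low_body_reads")
  })
  data.table::rbindlist(out)
}

#' Differential pausing between two conditions
#'
#' Replicate pause/body counts are summed per condition and each gene is
#' tested with Fisher's exact test on the 2x2 table (pause vs body, control
#' vs treated), followed by Benjamini-Hochberg correction. Classes at
#' `q < fdr`: `more_paused` when the treated PI exceeds the control PI,
#' `less_paused` when lower, otherwise `unchanged`.
#'
#' @param control,treated Lists of [pausing_index()] tables (one per
#'   replicate).
#' @param fdr FDR threshold (default 0.05).
#' @return `data.table` per gene: summed counts, PI per condition, `p`,
#'   `q`, `class`.
#' @export
differential_pausing <- function(control, treated, fdr = 0.05) {
  sum_cond <- function(tables) {
    all <- data.table::rbindlist(tables)
    all[, .(pause = sum(pause_count), body = sum(body_count),
            pause_len = pause_len[1], body_len = body_len[1]), by = gene]
  }
  a <- sum_cond(control); b <- sum_cond(treated)
  m <- merge(a, b, by = "gene", suffixes = c("_control", "_treated"))
  m <- m[is.finite(pause_control) & is.finite(pause_treated)]
  m[, pi_control := (pause_control / pause_len_control) / (body_control / body_len_control)]
  m[, pi_treated := (pause_treated / pause_len_treated) / (body_treated / body_len_treated)]
  m[, p := vapply(seq_len(.N), function(i)
    stats::fisher.test(matrix(round(c(pause_control[i], body_control[i],
                                      pause_treated[i], body_treated[i])), 2))$p.value, 1)]
  m[, q := stats::p.adjust(p, method = "BH")]
  m[, class := "unchanged"]
  m[q < fdr & pi_treated > pi_control, class := "more_paused"]
  m[q < fdr & pi_treated < pi_control, class := "less_paused"]
  m[]
}

midpoint_in <- function(chrom, mid, regions) {
  hit <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(regions)))
    hit <- hit | (chrom == regions$chrom[i] & mid >= regions$start[i] & mid < regions$end[i])
  hit
}

#' Span-normalised enrichment of deregulated genes on HDS regions
#'
#' For one gene class, enrichment = (genes overlapping HDS regions per Mb of
#' HDS span) / (genes overlapping unaffected regions per Mb of unaffected
#' span); midpoint containment.
#'
#' @param genes Gene table (`chrom`, `start`, `end`) for one class.
#' @param hds_regions,unaffected_regions Region tables (`chrom`, `start`,
#'   `end`).
#' @return List: `enrichment`, `n_hds`, `n_unaffected`, spans in Mb.
#' @export
deregulated_boundary_enrichment <- function(genes, hds_regions, unaffected_regions) {
  genes <- data.table::as.data.table(genes)
  mid <- (genes$start + genes$end) / 2
  n_h <- sum(midpoint_in(genes$chrom, mid, hds_regions))
  n_u <- sum(midpoint_in(genes$chrom, mid, unaffected_regions))
  span_h <- sum(hds_regions$end - hds_regions$start) / 1e6
  span_u <- sum(unaffected_regions$end - unaffected_regions$start) / 1e6
  list(enrichment = (n_h / span_h) / (n_u / span_u),
       n_hds = n_h, n_unaffected = n_u, span_hds_mb = span_h, span_unaffected_mb = span_u)
}

#' Fraction of boundary transcripts originating from HDS boundaries
#'
#' Among transcripts whose midpoint falls in any boundary region, the
#' fraction whose region is HDS.
#'
#' @param transcripts Interval table (`chrom`, `start`, `end`).
#' @param hds_regions HDS boundary regions.
#' @param all_boundary_regions All boundary regions (superset of HDS).
#' @return Fraction in \[0, 1\] (0 when no boundary transcripts exist).
#' @export
fraction_boundary_transcripts <- function(transcripts, hds_regions, all_boundary_regions) {
  transcripts <- data.table::as.data.table(transcripts)
  mid <- (transcripts$start + transcripts$end) / 2
  on_any <- midpoint_in(transcripts$chrom, mid, all_boundary_regions)
  if (!any(on_any)) return(0)
  on_hds <- midpoint_in(transcripts$chrom, mid, hds_regions)
  sum(on_any & on_hds) / sum(on_any)
}
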