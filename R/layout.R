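#' Describe a genome as an ordered set of chromosomes
#'
#' A genome layout records chromosome names, their lengths in base pairs and,
#' optionally, centromere intervals. It is the coordinate frame against which
#' every bin table and interval in the pipeline is validated.
#'
#' @param chroms Character vector of unique chromosome names, in the order
#'   they should appear in bin tables and outputs.
#' @param lengths Numeric vector of chromosome lengths (bp), parallel to
#'   `chroms`; all must be positive.
#' @param centromeres Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open) giving one centromere interval per chromosome.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chroms, lengths, centromeres = NULL) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(lengths) != length(chroms)) stop("chroms and lengths differ in length")
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) stop("chromosome lengths must be positive")
  names(lengths) <- chroms
  if (!is.null(centromeres)) {
    centromeres <- data.table::as.data.table(centromeres)[, .(chrom = as.character(chrom),
                                                              start = as.numeric(start),
                                                              end = as.numeric(end))]
    bad <- centromeres[!(chrom %in% chroms)]
    if (nrow(bad)) stop("centromere on unknown chromosome: ", bad$chrom[1])
    ln <- lengths[centromeres$chrom]
    if (any(centromeres$start < 0) || any(centromeres$end > ln) ||
        any(centromeres$start >= centromeres$end))
      stop("centromere interval outside [0, chromosome length)")
  }
  structure(list(chroms = chroms, lengths = lengths, centromeres = centromeres),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.1f Mb total%s\n",
              length(x$chroms), sum(x$lengths) / 1e6,
              if (is.null(x$centromeres)) "" else sprintf(", %d centromere(s)", nrow(x$centromeres))))
  invisible(x)
}

#' Tile a genome into fixed-size bins
#'
#' Bins tile each chromosome without gaps or overlaps, 0-based half-open;
#' the last bin per chromosome may be shorter than `bin_size`. Bins carry a
#' dense global index `bin_id` running 0..N-1 in (chromosome order, start
#' order).
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (> 0).
#' @return A `data.table` of class `bin_table` with columns `chrom`, `start`,
#'   `end`, `bin_id`; attributes `bin_size` and `layout`.
#' @export
make_bin_table <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  bins <- data.table::rbindlist(lapply(layout$chroms, function(ch) {
    len <- layout$lengths[[ch]]
    starts <- (seq_len(ceiling(len / bin_size)) - 1) * bin_size
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + bin_size, len))
  }))
  bins[, bin_id := seq_len(.N) - 1L]
  data.table::setattr(bins, "bin_size", bin_size)
  data.table::setattr(bins, "layout", layout)
  data.table::setattr(bins, "class", c("bin_table", class(bins)))
  bins[]
}

bin_size_of <- function(bins) attr(bins, "bin_size", exact = TRUE)
layout_of   <- function(bins) attr(bins, "layout", exact = TRUE)

#' Per-chromosome offsets of global bin ids
#' @keywords internal
chrom_offsets <- function(bins) {
  off <- bins[, .(offset = min(bin_id), n = .N), by = chrom]
  data.table::setkey(off, chrom)
  off
}

#' Map (chrom, position) to a global bin id
#' @keywords internal
bin_id_at <- function(bins, chrom, pos) {
  ch_query <- chrom
  off <- chrom_offsets(bins)
  o <- off[data.table::data.table(chrom = ch_query)]
  if (anyNA(o$offset)) stop("unknown chromosome: ", ch_query[is.na(o$offset)][1])
  id <- o$offset + floor(pos / bin_size_of(bins))
  if (any(pos < 0) || any(id >= o$offset + o$n)) stop("position outside chromosome")
  as.integer(id)
}

#' Validate a set of intervals against a genome layout
#'
#' @param x `data.frame` with at least `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param layout A [genome_layout()].
#' @return `x` invisibly; stops with an informative error on the first
#'   offending row.
#' @export
validate_intervals <- function(x, layout) {
  x <- data.table::as.data.table(x)
  unknown <- which(!(x$chrom %in% layout$chroms))
  if (length(unknown)) stop("record ", unknown[1], ": unknown chromosome '", x$chrom[unknown[1]], "'")
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad)) stop("record ", bad[1], ": invalid interval [", x$start[bad[1]], ",", x$end[bad[1]], ")")
  over <- which(x$end > layout$lengths[x$chrom])
  if (length(over)) stop("record ", over[1], ": interval end ", x$end[over[1]],
                         " beyond length of ", x$chrom[over[1]])
  invisible(x)
}
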