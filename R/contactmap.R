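#' Sparse contact map over a bin table
#'
#' Stores nonzero bin-pair counts with `bin1 <= bin2` (global ids); cis maps
#' are symmetric by construction, with only the upper triangle stored.
#'
#' @param bins A [make_bin_table()] bin table.
#' @param pixels `data.frame` with columns `bin1`, `bin2`, `count`.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(bins, pixels) {
  px <- data.table::as.data.table(pixels)[, .(bin1 = as.integer(bin1),
                                              bin2 = as.integer(bin2),
                                              count = as.numeric(count))]
  if (nrow(px)) {
    swap <- px$bin1 > px$bin2
    if (any(swap)) px[swap, c("bin1", "bin2") := .(bin2, bin1)]
    px <- px[, .(count = sum(count)), by = .(bin1, bin2)]
    if (any(px$bin1 < 0L) || any(px$bin2 >= nrow(bins))) stop("pixel bin id outside bin table")
  }
  data.table::setkey(px, bin1, bin2)
  structure(list(bins = bins, pixels = px), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d bins (bin size %s bp), %d nonzero pixels, total count %.4g\n",
              nrow(x$bins), format(bin_size_of(x$bins), big.mark = ","),
              nrow(x$pixels), sum(x$pixels$count)))
  invisible(x)
}

#' Dense symmetric cis matrix for one chromosome
#'
#' @param map A [contact_map()].
#' @param chrom Chromosome name.
#' @return A dense symmetric matrix whose rows/columns follow the
#'   chromosome's bins in order.
#' @export
cis_matrix <- function(map, chrom) {
  ch_query <- chrom
  off <- chrom_offsets(map$bins)[data.table::data.table(chrom = ch_query)]
  if (is.na(off$offset)) stop("unknown chromosome: ", ch_query)
  n <- off$n
  px <- map$pixels[bin1 >= off$offset & bin1 < off$offset + n &
                   bin2 >= off$offset & bin2 < off$offset + n]
  m <- matrix(0, n, n)
  if (nrow(px)) {
    i <- px$bin1 - off$offset + 1L
    j <- px$bin2 - off$offset + 1L
    m[cbind(i, j)] <- px$count
    m[cbind(j, i)] <- px$count
  }
  m
}

#' Dense rectangular trans matrix for a chromosome pair
#'
#' Rows follow `chrom1`'s bins, columns `chrom2`'s, regardless of the order
#' in which the pair was stored.
#' @param map A [contact_map()].
#' @param chrom1,chrom2 Distinct chromosome names.
#' @export
trans_matrix <- function(map, chrom1, chrom2) {
  if (chrom1 == chrom2) stop("trans_matrix needs two distinct chromosomes")
  offs <- chrom_offsets(map$bins)
  o1 <- offs[data.table::data.table(chrom = chrom1)]
  o2 <- offs[data.table::data.table(chrom = chrom2)]
  if (is.na(o1$offset) || is.na(o2$offset)) stop("unknown chromosome")
  in1 <- function(b) b >= o1$offset & b < o1$offset + o1$n
  in2 <- function(b) b >= o2$offset & b < o2$offset + o2$n
  px <- map$pixels[(in1(bin1) & in2(bin2)) | (in2(bin1) & in1(bin2))]
  m <- matrix(0, o1$n, o2$n)
  if (nrow(px)) {
    flip <- in2(px$bin1)
    r <- ifelse(flip, px$bin2, px$bin1) - o1$offset + 1L
    c <- ifelse(flip, px$bin1, px$bin2) - o2$offset + 1L
    m[cbind(r, c)] <- px$count
  }
  m
}

#' Build a contact map from a dense cis matrix
#' @keywords internal
map_from_cis_matrices <- function(bins, mats) {
  offs <- chrom_offsets(bins)
  px <- data.table::rbindlist(lapply(names(mats), function(ch) {
    m <- mats[[ch]]
    o <- offs[data.table::data.table(chrom = ch)]$offset
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    data.table::data.table(bin1 = o + idx[, 1] - 1L, bin2 = o + idx[, 2] - 1L,
                           count = m[idx])
  }))
  contact_map(bins, px)
}

#' Total count in a map, optionally trans-only
#' @keywords internal
total_count <- function(map, trans_only = FALSE) {
  if (!nrow(map$pixels)) return(0)
  if (!trans_only) return(sum(map$pixels$count))
  ch <- map$bins$chrom[map$pixels$bin1 + 1L] != map$bins$chrom[map$pixels$bin2 + 1L]
  sum(map$pixels$count[ch])
}
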