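#' Read a genome layout from a chrom-sizes file
#'
#' @param path Two-column TSV (chromosome, length).
#' @param centromeres_path Optional BED3 of centromere intervals.
#' @return A [genome_layout()].
#' @export
read_layout <- function(path, centromeres_path = NULL) {
  cs <- data.table::fread(path, header = FALSE, col.names = c("chrom", "length"))
  cen <- if (!is.null(centromeres_path)) read_bed(centromeres_path) else NULL
  genome_layout(cs$chrom, cs$length, centromeres = cen)
}

#' @rdname read_layout
#' @param layout A [genome_layout()] to write.
#' @export
write_layout <- function(layout, path, centromeres_path = NULL) {
  data.table::fwrite(data.table::data.table(chrom = layout$chroms,
                                            length = layout$lengths),
                     path, sep = "\t", col.names = FALSE)
  if (!is.null(centromeres_path) && !is.null(layout$centromeres))
    write_bed(layout$centromeres, centromeres_path)
  invisible(path)
}

#' Read / write sparse contact maps as bin-pair triplet TSV
#'
#' The on-disk format is a header line `# bin_size=<bp> assembly=<name>`
#' followed by tab-separated records `chrom1 start1 chrom2 start2 count`.
#' Cis records may appear in either orientation; symmetry is enforced on
#' read (upper triangle stored).
#'
#' @param path File path.
#' @param bins Bin table the records must align to.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, bins) {
  first <- readLines(path, n = 1)
  has_header <- startsWith(first, "#")
  if (has_header) {
    m <- regmatches(first, regexec("bin_size=([0-9]+)", first))[[1]]
    if (length(m) == 2 && as.numeric(m[2]) != bin_size_of(bins))
      stop("file bin size ", m[2], " does not match bin table (", bin_size_of(bins), ")")
  }
  dt <- data.table::fread(path, skip = as.integer(has_header), header = FALSE,
                          col.names = c("chrom1", "start1", "chrom2", "start2", "count"))
  lineno <- function(i) i + as.integer(has_header)
  layout <- layout_of(bins)
  for (side in c(1, 2)) {
    ch <- dt[[paste0("chrom", side)]]
    st <- dt[[paste0("start", side)]]
    bad <- which(!(ch %in% layout$chroms))
    if (length(bad)) stop("line ", lineno(bad[1]), ": unknown chromosome '", ch[bad[1]], "'")
    off <- which(st %% bin_size_of(bins) != 0 | st < 0 | st >= layout$lengths[ch])
    if (length(off)) stop("line ", lineno(off[1]), ": coordinate ", st[off[1]],
                          " not on the ", bin_size_of(bins), "-bp bin grid")
  }
  contact_map(bins, data.table::data.table(
    bin1 = bin_id_at(bins, dt$chrom1, dt$start1),
    bin2 = bin_id_at(bins, dt$chrom2, dt$start2),
    count = dt$count))
}

#' @rdname read_contacts
#' @param map A [contact_map()] to write.
#' @param assembly Assembly name recorded in the header.
#' @export
write_contacts <- function(map, path, assembly = "synthetic") {
  bins <- map$bins
  px <- map$pixels
  out <- data.table::data.table(chrom1 = bins$chrom[px$bin1 + 1L],
                                start1 = bins$start[px$bin1 + 1L],
                                chrom2 = bins$chrom[px$bin2 + 1L],
                                start2 = bins$start[px$bin2 + 1L],
                                count = px$count)
  writeLines(sprintf("# bin_size=%d assembly=%s", as.integer(bin_size_of(bins)), assembly), path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

read_tabular <- function(path, col.names, numeric_cols, layout = NULL) {
  dt <- tryCatch(data.table::fread(path, header = FALSE, fill = FALSE),
                 error = function(e) stop("malformed file ", path, ": ", conditionMessage(e)))
  if (ncol(dt) < length(col.names))
    stop("line 1: expected >= ", length(col.names), " columns, found ", ncol(dt))
  dt <- dt[, seq_along(col.names), with = FALSE]
  data.table::setnames(dt, col.names)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) & !is.na(dt[[cc]]))
    if (length(bad)) stop("line ", bad[1], ": non-numeric value '", dt[[cc]][bad[1]], "' in column ", cc)
    data.table::set(dt, j = cc, value = v)
  }
  if (!is.null(layout)) {
    dt2 <- data.table::copy(dt)
    ok <- tryCatch({ validate_intervals(dt2, layout); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) stop(conditionMessage(ok))
  }
  dt
}

#' Read / write bedGraph tracks
#'
#' 0-based half-open intervals with a numeric value column.
#' @param path File path.
#' @param layout Optional [genome_layout()] for validation.
#' @return `data.table` with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, layout = NULL) {
  read_tabular(path, c("chrom", "start", "end", "value"),
               c("start", "end", "value"), layout)
}

#' @rdname read_bedgraph
#' @param x Track `data.frame` to write.
#' @export
write_bedgraph <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x)[, .(chrom, start, end, value)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write BED3 / BED6 interval files
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] for validation.
#' @return `data.table` with `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path, layout = NULL) {
  dt <- tryCatch(data.table::fread(path, header = FALSE, fill = FALSE),
                 error = function(e) stop("malformed file ", path, ": ", conditionMessage(e)))
  if (ncol(dt) < 3) stop("line 1: BED needs >= 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol(dt), 6))]
  dt <- dt[, seq_along(nm), with = FALSE]
  data.table::setnames(dt, nm)
  for (cc in intersect(c("start", "end"), nm)) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v))
    if (length(bad)) stop("line ", bad[1], ": non-numeric ", cc)
    data.table::set(dt, j = cc, value = v)
  }
  if ("strand" %in% nm) {
    bad <- which(!(dt$strand %in% c("+", "-", ".")))
    if (length(bad)) stop("line ", bad[1], ": invalid strand '", dt$strand[bad[1]], "'")
  }
  if (!is.null(layout)) validate_intervals(dt, layout)
  dt
}

#' @rdname read_bed
#' @param x Interval `data.frame` to write; columns beyond `chrom`, `start`,
#'   `end` are written in BED6 order when present.
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  full <- c("chrom", "start", "end", "name", "score", "strand")
  # BED columns are positional: write the longest present prefix
  miss <- which(!(full %in% names(x)))
  keep <- if (length(miss)) full[seq_len(miss[1] - 1)] else full
  if (length(keep) < 3) stop("need chrom/start/end to write BED")
  data.table::fwrite(x[, keep, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene annotations (BED6 with mandatory strand)
#'
#' @inheritParams read_bed
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`; strand must be `+` or `-`.
#' @export
read_genes <- function(path, layout = NULL) {
  g <- read_bed(path, layout)
  if (!"strand" %in% names(g)) stop("gene BED must have 6 columns including strand")
  bad <- which(!(g$strand %in% c("+", "-")))
  if (length(bad)) stop("line ", bad[1], ": gene without +/- strand")
  g
}
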