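#' Reference genomes and bin tables
#'
#' A *reference* is an ordered set of chromosomes with lengths; a *bin table*
#' partitions each chromosome into fixed-size bins and assigns global,
#' 0-based bin ids chromosome by chromosome in reference order. All
#' coordinates in this package are 0-based, half-open.
#'
#' @name reference
NULL

#' Create a reference from chromosome names and lengths
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Positive integer vector of chromosome lengths in bp.
#' @return A `hic_reference`: a data.frame with columns `name` and `length`,
#'   row order authoritative.
#' @export
hic_reference <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) stop("reference must contain at least one chromosome")
  if (length(names) != length(lengths)) stop("names and lengths differ in length")
  if (anyDuplicated(names)) stop("duplicate chromosome names: ",
                                 paste(unique(names[duplicated(names)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0) || any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  structure(data.frame(name = names, length = lengths, stringsAsFactors = FALSE),
            class = c("hic_reference", "data.frame"))
}

#' Read a two-column chromosome-sizes file
#'
#' Tab-separated `name<TAB>length` lines; line order defines chromosome order.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [hic_reference()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("name", "length"))
  hic_reference(df$name, df$length)
}

#' Write a reference as a chromosome-sizes file
#' @param reference A [hic_reference()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(reference, path) {
  writeLines(sprintf("%s\t%d", reference$name, as.integer(reference$length)), path)
  invisible(path)
}

#' @export
print.hic_reference <- function(x, ...) {
  cat(sprintf("<reference: %d chromosomes, %.0f bp>\n", nrow(x), sum(x$length)))
  NextMethod()
}

same_reference <- function(a, b) {
  identical(a$name, b$name) && isTRUE(all.equal(a$length, b$length))
}

#' Build a fixed-width bin table over a reference
#'
#' Each chromosome is split into `ceiling(length / bin_size)` bins; the last
#' bin of a chromosome may be truncated. Global bin ids are 0-based and
#' assigned chromosome by chromosome in reference order.
#'
#' @param reference A [hic_reference()].
#' @param bin_size Bin width (resolution) in bp.
#' @return A `bin_table` object.
#' @export
bin_table <- function(reference, bin_size) {
  stopifnot(inherits(reference, "hic_reference"))
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0 ||
      bin_size != floor(bin_size))
    stop("bin_size must be a positive integer")
  nb <- ceiling(reference$length / bin_size)
  offsets <- c(0, cumsum(nb))     # chrom_offset, length nchrom + 1
  structure(list(reference = reference,
                 bin_size  = bin_size,
                 chrom_bins = nb,
                 offsets   = offsets,
                 n_bins    = offsets[length(offsets)]),
            class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin table: %d chromosomes, bin size %.0f bp, %d bins>\n",
              nrow(x$reference), x$bin_size, x$n_bins))
  invisible(x)
}

same_bin_table <- function(a, b) {
  a$bin_size == b$bin_size && same_reference(a$reference, b$reference)
}

chrom_index <- function(table_or_ref, chrom) {
  ref <- if (inherits(table_or_ref, "bin_table")) table_or_ref$reference else table_or_ref
  i <- match(chrom, ref$name)
  if (anyNA(i))
    stop("unknown chromosome(s): ", paste(chrom[is.na(i)], collapse = ", "),
         " (reference has: ", paste(utils::head(ref$name, 10), collapse = ", "), ")")
  i
}

#' Enumerate the bins of a bin table
#'
#' @param table A [bin_table()].
#' @return data.frame with `bin_id`, `chrom`, `start`, `end` for every bin.
#' @export
bins_df <- function(table) {
  ref <- table$reference
  chrom <- rep(ref$name, table$chrom_bins)
  local <- unlist(lapply(table$chrom_bins, function(n) seq_len(n) - 1), use.names = FALSE)
  start <- local * table$bin_size
  end <- pmin(start + table$bin_size, rep(ref$length, table$chrom_bins))
  data.frame(bin_id = seq_len(table$n_bins) - 1L, chrom = chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Map genomic positions to global bin ids
#'
#' @param table A [bin_table()].
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based position(s) in bp; must satisfy `pos < length(chrom)`.
#' @return Global 0-based bin id(s).
#' @export
pos_to_bin <- function(table, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.numeric(pos), n)
  ci <- chrom_index(table, chrom)
  bad <- pos < 0 | pos >= table$reference$length[ci]
  if (any(bad))
    stop(sprintf("position %.0f out of range for %s (length %.0f)",
                 pos[bad][1], chrom[bad][1], table$reference$length[ci][bad][1]))
  table$offsets[ci] + floor(pos / table$bin_size)
}

#' Map global bin ids back to genomic intervals
#'
#' Inverse of [pos_to_bin()] on bin starts; the end of a chromosome's last
#' bin is clipped to the chromosome length.
#'
#' @param table A [bin_table()].
#' @param bin_id Global 0-based bin id(s).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
bin_to_interval <- function(table, bin_id) {
  bin_id <- as.numeric(bin_id)
  if (any(bin_id < 0 | bin_id >= table$n_bins | bin_id != floor(bin_id)))
    stop("bin id out of range [0, ", table$n_bins, ")")
  ci <- findInterval(bin_id, table$offsets, left.open = FALSE)  # 1-based chrom index
  local <- bin_id - table$offsets[ci]
  start <- local * table$bin_size
  data.frame(chrom = table$reference$name[ci], start = start,
             end = pmin(start + table$bin_size, table$reference$length[ci]),
             stringsAsFactors = FALSE)
}

#' Genomic ranges
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds in bp.
#' @return A `genomic_range` list.
#' @export
genomic_range <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop(sprintf("invalid interval [%s, %s) on %s", format(start), format(end), chrom))
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_range")
}

#' @export
print.genomic_range <- function(x, ...) {
  cat(format_region(x), "\n"); invisible(x)
}

#' Parse a UCSC-style region string
#'
#' Accepts `chrom`, `chrom:start-end` with optional thousands separators
#' (commas, underscores, spaces) and en-dash. Coordinates are taken literally
#' as 0-based half-open; a bare chromosome name means the whole chromosome;
#' `end` is clamped to the chromosome length.
#'
#' @param text Region string, e.g. `"chr1:0-10,000,000"`.
#' @param reference A [hic_reference()].
#' @return A [genomic_range()].
#' @export
parse_region <- function(text, reference) {
  stopifnot(inherits(reference, "hic_reference"))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty region string")
  if (!grepl(":", text, fixed = TRUE)) {
    i <- chrom_index(reference, text)
    return(genomic_range(text, 0, reference$length[i]))
  }
  chrom <- sub(":[^:]*$", "", text)
  coords <- sub(".*:", "", text)
  coords <- gsub("[,_  ]", "", coords)
  coords <- gsub("–", "-", coords)  # en dash
  m <- regmatches(coords, regexec("^([0-9]+)-([0-9]+)$", coords))[[1]]
  if (length(m) != 3L) stop("malformed region string: ", text)
  i <- chrom_index(reference, chrom)
  start <- as.numeric(m[2]); end <- min(as.numeric(m[3]), reference$length[i])
  if (start >= end) stop("empty or inverted interval after clamping in: ", text)
  genomic_range(chrom, start, end)
}

#' Format a genomic range as a region string
#' @param range A [genomic_range()].
#' @return `"chrom:start-end"`.
#' @export
format_region <- function(range) {
  sprintf("%s:%.0f-%.0f", range$chrom, range$start, range$end)
}

#' Smallest bin-id span covering a genomic range
#'
#' @param table A [bin_table()].
#' @param range A [genomic_range()].
#' @return Numeric `c(first, last)`: half-open global bin-id span covering
#'   every bin that overlaps `range`.
#' @export
range_to_bin_span <- function(table, range) {
  i <- chrom_index(table, range$chrom)
  L <- table$reference$length[i]
  if (range$start >= L) stop("range start beyond chromosome end")
  off <- table$offsets[i]
  first <- off + floor(range$start / table$bin_size)
  last <- off + ceiling(min(range$end, L) / table$bin_size)
  c(first, last)
}
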