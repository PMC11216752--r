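#' Text interchange formats: 4DN pairs, bedGraph2 and COO
#'
#' 4DN pairs files are headered (`## pairs format v1.0`) and list read-pair
#' endpoints; bedGraph2 is the 7-column `chrom1 start1 end1 chrom2 start2
#' end2 count` record; COO is the bare `bin1_id bin2_id count` triplet.
#' All three are tab-separated and may be gzip-compressed on input. Pairs
#' positions are treated as 0-based unless `one_based = TRUE` (the 4DN
#' ecosystem contains both conventions); strand columns are accepted and
#' ignored.
#'
#' @name text_io
NULL

read_text_lines <- function(source) {
  if (length(source) == 1L && !grepl("[\n\t]", source) && file.exists(source)) {
    con <- file(source, "r")   # file() transparently decompresses gzip
    on.exit(close(con))
    return(readLines(con))
  }
  unlist(strsplit(source, "\n", fixed = TRUE))
}

PAIRS_DEFAULT_COLUMNS <- c("readID", "chrom1", "pos1", "chrom2", "pos2",
                           "strand1", "strand2")

#' Parse a 4DN pairs file
#'
#' The header must begin `## pairs format v1.0`; `#chromsize:` lines
#' define the reference when none is supplied; a `#columns:` line remaps
#' body columns (default `readID chrom1 pos1 chrom2 pos2 strand1
#' strand2`). Records naming chromosomes absent from the reference are
#' rejected with their 1-based line number.
#'
#' @param source Path (optionally .gz) or character vector of lines.
#' @param reference Optional [hic_reference()] overriding header chromsizes.
#' @param one_based Set TRUE for producers emitting 1-based positions.
#' @return list with `reference` and `records` (data.frame `chrom1, pos1,
#'   chrom2, pos2, strand1, strand2, readID`).
#' @export
parse_pairs <- function(source, reference = NULL, one_based = FALSE) {
  lines <- read_text_lines(source)
  if (length(lines) == 0L || !startsWith(lines[1], "## pairs format v1.0"))
    stop("missing 4DN pairs header ('## pairs format v1.0')")
  hdr <- grepl("^#", lines)
  header <- lines[hdr]
  body_idx <- which(!hdr & nzchar(lines))
  cs <- header[startsWith(header, "#chromsize:")]
  if (is.null(reference)) {
    if (length(cs) == 0L)
      stop("no reference: supply one or include #chromsize: header lines")
    parts <- strsplit(trimws(sub("^#chromsize:", "", cs)), "[ \t]+")
    reference <- hic_reference(vapply(parts, `[`, "", 1),
                               as.numeric(vapply(parts, `[`, "", 2)))
  }
  cols <- PAIRS_DEFAULT_COLUMNS
  cl <- header[startsWith(header, "#columns:")]
  if (length(cl)) cols <- strsplit(trimws(sub("^#columns:", "", cl[1])), "[ \t]+")[[1]]
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% cols))
    stop("#columns: header lacks required fields: ",
         paste(setdiff(need, cols), collapse = ", "))
  if (length(body_idx) == 0L)
    return(list(reference = reference,
                records = data.frame(chrom1 = character(), pos1 = numeric(),
                                     chrom2 = character(), pos2 = numeric(),
                                     strand1 = character(), strand2 = character(),
                                     readID = character())))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < length(need))) {
    bad <- body_idx[nf < length(need)][1]
    stop("malformed pairs record at line ", bad, ": ", lines[bad])
  }
  getcol <- function(nm, default = NA_character_) {
    i <- match(nm, cols)
    if (is.na(i)) return(rep(default, length(fields)))
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  rec <- data.frame(chrom1 = getcol("chrom1"), pos1 = as.numeric(getcol("pos1")),
                    chrom2 = getcol("chrom2"), pos2 = as.numeric(getcol("pos2")),
                    strand1 = getcol("strand1", "."), strand2 = getcol("strand2", "."),
                    readID = getcol("readID", "."), stringsAsFactors = FALSE)
  if (one_based) { rec$pos1 <- rec$pos1 - 1; rec$pos2 <- rec$pos2 - 1 }
  for (side in c(1, 2)) {
    ch <- rec[[paste0("chrom", side)]]
    unknown <- !(ch %in% reference$name)
    if (any(unknown))
      stop("unknown chromosome '", ch[unknown][0 + 1], "' at line ",
           body_idx[unknown][1])
    L <- reference$length[match(ch, reference$name)]
    pos <- rec[[paste0("pos", side)]]
    bad <- is.na(pos) | pos < 0 | pos >= L
    if (any(bad))
      stop("position out of range at line ", body_idx[bad][1])
  }
  list(reference = reference, records = rec)
}

#' Write pair records as a 4DN pairs file
#' @param records data.frame as returned by [parse_pairs()].
#' @param reference A [hic_reference()] (emitted as `#chromsize:` lines).
#' @param path Output path, or NULL to return the lines.
#' @export
format_pairs <- function(records, reference, path = NULL) {
  hdr <- c("## pairs format v1.0",
           sprintf("#chromsize: %s %d", reference$name, as.integer(reference$length)),
           paste("#columns:", paste(PAIRS_DEFAULT_COLUMNS, collapse = " ")))
  body <- if (nrow(records)) sprintf("%s\t%s\t%.0f\t%s\t%.0f\t%s\t%s",
    records$readID, records$chrom1, records$pos1, records$chrom2, records$pos2,
    records$strand1, records$strand2) else character()
  lines <- c(hdr, body)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Bin pair records into unit-count pixels
#'
#' Each record becomes one upper-triangle pixel of count 1 (ids swapped
#' when the second end maps to an earlier bin).
#'
#' @param records Pairs data.frame ([parse_pairs()] `$records`).
#' @param table A [bin_table()].
#' @return Pixel data.frame (unsorted, unaggregated; one row per record).
#' @export
pairs_to_pixels <- function(records, table) {
  if (nrow(records) == 0L) return(empty_pixels())
  b1 <- pos_to_bin(table, records$chrom1, records$pos1)
  b2 <- pos_to_bin(table, records$chrom2, records$pos2)
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  data.frame(bin1_id = b1, bin2_id = b2, count = rep(1L, length(b1)))
}

#' Parse bedGraph2 or COO interaction text into pixels
#'
#' bedGraph2 intervals must coincide exactly with bins of `table`; COO ids
#' must be in range. Counts parse as integers unless any real value is
#' seen, in which case the whole stream is real. Pixels are canonicalized
#' to the upper triangle. Every error carries a 1-based line number.
#'
#' @param source Path (optionally .gz) or character vector of lines.
#' @param dialect `"bg2"` or `"coo"`.
#' @param table A [bin_table()].
#' @return Pixel data.frame (unsorted, unaggregated).
#' @export
parse_interaction_text <- function(source, dialect = c("bg2", "coo"), table) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(source)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_pixels())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (dialect == "bg2") 7L else 3L
  short <- lengths(fields) < want
  if (any(short))
    stop(dialect, " record with fewer than ", want, " columns at line ",
         lineno[short][1])
  cnt_txt <- vapply(fields, `[`, "", want)
  cnt <- suppressWarnings(as.numeric(cnt_txt))
  if (anyNA(cnt)) stop("non-numeric count at line ", lineno[is.na(cnt)][1])
  integral <- all(grepl("^-?[0-9]+$", cnt_txt))
  if (dialect == "coo") {
    b1 <- as.numeric(vapply(fields, `[`, "", 1))
    b2 <- as.numeric(vapply(fields, `[`, "", 2))
    bad <- is.na(b1) | is.na(b2) | b1 < 0 | b2 < 0 |
      b1 >= table$n_bins | b2 >= table$n_bins | b1 != floor(b1) | b2 != floor(b2)
    if (any(bad)) stop("bin id out of range at line ", lineno[bad][1])
  } else {
    get <- function(i) vapply(fields, `[`, "", i)
    ch1 <- get(1); s1 <- as.numeric(get(2)); e1 <- as.numeric(get(3))
    ch2 <- get(4); s2 <- as.numeric(get(5)); e2 <- as.numeric(get(6))
    for (side in 1:2) {
      ch <- if (side == 1) ch1 else ch2
      unknown <- !(ch %in% table$reference$name)
      if (any(unknown))
        stop("unknown chromosome '", ch[unknown][1], "' at line ", lineno[unknown][1])
    }
    b1 <- pos_to_bin(table, ch1, s1)
    b2 <- pos_to_bin(table, ch2, s2)
    iv1 <- bin_to_interval(table, b1); iv2 <- bin_to_interval(table, b2)
    mis <- iv1$start != s1 | iv1$end != e1 | iv2$start != s2 | iv2$end != e2
    if (any(mis))
      stop("interval not aligned to the ", format(table$bin_size),
           " bp bin grid at line ", lineno[mis][1])
  }
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  data.frame(bin1_id = b1, bin2_id = b2,
             count = if (integral) as.integer(cnt) else cnt)
}

fmt_count <- function(count) {
  # integers bare; reals with shortest round-trip decimal representation
  if (is.integer(count) || all(count == floor(count)))
    sprintf("%.0f", count)
  else
    vapply(count, function(x) format(x, digits = 17, scientific = FALSE,
                                     trim = TRUE, drop0trailing = TRUE), "")
}

#' Format pixels as bedGraph2 or COO text lines
#'
#' @param px Sorted pixel data.frame.
#' @param dialect `"bg2"` (joined via [bin_to_interval()]) or `"coo"`.
#' @param table A [bin_table()] (required for bg2).
#' @return Character vector of tab-separated lines.
#' @export
format_pixels <- function(px, dialect = c("bg2", "coo"), table = NULL) {
  dialect <- match.arg(dialect)
  if (nrow(px) == 0L) return(character())
  cnt <- fmt_count(px$count)
  if (dialect == "coo")
    return(sprintf("%.0f\t%.0f\t%s", px$bin1_id, px$bin2_id, cnt))
  stopifnot(!is.null(table))
  j <- join_pixels(px, table)
  sprintf("%s\t%.0f\t%.0f\t%s\t%.0f\t%.0f\t%s",
          j$chrom1, j$start1, j$end1, j$chrom2, j$start2, j$end2, cnt)
}
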