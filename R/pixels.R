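#' Sparse pixels, normalization weights and expected profiles
#'
#' A *pixel* is one nonzero entry (bin1_id, bin2_id, count) of the
#' upper-triangular sparse contact matrix; the universal interchange record
#' of this package is a data.frame of such pixels sorted by (bin1_id,
#' bin2_id).
#'
#' @name pixels
NULL

#' Construct and validate a pixel table
#'
#' @param bin1_id,bin2_id Global 0-based bin ids with `bin1_id <= bin2_id`.
#' @param count Interaction counts (integer or real), nonzero.
#' @param table Optional [bin_table()] to bound-check ids against.
#' @return data.frame with columns `bin1_id`, `bin2_id`, `count`.
#' @export
thin_pixels <- function(bin1_id = numeric(), bin2_id = numeric(),
                        count = numeric(), table = NULL) {
  df <- data.frame(bin1_id = as.numeric(bin1_id), bin2_id = as.numeric(bin2_id),
                   count = count)
  validate_pixels(df, table)
  df
}

validate_pixels <- function(px, table = NULL, require_sorted = FALSE) {
  if (nrow(px) == 0L) return(invisible(px))
  if (any(px$bin1_id > px$bin2_id))
    stop("lower-triangle pixel: bin1_id > bin2_id at row ",
         which(px$bin1_id > px$bin2_id)[1])
  if (any(px$bin1_id < 0)) stop("negative bin id")
  if (!is.null(table) && any(px$bin2_id >= table$n_bins))
    stop("bin id out of range [0, ", table$n_bins, ")")
  if (require_sorted && !pixels_sorted(px))
    stop("pixel table not sorted by (bin1_id, bin2_id) or contains duplicates")
  invisible(px)
}

pixels_sorted <- function(px, strict = TRUE) {
  if (nrow(px) < 2L) return(TRUE)
  d1 <- diff(px$bin1_id); d2 <- diff(px$bin2_id)
  if (strict) all(d1 > 0 | (d1 == 0 & d2 > 0)) else all(d1 > 0 | (d1 == 0 & d2 >= 0))
}

#' Sort a pixel table and sum duplicate (bin1, bin2) keys
#'
#' @param px Pixel data.frame.
#' @return Sorted, duplicate-free pixel data.frame (zero-count rows kept:
#'   aggregation never drops keys).
#' @export
aggregate_pixels <- function(px) {
  if (nrow(px) == 0L) return(px[, c("bin1_id", "bin2_id", "count")])
  dt <- data.table::as.data.table(px[, c("bin1_id", "bin2_id", "count")])
  out <- dt[, list(count = sum(count)), keyby = c("bin1_id", "bin2_id")]
  as.data.frame(out)
}

empty_pixels <- function(real = FALSE) {
  data.frame(bin1_id = numeric(), bin2_id = numeric(),
             count = if (real) numeric() else integer())
}

#' Attach bin intervals to pixels (bedGraph2 layout)
#'
#' @param px Pixel data.frame.
#' @param table A [bin_table()].
#' @return data.frame `chrom1,start1,end1,chrom2,start2,end2,count`.
#' @export
join_pixels <- function(px, table) {
  i1 <- bin_to_interval(table, px$bin1_id)
  i2 <- bin_to_interval(table, px$bin2_id)
  data.frame(chrom1 = i1$chrom, start1 = i1$start, end1 = i1$end,
             chrom2 = i2$chrom, start2 = i2$start, end2 = i2$end,
             count = px$count, stringsAsFactors = FALSE)
}

#' Per-bin normalization weights
#'
#' Cooler-style balancing vectors are *multiplicative* (balanced count =
#' count * w1 * w2); .hic-style vectors (VC, VC_SQRT, KR, SCALE) are
#' *divisive* (balanced count = count / (w1 * w2)). Masked bins carry NaN.
#'
#' @param values One real per bin; NaN marks masked bins.
#' @param kind `"multiplicative"` or `"divisive"`.
#' @param name Public vector name (e.g. `"weight"`, `"KR"`).
#' @return A `norm_weights` object.
#' @export
norm_weights <- function(values, kind = c("multiplicative", "divisive"),
                         name = "weight") {
  kind <- match.arg(kind)
  structure(list(values = as.numeric(values), kind = kind, name = name),
            class = "norm_weights")
}

#' @export
print.norm_weights <- function(x, ...) {
  cat(sprintf("<norm weights '%s': %s, %d bins, %d masked>\n", x$name, x$kind,
              length(x$values), sum(!is.finite(x$values))))
  invisible(x)
}

#' Apply a normalization vector to pixel counts
#'
#' @param px Pixel data.frame.
#' @param weights A [norm_weights()]; length must equal the bin-table size.
#' @param table Optional [bin_table()] for the length check.
#' @return Numeric vector of normalized counts; NaN where a masked bin is
#'   involved.
#' @export
apply_norm <- function(px, weights, table = NULL) {
  stopifnot(inherits(weights, "norm_weights"))
  if (!is.null(table) && length(weights$values) != table$n_bins)
    stop("weight vector length ", length(weights$values),
         " does not match bin table (", table$n_bins, " bins)")
  if (nrow(px) > 0 && max(px$bin2_id) >= length(weights$values))
    stop("pixel bin id exceeds weight vector length")
  w1 <- weights$values[px$bin1_id + 1]
  w2 <- weights$values[px$bin2_id + 1]
  if (weights$kind == "multiplicative") px$count * w1 * w2 else px$count / (w1 * w2)
}

#' Expected contact counts by genomic distance
#'
#' @param values Expected count per distance d = 0..D-1 (in bins), applying
#'   to intra-chromosomal pixels; distances beyond D-1 clamp to the last
#'   entry.
#' @param scale Named positive scale factor per chromosome.
#' @param resolution Bin size in bp the profile was computed at.
#' @return An `expected_profile` object.
#' @export
expected_profile <- function(values, scale, resolution) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("expected profile must have at least one value")
  if (any(values < 0, na.rm = TRUE)) stop("expected values must be non-negative")
  if (is.null(names(scale))) stop("scale must be a named (by chromosome) vector")
  sc <- as.numeric(scale)
  names(sc) <- names(scale)
  structure(list(values = values, scale = sc, resolution = as.numeric(resolution)),
            class = "expected_profile")
}

#' @export
print.expected_profile <- function(x, ...) {
  cat(sprintf("<expected profile: %d distances at %.0f bp, %d chromosome scale factors>\n",
              length(x$values), x$resolution, length(x$scale)))
  invisible(x)
}

#' Observed/expected transform of intra-chromosomal pixel counts
#'
#' Divides each count by `values[d] * scale[chrom]` where d is the
#' chromosome-local bin distance `bin2_id - bin1_id`.
#'
#' @param px Pixel data.frame (intra-chromosomal only).
#' @param table A [bin_table()].
#' @param profile An [expected_profile()].
#' @return Numeric vector of O/E counts.
#' @export
oe_transform <- function(px, table, profile) {
  stopifnot(inherits(profile, "expected_profile"))
  if (nrow(px) == 0L) return(numeric())
  ci1 <- findInterval(px$bin1_id, table$offsets, left.open = FALSE)
  ci2 <- findInterval(px$bin2_id, table$offsets, left.open = FALSE)
  if (any(ci1 != ci2))
    stop("observed/expected is defined for intra-chromosomal pixels only")
  d <- px$bin2_id - px$bin1_id
  d <- pmin(d, length(profile$values) - 1)          # clamp to last entry
  e <- profile$values[d + 1]
  sc <- profile$scale[table$reference$name[ci1]]
  if (anyNA(sc)) stop("expected profile lacks scale factor for chromosome ",
                      table$reference$name[ci1][is.na(sc)][1])
  denom <- e * as.numeric(sc)
  if (any(denom == 0)) stop("zero expected value at distance ", d[denom == 0][1])
  px$count / denom
}
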