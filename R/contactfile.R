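#' Uniform query interface over Cooler and .hic backends
#'
#' [open_contacts()] auto-detects the on-disk format by file signature and
#' returns a `contact_file` whose public behavior is identical for both
#' backends. [fetch()] answers 2-D genomic range queries with a lazy
#' `pixel_selector` supporting raw, balanced, expected and
#' observed/expected counts and sparse or dense materialization.
#'
#' @name query_engine
NULL

sniff_format <- function(path) {
  sig <- readBin(path, raw(), n = 4L)
  if (length(sig) >= 4L && identical(sig, c(as.raw(0x89), charToRaw("HDF"))))
    return("hdf5")
  if (length(sig) >= 4L && identical(sig, c(charToRaw("HIC"), as.raw(0L))))
    return("hic")
  "unknown"
}

#' Open a contact matrix file of either family
#'
#' @param uri Path to a `.cool`, `.mcool`, `.scool` (with `::/cells/<name>`)
#'   or `.hic` file; Cooler group URIs (`path::/group`) are honored.
#' @param resolution Bin size in bp; required for `.mcool` and `.hic`
#'   (unless the `.hic` stores a single resolution), ignored with a
#'   warning for `.cool`.
#' @return A `contact_file`.
#' @export
open_contacts <- function(uri, resolution = NULL) {
  loc <- cooler_parse_uri(uri)
  if (!file.exists(loc$path)) stop("no such file: ", loc$path)
  kind <- sniff_format(loc$path)
  if (kind == "unknown")
    stop(loc$path, " is not a contact file (neither HDF5 nor .hic signature)")
  if (kind == "hic") {
    hdr <- parse_hic_header(readBin(loc$path, raw(), n = file.size(loc$path)))
    if (is.null(resolution)) {
      if (length(hdr$resolutions) != 1L)
        stop(".hic file stores several resolutions (",
             paste(hdr$resolutions, collapse = ", "), "); pick one")
      resolution <- hdr$resolutions[1]
    }
    h <- open_hic(loc$path, resolution)
    return(structure(list(backend = "hic", handle = h, table = h$table,
                          path = loc$path, uri = uri,
                          resolution = h$resolution,
                          norms = h$norm_names,
                          cache = new.env(parent = emptyenv())),
                     class = "contact_file"))
  }
  target <- uri
  if (loc$group == "/") {
    attrs <- rhdf5::h5readAttributes(loc$path, "/")
    fmt <- if (is.null(attrs$format)) "" else as.character(attrs$format)
    if (fmt == MCOOL_FORMAT || h5_group_exists(loc$path, "/resolutions")) {
      avail <- mcool_resolutions(loc$path)
      if (is.null(resolution))
        stop(".mcool requires a resolution; available: ",
             paste(avail, collapse = ", "))
      if (!resolution %in% avail)
        stop("resolution ", resolution, " not stored; available: ",
             paste(avail, collapse = ", "))
      target <- sprintf("%s::/resolutions/%.0f", loc$path, resolution)
    } else if (fmt == SCOOL_FORMAT) {
      stop(loc$path, " is an .scool container; open one cell, e.g. ",
           loc$path, "::/cells/", scool_cells(loc$path)[1])
    } else if (!is.null(resolution)) {
      warning("resolution ignored for single-resolution Cooler ", loc$path)
    }
  }
  h <- open_cooler(target)
  if (!is.null(resolution) && loc$group != "/" && h$table$bin_size != resolution)
    warning("requested resolution ", resolution, " differs from group bin size ",
            h$table$bin_size)
  structure(list(backend = "cooler", handle = h, table = h$table,
                 path = loc$path, uri = target, resolution = h$table$bin_size,
                 norms = c("NONE", h$weight_names),
                 cache = new.env(parent = emptyenv())),
            class = "contact_file")
}

#' @export
print.contact_file <- function(x, ...) {
  cat(sprintf("<contact file [%s] %s @ %.0f bp; normalizations: %s>\n", x$backend,
              x$path, x$resolution, paste(x$norms, collapse = ", ")))
  invisible(x)
}

#' All stored pixels of a contact file
#' @param file A [open_contacts()] `contact_file`.
#' @return Sorted genome-wide pixel data.frame (raw counts).
#' @export
contacts_dump <- function(file) {
  if (file$backend == "cooler") cooler_pixel_slab(file$handle)
  else hic_dump(file$handle)
}

resolve_norm <- function(file, normalization) {
  if (is.null(normalization) || identical(normalization, "NONE")) return(NULL)
  if (file$backend == "cooler") {
    if (!normalization %in% file$handle$weight_names)
      stop("unknown normalization '", normalization, "'; available: ",
           paste(file$norms, collapse = ", "))
    cooler_read_weights(file$handle, normalization)
  } else {
    if (!normalization %in% file$norms)
      stop("unknown normalization '", normalization, "'; available: ",
           paste(file$norms, collapse = ", "))
    hic_read_norm(file$handle, normalization)
  }
}

file_expected <- function(file) {
  if (is.null(file$cache$expected)) {
    file$cache$expected <- if (file$backend == "hic")
      hic_read_expected(file$handle, "NONE")
    else compute_expected_pixels(contacts_dump(file), file$table)
  }
  file$cache$expected
}

#' Query a contact file
#'
#' With no ranges the query is genome-wide; with one range it is the
#' symmetric block `range x range`; symmetric queries return
#' upper-triangle pixels only. If `range1` follows `range2` in genome
#' order the query is transposed internally and answered in canonical
#' orientation with `transposed = TRUE` recorded on the selector.
#'
#' @param file A [open_contacts()] `contact_file`.
#' @param range1,range2 Region strings or [genomic_range()] objects.
#' @param normalization Stored weight name, or NULL/"NONE" for raw counts.
#' @param matrix_type `"observed"`, `"expected"` or `"oe"` (intra only).
#' @param output `"thin"` (bin ids) or `"joined"` (bin intervals).
#' @return A lazy `pixel_selector`.
#' @export
fetch <- function(file, range1 = NULL, range2 = NULL, normalization = NULL,
                  matrix_type = c("observed", "expected", "oe"),
                  output = c("thin", "joined")) {
  stopifnot(inherits(file, "contact_file"))
  matrix_type <- match.arg(matrix_type)
  output <- match.arg(output)
  tb <- file$table
  as_range <- function(r) {
    if (is.null(r)) NULL
    else if (inherits(r, "genomic_range")) r
    else parse_region(r, tb$reference)
  }
  r1 <- as_range(range1); r2 <- as_range(range2)
  if (is.null(r1) && !is.null(r2)) { r1 <- r2; r2 <- NULL }
  if (!is.null(r1) && is.null(r2)) r2 <- r1
  weights <- resolve_norm(file, normalization)
  if (!is.null(weights) && length(weights$values) != tb$n_bins)
    stop("normalization vector length mismatch")
  transposed <- FALSE
  if (!is.null(r1)) {
    s1 <- range_to_bin_span(tb, r1); s2 <- range_to_bin_span(tb, r2)
    if (s1[1] > s2[1] || (s1[1] == s2[1] && s1[2] > s2[2])) {
      tmp <- r1; r1 <- r2; r2 <- tmp
      tmp <- s1; s1 <- s2; s2 <- tmp
      transposed <- TRUE
    }
  } else {
    s1 <- c(0, tb$n_bins); s2 <- c(0, tb$n_bins)
  }
  if (matrix_type %in% c("expected", "oe")) {
    if (is.null(r1))
      stop(matrix_type, " queries require an intra-chromosomal range")
    if (r1$chrom != r2$chrom)
      stop(matrix_type, " is undefined for inter-chromosomal queries")
  }
  structure(list(file = file, range1 = r1, range2 = r2, span1 = s1, span2 = s2,
                 symmetric = identical(s1, s2), transposed = transposed,
                 weights = weights, matrix_type = matrix_type, output = output),
            class = "pixel_selector")
}

#' @export
print.pixel_selector <- function(x, ...) {
  r <- function(g) if (is.null(g)) "genome-wide" else format_region(g)
  cat(sprintf("<selector %s x %s; %s%s%s>\n", r(x$range1), r(x$range2),
              x$matrix_type,
              if (is.null(x$weights)) "" else paste0(", ", x$weights$name),
              if (x$transposed) ", transposed" else ""))
  invisible(x)
}

# stored canonical pixels intersecting the query rectangle (or its mirror)
selector_raw <- function(sel, span1 = sel$span1, span2 = sel$span2) {
  file <- sel$file; tb <- file$table
  whole <- span1[1] == 0 && span1[2] == tb$n_bins &&
    span2[1] == 0 && span2[2] == tb$n_bins
  if (file$backend == "cooler") {
    if (whole) return(cooler_pixel_slab(file$handle))
    px <- cooler_pixel_slab(file$handle, span1, span2)
    if (!identical(span1, span2))     # mirrored hits: stored (b1 in s2, b2 in s1)
      px <- dedupe_rect_union(px, cooler_pixel_slab(file$handle, span2, span1))
    return(px)
  }
  if (whole) return(hic_dump(file$handle))
  h <- file$handle
  iv1 <- bin_to_interval(tb, span1[1]); iv2 <- bin_to_interval(tb, span2[1])
  c1 <- iv1$chrom; c2 <- iv2$chrom
  ci1 <- chrom_index(tb, c1); ci2 <- chrom_index(tb, c2)
  box <- c(span1 - tb$offsets[ci1], span2 - tb$offsets[ci2])
  hic_fetch(h, c1, c2, box = box)
}

span_intersect <- function(a, b) c(max(a[1], b[1]), min(a[2], b[2]))

dedupe_rect_union <- function(a, b) {
  px <- rbind(a, b)
  if (nrow(px) == 0L) return(a)
  key <- paste(px$bin1_id, px$bin2_id)
  px <- px[!duplicated(key), , drop = FALSE]
  px <- px[order(px$bin1_id, px$bin2_id), , drop = FALSE]
  rownames(px) <- NULL
  px
}

all_rect_pairs <- function(sel) {
  # every (bin1, bin2) pair of the query rectangle, canonical orientation
  s1 <- sel$span1; s2 <- sel$span2
  n <- (s1[2] - s1[1]) * (s2[2] - s2[1])
  if (n > 2^26) stop("expected-matrix query too large (", n, " pairs)")
  g <- expand.grid(bin1_id = seq(s1[1], s1[2] - 1), bin2_id = seq(s2[1], s2[2] - 1))
  swap <- g$bin1_id > g$bin2_id
  tmp <- g$bin1_id[swap]; g$bin1_id[swap] <- g$bin2_id[swap]; g$bin2_id[swap] <- tmp
  g <- g[!duplicated(paste(g$bin1_id, g$bin2_id)), , drop = FALSE]
  if (sel$symmetric) g <- g[g$bin1_id >= s1[1] & g$bin2_id < s2[2], , drop = FALSE]
  g[order(g$bin1_id, g$bin2_id), , drop = FALSE]
}

#' Materialize a selector as a pixel data.frame
#'
#' @param sel A [fetch()] selector.
#' @return data.frame in `(bin1_id, bin2_id)` ascending order; `joined`
#'   selectors carry bin intervals instead of ids.
#' @export
selector_pixels <- function(sel) {
  stopifnot(inherits(sel, "pixel_selector"))
  tb <- sel$file$table
  if (sel$matrix_type == "expected") {
    px <- all_rect_pairs(sel)
    prof <- file_expected(sel$file)
    ci <- findInterval(px$bin1_id, tb$offsets, left.open = FALSE)
    d <- pmin(px$bin2_id - px$bin1_id, length(prof$values) - 1)
    px$count <- prof$values[d + 1] * as.numeric(prof$scale[tb$reference$name[ci]])
  } else {
    px <- selector_raw(sel)
    if (!is.null(sel$weights)) px$count <- apply_norm(px, sel$weights, tb)
    if (sel$matrix_type == "oe") {
      prof <- file_expected(sel$file)
      px$count <- oe_transform(px, tb, prof)
    }
  }
  rownames(px) <- NULL
  if (sel$output == "joined") join_pixels(px, tb) else px
}

#' @export
as.data.frame.pixel_selector <- function(x, ...) selector_pixels(x)

chroms_in_span <- function(tb, span) {
  off <- tb$offsets
  which(off[-length(off)] < span[2] & off[-1] > span[1])
}

# stored pixels with bin1 in span1 AND bin2 in span2, canonical ids, no mirror
fetch_direct <- function(file, span1, span2) {
  tb <- file$table
  if (file$backend == "cooler") return(cooler_pixel_slab(file$handle, span1, span2))
  parts <- list()
  for (i in chroms_in_span(tb, span1)) for (j in chroms_in_span(tb, span2)) {
    if (i > j) next                  # stored orientation is bin1 chrom <= bin2 chrom
    b1 <- c(max(span1[1], tb$offsets[i]), min(span1[2], tb$offsets[i + 1]))
    b2 <- c(max(span2[1], tb$offsets[j]), min(span2[2], tb$offsets[j + 1]))
    parts[[length(parts) + 1L]] <- hic_fetch(
      file$handle, tb$reference$name[i], tb$reference$name[j],
      box = c(b1 - tb$offsets[i], b2 - tb$offsets[j]), mirror = FALSE)
  }
  if (length(parts) == 0L) return(empty_pixels(real = TRUE))
  px <- do.call(rbind, parts)
  px <- px[order(px$bin1_id, px$bin2_id), , drop = FALSE]
  rownames(px) <- NULL
  px
}

#' Row-chunked traversal of a selector
#'
#' Yields the selector's pixels in windows of `chunk_rows` rows so that at
#' most one backend slab is held in memory at a time, and each qualifying
#' pixel exactly once: a direct phase over `span1` rows, then (for
#' asymmetric queries) a mirror phase over `span2` rows that skips pixels
#' the direct phase already produced. Used by the streaming statistics and
#' the CLI dump path.
#'
#' @param sel A [fetch()] selector (`thin` output).
#' @param chunk_rows Rows (bin1 values) per chunk.
#' @return An iterator function; each call returns the next pixel
#'   data.frame or NULL. The `meter` attribute environment records the
#'   largest row window held (`peak_rows`) and chunks yielded (`chunks`).
#' @export
selector_chunks <- function(sel, chunk_rows = 1024L) {
  stopifnot(sel$output == "thin", sel$matrix_type != "expected")
  meter <- new.env(parent = emptyenv()); meter$peak_rows <- 0L; meter$chunks <- 0L
  windows <- function(span) {
    if (span[2] <= span[1]) return(NULL)
    starts <- seq(span[1], span[2] - 1, by = chunk_rows)
    lapply(starts, function(s) c(s, min(s + chunk_rows, span[2])))
  }
  plan <- lapply(windows(sel$span1), function(w) list(w = w, phase = "direct"))
  if (!sel$symmetric)
    plan <- c(plan, lapply(windows(sel$span2),
                           function(w) list(w = w, phase = "mirror")))
  i <- 0L
  it <- function() {
    i <<- i + 1L
    if (i > length(plan)) return(NULL)
    step <- plan[[i]]
    px <- if (step$phase == "direct") fetch_direct(sel$file, step$w, sel$span2)
          else fetch_direct(sel$file, step$w, sel$span1)
    if (step$phase == "mirror" && nrow(px)) {
      seen <- px$bin1_id >= sel$span1[1] & px$bin1_id < sel$span1[2] &
        px$bin2_id >= sel$span2[1] & px$bin2_id < sel$span2[2]
      px <- px[!seen, , drop = FALSE]
    }
    if (!is.null(sel$weights)) px$count <- apply_norm(px, sel$weights, sel$file$table)
    if (sel$matrix_type == "oe")
      px$count <- oe_transform(px, sel$file$table, file_expected(sel$file))
    meter$peak_rows <- max(meter$peak_rows, step$w[2] - step$w[1])
    meter$chunks <- meter$chunks + 1L
    px
  }
  attr(it, "meter") <- meter
  it
}

#' Sparse-triplet view of a selector, relative to the query origin
#'
#' @param sel A [fetch()] selector.
#' @return list `rows`, `cols`, `counts`: 0-based offsets from the query
#'   origin `(span1 start, span2 start)`, in iteration order.
#' @export
selector_to_coo <- function(sel) {
  px <- if (sel$output == "joined") stop("COO needs a thin selector") else selector_pixels(sel)
  o1 <- sel$span1[1]; o2 <- sel$span2[1]
  if (sel$symmetric)
    return(list(rows = px$bin1_id - o1, cols = px$bin2_id - o2, counts = px$count))
  in_rect <- function(a, b) a >= sel$span1[1] & a < sel$span1[2] &
    b >= sel$span2[1] & b < sel$span2[2]
  rows <- numeric(0); cols <- numeric(0); cnt <- px$count[0]
  direct <- in_rect(px$bin1_id, px$bin2_id)
  mirror <- in_rect(px$bin2_id, px$bin1_id) & !(direct & px$bin1_id == px$bin2_id)
  rows <- c(px$bin1_id[direct], px$bin2_id[mirror]) - o1
  cols <- c(px$bin2_id[direct], px$bin1_id[mirror]) - o2
  cnt <- c(px$count[direct], px$count[mirror])
  ord <- order(rows, cols)
  list(rows = rows[ord], cols = cols[ord], counts = cnt[ord])
}

#' Dense-matrix view of a selector
#'
#' Symmetric queries mirror counts across the diagonal; absent pixels are
#' zero, or NaN where a masked bin is involved under normalization.
#'
#' @param sel A [fetch()] selector.
#' @param max_elements Area guard; queries above it must use sparse output.
#' @return list with `row_span`, `col_span` and `matrix`.
#' @export
selector_to_dense <- function(sel, max_elements = 2^26) {
  n1 <- sel$span1[2] - sel$span1[1]; n2 <- sel$span2[2] - sel$span2[1]
  if (n1 * n2 > max_elements)
    stop("dense tile of ", n1 * n2, " elements exceeds the limit (",
         max_elements, "); use selector_to_coo()")
  m <- matrix(0, n1, n2)
  if (!is.null(sel$weights)) {
    w <- sel$weights$values
    bad1 <- !is.finite(w[seq(sel$span1[1], sel$span1[2] - 1) + 1])
    bad2 <- !is.finite(w[seq(sel$span2[1], sel$span2[2] - 1) + 1])
    m[bad1, ] <- NaN; m[, bad2] <- NaN
  }
  coo <- selector_to_coo(sel)
  if (length(coo$rows)) {
    m[cbind(coo$rows + 1, coo$cols + 1)] <- coo$counts
    if (sel$symmetric) {
      off <- coo$rows != coo$cols
      m[cbind(coo$cols[off] + 1, coo$rows[off] + 1)] <- coo$counts[off]
    }
  }
  list(row_span = sel$span1, col_span = sel$span2, matrix = m)
}

#' Streaming summary statistics of a selector
#'
#' Single chunked pass; the selector remains reusable.
#'
#' @param sel A [fetch()] selector.
#' @return list `nnz`, `sum`, `min`, `max` (`min`/`max` NULL when empty).
#' @export
selector_stats <- function(sel) {
  it <- selector_chunks(sel)
  nnz <- 0; s <- 0; mn <- NULL; mx <- NULL
  repeat {
    px <- it()
    if (is.null(px)) break
    if (nrow(px) == 0L) next
    nnz <- nnz + nrow(px)
    s <- s + sum(px$count)
    mn <- if (is.null(mn)) min(px$count) else min(mn, min(px$count))
    mx <- if (is.null(mx)) max(px$count) else max(mx, max(px$count))
  }
  list(nnz = nnz, sum = s, min = mn, max = mx)
}
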