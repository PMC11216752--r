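#' Native .hic reader (version 8; version 9 best-effort)
#'
#' Parses the header, master-index footer, stored normalization vectors and
#' expected-value vectors of .hic files and decompresses the zlib block
#' grid on demand. Version 8 queries decompress only blocks whose grid
#' coordinates intersect the bounding box; version 9 files (which use a
#' diagonal intra-chromosomal block numbering) are read by decompressing
#' every indexed block of the queried chromosome pair and filtering —
#' correct, if not minimal-I/O. Files that are neither version are
#' rejected, never misread.
#'
#' @name hic_read
NULL

parse_hic_header <- function(raw) {
  cur <- new_cursor(raw)
  magic <- cur_take(cur, 4L)
  if (!identical(magic, c(charToRaw("HIC"), as.raw(0L))))
    stop("not a .hic file (bad magic)")
  version <- r_i4(cur)
  if (!version %in% c(8L, 9L))
    stop("unsupported .hic version ", version, " (8 and 9 are supported)")
  master <- r_i8(cur)
  genome <- r_str(cur)
  if (version >= 9L) { r_i8(cur); r_i8(cur) }      # norm-vector-index pos/len
  nattr <- r_i4(cur)
  attrs <- list()
  for (i in seq_len(nattr)) { k <- r_str(cur); attrs[[k]] <- r_str(cur) }
  nchr <- r_i4(cur)
  cn <- character(nchr); cl <- numeric(nchr)
  for (i in seq_len(nchr)) {
    cn[i] <- r_str(cur)
    cl[i] <- if (version >= 9L) r_i8(cur) else r_i4(cur)
  }
  nres <- r_i4(cur)
  res <- if (nres > 0) r_i4(cur, nres) else integer()
  list(version = version, master = master, genome = genome, attrs = attrs,
       chrom_names = cn, chrom_lengths = cl, resolutions = as.numeric(res))
}

parse_hic_footer <- function(raw, master, version) {
  cur <- new_cursor(raw, master + 1)
  if (version >= 9L) r_i8(cur) else r_i4(cur)      # footer byte count (unused)
  nent <- r_i4(cur)
  entries <- vector("list", nent); keys <- character(nent)
  for (i in seq_len(nent)) {
    keys[i] <- r_str(cur)
    entries[[i]] <- list(pos = r_i8(cur), size = r_i4(cur))
  }
  names(entries) <- keys
  read_ev_block <- function(with_type) {
    n <- r_i4(cur)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      type <- if (with_type) r_str(cur) else "NONE"
      unit <- r_str(cur)
      bs <- r_i4(cur)
      nv <- if (version >= 9L) r_i8(cur) else r_i4(cur)
      vals <- if (version >= 9L) r_f4(cur, nv) else r_f8(cur, nv)
      nsf <- r_i4(cur)
      sf_idx <- integer(nsf); sf <- numeric(nsf)
      for (j in seq_len(nsf)) {
        sf_idx[j] <- r_i4(cur)
        sf[j] <- if (version >= 9L) r_f4(cur) else r_f8(cur)
      }
      out[[i]] <- list(type = type, unit = unit, bin_size = bs, values = vals,
                       scale_idx = sf_idx, scale = sf)
    }
    out
  }
  expected <- read_ev_block(with_type = FALSE)
  norm_expected <- read_ev_block(with_type = TRUE)
  nnv <- r_i4(cur)
  norms <- vector("list", nnv)
  for (i in seq_len(nnv)) {
    norms[[i]] <- list(type = r_str(cur), chr_idx = r_i4(cur), unit = r_str(cur),
                       bin_size = r_i4(cur), pos = r_i8(cur),
                       size = if (version >= 9L) r_i8(cur) else r_i4(cur))
  }
  list(entries = entries, expected = expected, norm_expected = norm_expected,
       norms = norms)
}

#' Open a .hic file at one resolution
#'
#' @param path Path to a .hic file.
#' @param resolution Bin size in bp; must be among the file's BP
#'   resolutions (the error lists what is available).
#' @return A `hic_handle` exposing the reference (without any "All"
#'   pseudo-chromosome), resolutions and normalization names.
#' @export
open_hic <- function(path, resolution) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, raw(), n = file.size(path))
  hdr <- parse_hic_header(raw)
  if (!resolution %in% hdr$resolutions)
    stop("resolution ", resolution, " not in file; available: ",
         paste(hdr$resolutions, collapse = ", "))
  ftr <- parse_hic_footer(raw, hdr$master, hdr$version)
  keep <- !tolower(hdr$chrom_names) %in% c("all")
  ref <- hic_reference(hdr$chrom_names[keep], hdr$chrom_lengths[keep])
  norm_names <- unique(c("NONE", vapply(ftr$norms, `[[`, "", "type")))
  structure(list(path = path, raw = raw, version = hdr$version,
                 genome = hdr$genome, resolutions = hdr$resolutions,
                 resolution = as.numeric(resolution),
                 reference = ref, table = bin_table(ref, resolution),
                 file_chrom_names = hdr$chrom_names,   # indices incl. any "All"
                 footer = ftr, norm_names = norm_names),
            class = "hic_handle")
}

#' @export
print.hic_handle <- function(x, ...) {
  cat(sprintf("<hic v%d %s: %.0f bp (of %s), %d chromosomes>\n", x$version, x$path,
              x$resolution, paste(x$resolutions, collapse = "/"),
              nrow(x$reference)))
  invisible(x)
}

parse_hic_block <- function(blob, version, declared_n = NULL) {
  payload <- tryCatch(memDecompress(blob, type = "gzip"),
                      error = function(e) stop("corrupt .hic block: ",
                                               conditionMessage(e)))
  cur <- new_cursor(payload)
  n <- r_i4(cur)
  bx_off <- r_i4(cur); by_off <- r_i4(cur)
  use_float <- r_i1(cur) != 0L                      # 0 = int16, 1 = float32
  int_x <- FALSE; int_y <- FALSE
  if (version >= 9L) { int_x <- r_i1(cur) != 0L; int_y <- r_i1(cur) != 0L }
  type <- r_i1(cur)
  x <- numeric(n); y <- numeric(n); cnt <- numeric(n); k <- 0L
  if (type == 1L) {                                 # list of rows
    nrows <- if (int_y) r_i4(cur) else r_i2(cur)
    for (i in seq_len(nrows)) {
      rn <- if (int_y) r_i4(cur) else r_i2(cur)
      nrec <- r_i2(cur)
      for (j in seq_len(nrec)) {
        k <- k + 1L
        x[k] <- bx_off + (if (int_x) r_i4(cur) else r_i2(cur))
        y[k] <- by_off + rn
        cnt[k] <- if (use_float) r_f4(cur) else r_i2(cur)
      }
    }
  } else if (type == 2L) {                          # dense window
    npts <- r_i4(cur); w <- r_i2(cur)
    for (i in seq_len(npts)) {
      v <- if (use_float) r_f4(cur) else r_i2(cur)
      if ((use_float && is.nan(v)) || (!use_float && v == -32768)) next
      k <- k + 1L
      row <- (i - 1L) %/% w; col <- (i - 1L) %% w
      x[k] <- bx_off + col; y[k] <- by_off + row
      cnt[k] <- v
    }
  } else stop("unknown .hic block representation type ", type)
  if (type == 1L && k != n)
    stop("corrupt .hic block: record count mismatch (declared ", n,
         ", parsed ", k, ")")
  data.frame(x = x[seq_len(k)], y = y[seq_len(k)], count = cnt[seq_len(k)])
}

hic_matrix_record <- function(handle, ci1, ci2) {
  # ci1/ci2: 0-based indices into the file chromosome list
  key <- paste0(ci1, "_", ci2)
  ent <- handle$footer$entries[[key]]
  swapped <- FALSE
  if (is.null(ent)) {
    ent <- handle$footer$entries[[paste0(ci2, "_", ci1)]]
    swapped <- TRUE
  }
  if (is.null(ent)) return(NULL)
  cur <- new_cursor(handle$raw, ent$pos + 1)
  r_i4(cur); r_i4(cur)                              # chrIdx pair, already known
  nres <- r_i4(cur)
  zooms <- vector("list", nres)
  for (i in seq_len(nres)) {
    unit <- r_str(cur)
    r_i4(cur)                                       # zoom index
    sum_counts <- r_f4(cur)
    r_i4(cur); r_f4(cur); r_f4(cur)                 # unused summary fields
    bs <- r_i4(cur)
    bbc <- r_i4(cur); bcc <- r_i4(cur)
    nb <- r_i4(cur)
    ids <- numeric(nb); pos <- numeric(nb); sz <- numeric(nb)
    for (j in seq_len(nb)) { ids[j] <- r_i4(cur); pos[j] <- r_i8(cur); sz[j] <- r_i4(cur) }
    zooms[[i]] <- list(unit = unit, bin_size = bs, sum_counts = sum_counts,
                       block_bin_count = bbc, block_column_count = bcc,
                       block_ids = ids, block_pos = pos, block_size = sz)
  }
  list(zooms = zooms, swapped = swapped)
}

v8_block_ids_for_box <- function(zoom, x_span, y_span, intra) {
  bbc <- zoom$block_bin_count; bcc <- zoom$block_column_count
  cols <- seq(x_span[1] %/% bbc, max(x_span[1], x_span[2] - 1) %/% bbc)
  rows <- seq(y_span[1] %/% bbc, max(y_span[1], y_span[2] - 1) %/% bbc)
  ids <- as.vector(outer(rows * bcc, cols, `+`))
  if (intra) {
    cols2 <- seq(y_span[1] %/% bbc, max(y_span[1], y_span[2] - 1) %/% bbc)
    rows2 <- seq(x_span[1] %/% bbc, max(x_span[1], x_span[2] - 1) %/% bbc)
    ids <- c(ids, as.vector(outer(rows2 * bcc, cols2, `+`)))
  }
  unique(ids)
}

#' Fetch pixels of one chromosome pair from a .hic file
#'
#' @param handle A [open_hic()] handle.
#' @param chrom1,chrom2 Chromosome names (reference order need not match
#'   the argument order; results are canonical upper-triangle).
#' @param box Optional local-bin bounding box
#'   `c(bin1_lo, bin1_hi, bin2_lo, bin2_hi)` (half-open, chromosome-local
#'   bins on chrom1/chrom2); NULL means the full pair extent.
#' @param mirror For intra-chromosomal queries, also return stored pixels
#'   whose transpose falls in the box (the symmetric-matrix semantics);
#'   FALSE filters strictly on canonical `(bin1, bin2)` orientation.
#' @return Pixel data.frame with global bin ids, sorted by
#'   `(bin1_id, bin2_id)`, duplicate-free.
#' @export
hic_fetch <- function(handle, chrom1, chrom2 = chrom1, box = NULL, mirror = TRUE) {
  tb <- handle$table
  i1 <- chrom_index(tb, chrom1); i2 <- chrom_index(tb, chrom2)
  if (i1 > i2) {                                    # canonical pair order
    tmp <- i1; i1 <- i2; i2 <- tmp
    if (!is.null(box)) box <- box[c(3, 4, 1, 2)]
  }
  nb1 <- tb$chrom_bins[i1]; nb2 <- tb$chrom_bins[i2]
  if (is.null(box)) box <- c(0, nb1, 0, nb2)
  if (box[1] < 0 || box[2] > nb1 || box[3] < 0 || box[4] > nb2)
    stop("bounding box outside chromosome-pair bin extents")
  fi1 <- match(tb$reference$name[i1], handle$file_chrom_names) - 1L
  fi2 <- match(tb$reference$name[i2], handle$file_chrom_names) - 1L
  rec <- hic_matrix_record(handle, fi1, fi2)
  if (is.null(rec)) return(empty_pixels(real = TRUE))
  zoom <- NULL
  for (z in rec$zooms)
    if (z$unit == "BP" && z$bin_size == handle$resolution) zoom <- z
  if (is.null(zoom)) return(empty_pixels(real = TRUE))
  intra <- i1 == i2
  want <- if (handle$version == 8L) {
    # axis convention: x runs along the pair's first chromosome
    xs <- if (rec$swapped) box[3:4] else box[1:2]
    ys <- if (rec$swapped) box[1:2] else box[3:4]
    v8_block_ids_for_box(zoom, xs, ys, intra)   # includes mirror blocks; cheap

  } else zoom$block_ids                             # v9: filter-all fallback
  sel <- zoom$block_ids %in% want
  parts <- vector("list", sum(sel))
  k <- 0L
  for (j in which(sel)) {
    blob <- handle$raw[(zoom$block_pos[j] + 1):(zoom$block_pos[j] + zoom$block_size[j])]
    k <- k + 1L
    parts[[k]] <- parse_hic_block(blob, handle$version)
  }
  if (k == 0L) return(empty_pixels(real = TRUE))
  df <- do.call(rbind, parts)
  if (rec$swapped) df <- data.frame(x = df$y, y = df$x, count = df$count)
  if (intra) {                                      # canonicalize upper triangle
    swap <- df$x > df$y
    tmp <- df$x[swap]; df$x[swap] <- df$y[swap]; df$y[swap] <- tmp
  }
  keep <- (df$x >= box[1] & df$x < box[2] & df$y >= box[3] & df$y < box[4])
  if (intra && mirror)
    keep <- keep | (df$y >= box[1] & df$y < box[2] & df$x >= box[3] & df$x < box[4])
  df <- df[keep, , drop = FALSE]
  out <- data.frame(bin1_id = tb$offsets[i1] + df$x, bin2_id = tb$offsets[i2] + df$y,
                    count = df$count)
  out <- aggregate_pixels(out)                      # dedupe mirrored records
  validate_pixels(out, tb)
  out
}

#' Genome-wide dump of every stored pixel of a .hic file
#' @param handle A [open_hic()] handle.
#' @return Sorted pixel data.frame over all chromosome pairs.
#' @export
hic_dump <- function(handle) {
  ref <- handle$reference
  parts <- list()
  for (i in seq_len(nrow(ref)))
    for (j in i:nrow(ref))
      parts[[length(parts) + 1L]] <- hic_fetch(handle, ref$name[i], ref$name[j])
  px <- do.call(rbind, parts)
  px <- px[order(px$bin1_id, px$bin2_id), , drop = FALSE]
  rownames(px) <- NULL
  px
}

#' Read a stored normalization vector as genome-length divisive weights
#'
#' Per-chromosome vectors stored for the handle's resolution are assembled
#' into one genome-length [norm_weights()] of kind `"divisive"`; bins of
#' chromosomes without a stored vector are masked (NaN). `"NONE"` yields
#' all ones.
#'
#' @param handle A [open_hic()] handle.
#' @param name Normalization name (e.g. `"KR"`, `"VC"`, `"SCALE"`).
#' @return A [norm_weights()].
#' @export
hic_read_norm <- function(handle, name) {
  tb <- handle$table
  if (name == "NONE")
    return(norm_weights(rep(1, tb$n_bins), kind = "divisive", name = "NONE"))
  hits <- Filter(function(nv) nv$type == name && nv$unit == "BP" &&
                   nv$bin_size == handle$resolution, handle$footer$norms)
  if (length(hits) == 0L)
    stop("normalization '", name, "' not stored at ", handle$resolution,
         " bp; available: ", paste(handle$norm_names, collapse = ", "))
  values <- rep(NaN, tb$n_bins)
  for (nv in hits) {
    cname <- handle$file_chrom_names[nv$chr_idx + 1L]
    ci <- match(cname, tb$reference$name)
    if (is.na(ci)) next                             # e.g. vector for "All"
    cur <- new_cursor(handle$raw, nv$pos + 1)
    n <- if (handle$version >= 9L) r_i8(cur) else r_i4(cur)
    v <- if (handle$version >= 9L) r_f4(cur, n) else r_f8(cur, n)
    n <- min(n, tb$chrom_bins[ci])
    values[tb$offsets[ci] + seq_len(n)] <- v[seq_len(n)]
  }
  norm_weights(values, kind = "divisive", name = name)
}

#' Read a stored expected-value vector
#'
#' @param handle A [open_hic()] handle.
#' @param normalization `"NONE"` for the raw expected vector, or a stored
#'   normalization name.
#' @return An [expected_profile()] at the handle's resolution.
#' @export
hic_read_expected <- function(handle, normalization = "NONE") {
  pool <- if (normalization == "NONE") handle$footer$expected
          else Filter(function(e) e$type == normalization, handle$footer$norm_expected)
  hit <- NULL
  for (e in pool)
    if (e$unit == "BP" && e$bin_size == handle$resolution) hit <- e
  if (is.null(hit))
    stop("no expected-value vector for normalization '", normalization,
         "' at ", handle$resolution, " bp")
  sc <- rep(1, nrow(handle$reference))
  names(sc) <- handle$reference$name
  if (length(hit$scale_idx)) {
    cn <- handle$file_chrom_names[hit$scale_idx + 1L]
    ok <- cn %in% names(sc)
    sc[cn[ok]] <- hit$scale[ok]
  }
  expected_profile(hit$values, sc, handle$resolution)
}

#' Structural validation of a .hic file
#'
#' Parses header and footer, decompresses every indexed block and checks
#' per-pair record bounds.
#'
#' @param path Path to a .hic file.
#' @return list with `ok` and `violations`.
#' @export
validate_hic <- function(path) {
  v <- character()
  hdr <- tryCatch({
    raw <- readBin(path, raw(), n = file.size(path))
    parse_hic_header(raw)
  }, error = function(e) conditionMessage(e))
  if (is.character(hdr)) return(list(ok = FALSE, violations = paste("header unreadable:", hdr)))
  h <- tryCatch(open_hic(path, hdr$resolutions[1]), error = function(e) conditionMessage(e))
  if (is.character(h)) return(list(ok = FALSE, violations = paste("footer unreadable:", h)))
  for (res in h$resolutions) {
    hr <- open_hic(path, res)
    px <- tryCatch(hic_dump(hr), error = function(e) conditionMessage(e))
    if (is.character(px)) { v <- c(v, sprintf("resolution %.0f: %s", res, px)); next }
    chk <- tryCatch({ validate_pixels(px, hr$table, require_sorted = TRUE); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(chk)) v <- c(v, sprintf("resolution %.0f: %s", res, chk))
  }
  list(ok = length(v) == 0L, violations = v)
}
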