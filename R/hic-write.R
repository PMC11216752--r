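#' Minimal .hic version 8 writer
#'
#' Writes a format-legal .hic v8 file: header, per-chromosome-pair matrix
#' records with zlib-compressed blocks on a fixed 256x256-bin grid,
#' optional stored normalization vectors, and a footer holding the master
#' index plus expected-value vectors computed from the data (the implicit
#' NONE normalization). The "All" pseudo-chromosome is not written.
#'
#' @name hic_write
NULL

HIC_BLOCK_BINS <- 256L   # writer block grid; readers must honor declared counts

# value encoding per block: counts as int16 when they are whole and fit,
# else float32 (the byte flag in each block records which was used)
block_use_float <- function(counts) {
  !(all(counts == floor(counts)) && max(abs(counts)) < 32768)
}

encode_hic_block <- function(x, y, counts, bx_off, by_off) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  use_float <- block_use_float(counts)
  w_i4(con, length(x))
  w_i4(con, bx_off)
  w_i4(con, by_off)
  w_i1(con, if (use_float) 1L else 0L)   # 0 = int16 values, 1 = float32
  w_i1(con, 1L)                          # representation 1 = list of rows
  ord <- order(y, x)
  x <- x[ord]; y <- y[ord]; counts <- counts[ord]
  rows <- split(seq_along(y), y - by_off)
  w_i2(con, length(rows))
  for (rn in names(rows)) {
    idx <- rows[[rn]]
    w_i2(con, as.integer(rn))
    w_i2(con, length(idx))
    for (i in idx) {
      w_i2(con, x[i] - bx_off)
      if (use_float) w_f4(con, counts[i]) else w_i2(con, counts[i])
    }
  }
  memCompress(rawConnectionValue(con), type = "gzip")
}

#' Write pixel streams to a .hic version 8 file
#'
#' @param path Output file path.
#' @param table Base-resolution [bin_table()]; coarser resolutions use
#'   tables derived from the same reference.
#' @param streams Named list, resolution (bp) -> sorted upper-triangle
#'   pixel data.frame on that resolution's bin table. Names must be
#'   ascending resolutions.
#' @param norms Optional list of stored normalization vectors, each a list
#'   with `name` (e.g. "KR"), `chrom`, `resolution`, `values` (one per bin
#'   of that chromosome at that resolution). Written verbatim; this
#'   package never computes KR/VC vectors.
#' @param genome_id Genome identifier string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_hic_v8 <- function(path, table, streams, norms = list(),
                         genome_id = "synthetic") {
  ref <- table$reference
  if (nrow(ref) == 0L) stop("empty reference")
  res <- as.numeric(names(streams))
  if (length(res) == 0L || any(is.na(res))) stop("streams must be named by resolution")
  if (is.unsorted(res, strictly = TRUE)) stop("resolutions must be ascending")
  tables <- lapply(res, function(r) if (r == table$bin_size) table else bin_table(ref, r))
  for (i in seq_along(streams))
    validate_pixels(streams[[i]], tables[[i]], require_sorted = TRUE)

  con <- file(path, "wb")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(path) })

  # ---- header ----
  writeBin(charToRaw("HIC"), con); writeBin(as.raw(0L), con)
  w_i4(con, 8L)
  master_field_at <- seek(con)
  w_i8(con, 0)                      # master index position, patched below
  w_str(con, genome_id)
  w_i4(con, 1L); w_str(con, "software"); w_str(con, GENERATED_BY)
  w_i4(con, nrow(ref))
  for (i in seq_len(nrow(ref))) { w_str(con, ref$name[i]); w_i4(con, ref$length[i]) }
  w_i4(con, length(res))
  for (r in res) w_i4(con, r)
  w_i4(con, 0L)                     # no FRAG resolutions

  # ---- body: compressed blocks, grouped by chromosome pair ----
  # per pair: list(res_idx -> list(zoom header fields, block index))
  pair_zooms <- list()
  for (ri in seq_along(res)) {
    tb <- tables[[ri]]
    px <- streams[[ri]]
    if (nrow(px) == 0L) next
    ci1 <- findInterval(px$bin1_id, tb$offsets, left.open = FALSE)
    ci2 <- findInterval(px$bin2_id, tb$offsets, left.open = FALSE)
    x <- px$bin1_id - tb$offsets[ci1]   # chrom-local bins, chr1 axis
    y <- px$bin2_id - tb$offsets[ci2]
    for (key in unique(paste0(ci1 - 1L, "_", ci2 - 1L))) {
      sel <- paste0(ci1 - 1L, "_", ci2 - 1L) == key
      c1 <- ci1[sel][1]
      bcc <- ceiling(tb$chrom_bins[c1] / HIC_BLOCK_BINS)
      brow <- y[sel] %/% HIC_BLOCK_BINS
      bcol <- x[sel] %/% HIC_BLOCK_BINS
      bn <- brow * bcc + bcol
      blocks <- list()
      for (b in sort(unique(bn))) {
        bi <- sel; bi[sel] <- bn == b
        blob <- encode_hic_block(x[bi], y[bi], px$count[bi],
                                 bx_off = (b %% bcc) * HIC_BLOCK_BINS,
                                 by_off = (b %/% bcc) * HIC_BLOCK_BINS)
        pos <- seek(con)
        writeBin(blob, con)
        blocks[[length(blocks) + 1L]] <- list(id = b, pos = pos, size = length(blob))
      }
      zoom <- list(res_idx = ri - 1L, bin_size = res[ri],
                   sum_counts = sum(px$count[sel]),
                   block_bin_count = HIC_BLOCK_BINS, block_column_count = bcc,
                   blocks = blocks)
      pair_zooms[[key]] <- c(pair_zooms[[key]], list(zoom))
    }
  }

  # ---- stored normalization vector payloads ----
  norm_index <- list()
  for (nv in norms) {
    ci <- chrom_index(ref, nv$chrom)
    pos <- seek(con)
    w_i4(con, length(nv$values))
    w_f8(con, nv$values)
    norm_index[[length(norm_index) + 1L]] <-
      list(type = nv$name, chr_idx = ci - 1L, bin_size = nv$resolution,
           pos = pos, size = 4L + 8L * length(nv$values))
  }

  # ---- matrix metadata records ----
  master <- list()
  for (key in names(pair_zooms)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    pos <- seek(con)
    w_i4(con, ij[1]); w_i4(con, ij[2])
    zooms <- pair_zooms[[key]]
    w_i4(con, length(zooms))
    for (z in zooms) {
      w_str(con, "BP")
      w_i4(con, z$res_idx)
      w_f4(con, z$sum_counts)
      w_i4(con, 0L)                 # occupied cell count (unused)
      w_f4(con, 0); w_f4(con, 0)    # percentile fields (unused)
      w_i4(con, z$bin_size)
      w_i4(con, z$block_bin_count)
      w_i4(con, z$block_column_count)
      w_i4(con, length(z$blocks))
      for (b in z$blocks) { w_i4(con, b$id); w_i8(con, b$pos); w_i4(con, b$size) }
    }
    master[[length(master) + 1L]] <-
      list(key = key, pos = pos, size = seek(con) - pos)
  }

  # ---- footer: master index + expected vectors + norm vector index ----
  master_pos <- seek(con)
  body <- rawConnection(raw(0), "wb")
  w_i4(body, length(master))
  for (m in master) { w_str(body, m$key); w_i8(body, m$pos); w_i4(body, m$size) }
  has_intra <- vapply(seq_along(res), function(ri) {
    px <- streams[[ri]]
    if (nrow(px) == 0L) return(FALSE)
    tb <- tables[[ri]]
    any(findInterval(px$bin1_id, tb$offsets) == findInterval(px$bin2_id, tb$offsets))
  }, logical(1))
  w_i4(body, sum(has_intra))        # one NONE expected vector per resolution with data
  for (ri in which(has_intra)) {
    prof <- compute_expected_pixels(streams[[ri]], tables[[ri]])
    w_str(body, "BP")
    w_i4(body, res[ri])
    w_i4(body, length(prof$values))
    w_f8(body, prof$values)
    sc <- prof$scale[is.finite(prof$scale)]
    w_i4(body, length(sc))
    for (cn in names(sc)) { w_i4(body, chrom_index(ref, cn) - 1L); w_f8(body, sc[[cn]]) }
  }
  w_i4(body, 0L)                    # no normalized expected-value vectors
  blob <- rawConnectionValue(body); close(body)
  w_i4(con, length(blob))           # footer size field
  writeBin(blob, con)
  w_i4(con, length(norm_index))
  for (nv in norm_index) {
    w_str(con, nv$type)
    w_i4(con, nv$chr_idx)
    w_str(con, "BP")
    w_i4(con, nv$bin_size)
    w_i8(con, nv$pos)
    w_i4(con, nv$size)
  }

  seek(con, master_field_at)
  w_i8(con, master_pos)
  ok <- TRUE
  invisible(path)
}
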