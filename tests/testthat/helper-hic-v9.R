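# Minimal .hic version 9 writer used only to exercise the v9 read path.
# Follows the public v9 layout: int64 chromosome lengths and footer sizes,
# float expected/normalization values, per-block int-position flags.

write_hic_v9_fixture <- function(path, chrom, chrom_len, bin_size, px,
                                 norm = NULL) {
  w_i1 <- hicbridge:::w_i1; w_i2 <- hicbridge:::w_i2; w_i4 <- hicbridge:::w_i4
  w_i8 <- hicbridge:::w_i8; w_f4 <- hicbridge:::w_f4; w_str <- hicbridge:::w_str
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HIC"), con); writeBin(as.raw(0L), con)
  w_i4(con, 9L)
  master_at <- seek(con); w_i8(con, 0)
  w_str(con, "synthetic-v9")
  w_i8(con, 0); w_i8(con, 0)            # norm vector index position/length
  w_i4(con, 0L)                         # no attributes
  w_i4(con, 1L); w_str(con, chrom); w_i8(con, chrom_len)
  w_i4(con, 1L); w_i4(con, bin_size)
  w_i4(con, 0L)                         # no FRAG resolutions
  # one block, list-of-rows, float counts, short positions
  body <- rawConnection(raw(0), "wb")
  w_i4(body, nrow(px)); w_i4(body, 0L); w_i4(body, 0L)
  w_i1(body, 1L)                        # float counts
  w_i1(body, 0L); w_i1(body, 0L)        # short binX / short binY
  w_i1(body, 1L)                        # list of rows
  rows <- split(seq_len(nrow(px)), px$bin2_id)
  w_i2(body, length(rows))
  for (rn in names(rows)) {
    w_i2(body, as.integer(rn)); w_i2(body, length(rows[[rn]]))
    for (i in rows[[rn]]) { w_i2(body, px$bin1_id[i]); w_f4(body, px$count[i]) }
  }
  blob <- memCompress(rawConnectionValue(body), type = "gzip"); close(body)
  block_pos <- seek(con); writeBin(blob, con)
  # norm vector payload (float values, int64 count)
  norm_pos <- NULL
  if (!is.null(norm)) {
    norm_pos <- seek(con)
    w_i8(con, length(norm)); w_f4(con, norm)
  }
  mat_pos <- seek(con)
  w_i4(con, 0L); w_i4(con, 0L); w_i4(con, 1L)
  w_str(con, "BP"); w_i4(con, 0L)
  w_f4(con, sum(px$count)); w_i4(con, 0L); w_f4(con, 0); w_f4(con, 0)
  w_i4(con, bin_size)
  w_i4(con, 256L); w_i4(con, as.integer(ceiling(ceiling(chrom_len / bin_size) / 256)))
  w_i4(con, 1L); w_i4(con, 0L); w_i8(con, block_pos); w_i4(con, length(blob))
  mat_size <- seek(con) - mat_pos
  master <- seek(con)
  w_i8(con, 0)                          # footer nBytes (unused by the reader)
  w_i4(con, 1L); w_str(con, "0_0"); w_i8(con, mat_pos); w_i4(con, mat_size)
  # one NONE expected vector: float values, int64 count
  nb <- ceiling(chrom_len / bin_size)
  w_i4(con, 1L); w_str(con, "BP"); w_i4(con, bin_size)
  w_i8(con, nb); w_f4(con, rep(1, nb))
  w_i4(con, 1L); w_i4(con, 0L); w_f4(con, 2)   # scale factor 2 for the chromosome
  w_i4(con, 0L)                         # no normalized expected vectors
  if (is.null(norm_pos)) w_i4(con, 0L) else {
    w_i4(con, 1L)
    w_str(con, "VC"); w_i4(con, 0L); w_str(con, "BP"); w_i4(con, bin_size)
    w_i8(con, norm_pos); w_i8(con, 8 + 4 * length(norm))
  }
  seek(con, master_at); w_i8(con, master)
  invisible(path)
}
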