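#' @name hic_binary
#' @title Little-endian binary primitives for the .hic format
#' @description Internal helpers: a raw-vector read cursor and
#'   connection-based writers for the integer, float and NUL-terminated
#'   string fields of the .hic container. 64-bit integers are carried in
#'   doubles (exact below 2^53, far beyond any file offset handled here).
#' @keywords internal
NULL

# ---- writing (to a "wb" connection) ----

w_i1 <- function(con, x) writeBin(as.raw(bitwAnd(as.integer(x), 255L)), con)
w_i2 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
w_i4 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")
w_f4 <- function(con, x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
w_f8 <- function(con, x) writeBin(as.numeric(x), con, size = 8L, endian = "little")

int64_raw <- function(x) {
  # little-endian 8-byte encoding of non-negative doubles < 2^53
  out <- raw(8L * length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    b <- integer(8)
    for (j in 1:8) { b[j] <- v %% 256; v <- v %/% 256 }
    out[(8L * (i - 1L) + 1L):(8L * i)] <- as.raw(b)
  }
  out
}

w_i8 <- function(con, x) writeBin(int64_raw(as.numeric(x)), con)

w_str <- function(con, s) {
  writeBin(charToRaw(enc2utf8(s)), con)
  writeBin(as.raw(0L), con)
}

# ---- reading (from a raw vector, via a cursor environment) ----

new_cursor <- function(raw, pos = 1) {
  e <- new.env(parent = emptyenv())
  e$raw <- raw; e$pos <- pos
  e
}

cur_take <- function(cur, n) {
  if (cur$pos + n - 1 > length(cur$raw))
    stop("unexpected end of .hic data (truncated file?)")
  out <- cur$raw[cur$pos:(cur$pos + n - 1)]
  cur$pos <- cur$pos + n
  out
}

r_i1 <- function(cur) as.integer(cur_take(cur, 1L))
r_i2 <- function(cur, n = 1L)
  readBin(cur_take(cur, 2L * n), "integer", n = n, size = 2L, endian = "little", signed = TRUE)
r_i4 <- function(cur, n = 1L)
  readBin(cur_take(cur, 4L * n), "integer", n = n, size = 4L, endian = "little")
r_f4 <- function(cur, n = 1L)
  readBin(cur_take(cur, 4L * n), "double", n = n, size = 4L, endian = "little")
r_f8 <- function(cur, n = 1L)
  readBin(cur_take(cur, 8L * n), "double", n = n, size = 8L, endian = "little")

r_i8 <- function(cur, n = 1L) {
  b <- as.integer(cur_take(cur, 8L * n))
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- sum(b[(8L * (i - 1L) + 1L):(8L * i)] * 256^(0:7))
  out
}

r_str <- function(cur) {
  nul <- which(cur$raw[cur$pos:length(cur$raw)] == as.raw(0L))[1]
  if (is.na(nul)) stop("unterminated string in .hic data")
  s <- if (nul == 1L) "" else rawToChar(cur$raw[cur$pos:(cur$pos + nul - 2L)])
  cur$pos <- cur$pos + nul
  s
}
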