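# Shared fixtures for the suite. Everything is generated in code at run
# time; the expensive desk-scale matrix and its on-disk materializations
# are built once per session and reused.

# the two-chromosome toy table used across the format examples
tiny_table <- function() bin_table(hic_reference(c("chr1", "chr2"), c(25, 10)), 10)

tiny_pixels <- function() {
  data.frame(bin1_id = c(0, 0, 3), bin2_id = c(0, 3, 3), count = c(4L, 2L, 1L))
}

# brute-force oracle: filter a full dump by bin spans
brute_filter <- function(px, span1, span2) {
  keep <- px$bin1_id >= span1[1] & px$bin1_id < span1[2] &
    px$bin2_id >= span2[1] & px$bin2_id < span2[2]
  out <- px[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force rectangle query: canonical stored pixels whose (b1,b2) or
# mirrored (b2,b1) orientation falls in span1 x span2
brute_rect <- function(px, span1, span2) {
  direct <- px$bin1_id >= span1[1] & px$bin1_id < span1[2] &
    px$bin2_id >= span2[1] & px$bin2_id < span2[2]
  mirrored <- px$bin2_id >= span1[1] & px$bin2_id < span1[2] &
    px$bin1_id >= span2[1] & px$bin1_id < span2[2]
  out <- px[direct | mirrored, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.fixture_cache <- new.env(parent = emptyenv())

# desk-scale synthetic matrix materialized as .cool and .hic, built once
shared_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  p <- sim_params(seed = 2024L, n_chroms = 3, chrom_range = c(2e5, 6e5),
                  bin_size = 1e4, n_pairs = 3e4)
  m <- simulate_matrix(p)
  dir <- file.path(tempdir(), "hicbridge-shared-fixture")
  dir.create(dir, showWarnings = FALSE)
  cool <- file.path(dir, "shared.cool")
  hic <- file.path(dir, "shared.hic")
  if (file.exists(cool)) unlink(cool)
  create_cooler(cool, m$table, m$pixels)
  write_hic_v8(hic, m$table, stats::setNames(list(m$pixels), p$bin_size))
  .fixture_cache$fx <- list(params = p, table = m$table, pixels = m$pixels,
                            cool = cool, hic = hic)
  .fixture_cache$fx
}

random_span <- function(n_bins, rng_max = n_bins) {
  a <- sort(sample.int(n_bins + 1, 2) - 1)
  if (a[1] == a[2]) a[2] <- a[2] + 1
  a
}

expect_same_pixels <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$bin1_id, b$bin1_id)
  expect_equal(a$bin2_id, b$bin2_id)
  expect_equal(as.numeric(a$count), as.numeric(b$count))
}

# dense reference implementation of the same iteration
dense_ice <- function(px, table, params) {
  nb <- table$n_bins
  A <- matrix(0, nb, nb)
  A[cbind(px$bin1_id + 1, px$bin2_id + 1)] <- px$count
  A <- A + t(A) - diag(diag(A))
  mask <- compute_bin_mask(px, table, params)
  ci <- findInterval(0:(nb - 1), table$offsets, left.open = FALSE)
  if (params$ignore_diags > 0)
    for (d in 0:(params$ignore_diags - 1)) {
      idx <- seq_len(nb - d)
      same <- ci[idx] == ci[idx + d]       # diagonals are intra-chromosomal
      A[cbind(idx[same], idx[same] + d)] <- 0
      A[cbind(idx[same] + d, idx[same])] <- 0
    }
  A[mask, ] <- 0; A[, mask] <- 0
  w <- as.numeric(!mask)
  for (i in seq_len(params$max_iter)) {
    m <- as.vector(A %*% w) * w
    mh <- m[!mask] / mean(m[!mask])
    w[!mask] <- w[!mask] / mh
    if (stats::var(mh) < params$tol) break
  }
  m <- as.vector(A %*% w) * w
  w[!mask] <- w[!mask] / sqrt(mean(m[!mask]))
  w[mask] <- NaN
  w
}

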