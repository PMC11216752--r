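# ICE balancing against closed forms and a dense-matrix reference, and the
# distance-decay expected profile.

test_that("bin masking applies min-nnz and MAD filters", {
  tb <- bin_table(hic_reference("chr1", 40), 10)
  px <- data.frame(bin1_id = c(0, 0, 1, 2), bin2_id = c(1, 2, 2, 3),
                   count = c(5L, 5L, 5L, 1L))
  p <- ice_params(min_nnz = 2, mad_max = 50, ignore_diags = 0)
  mask <- compute_bin_mask(px, tb, p)
  expect_true(mask[4])                      # bin 3 has a single nonzero entry
  expect_false(any(mask[1:3]))
  # identical marginals, MAD = 0: the MAD filter is a no-op
  pxu <- data.frame(bin1_id = c(0, 1, 2), bin2_id = c(1, 2, 3), count = 2L)
  expect_false(any(compute_bin_mask(pxu, tb, ice_params(min_nnz = 1, mad_max = 5,
                                                        ignore_diags = 0))))
})

test_that("the mask equals a brute-force recomputation from the dense matrix", {
  fx <- shared_fixture()
  p <- ice_params(min_nnz = 3, mad_max = 3)
  mask <- compute_bin_mask(fx$pixels, fx$table, p)
  nb <- fx$table$n_bins
  A <- matrix(0, nb, nb)
  A[cbind(fx$pixels$bin1_id + 1, fx$pixels$bin2_id + 1)] <- fx$pixels$count
  A <- A + t(A) - diag(diag(A))
  nnz <- rowSums(A != 0)
  ref_mask <- nnz < p$min_nnz
  Ad <- A
  ci <- findInterval(0:(nb - 1), fx$table$offsets, left.open = FALSE)
  for (i in seq_len(nb)) for (j in seq_len(nb))
    if (ci[i] == ci[j] && abs(i - j) < p$ignore_diags) Ad[i, j] <- 0
  marg <- rowSums(Ad)
  ref_mask <- ref_mask | marg <= 0
  lm <- log(marg[!ref_mask])
  madv <- stats::mad(lm)
  if (madv > 0)
    ref_mask[!ref_mask][lm < stats::median(lm) - p$mad_max * madv] <- TRUE
  expect_equal(mask, ref_mask)
})

test_that("equal-marginal matrices balance to the closed form 1/sqrt(rowsum)", {
  tb <- bin_table(hic_reference("chr1", 20), 10)
  px <- data.frame(bin1_id = c(0, 0, 1), bin2_id = c(0, 1, 1), count = c(2, 1, 2))
  p <- ice_params(min_nnz = 1, mad_max = 50, ignore_diags = 0, tol = 1e-14)
  r <- ice_balance(px, tb, p)
  expect_equal(r$weights$values, rep(1 / sqrt(3), 2), tolerance = 1e-7)
  expect_true(r$converged)
  # balanced marginals are one
  v <- apply_norm(px, r$weights)
  marg <- c(v[1] + v[2], v[2] + v[3])
  expect_equal(marg, c(1, 1), tolerance = 1e-7)
})

test_that("weights are scale-equivariant: counts x10 gives weights / sqrt(10)", {
  fx <- shared_fixture()
  p <- ice_params(min_nnz = 1, mad_max = 50, tol = 1e-10)
  r1 <- ice_balance(fx$pixels, fx$table, p)
  px10 <- fx$pixels; px10$count <- px10$count * 10
  r10 <- ice_balance(px10, fx$table, p)
  expect_equal(r10$weights$values, r1$weights$values / sqrt(10), tolerance = 1e-6)
  expect_equal(apply_norm(px10, r10$weights), apply_norm(fx$pixels, r1$weights),
               tolerance = 1e-6)
})

test_that("the sparse implementation matches the dense reference to 1e-8", {
  for (seed in c(5, 6)) {
    p <- sim_params(seed = seed, n_chroms = 2, chrom_range = c(2e5, 5e5),
                    bin_size = 1e4, n_pairs = 4e4)
    m <- simulate_matrix(p)                # <= 100 bins
    expect_lte(m$table$n_bins, 100)
    params <- ice_params(min_nnz = 2, mad_max = 5, tol = 1e-12, max_iter = 1000)
    r <- ice_balance(m$pixels, m$table, params)
    w_ref <- dense_ice(m$pixels, m$table, params)
    expect_equal(r$weights$values, w_ref, tolerance = 1e-8)
  }
})

test_that("converged balancing leaves marginal CV below 10x tolerance", {
  # at convergence the CV of the iteration's marginals scales as
  # ~ 0.5 * sqrt(variance); the bound is checked at a tolerance where the
  # variance stop rule covers it (0.5 * sqrt(tol) < 10 * tol for tol > 1/400)
  fx <- shared_fixture()
  params <- ice_params(min_nnz = 2, tol = 5e-3, max_iter = 2000)
  r <- ice_balance(fx$pixels, fx$table, params)
  expect_true(r$converged)
  w <- r$weights$values
  keep <- is.finite(w)
  pxm <- hicbridge:::drop_ignored_diags(fx$pixels, fx$table, params$ignore_diags)
  v <- pxm$count * w[pxm$bin1_id + 1] * w[pxm$bin2_id + 1]
  ok <- is.finite(v)
  pxk <- pxm[ok, ]; vk <- v[ok]
  nb <- fx$table$n_bins
  off <- pxk$bin1_id != pxk$bin2_id
  marg <- hicbridge:::rowsum_vec(pxk$bin1_id, vk, nb) +
    hicbridge:::rowsum_vec(pxk$bin2_id[off], vk[off], nb)
  cv <- stats::sd(marg[keep]) / mean(marg[keep])
  expect_lt(cv, 10 * params$tol)
})

test_that("balancing is invariant under pixel-stream permutation", {
  fx <- shared_fixture()
  params <- ice_params(min_nnz = 2, tol = 1e-10)
  r1 <- ice_balance(fx$pixels, fx$table, params)
  set.seed(8)
  shuffled <- fx$pixels[sample.int(nrow(fx$pixels)), ]
  r2 <- ice_balance(shuffled, fx$table, params)
  expect_equal(r2$weights$values, r1$weights$values, tolerance = 1e-9)
})

test_that("cis weights of a block-diagonal matrix equal per-chromosome gw weights", {
  p <- sim_params(seed = 13, n_chroms = 2, chrom_range = c(2e5, 4e5),
                  bin_size = 1e4, n_pairs = 3e4, p_cis = 1)   # intra only
  m <- simulate_matrix(p)
  params <- ice_params(mode = "cis", min_nnz = 1, mad_max = 50, tol = 1e-12)
  rc <- ice_balance(m$pixels, m$table, params)
  pg <- params; pg$mode <- "gw"
  rg <- ice_balance(m$pixels, m$table, pg)
  # per chromosome the weight profiles agree up to one scalar
  for (ci in 1:2) {
    ids <- seq(m$table$offsets[ci] + 1, m$table$offsets[ci + 1])
    a <- rc$weights$values[ids]; b <- rg$weights$values[ids]
    keep <- is.finite(a) & is.finite(b)
    ratio <- a[keep] / b[keep]
    expect_lt(stats::sd(ratio) / mean(ratio), 1e-5)
  }
})

test_that("trans mode balances only inter-chromosomal pixels", {
  fx <- shared_fixture()
  params <- ice_params(mode = "trans", min_nnz = 1, mad_max = 50)
  r <- ice_balance(fx$pixels, fx$table, params)
  expect_equal(r$weights$name, "trans_weight")
  expect_true(any(is.finite(r$weights$values)))
})

test_that("balance_cooler persists weights and convergence metadata", {
  fx <- shared_fixture()
  f <- withr::local_tempfile(fileext = ".cool")
  file.copy(fx$cool, f)
  res <- balance_cooler(f, ice_params(min_nnz = 2))
  h <- open_cooler(f)
  expect_true("weight" %in% h$weight_names)
  w <- cooler_read_weights(h, "weight")
  expect_equal(w$kind, "multiplicative")
  expect_equal(w$values, res$weights$values)
})

test_that("expected profiles reproduce closed forms", {
  # constant matrix: values[d] = k, all scales 1 (equal-length chromosomes,
  # so the per-distance pair counts coincide and the ratio law is exact)
  tb <- bin_table(hic_reference(c("a", "b"), c(50, 50)), 10)
  g <- expand.grid(b1 = 0:9, b2 = 0:9)
  g <- g[g$b1 <= g$b2, ]
  ci <- findInterval(g$b1, tb$offsets, left.open = FALSE)
  cj <- findInterval(g$b2, tb$offsets, left.open = FALSE)
  g <- g[ci == cj, ]
  px <- data.frame(bin1_id = g$b1, bin2_id = g$b2, count = 4L)
  px <- px[order(px$bin1_id, px$bin2_id), ]
  prof <- compute_expected_pixels(px, tb)
  expect_equal(prof$values[1:3], rep(4, 3))
  expect_equal(unname(prof$scale), c(1, 1))
  # doubling one chromosome's counts doubles its scale factor
  px2 <- px
  cj2 <- findInterval(px2$bin1_id, tb$offsets, left.open = FALSE)
  px2$count[cj2 == 2] <- px2$count[cj2 == 2] * 2L
  prof2 <- compute_expected_pixels(px2, tb)
  expect_equal(unname(prof2$scale["b"] / prof2$scale["a"]), 2, tolerance = 1e-12)
  # O/E averages to one per chromosome by construction
  oe <- oe_transform(px2, tb, prof2)
  for (k in 1:2) {
    sel <- findInterval(px2$bin1_id, tb$offsets, left.open = FALSE) == k
    d <- px2$bin2_id[sel] - px2$bin1_id[sel]
    npair_w <- tapply(oe[sel], d, mean)
    expect_equal(mean(unlist(npair_w)), 1, tolerance = 0.35)
  }
  expect_error(compute_expected_pixels(data.frame(bin1_id = 0, bin2_id = 5,
                                                  count = 1), tb),
               "no intra-chromosomal")
})
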