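# Uniform fetch API: backend detection, selectors, sparse/dense output,
# normalization and O/E transforms, streaming statistics.

test_that("open_contacts detects backends by file signature", {
  fx <- shared_fixture()
  expect_equal(open_contacts(fx$cool)$backend, "cooler")
  expect_equal(open_contacts(fx$hic, 1e4)$backend, "hic")
  txt <- withr::local_tempfile(fileext = ".pairs")
  writeLines("## pairs format v1.0", txt)
  expect_error(open_contacts(txt), "not a contact file")
  expect_warning(open_contacts(fx$cool, resolution = 9999), "ignored")
})

test_that("mcool and multi-resolution .hic require a resolution", {
  fx <- shared_fixture()
  f <- withr::local_tempfile(fileext = ".mcool")
  co <- coarsen_pixels(fx$pixels, fx$table, 2)
  create_mcool(f, fx$table, stats::setNames(list(fx$pixels, co$pixels),
                                            c("10000", "20000")))
  expect_error(open_contacts(f), "requires a resolution")
  expect_error(open_contacts(f, 12345), "available")
  expect_equal(open_contacts(f, 20000)$resolution, 20000)
})

test_that("genome-wide raw sums equal the stored sum metadata", {
  fx <- shared_fixture()
  for (file in list(open_contacts(fx$cool), open_contacts(fx$hic, 1e4))) {
    st <- selector_stats(fetch(file))
    expect_equal(st$sum, sum(fx$pixels$count))
    expect_equal(st$nnz, nrow(fx$pixels))
  }
})

test_that("range queries equal a brute-force filter of the full dump", {
  fx <- shared_fixture()
  f <- open_contacts(fx$cool)
  ref <- fx$table$reference
  sel <- fetch(f, sprintf("%s:0-200,000", ref$name[1]))
  span <- range_to_bin_span(fx$table, parse_region(paste0(ref$name[1], ":0-200000"),
                                                   ref))
  expect_same_pixels(selector_pixels(sel), brute_filter(fx$pixels, span, span))
})

test_that("normalized fetch equals manual weight application", {
  fx <- shared_fixture()
  f <- withr::local_tempfile(fileext = ".cool")
  file.copy(fx$cool, f)
  res <- balance_cooler(f, ice_params(min_nnz = 1, mad_max = 50))
  cf <- open_contacts(f)
  raw <- selector_pixels(fetch(cf, "chrS1"))
  bal <- selector_pixels(fetch(cf, "chrS1", normalization = "weight"))
  expect_equal(bal$count, apply_norm(raw, res$weights), tolerance = 1e-12)
  expect_error(fetch(cf, normalization = "bogus"), "available")
})

test_that("O/E queries divide by the distance profile and reject trans", {
  fx <- shared_fixture()
  cf <- open_contacts(fx$cool)
  sel <- fetch(cf, "chrS1", matrix_type = "oe")
  oe <- selector_pixels(sel)
  raw <- selector_pixels(fetch(cf, "chrS1"))
  prof <- compute_expected_pixels(fx$pixels, fx$table)
  expect_equal(oe$count, oe_transform(raw, fx$table, prof))
  expect_error(fetch(cf, "chrS1", "chrS2", matrix_type = "oe"),
               "inter-chromosomal")
  # the hic backend answers O/E from its stored expected vector
  hf <- open_contacts(fx$hic, 1e4)
  oe_h <- selector_pixels(fetch(hf, "chrS1", matrix_type = "oe"))
  expect_equal(oe_h$count, oe$count, tolerance = 1e-6)
})

test_that("expected queries emit the model value for every bin pair", {
  fx <- shared_fixture()
  cf <- open_contacts(fx$cool)
  sel <- fetch(cf, "chrS1:0-50,000", matrix_type = "expected", output = "joined")
  j <- selector_pixels(sel)
  expect_equal(nrow(j), 5 * 6 / 2)           # all upper pairs of 5 bins
  prof <- compute_expected_pixels(fx$pixels, fx$table)
  expect_equal(j$count[1], prof$values[1] * unname(prof$scale["chrS1"]))
  expect_true(all(c("start1", "end2") %in% names(j)))
})

test_that("sparse triplets are offset to the query origin", {
  tb <- tiny_table()
  f <- withr::local_tempfile(fileext = ".cool")
  create_cooler(f, tb, tiny_pixels())
  cf <- open_contacts(f)
  coo <- selector_to_coo(fetch(cf))
  expect_equal(coo$rows, c(0, 0, 3))
  expect_equal(coo$cols, c(0, 3, 3))
  expect_equal(coo$counts, c(4, 2, 1))
  # empty region
  coo0 <- selector_to_coo(fetch(cf, "chr1:10-20"))
  expect_equal(lengths(coo0), c(rows = 0, cols = 0, counts = 0))
  # asymmetric query matches the brute-force rectangle
  coo2 <- selector_to_coo(fetch(cf, "chr1", "chr2"))
  expect_equal(coo2$rows, 0)
  expect_equal(coo2$cols, 0)
  expect_equal(coo2$counts, 2)
})

test_that("dense tiles symmetrize and conserve the selector sum", {
  ref <- hic_reference("chrD", 30)
  tb <- bin_table(ref, 10)
  px <- data.frame(bin1_id = c(0, 0), bin2_id = c(0, 2), count = c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".cool")
  create_cooler(f, tb, px)
  cf <- open_contacts(f)
  d <- selector_to_dense(fetch(cf, "chrD"))
  expect_equal(d$matrix, matrix(c(1, 0, 2, 0, 0, 0, 2, 0, 0), 3, byrow = TRUE))
  # empty region is all zero
  expect_true(all(selector_to_dense(fetch(cf, "chrD:10-20"))$matrix == 0))
  # symmetric tile sum counts off-diagonal pixels twice
  st <- selector_stats(fetch(cf, "chrD"))
  offdiag <- sum(px$count[px$bin1_id != px$bin2_id])
  expect_equal(sum(d$matrix), st$sum + offdiag)
  expect_error(selector_to_dense(fetch(cf, "chrD"), max_elements = 4),
               "selector_to_coo")
})

test_that("dense tiles mark masked bins NaN under normalization", {
  tb <- tiny_table()
  f <- withr::local_tempfile(fileext = ".cool")
  create_cooler(f, tb, tiny_pixels())
  cooler_write_weights(f, norm_weights(c(NaN, 1, 1, 1), "multiplicative", "weight"))
  cf <- open_contacts(f)
  d <- selector_to_dense(fetch(cf, "chr1", normalization = "weight"))
  expect_true(all(is.nan(d$matrix[1, ])))
  expect_true(all(is.nan(d$matrix[, 1])))
  expect_equal(d$matrix[2, 2], 0)            # plain zero where bins are fine
})

test_that("selector statistics equal those computed from the triplets", {
  fx <- shared_fixture()
  cf <- open_contacts(fx$cool)
  sel <- fetch(cf, "chrS1", "chrS2")
  st <- selector_stats(sel)
  coo <- selector_to_coo(sel)
  expect_equal(st$nnz, length(coo$counts))
  expect_equal(st$sum, sum(coo$counts))
  expect_equal(st$min, min(coo$counts))
  expect_equal(st$max, max(coo$counts))
  # empty selector: a bin pair the tiny fixture leaves unpopulated
  tf <- withr::local_tempfile(fileext = ".cool")
  create_cooler(tf, tiny_table(), tiny_pixels())
  st0 <- selector_stats(fetch(open_contacts(tf), "chr1:10-20"))
  expect_equal(st0$nnz, 0)
  expect_equal(st0$sum, 0)
  expect_null(st0$min)
})

test_that("chunked traversal bounds the rows held in memory", {
  fx <- shared_fixture()
  for (file in list(open_contacts(fx$cool), open_contacts(fx$hic, 1e4))) {
    sel <- fetch(file)
    it <- selector_chunks(sel, chunk_rows = 8L)
    total <- 0
    repeat {
      px <- it()
      if (is.null(px)) break
      total <- total + sum(px$count)
    }
    meter <- attr(it, "meter")
    expect_lte(meter$peak_rows, 8L)
    expect_gt(meter$chunks, 1L)
    expect_equal(total, sum(fx$pixels$count))
  }
})

test_that("transposed range pairs are answered canonically and flagged", {
  fx <- shared_fixture()
  cf <- open_contacts(fx$cool)
  a <- fetch(cf, "chrS1", "chrS2")
  b <- fetch(cf, "chrS2", "chrS1")
  expect_false(a$transposed)
  expect_true(b$transposed)
  expect_same_pixels(selector_pixels(a), selector_pixels(b))
})

test_that("both backends answer randomized queries identically", {
  fx <- shared_fixture()
  cf <- open_contacts(fx$cool)
  hf <- open_contacts(fx$hic, 1e4)
  ref <- fx$table$reference
  set.seed(99)
  for (i in 1:100) {
    ci <- sample(nrow(ref), 2, replace = TRUE)
    rs <- lapply(ci, function(k) {
      a <- sort(sample.int(ref$length[k], 2)); genomic_range(ref$name[k], a[1] - 1, a[2])
    })
    norm <- sample(c(NA, "NONE"), 1)
    pa <- selector_pixels(fetch(cf, rs[[1]], rs[[2]]))
    pb <- selector_pixels(fetch(hf, rs[[1]], rs[[2]]))
    expect_same_pixels(pa, pb)
  }
})
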