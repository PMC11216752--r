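# Ingestion with spill chunks, k-way merging, coarsening, zoomify ladders,
# conversion round trips and whole-file validation.

test_that("loading aggregates duplicate bins and verifies sorted input", {
  tb <- tiny_table()
  lines <- c("## pairs format v1.0", "#chromsize: chr1 25", "#chromsize: chr2 10",
             "a\tchr1\t1\tchr1\t12\t+\t+",    # bins (0,1)
             "b\tchr1\t14\tchr1\t3\t+\t+",    # bins (0,1) swapped ends
             "c\tchr1\t22\tchr2\t5\t+\t+")    # bins (2,3)
  px <- load_pixels(lines, tb, "pairs")
  expect_equal(px, data.frame(bin1_id = c(0, 2), bin2_id = c(1, 3),
                              count = c(2L, 1L)))
  expect_error(load_pixels(c(lines[1:3], lines[6], lines[4]), tb, "pairs",
                           assume_sorted = TRUE),
               "not sorted.*record")
})

test_that("spill-chunked loading equals in-memory aggregation", {
  fx <- shared_fixture()
  pairs <- simulate_pairs(fx$params)
  path <- withr::local_tempfile(fileext = ".pairs")
  format_pairs(pairs, fx$table$reference, path)
  whole <- load_pixels(path, fx$table, "pairs", chunk_capacity = 1e7)
  for (cap in c(997, 10000)) {
    chunked <- load_pixels(path, fx$table, "pairs", chunk_capacity = cap)
    expect_identical(chunked, whole)
  }
  expect_equal(sum(whole$count), nrow(pairs))   # conservation
  # chunked and unchunked streams produce files with identical dumps
  f1 <- withr::local_tempfile(fileext = ".cool")
  f2 <- withr::local_tempfile(fileext = ".cool")
  create_cooler(f1, fx$table, whole)
  create_cooler(f2, fx$table, load_pixels(path, fx$table, "pairs",
                                          chunk_capacity = 1231))
  expect_identical(format_pixels(cooler_pixel_slab(open_cooler(f1)), "coo"),
                   format_pixels(cooler_pixel_slab(open_cooler(f2)), "coo"))
})

test_that("merging doubles a self-merge and handles disjoint streams", {
  fx <- shared_fixture()
  mg <- merge_streams(list(fx$pixels, fx$pixels), fx$table)
  expect_equal(mg$count, 2 * fx$pixels$count)
  expect_equal(mg$bin1_id, fx$pixels$bin1_id)
  a <- data.frame(bin1_id = c(0, 1), bin2_id = c(0, 1), count = c(1L, 2L))
  b <- data.frame(bin1_id = c(5, 7), bin2_id = c(6, 8), count = c(3L, 4L))
  mab <- merge_streams(list(b, a), fx$table)
  expect_equal(mab$bin1_id, c(0, 1, 5, 7))    # concatenation in sort order
  expect_equal(mab$count, c(1L, 2L, 3L, 4L))
})

test_that("k-way merge equals the concatenate-sort-aggregate oracle", {
  set.seed(5)
  tb <- bin_table(hic_reference("chrM", 1000), 10)
  streams <- lapply(1:5, function(i) {
    n <- sample(50:200, 1)
    b <- t(apply(matrix(sample.int(100, 2 * n, TRUE) - 1, ncol = 2), 1, sort))
    aggregate_pixels(data.frame(bin1_id = b[, 1], bin2_id = b[, 2],
                                count = sample(1:9, n, TRUE)))
  })
  got <- merge_streams(streams, tb)
  oracle <- aggregate_pixels(do.call(rbind, streams))
  expect_equal(got, oracle)
  # mixing integer and real streams promotes to real
  sr <- streams[[1]]; sr$count <- sr$count + 0.5
  expect_type(merge_streams(list(streams[[2]], sr), tb)$count, "double")
  # unsorted stream is rejected
  bad <- streams[[1]][c(2, 1), ]
  expect_error(merge_streams(list(bad), tb), "not sorted")
})

test_that("file-level merge follows the input format and rejects mixed references", {
  fx <- shared_fixture()
  out <- withr::local_tempfile(fileext = ".cool")
  merge_files(c(fx$cool, fx$cool), out)
  merged <- cooler_pixel_slab(open_cooler(out))
  expect_equal(merged$count, 2L * fx$pixels$count)
  outh <- withr::local_tempfile(fileext = ".hic")
  merge_files(c(fx$hic, fx$hic), outh, resolution = 1e4)
  expect_equal(hic_dump(open_hic(outh, 1e4))$count, 2 * fx$pixels$count)
  # different reference is an error, not a union
  other <- withr::local_tempfile(fileext = ".cool")
  tb2 <- bin_table(hic_reference("chrZ", 1e5), 1e4)
  create_cooler(other, tb2, empty_pixels())
  expect_error(merge_files(c(fx$cool, other), withr::local_tempfile(fileext = ".cool")),
               "refusing to merge")
})

test_that("coarsening remaps per chromosome and conserves totals", {
  tb <- bin_table(hic_reference("chr1", 40), 10)
  px <- data.frame(bin1_id = c(0, 2), bin2_id = c(1, 3), count = c(3L, 5L))
  co <- coarsen_pixels(px, tb, 2)
  expect_equal(co$pixels, data.frame(bin1_id = c(0, 1), bin2_id = c(0, 1),
                                     count = c(3L, 5L)))
  expect_equal(co$table$bin_size, 20)
  expect_error(coarsen_pixels(px, tb, 1), ">= 2")
  fx <- shared_fixture()
  co2 <- coarsen_pixels(fx$pixels, fx$table, 4)
  expect_equal(sum(co2$pixels$count), sum(fx$pixels$count))
})

test_that("coarsening never crosses chromosome boundaries", {
  # chr1 has 3 fine bins; with k = 2 its last bin must stay in chr1's
  # second coarse bin, not bleed into chr2's first
  tb <- tiny_table()
  px <- data.frame(bin1_id = 2, bin2_id = 3, count = 7L)   # chr1 tail x chr2 head
  co <- coarsen_pixels(px, tb, 2)
  b <- bins_df(co$table)
  expect_equal(b$chrom[co$pixels$bin1_id + 1], "chr1")
  expect_equal(b$chrom[co$pixels$bin2_id + 1], "chr2")
  expect_equal(co$pixels$bin1_id, 1)
  expect_equal(co$pixels$bin2_id, 2)
})

test_that("zoomify ladders recurse through divisors and match direct coarsening", {
  fx <- shared_fixture()
  out <- withr::local_tempfile(fileext = ".mcool")
  zoomify(fx$cool, out, c(2e4, 4e4))
  expect_equal(mcool_resolutions(out), c(1e4, 2e4, 4e4))
  via_ladder <- cooler_pixel_slab(open_cooler(sprintf("%s::/resolutions/40000", out)))
  direct <- coarsen_pixels(fx$pixels, fx$table, 4)$pixels
  expect_same_pixels(via_ladder, direct)
  expect_error(zoomify(fx$cool, withr::local_tempfile(fileext = ".mcool"), 2.5e4),
               "not a multiple")
})

test_that("the default ladder is {1,2,5}x10^k multiples of the base", {
  expect_equal(default_ladder(1000),
               c(1000, 2000, 5000, 1e4, 2e4, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6, 5e6, 1e7))
  # a base not dividing any {1,2,5}x10^k value keeps only itself
  expect_equal(default_ladder(3000), 3000)
  expect_equal(default_ladder(2500), c(2500, 5000, 1e4, 2e4, 5e4, 1e5, 2e5,
                                       5e5, 1e6, 2e6, 5e6, 1e7))
})

test_that("conversion round trips preserve every resolution", {
  fx <- shared_fixture()
  co <- coarsen_pixels(fx$pixels, fx$table, 2)
  mc <- withr::local_tempfile(fileext = ".mcool")
  create_mcool(mc, fx$table, stats::setNames(list(fx$pixels, co$pixels),
                                             c("10000", "20000")))
  hic <- withr::local_tempfile(fileext = ".hic")
  mc2 <- withr::local_tempfile(fileext = ".mcool")
  convert(mc, hic)
  convert(hic, mc2)
  for (r in c(1e4, 2e4)) {
    a <- contacts_dump(open_contacts(mc, r))
    b <- contacts_dump(open_contacts(hic, r))
    d <- contacts_dump(open_contacts(mc2, r))
    expect_same_pixels(a, b)
    expect_same_pixels(a, d)
  }
  # .cool -> .hic -> .cool identity
  h2 <- withr::local_tempfile(fileext = ".hic")
  c2 <- withr::local_tempfile(fileext = ".cool")
  convert(fx$cool, h2)
  convert(h2, c2)
  expect_same_pixels(cooler_pixel_slab(open_cooler(c2)), fx$pixels)
  expect_error(convert(fx$cool, "out.xyz"), "unknown output format")
  expect_error(convert(fx$cool, withr::local_tempfile(fileext = ".hic"),
                       resolutions = 123), "not in")
})

test_that("converting .hic imports stored normalization vectors as divisive columns", {
  tb <- tiny_table()
  f <- withr::local_tempfile(fileext = ".hic")
  write_hic_v8(f, tb, list(`10` = tiny_pixels()),
               norms = list(list(name = "KR", chrom = "chr1", resolution = 10,
                                 values = c(2, 4, 1)),
                            list(name = "KR", chrom = "chr2", resolution = 10,
                                 values = 3)))
  out <- withr::local_tempfile(fileext = ".cool")
  convert(f, out)
  h <- open_cooler(out)
  expect_true("KR" %in% h$weight_names)
  kr <- cooler_read_weights(h, "KR")
  expect_equal(kr$kind, "divisive")
  expect_equal(kr$values, c(2, 4, 1, 3))
})

test_that("whole-file validation localizes damage to its group", {
  fx <- shared_fixture()
  expect_true(validate_file(fx$cool)$ok)
  expect_true(validate_file(fx$hic)$ok)
  # truncated .hic
  ft <- withr::local_tempfile(fileext = ".hic")
  raw <- readBin(fx$hic, raw(), n = file.size(fx$hic))
  writeBin(raw[1:200], ft)
  expect_false(validate_file(ft)$ok)
  # .mcool with one corrupted resolution names the group
  mc <- withr::local_tempfile(fileext = ".mcool")
  co <- coarsen_pixels(fx$pixels, fx$table, 2)
  create_mcool(mc, fx$table, stats::setNames(list(fx$pixels, co$pixels),
                                             c("10000", "20000")))
  nb2 <- co$table$n_bins
  rhdf5::h5write(rev(as.integer(rhdf5::h5read(mc, "/resolutions/20000/indexes/bin1_offset"))),
                 mc, "/resolutions/20000/indexes/bin1_offset")
  rep <- validate_file(mc)
  expect_false(rep$ok)
  expect_true(any(grepl("/resolutions/20000", rep$violations)))
  expect_false(any(grepl("/resolutions/10000", rep$violations)))
})
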