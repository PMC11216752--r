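#' Seeded synthetic Hi-C data
#'
#' Generators for references, read pairs with a power-law distance decay,
#' and complete on-disk fixture sets in every supported format. Contact
#' probability between loci at genomic distance s (in bins) falls off as
#' `(1 + s)^-alpha`; the `1 + s` shift avoids the s = 0 singularity while
#' keeping self-interactions possible. All generators are pure functions
#' of `(seed, params)`.
#'
#' @name synthetic_data
NULL

#' Simulation parameter set
#'
#' Defaults describe a desk-scale profile: 3 chromosomes of 1-5 Mbp,
#' 10 kbp bins and 1e5 pairs, small enough that every downstream test runs
#' in seconds yet large enough to populate thousands of matrix bins.
#'
#' @param seed RNG seed; every generator output is a pure function of it.
#' @param n_chroms Number of chromosomes (named chrS1, chrS2, ...).
#' @param chrom_range Chromosome length range in bp.
#' @param bin_size Bin width in bp.
#' @param n_pairs Total read pairs to simulate.
#' @param p_cis Probability that a pair is intra-chromosomal.
#' @param alpha Distance-decay exponent (contact probability proportional
#'   to `(1 + s)^-alpha` for distance s in bins).
#' @param count_type `"int"` or `"float"` fixture counts.
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L, n_chroms = 3L, chrom_range = c(1e6, 5e6),
                      bin_size = 1e4, n_pairs = 1e5, p_cis = 0.7, alpha = 1,
                      count_type = c("int", "float")) {
  count_type <- match.arg(count_type)
  stopifnot(p_cis >= 0, p_cis <= 1, alpha >= 0, n_pairs >= 0, n_chroms >= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_range = as.numeric(chrom_range), bin_size = as.numeric(bin_size),
                 n_pairs = as.numeric(n_pairs), p_cis = p_cis, alpha = alpha,
                 count_type = count_type),
            class = "sim_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a deterministic synthetic reference
#'
#' @param params A [sim_params()].
#' @return A [hic_reference()] with chromosomes chrS1..chrSn and lengths
#'   drawn uniformly from `params$chrom_range`.
#' @export
make_reference <- function(params) {
  with_seed(params$seed, {
    lens <- round(stats::runif(params$n_chroms, params$chrom_range[1],
                               params$chrom_range[2]))
    hic_reference(paste0("chrS", seq_len(params$n_chroms)), lens)
  })
}

sample_decay_distance <- function(n, max_s, alpha, u = stats::runif(n)) {
  # discrete law P(s) ~ (1+s)^-alpha on s = 0..max_s, via inverse CDF
  s <- 0:max_s
  w <- (1 + s)^(-alpha)
  cdf <- cumsum(w) / sum(w)
  findInterval(u, cdf) # 0-based distance
}

#' Simulate read pairs with distance decay
#'
#' A pair is cis with probability `p_cis`. Cis pairs pick a chromosome
#' proportionally to its length, a bin distance s from the truncated
#' `(1 + s)^-alpha` law, then an anchor bin uniform among those leaving
#' the mate inside the chromosome; positions are uniform within their
#' bins. Trans pairs place both ends uniformly on two distinct
#' chromosomes.
#'
#' @param params A [sim_params()].
#' @param reference A [hic_reference()] (defaults to
#'   [make_reference()]`(params)`).
#' @return Pairs data.frame (`chrom1, pos1, chrom2, pos2, strand1,
#'   strand2, readID`), deterministic per seed.
#' @export
simulate_pairs <- function(params, reference = make_reference(params)) {
  tb <- bin_table(reference, params$bin_size)
  n <- params$n_pairs
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      strand1 = character(), strand2 = character(),
                      readID = character())
  if (n == 0) return(empty)
  with_seed(params$seed + 1L, {
    cis <- stats::runif(n) < params$p_cis
    chrom1 <- character(n); pos1 <- numeric(n)
    chrom2 <- character(n); pos2 <- numeric(n)
    # --- cis ---
    nc <- sum(cis)
    if (nc > 0) {
      ci <- sample.int(nrow(reference), nc, replace = TRUE,
                       prob = reference$length)
      nbins <- tb$chrom_bins[ci]
      s <- sample_decay_distance(nc, max(nbins) - 1, params$alpha)
      s <- pmin(s, nbins - 1)              # truncate at chromosome extent
      a <- floor(stats::runif(nc) * (nbins - s))   # anchor bin, mate stays inside
      bs <- params$bin_size
      L <- reference$length[ci]
      p1 <- pmin(a * bs + floor(stats::runif(nc) * bs), L - 1)
      p2 <- pmin((a + s) * bs + floor(stats::runif(nc) * bs), L - 1)
      chrom1[cis] <- reference$name[ci]; chrom2[cis] <- reference$name[ci]
      pos1[cis] <- p1; pos2[cis] <- p2
    }
    # --- trans ---
    nt <- n - nc
    if (nt > 0) {
      if (nrow(reference) < 2L)
        stop("trans pairs require at least two chromosomes (lower p_cis?)")
      ca <- sample.int(nrow(reference), nt, replace = TRUE)
      shift <- sample.int(nrow(reference) - 1L, nt, replace = TRUE)
      cb <- 1L + (ca - 1L + shift) %% nrow(reference)  # distinct from ca
      pos1[!cis] <- floor(stats::runif(nt) * reference$length[ca])
      pos2[!cis] <- floor(stats::runif(nt) * reference$length[cb])
      chrom1[!cis] <- reference$name[ca]; chrom2[!cis] <- reference$name[cb]
    }
    data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
               strand1 = sample(c("+", "-"), n, replace = TRUE),
               strand2 = sample(c("+", "-"), n, replace = TRUE),
               readID = sprintf("r%06d", seq_len(n)), stringsAsFactors = FALSE)
  })
}

#' Simulated sorted pixel matrix
#'
#' Convenience wrapper: simulate pairs, bin and aggregate them. Float
#' fixtures scale each count by a deterministic non-integer factor so
#' real-count code paths are exercised.
#'
#' @param params A [sim_params()].
#' @param reference Optional [hic_reference()].
#' @return list with `table` and sorted `pixels`.
#' @export
simulate_matrix <- function(params, reference = make_reference(params)) {
  tb <- bin_table(reference, params$bin_size)
  px <- aggregate_pixels(pairs_to_pixels(simulate_pairs(params, reference), tb))
  if (params$count_type == "float") px$count <- px$count * 0.5
  else px$count <- as.integer(px$count)
  list(table = tb, pixels = px)
}

#' Write a complete fixture set in every supported format
#'
#' Emits 4DN pairs text, `.cool`, `.mcool` (a 2-step ladder), `.hic` v8,
#' `.scool` (pairs split into pseudo-cells) and a plain-text COO dump per
#' matrix file as the brute-force oracle, plus a tab-separated manifest
#' with per-file checksums.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if absent).
#' @return data.frame manifest: `name`, `path`, `md5`.
#' @export
build_fixture_set <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(params)
  pairs <- simulate_pairs(params, ref)
  m <- simulate_matrix(params, ref)
  paths <- c(pairs = file.path(dir, "sim.pairs"),
             cool = file.path(dir, "sim.cool"),
             mcool = file.path(dir, "sim.mcool"),
             hic = file.path(dir, "sim.hic"),
             scool = file.path(dir, "sim.scool"),
             dump_cool = file.path(dir, "sim.cool.dump.txt"),
             dump_hic = file.path(dir, "sim.hic.dump.txt"))
  format_pairs(pairs, ref, paths["pairs"])
  if (file.exists(paths["cool"])) unlink(paths["cool"])
  create_cooler(paths["cool"], m$table, m$pixels)
  co <- coarsen_pixels(m$pixels, m$table, 2L)
  streams <- stats::setNames(list(m$pixels, co$pixels),
                             sprintf("%.0f", c(params$bin_size, params$bin_size * 2)))
  create_mcool(paths["mcool"], m$table, streams)
  write_hic_v8(paths["hic"], m$table, streams[1])
  # pseudo-cells: pairs round-robin over 4 cells
  cell_of <- rep_len(seq_len(4L), nrow(pairs))
  cells <- lapply(split(seq_len(nrow(pairs)), cell_of), function(i)
    aggregate_pixels(pairs_to_pixels(pairs[i, , drop = FALSE], m$table)))
  names(cells) <- sprintf("cell%d", seq_along(cells))
  create_scool(paths["scool"], m$table, cells)
  writeLines(format_pixels(cooler_pixel_slab(open_cooler(paths[["cool"]])),
                           "coo"), paths["dump_cool"])
  writeLines(format_pixels(hic_dump(open_hic(paths[["hic"]], params$bin_size)),
                           "coo"), paths["dump_hic"])
  manifest <- data.frame(name = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
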