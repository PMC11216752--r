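#' Building-block operations: ingestion, merging, coarsening, conversion
#'
#' Out-of-core ingestion sorts and aggregates interaction text in bounded
#' memory by spilling sorted runs to temporary storage and k-way merging
#' them; coarsening and zoomify aggregate matrices to coarser resolutions
#' chromosome-by-chromosome; conversion is a pure stream translation
#' between the Cooler and .hic containers.
#'
#' @name toolkit_ops
NULL

pixel_key <- function(px, nb) px$bin1_id * nb + px$bin2_id

#' K-way merge of sorted pixel streams
#'
#' Streams are consumed chunk-wise; equal `(bin1_id, bin2_id)` keys are
#' summed on the fly, so the output is sorted and duplicate-free. Mixing
#' integer and real streams promotes to real.
#'
#' @param streams List of sorted pixel data.frames or chunk-iterator
#'   functions (NULL when exhausted) sharing one bin table.
#' @param table The shared [bin_table()].
#' @param sink Optional function called with each merged output chunk; when
#'   NULL the merged stream is returned as one data.frame.
#' @return Merged pixel data.frame (invisible NULL when `sink` is given).
#' @export
merge_streams <- function(streams, table, sink = NULL) {
  nb <- table$n_bins
  its <- lapply(streams, as_pixel_chunks)
  n <- length(its)
  bufs <- vector("list", n)
  done <- logical(n)
  last_key <- rep(-1, n)               # sortedness guard per stream
  pull <- function(i) {
    while (!done[i] && (is.null(bufs[[i]]) || nrow(bufs[[i]]) == 0L)) {
      ch <- its[[i]]()
      if (is.null(ch)) { done[i] <<- TRUE; break }
      if (nrow(ch) == 0L) next
      validate_pixels(ch, table)
      k <- pixel_key(ch, nb)
      if (any(diff(c(last_key[i], k)) <= 0))
        stop("input stream ", i, " is not sorted/duplicate-free")
      last_key[i] <<- k[length(k)]
      bufs[[i]] <<- ch
    }
  }
  for (i in seq_len(n)) pull(i)
  out <- list(); carry <- NULL
  emit <- function(px) {
    if (nrow(px) == 0L) return(invisible(NULL))
    if (is.null(sink)) out[[length(out) + 1L]] <<- px else sink(px)
  }
  repeat {
    active <- which(!vapply(bufs, is.null, TRUE) &
                      vapply(bufs, function(b) !is.null(b) && nrow(b) > 0, TRUE))
    if (length(active) == 0L) break
    # keys <= the smallest "buffer tail" of any unexhausted stream are final
    tails <- vapply(active, function(i) {
      k <- pixel_key(bufs[[i]], nb)
      if (done[i]) Inf else k[length(k)]
    }, 0)
    safe <- min(tails)
    chunk <- list()
    for (i in active) {
      k <- pixel_key(bufs[[i]], nb)
      take <- k <= safe
      chunk[[length(chunk) + 1L]] <- bufs[[i]][take, , drop = FALSE]
      bufs[[i]] <- bufs[[i]][!take, , drop = FALSE]
    }
    merged <- aggregate_pixels(do.call(rbind, chunk))
    if (!is.null(carry)) {             # boundary key may continue, hold one row
      if (nrow(merged) && carry$bin1_id == merged$bin1_id[1] &&
          carry$bin2_id == merged$bin2_id[1]) {
        merged$count[1] <- merged$count[1] + carry$count
      } else emit(carry)
      carry <- NULL
    }
    if (nrow(merged)) {
      carry <- merged[nrow(merged), , drop = FALSE]
      emit(merged[-nrow(merged), , drop = FALSE])
    }
    for (i in seq_len(n)) pull(i)
  }
  if (!is.null(carry)) emit(carry)
  if (is.null(sink)) {
    if (length(out) == 0L) return(empty_pixels())
    res <- do.call(rbind, out); rownames(res) <- NULL
    res
  } else invisible(NULL)
}

#' Ingest interaction text into a sorted aggregated pixel stream
#'
#' Unsorted input fills an in-memory buffer up to `chunk_capacity` records,
#' which is then sorted, aggregated and spilled to a temporary run; all
#' runs are k-way merged with on-the-fly aggregation. Pre-sorted input is
#' verified and aggregated in a single pass.
#'
#' @param source Path or lines of the input text.
#' @param table A [bin_table()].
#' @param format `"pairs"`, `"bg2"` or `"coo"`.
#' @param assume_sorted Input already sorted by (bin1_id, bin2_id); an
#'   out-of-order record is an error naming the offending line.
#' @param chunk_capacity Records per in-memory buffer (>= 1).
#' @param one_based Pairs positions are 1-based.
#' @return Sorted, aggregated pixel data.frame.
#' @export
load_pixels <- function(source, table, format = c("pairs", "bg2", "coo"),
                        assume_sorted = FALSE, chunk_capacity = 1e6,
                        one_based = FALSE) {
  format <- match.arg(format)
  stopifnot(chunk_capacity >= 1)
  px <- switch(format,
    pairs = pairs_to_pixels(parse_pairs(source, one_based = one_based)$records, table),
    parse_interaction_text(source, format, table))
  validate_pixels(px, table)
  if (assume_sorted) {
    if (nrow(px) >= 2L) {
      k <- pixel_key(px, table$n_bins)
      bad <- which(diff(k) < 0)
      if (length(bad))
        stop("input not sorted: record ", bad[1] + 1,
             " precedes its predecessor (use assume_sorted = FALSE)")
    }
    return(aggregate_pixels(px))
  }
  n <- nrow(px)
  if (n <= chunk_capacity) return(aggregate_pixels(px))
  runs <- character()
  tmp_prefix <- tempfile(pattern = sprintf("hicbridge-spill-%d-", Sys.getpid()))
  on.exit(unlink(runs), add = TRUE)
  starts <- seq(1, n, by = chunk_capacity)
  for (s in starts) {
    run <- aggregate_pixels(px[s:min(s + chunk_capacity - 1, n), , drop = FALSE])
    f <- sprintf("%s-%03d.rds", tmp_prefix, length(runs) + 1L)
    saveRDS(run, f)
    runs <- c(runs, f)
  }
  merge_streams(lapply(runs, function(f) {
    sent <- FALSE
    function() { if (sent) NULL else { sent <<- TRUE; readRDS(f) } }
  }), table)
}

#' Coarsen a pixel stream by an integer factor
#'
#' Each pixel maps by chromosome-local integer division of its bin index;
#' chromosome boundaries are respected (a bin never crosses into the next
#' chromosome's coarse bins) and colliding targets are summed, so the
#' total count is conserved exactly.
#'
#' @param px Sorted pixel data.frame on `table`.
#' @param table Source [bin_table()].
#' @param k Coarsening factor (>= 2).
#' @return list with `pixels` (sorted, on the coarse table) and `table`
#'   (the `bin_size * k` [bin_table()]).
#' @export
coarsen_pixels <- function(px, table, k) {
  if (k < 2) stop("coarsening factor must be >= 2")
  coarse <- bin_table(table$reference, table$bin_size * k)
  if (nrow(px) == 0L) return(list(pixels = px, table = coarse))
  ci1 <- findInterval(px$bin1_id, table$offsets, left.open = FALSE)
  ci2 <- findInterval(px$bin2_id, table$offsets, left.open = FALSE)
  b1 <- coarse$offsets[ci1] + (px$bin1_id - table$offsets[ci1]) %/% k
  b2 <- coarse$offsets[ci2] + (px$bin2_id - table$offsets[ci2]) %/% k
  out <- aggregate_pixels(data.frame(bin1_id = b1, bin2_id = b2, count = px$count))
  list(pixels = out, table = coarse)
}

#' Default zoomify resolution ladder
#'
#' Multiples of the base among `{1, 2, 5} x 10^k`, capped at 10 Mbp.
#'
#' @param base Base resolution in bp.
#' @param max_res Largest resolution to include.
#' @return Ascending resolutions, starting at `base`.
#' @export
default_ladder <- function(base, max_res = 1e7) {
  nice <- sort(as.vector(outer(c(1, 2, 5), 10^(0:8))))
  cand <- nice[nice > base & nice <= max_res & nice %% base == 0]
  c(base, cand)
}

#' Build a multi-resolution file by recursive coarsening
#'
#' Every target resolution is computed from the largest already-computed
#' divisor (not always from base), which is equivalent to direct
#' coarsening because integer aggregation is associative.
#'
#' @param input Path/URI of a single-resolution source (.cool or .hic).
#' @param output Output path; `.mcool` or `.hic` decides the container.
#' @param resolutions Target resolutions; NULL for [default_ladder()].
#'   Each must be a multiple of some smaller member (base included).
#' @param resolution Input resolution (for .hic sources storing several).
#' @return `output`, invisibly.
#' @export
zoomify <- function(input, output, resolutions = NULL, resolution = NULL) {
  f <- open_contacts(input, resolution)
  base <- f$resolution
  res <- if (is.null(resolutions)) default_ladder(base)
         else sort(unique(c(base, as.numeric(resolutions))))
  bad <- res[res %% base != 0]
  if (length(bad))
    stop("resolution ", bad[1], " is not a multiple of the base (", base, " bp)")
  px <- list()
  px[[as.character(base)]] <- contacts_dump(f)
  tables <- list(); tables[[as.character(base)]] <- f$table
  for (r in res[res != base]) {
    divs <- res[res < r & r %% res == 0]
    src <- max(divs)                   # largest already-computed divisor
    co <- coarsen_pixels(px[[as.character(src)]], tables[[as.character(src)]],
                         r / src)
    px[[as.character(r)]] <- co$pixels
    tables[[as.character(r)]] <- co$table
  }
  px <- px[order(as.numeric(names(px)))]
  write_multires(output, f$table, px)
  invisible(output)
}

write_multires <- function(output, base_table, streams) {
  ext <- tolower(tools::file_ext(output))
  if (ext == "hic") write_hic_v8(output, base_table, streams)
  else if (ext == "mcool") create_mcool(output, base_table, streams)
  else if (ext == "cool") {
    if (length(streams) != 1L) stop(".cool holds a single resolution")
    if (file.exists(output)) unlink(output)
    create_cooler(output, base_table, streams[[1]])
  } else stop("unknown output format '.", ext, "' (use .cool, .mcool or .hic)")
  invisible(output)
}

#' Merge contact files of one format and resolution
#'
#' @param inputs Paths of two or more files sharing reference and
#'   resolution (the output format follows the inputs).
#' @param output Output path.
#' @param resolution Required when inputs are multi-resolution.
#' @return `output`, invisibly.
#' @export
merge_files <- function(inputs, output, resolution = NULL) {
  if (length(inputs) < 2L) stop("merge needs at least two inputs")
  files <- lapply(inputs, open_contacts, resolution = resolution)
  tb <- files[[1]]$table
  for (f in files[-1]) {
    if (!same_bin_table(f$table, tb))
      stop("bin tables differ between ", inputs[1], " and ", f$path,
           "; refusing to merge")
  }
  merged <- merge_streams(lapply(files, contacts_dump), tb)
  write_multires(output, tb, stats::setNames(list(merged),
                                             sprintf("%.0f", tb$bin_size)))
  invisible(output)
}

#' Convert between Cooler-family and .hic containers
#'
#' A pure stream translation: bin tables are re-emitted and raw pixels
#' copied per resolution, guaranteeing dump equality with the source.
#' Converting .hic to Cooler imports stored normalization vectors as
#' divisive weight columns; converting to .hic writes version 8 with the
#' implicit NONE normalization only. Vectors are copied, never recomputed.
#'
#' @param input Source path (.cool/.mcool/.hic).
#' @param output Destination path; extension selects the format.
#' @param resolutions Subset of resolutions to convert (default: all
#'   available, or the single resolution of a .cool).
#' @return `output`, invisibly.
#' @export
convert <- function(input, output, resolutions = NULL) {
  in_kind <- sniff_format(input)
  out_ext <- tolower(tools::file_ext(output))
  if (!out_ext %in% c("cool", "mcool", "hic"))
    stop("unknown output format '.", out_ext, "'")
  avail <- if (in_kind == "hic")
    parse_hic_header(readBin(input, raw(), n = file.size(input)))$resolutions
  else if (h5_group_exists(input, "/resolutions")) mcool_resolutions(input)
  else open_cooler(input)$table$bin_size
  res <- if (is.null(resolutions)) avail else as.numeric(resolutions)
  missing <- setdiff(res, avail)
  if (length(missing))
    stop("resolution ", missing[1], " not in ", input, "; available: ",
         paste(avail, collapse = ", "))
  res <- sort(res)
  single_cool <- in_kind == "hdf5" && !h5_group_exists(input, "/resolutions")
  streams <- list(); norm_cols <- list(); base_table <- NULL
  for (r in res) {
    f <- open_contacts(input, if (single_cool) NULL else r)
    streams[[sprintf("%.0f", r)]] <- contacts_dump(f)
    if (is.null(base_table)) base_table <- f$table
    if (in_kind == "hic" && out_ext %in% c("cool", "mcool")) {
      for (nm in setdiff(f$norms, "NONE"))
        norm_cols[[sprintf("%.0f", r)]][[nm]] <-
          tryCatch(hic_read_norm(f$handle, nm), error = function(e) NULL)
    }
  }
  if (out_ext == "cool" && length(res) != 1L)
    stop("a .cool output holds one resolution; pick one with resolutions=")
  if (file.exists(output)) unlink(output)
  write_multires(output, base_table, streams)
  for (r in names(norm_cols)) {
    uri <- if (out_ext == "cool") output else sprintf("%s::/resolutions/%s", output, r)
    for (nm in names(norm_cols[[r]])) {
      w <- norm_cols[[r]][[nm]]
      if (!is.null(w)) cooler_write_weights(uri, w, name = nm)
    }
  }
  invisible(output)
}

#' Structural validation of any supported contact file
#'
#' Dispatches to the Cooler or .hic structural checks; multi-resolution
#' and single-cell containers are validated group by group.
#'
#' @param path File path.
#' @return list with `ok` and `violations` (each violation names its
#'   group).
#' @export
validate_file <- function(path) {
  if (!file.exists(path)) return(list(ok = FALSE, violations = "no such file"))
  kind <- sniff_format(path)
  if (kind == "hic") return(validate_hic(path))
  if (kind != "hdf5")
    return(list(ok = FALSE, violations = "unrecognized file signature"))
  attrs <- rhdf5::h5readAttributes(path, "/")
  fmt <- if (is.null(attrs$format)) "" else as.character(attrs$format)
  if (fmt == MCOOL_FORMAT || h5_group_exists(path, "/resolutions")) {
    v <- character()
    for (r in mcool_resolutions(path)) {
      rep <- validate_cooler(sprintf("%s::/resolutions/%.0f", path, r))
      if (!rep$ok)
        v <- c(v, sprintf("/resolutions/%.0f: %s", r, rep$violations))
    }
    return(list(ok = length(v) == 0L, violations = v))
  }
  if (fmt == SCOOL_FORMAT) {
    v <- character()
    for (cell in scool_cells(path)) {
      rep <- validate_cooler(sprintf("%s::/cells/%s", path, cell))
      if (!rep$ok) v <- c(v, sprintf("/cells/%s: %s", cell, rep$violations))
    }
    return(list(ok = length(v) == 0L, violations = v))
  }
  validate_cooler(path)
}
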