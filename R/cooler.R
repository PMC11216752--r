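#' Native Cooler (.cool / .mcool / .scool) reader and writer
#'
#' Implements the Cooler HDF5 schema, format version 3: groups
#' `chroms{name,length}`, `bins{chrom,start,end,...}`,
#' `pixels{bin1_id,bin2_id,count}` and the CSR indexes
#' `indexes/chrom_offset` and `indexes/bin1_offset` (a prefix sum over
#' per-row pixel occupancy). Storage is symmetric-upper: only pixels with
#' `bin1_id <= bin2_id` are kept. URIs use the `path::/group` syntax.
#'
#' @name cooler
NULL

COOLER_FORMAT <- "HDF5::Cooler"
MCOOL_FORMAT <- "HDF5::MCOOL"
SCOOL_FORMAT <- "HDF5::SCOOL"
COOLER_VERSION <- 3L
GENERATED_BY <- "hicbridge-0.1.0"
.h5chunk <- 65536L   # records per HDF5 chunk, gzip level 6; not format-visible

#' Split a Cooler URI into file path and internal group
#' @param uri `"path"` or `"path::/group"`.
#' @return list with `path` and `group` (default `"/"`).
#' @export
cooler_parse_uri <- function(uri) {
  parts <- strsplit(uri, "::", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("malformed Cooler URI: ", uri)
  group <- if (length(parts) == 2L) parts[2] else "/"
  if (!startsWith(group, "/")) group <- paste0("/", group)
  list(path = parts[1], group = group)
}

h5_exists <- function(path, name) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::H5Lexists(fid, name)
}

h5_group_exists <- function(path, group) {
  if (group %in% c("", "/")) return(TRUE)
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::H5Lexists(fid, group)
}

h5_ls_group <- function(path, group) {
  df <- rhdf5::h5ls(path, recursive = TRUE)
  gg <- sub("/+$", "", group); if (gg == "") gg <- "/"
  df[df$group == gg, "name"]
}

h5_write_attrs <- function(path, group, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  oid <- if (group %in% c("", "/")) rhdf5::H5Gopen(fid, "/") else rhdf5::H5Gopen(fid, group)
  on.exit(rhdf5::H5Gclose(oid), add = TRUE, after = FALSE)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (is.logical(v)) v <- as.integer(v)   # HDF5 has no native bool here
    rhdf5::h5writeAttribute(v, oid, nm)
  }
  invisible(NULL)
}

h5_make_groups <- function(path, group) {
  # create intermediate groups of an absolute group path as needed
  if (group %in% c("", "/")) return(invisible(NULL))
  parts <- strsplit(sub("^/", "", group), "/", fixed = TRUE)[[1]]
  acc <- ""
  for (p in parts) {
    acc <- paste0(acc, "/", p)
    if (!h5_group_exists(path, acc)) rhdf5::h5createGroup(path, acc)
  }
  invisible(NULL)
}

g_path <- function(group, ...) {
  base <- sub("/+$", "", group)
  paste0(base, "/", paste(c(...), collapse = "/"))
}

as_pixel_chunks <- function(pixels, chunk = 1e6) {
  # normalize data.frame | function() -> chunk | list of data.frames into an iterator
  if (is.function(pixels)) return(pixels)
  if (is.data.frame(pixels)) {
    done <- FALSE
    return(function() {
      if (done) return(NULL)
      done <<- TRUE
      pixels
    })
  }
  if (is.list(pixels)) {
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(pixels)) NULL else pixels[[i]]
    })
  }
  stop("pixels must be a data.frame, a list of data.frames, or a chunk iterator function")
}

#' Create a single-resolution Cooler group
#'
#' Writes the full Cooler v3 schema in a single pass over the pixel stream
#' with bounded memory. The stream must be sorted by `(bin1_id, bin2_id)`
#' with duplicates pre-aggregated; violations abort the write and remove the
#' partially written group.
#'
#' @param uri Target `path::/group` URI (plain path writes to the root).
#' @param table A [bin_table()].
#' @param pixels Pixel data.frame, list of chunks, or chunk-iterator
#'   function returning data.frames (NULL when exhausted).
#' @param metadata Named list of extra root attributes.
#' @param count_type `"int"`, `"float"`, or NULL to infer from the data.
#' @return A [open_cooler()] handle on the new group.
#' @export
create_cooler <- function(uri, table, pixels, metadata = list(), count_type = NULL) {
  loc <- cooler_parse_uri(uri)
  if (!file.exists(loc$path)) rhdf5::h5createFile(loc$path)
  if (loc$group != "/" && h5_group_exists(loc$path, loc$group))
    stop("group already exists: ", uri)
  h5_make_groups(loc$path, loc$group)
  ok <- FALSE
  on.exit({
    rhdf5::h5closeAll()
    if (!ok) {
      if (loc$group == "/") unlink(loc$path) else
        try(rhdf5::h5delete(loc$path, loc$group), silent = TRUE)
    }
  })
  writer <- cooler_group_writer(loc$path, loc$group, table, count_type)
  it <- as_pixel_chunks(pixels)
  repeat {
    chunk <- it()
    if (is.null(chunk)) break
    writer$append(chunk)
  }
  writer$finish(metadata)
  ok <- TRUE
  on.exit(NULL)
  rhdf5::h5closeAll()
  open_cooler(uri)
}

# Incremental writer for one cooler group; append() enforces global sort
# order and id bounds, finish() writes indexes and attributes.
cooler_group_writer <- function(path, group, table, count_type = NULL,
                                write_bins = TRUE) {
  ref <- table$reference
  if (write_bins) {
    rhdf5::h5createGroup(path, g_path(group, "chroms"))
    rhdf5::h5write(ref$name, path, g_path(group, "chroms/name"))
    rhdf5::h5write(as.integer(ref$length), path, g_path(group, "chroms/length"))
    b <- bins_df(table)
    rhdf5::h5createGroup(path, g_path(group, "bins"))
    rhdf5::h5write(as.integer(match(b$chrom, ref$name) - 1L), path, g_path(group, "bins/chrom"))
    rhdf5::h5write(as.integer(b$start), path, g_path(group, "bins/start"))
    rhdf5::h5write(as.integer(b$end), path, g_path(group, "bins/end"))
  }
  rhdf5::h5createGroup(path, g_path(group, "pixels"))
  rhdf5::h5createGroup(path, g_path(group, "indexes"))

  state <- new.env(parent = emptyenv())
  state$nnz <- 0
  state$sum <- 0
  state$rowcount <- numeric(table$n_bins)
  state$last1 <- -1; state$last2 <- -1
  state$ctype <- count_type
  state$created <- FALSE

  ensure_dsets <- function(ctype) {
    ck <- .h5chunk
    for (col in c("bin1_id", "bin2_id"))
      rhdf5::h5createDataset(path, g_path(group, "pixels", col), dims = 0,
                             maxdims = rhdf5::H5Sunlimited(), storage.mode = "integer",
                             chunk = ck, level = 6)
    rhdf5::h5createDataset(path, g_path(group, "pixels/count"), dims = 0,
                           maxdims = rhdf5::H5Sunlimited(),
                           storage.mode = if (ctype == "int") "integer" else "double",
                           chunk = ck, level = 6)
    state$created <- TRUE
  }

  append <- function(chunk) {
    if (is.null(chunk) || nrow(chunk) == 0L) return(invisible(NULL))
    b1 <- as.numeric(chunk$bin1_id); b2 <- as.numeric(chunk$bin2_id)
    cnt <- chunk$count
    if (is.null(state$ctype))
      state$ctype <- if (is.integer(cnt) || all(cnt == floor(cnt))) "int" else "float"
    if (!state$created) ensure_dsets(state$ctype)
    if (any(b1 > b2)) stop("lower-triangle pixel in stream (bin1_id > bin2_id)")
    if (any(b1 < 0) || any(b2 >= table$n_bins)) stop("pixel bin id out of range")
    key <- c(state$last1 * table$n_bins + state$last2, b1 * table$n_bins + b2)
    if (any(diff(key) <= 0))
      stop("pixel stream is not strictly sorted by (bin1_id, bin2_id) ",
           "(unsorted or duplicate keys)")
    state$last1 <- b1[length(b1)]; state$last2 <- b2[length(b2)]
    n0 <- state$nnz; n1 <- n0 + length(b1)
    idx <- list(seq(n0 + 1, n1))
    for (col in c("bin1_id", "bin2_id", "count")) {
      ds <- g_path(group, "pixels", col)
      rhdf5::h5set_extent(path, ds, n1)
    }
    rhdf5::h5write(as.integer(b1), path, g_path(group, "pixels/bin1_id"), index = idx)
    rhdf5::h5write(as.integer(b2), path, g_path(group, "pixels/bin2_id"), index = idx)
    cnt_out <- if (state$ctype == "int") as.integer(cnt) else as.numeric(cnt)
    rhdf5::h5write(cnt_out, path, g_path(group, "pixels/count"), index = idx)
    state$nnz <- n1
    state$sum <- state$sum + sum(as.numeric(cnt))
    tab <- tabulate(b1 + 1, nbins = table$n_bins)
    state$rowcount <- state$rowcount + tab
    invisible(NULL)
  }

  finish <- function(metadata = list()) {
    if (!state$created) {
      if (is.null(state$ctype)) state$ctype <- "int"
      ensure_dsets(state$ctype)
    }
    rhdf5::h5write(as.integer(table$offsets), path, g_path(group, "indexes/chrom_offset"))
    bin1_offset <- c(0, cumsum(state$rowcount))
    rhdf5::h5write(as.integer(bin1_offset), path, g_path(group, "indexes/bin1_offset"))
    attrs <- list(`format` = COOLER_FORMAT, `format-version` = COOLER_VERSION,
                  `bin-type` = "fixed", `bin-size` = as.integer(table$bin_size),
                  `nbins` = as.integer(table$n_bins), `nchroms` = nrow(ref),
                  `nnz` = as.integer(state$nnz),
                  `sum` = if (state$ctype == "int") as.integer(state$sum) else state$sum,
                  `generated-by` = GENERATED_BY,
                  `storage-mode` = "symmetric-upper",
                  `count-type` = state$ctype)
    attrs[names(metadata)] <- metadata
    h5_write_attrs(path, group, attrs)
    invisible(NULL)
  }
  list(append = append, finish = finish)
}

#' Open a Cooler group read-only
#'
#' @param uri `path` or `path::/group` of a single-resolution Cooler.
#' @return A `cooler_handle` exposing the bin table, attributes and
#'   available normalization-weight names.
#' @export
open_cooler <- function(uri) {
  loc <- cooler_parse_uri(uri)
  if (!file.exists(loc$path)) stop("no such file: ", loc$path)
  if (!h5_group_exists(loc$path, loc$group))
    stop("no such group '", loc$group, "' in ", loc$path)
  attrs <- rhdf5::h5readAttributes(loc$path, loc$group)
  if (is.null(attrs$format) || attrs$format != COOLER_FORMAT) {
    # an .scool cell group holds pixels only; bins live at the container root
    if (!is.null(attrs$format) || !"pixels" %in% h5_ls_group(loc$path, loc$group))
      stop(loc$path, "::", loc$group, " is not a Cooler group (format attribute ",
           if (is.null(attrs$format)) "missing" else paste0("'", attrs$format, "'"), ")")
  }
  if (!is.null(attrs$`format-version`) && attrs$`format-version` > COOLER_VERSION)
    stop("unsupported Cooler format-version: ", attrs$`format-version`)
  bins_group <- if (h5_exists(loc$path, g_path(loc$group, "chroms"))) loc$group else "/"
  name <- as.character(rhdf5::h5read(loc$path, g_path(bins_group, "chroms/name")))
  len <- as.numeric(rhdf5::h5read(loc$path, g_path(bins_group, "chroms/length")))
  ref <- hic_reference(name, len)
  bin_size <- as.numeric(attrs$`bin-size`)
  if (length(bin_size) == 0L || is.na(bin_size)) {
    ba <- rhdf5::h5readAttributes(loc$path, bins_group)
    bin_size <- as.numeric(ba$`bin-size`)
  }
  table <- bin_table(ref, bin_size)
  cols <- h5_ls_group(loc$path, g_path(bins_group, "bins"))
  weight_names <- setdiff(cols, c("chrom", "start", "end"))
  structure(list(uri = uri, path = loc$path, group = loc$group,
                 bins_group = bins_group, table = table, attrs = attrs,
                 weight_names = weight_names,
                 count_type = if (is.null(attrs$`count-type`)) NA_character_
                              else as.character(attrs$`count-type`)),
            class = "cooler_handle")
}

#' @export
print.cooler_handle <- function(x, ...) {
  cat(sprintf("<cooler %s: %.0f bp, %d bins, nnz %s>\n", x$uri, x$table$bin_size,
              x$table$n_bins, format(x$attrs$nnz)), sep = "")
  invisible(x)
}

#' Read the stored pixels of a rectangular bin-id query
#'
#' Uses the `bin1_offset` CSR index so that only rows within `span1` are
#' touched; `bin2_id` is then range-filtered within the row slab.
#'
#' @param handle A [open_cooler()] handle.
#' @param span1,span2 Half-open global bin-id spans `c(first, last)`; NULL
#'   means the full extent.
#' @return Pixel data.frame in `(bin1_id, bin2_id)` order.
#' @export
cooler_pixel_slab <- function(handle, span1 = NULL, span2 = NULL) {
  nb <- handle$table$n_bins
  if (is.null(span1)) span1 <- c(0, nb)
  if (is.null(span2)) span2 <- c(0, nb)
  if (span1[1] < 0 || span1[2] > nb || span2[1] < 0 || span2[2] > nb)
    stop("bin span out of range [0, ", nb, ")")
  if (span1[1] >= span1[2] || span2[1] >= span2[2])
    return(empty_pixels(real = identical(handle$count_type, "float")))
  off <- rhdf5::h5read(handle$path, g_path(handle$group, "indexes/bin1_offset"),
                       index = list(seq(span1[1] + 1, span1[2] + 1)))
  lo <- as.numeric(off[1]); hi <- as.numeric(off[length(off)])
  if (hi <= lo) return(empty_pixels(real = identical(handle$count_type, "float")))
  idx <- list(seq(lo + 1, hi))
  b1 <- as.numeric(rhdf5::h5read(handle$path, g_path(handle$group, "pixels/bin1_id"), index = idx))
  b2 <- as.numeric(rhdf5::h5read(handle$path, g_path(handle$group, "pixels/bin2_id"), index = idx))
  cnt <- rhdf5::h5read(handle$path, g_path(handle$group, "pixels/count"), index = idx)
  keep <- b2 >= span2[1] & b2 < span2[2]
  data.frame(bin1_id = b1[keep], bin2_id = b2[keep], count = cnt[keep])
}

#' Read a stored normalization-weight column
#'
#' @param handle A [open_cooler()] handle.
#' @param name Column name under `bins/` (e.g. `"weight"`).
#' @return A [norm_weights()]; Cooler-native vectors are multiplicative
#'   unless the column carries a divisive tag (vectors imported from .hic).
#' @export
cooler_read_weights <- function(handle, name) {
  if (!name %in% handle$weight_names)
    stop("no weight column '", name, "'; available: ",
         if (length(handle$weight_names)) paste(handle$weight_names, collapse = ", ")
         else "(none)")
  ds <- g_path(handle$bins_group, "bins", name)
  v <- as.numeric(rhdf5::h5read(handle$path, ds))
  at <- rhdf5::h5readAttributes(handle$path, ds)
  kind <- if (!is.null(at$divisive_weights) && as.logical(at$divisive_weights)[1])
    "divisive" else "multiplicative"
  norm_weights(v, kind = kind, name = name)
}

#' Store a normalization-weight column under bins/
#'
#' @param uri Cooler URI (must be writable).
#' @param weights A [norm_weights()].
#' @param name Column name; defaults to the vector's own name.
#' @param metadata Extra column attributes (e.g. ICE convergence info).
#' @export
cooler_write_weights <- function(uri, weights, name = weights$name, metadata = list()) {
  h <- open_cooler(uri)
  if (length(weights$values) != h$table$n_bins)
    stop("weight length ", length(weights$values), " != nbins ", h$table$n_bins)
  ds <- g_path(h$bins_group, "bins", name)
  if (h5_exists(h$path, ds)) rhdf5::h5delete(h$path, ds)
  rhdf5::h5write(as.numeric(weights$values), h$path, ds)
  attrs <- c(list(divisive_weights = weights$kind == "divisive"), metadata)
  fid <- rhdf5::H5Fopen(h$path)
  on.exit({rhdf5::h5closeAll()})
  did <- rhdf5::H5Dopen(fid, ds)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (is.logical(v)) v <- as.integer(v)
    if (length(v)) rhdf5::h5writeAttribute(v, did, nm)
  }
  rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  invisible(uri)
}

#' Create a multi-resolution (.mcool) container
#'
#' @param path Output path.
#' @param table Base-resolution [bin_table()].
#' @param streams Named list: resolution (bp, as name) -> pixel source
#'   accepted by [create_cooler()]. Resolutions must be strictly increasing
#'   multiples of the base (first) resolution.
#' @param metadata Extra attributes for each resolution group.
#' @return `path`, invisibly.
#' @export
create_mcool <- function(path, table, streams, metadata = list()) {
  res <- as.numeric(names(streams))
  if (any(is.na(res))) stop("streams must be named by resolution in bp")
  if (is.unsorted(res, strictly = TRUE)) stop("resolutions must be strictly increasing")
  if (any(res %% res[1] != 0))
    stop("every resolution must be a multiple of the base (", res[1], " bp)")
  if (res[1] != table$bin_size) stop("base resolution does not match bin table")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "/resolutions")
  h5_write_attrs(path, "/", list(format = MCOOL_FORMAT, `format-version` = 2L,
                                 `generated-by` = GENERATED_BY))
  for (i in seq_along(res)) {
    r <- res[i]
    tb <- if (r == table$bin_size) table else bin_table(table$reference, r)
    create_cooler(sprintf("%s::/resolutions/%.0f", path, r), tb, streams[[i]],
                  metadata = metadata)
  }
  invisible(path)
}

#' List the resolutions stored in an .mcool container
#' @param path Path to an .mcool file.
#' @return Ascending numeric vector of resolutions in bp.
#' @export
mcool_resolutions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (!is.null(attrs$format) && attrs$format == COOLER_FORMAT)
    stop(path, " is a single-resolution Cooler; use open_cooler()")
  if (!h5_group_exists(path, "/resolutions"))
    stop(path, " has no /resolutions group; not an .mcool file")
  sort(as.numeric(h5_ls_group(path, "/resolutions")))
}

#' Create a single-cell (.scool) container
#'
#' Bins and chromosomes are stored once at the container root; each cell
#' keeps its own pixels and CSR index under `/cells/<name>`.
#'
#' @param path Output path.
#' @param table Shared [bin_table()].
#' @param cells Named list: cell name -> pixel source ([create_cooler()]
#'   forms). Zero cells is a valid (empty) container.
#' @return `path`, invisibly.
#' @export
create_scool <- function(path, table, cells) {
  if (length(cells) && anyDuplicated(names(cells)))
    stop("duplicate cell name: ", names(cells)[duplicated(names(cells))][1])
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  ref <- table$reference
  rhdf5::h5createGroup(path, "/chroms")
  rhdf5::h5write(ref$name, path, "/chroms/name")
  rhdf5::h5write(as.integer(ref$length), path, "/chroms/length")
  b <- bins_df(table)
  rhdf5::h5createGroup(path, "/bins")
  rhdf5::h5write(as.integer(match(b$chrom, ref$name) - 1L), path, "/bins/chrom")
  rhdf5::h5write(as.integer(b$start), path, "/bins/start")
  rhdf5::h5write(as.integer(b$end), path, "/bins/end")
  rhdf5::h5createGroup(path, "/cells")
  h5_write_attrs(path, "/", list(format = SCOOL_FORMAT, `format-version` = 1L,
                                 `bin-size` = as.integer(table$bin_size),
                                 `bin-type` = "fixed",
                                 `nbins` = as.integer(table$n_bins),
                                 `nchroms` = nrow(ref),
                                 ncells = length(cells),
                                 `generated-by` = GENERATED_BY,
                                 `cell-order` = if (length(cells)) names(cells) else ""))
  h5_write_attrs(path, "/bins", list(`bin-size` = as.integer(table$bin_size)))
  for (nm in names(cells)) {
    grp <- paste0("/cells/", nm)
    rhdf5::h5createGroup(path, grp)
    w <- cooler_group_writer(path, grp, table, write_bins = FALSE)
    it <- as_pixel_chunks(cells[[nm]])
    repeat { ch <- it(); if (is.null(ch)) break; w$append(ch) }
    w$finish()
    # per-cell groups carry Cooler attributes but defer bins to the root
    h5_write_attrs(path, grp, list(format = COOLER_FORMAT))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' List cells of an .scool container in insertion order
#' @param path Path to an .scool file.
#' @return Character vector of cell names.
#' @export
scool_cells <- function(path) {
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$format) || attrs$format != SCOOL_FORMAT)
    stop(path, " is not an .scool container")
  ord <- as.character(attrs$`cell-order`)
  ord[nzchar(ord)]
}

#' Structural validation of a Cooler group
#'
#' Checks every schema invariant: attribute presence and consistency
#' (nbins, nchroms, nnz, sum), strict (bin1_id, bin2_id) pixel ordering,
#' id bounds, and the shape, monotonicity and endpoints of both CSR
#' indexes, including agreement of `bin1_offset` with actual row occupancy.
#'
#' @param uri Cooler URI.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_cooler <- function(uri) {
  v <- character()
  h <- tryCatch(open_cooler(uri), error = function(e) conditionMessage(e))
  if (is.character(h)) return(list(ok = FALSE, violations = paste("unopenable:", h)))
  p <- h$path; g <- h$group
  nb <- h$table$n_bins
  a <- h$attrs
  for (req in c("format", "format-version", "bin-size", "nbins", "nchroms", "nnz", "sum"))
    if (is.null(a[[req]])) v <- c(v, paste0("missing attribute '", req, "'"))
  if (!is.null(a$nbins) && as.numeric(a$nbins) != nb)
    v <- c(v, sprintf("nbins attribute %s != bin table size %d", format(a$nbins), nb))
  if (!is.null(a$nchroms) && as.numeric(a$nchroms) != nrow(h$table$reference))
    v <- c(v, "nchroms attribute inconsistent with chroms table")
  b1 <- as.numeric(rhdf5::h5read(p, g_path(g, "pixels/bin1_id")))
  b2 <- as.numeric(rhdf5::h5read(p, g_path(g, "pixels/bin2_id")))
  cnt <- as.numeric(rhdf5::h5read(p, g_path(g, "pixels/count")))
  if (length(b1)) {
    key <- b1 * nb + b2
    if (any(diff(key) <= 0)) v <- c(v, "pixels not strictly sorted by (bin1_id, bin2_id)")
    if (any(b1 > b2)) v <- c(v, "lower-triangle pixel present")
    if (min(b1) < 0 || max(b2) >= nb) v <- c(v, "pixel bin id out of range")
  }
  if (!is.null(a$nnz) && as.numeric(a$nnz) != length(b1))
    v <- c(v, sprintf("nnz attribute %s != stored pixel count %d", format(a$nnz), length(b1)))
  if (!is.null(a$sum) && abs(as.numeric(a$sum) - sum(cnt)) > 1e-6 * max(1, abs(sum(cnt))))
    v <- c(v, sprintf("sum attribute %s != stored count total %s",
                      format(a$sum), format(sum(cnt))))
  co <- as.numeric(rhdf5::h5read(p, g_path(g, "indexes/chrom_offset")))
  if (length(co) != nrow(h$table$reference) + 1L)
    v <- c(v, "chrom_offset has wrong length")
  if (length(co) && (co[1] != 0 || co[length(co)] != nb || is.unsorted(co)))
    v <- c(v, "chrom_offset endpoints or monotonicity violated")
  bo <- as.numeric(rhdf5::h5read(p, g_path(g, "indexes/bin1_offset")))
  if (length(bo) != nb + 1L) v <- c(v, "bin1_offset has wrong length")
  if (length(bo)) {
    if (any(diff(bo) < 0)) v <- c(v, "index not monotone: bin1_offset decreases")
    if (bo[1] != 0) v <- c(v, "bin1_offset[0] != 0")
    if (bo[length(bo)] != length(b1)) v <- c(v, "bin1_offset tail != nnz")
    expect <- c(0, cumsum(tabulate(b1 + 1, nbins = nb)))
    if (length(bo) == nb + 1L && !isTRUE(all.equal(bo, expect)))
      v <- c(v, "bin1_offset disagrees with pixel row occupancy")
  }
  list(ok = length(v) == 0L, violations = v)
}
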