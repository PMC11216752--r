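#' ICE matrix balancing and expected-profile computation
#'
#' Iterative correction (ICE) equalizes the marginals of the symmetric
#' contact matrix by a per-bin multiplicative weight vector: balanced
#' counts are `A_ij * w_i * w_j`. Poorly covered bins are masked before
#' balancing (minimum-nonzero and MAD-max filters); the first few
#' diagonals, dominated by self-ligation artifacts, are dropped from the
#' marginal computation.
#'
#' @name balancing
NULL

#' ICE parameter set
#'
#' @param mode `"gw"` (all pixels, one solve), `"cis"` (intra-chromosomal,
#'   solved per chromosome) or `"trans"` (inter-chromosomal only).
#' @param tol Convergence tolerance on the variance of rescaled unmasked
#'   marginals.
#' @param max_iter Iteration cap.
#' @param min_nnz Mask bins with fewer nonzero entries than this.
#' @param mad_max Mask bins whose log marginal falls more than this many
#'   median-absolute-deviations below the median log marginal.
#' @param ignore_diags Number of leading diagonals (d = 0, 1, ...) dropped
#'   from marginal computation.
#' @return An `ice_params` list.
#' @export
ice_params <- function(mode = c("gw", "cis", "trans"), tol = 1e-5, max_iter = 500L,
                       min_nnz = 10L, mad_max = 5, ignore_diags = 2L) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(mode = mode, tol = tol, max_iter = as.integer(max_iter),
                 min_nnz = as.integer(min_nnz), mad_max = mad_max,
                 ignore_diags = as.integer(ignore_diags)),
            class = "ice_params")
}

pixel_chrom_pair <- function(px, table) {
  list(ci1 = findInterval(px$bin1_id, table$offsets, left.open = FALSE),
       ci2 = findInterval(px$bin2_id, table$offsets, left.open = FALSE))
}

# marginal-relevant pixel subset: drops the first ignore_diags intra diagonals
drop_ignored_diags <- function(px, table, ignore_diags) {
  if (ignore_diags <= 0L || nrow(px) == 0L) return(px)
  cp <- pixel_chrom_pair(px, table)
  d <- px$bin2_id - px$bin1_id
  px[!(cp$ci1 == cp$ci2 & d < ignore_diags), , drop = FALSE]
}

#' Pre-balancing bin mask
#'
#' @param px Full pixel data.frame of the matrix to balance.
#' @param table A [bin_table()].
#' @param params An [ice_params()].
#' @return Logical vector, TRUE = bin masked (excluded from balancing).
#' @export
compute_bin_mask <- function(px, table, params = ice_params()) {
  nb <- table$n_bins
  nnz <- numeric(nb)
  if (nrow(px)) {
    nnz <- tabulate(px$bin1_id + 1, nbins = nb) +
      tabulate(px$bin2_id[px$bin2_id != px$bin1_id] + 1, nbins = nb)
  }
  mask <- nnz < params$min_nnz
  pxm <- drop_ignored_diags(px, table, params$ignore_diags)
  marg <- numeric(nb)
  if (nrow(pxm)) {
    marg <- marg + rowsum_vec(pxm$bin1_id, pxm$count, nb)
    off <- pxm$bin1_id != pxm$bin2_id
    marg <- marg + rowsum_vec(pxm$bin2_id[off], pxm$count[off], nb)
  }
  mask <- mask | marg <= 0
  lm <- log(marg[!mask])
  if (length(lm)) {
    mad <- stats::mad(lm)
    if (mad > 0)                      # MAD = 0 (e.g. all equal): filter is a no-op
      mask[!mask][lm < stats::median(lm) - params$mad_max * mad] <- TRUE
  }
  mask
}

rowsum_vec <- function(ids, values, nb) {
  out <- numeric(nb)
  if (length(ids)) {
    s <- rowsum(as.numeric(values), ids, reorder = FALSE)
    out[as.numeric(rownames(s)) + 1] <- s[, 1]
  }
  out
}

ice_core <- function(px, table, params, bin_ids = NULL) {
  # bin_ids: 0-based global ids participating (cis mode restricts to one
  # chromosome); weights returned over all n_bins, non-participating = NA
  nb <- table$n_bins
  participate <- rep(TRUE, nb)
  if (!is.null(bin_ids)) participate <- (seq_len(nb) - 1) %in% bin_ids
  mask_local <- compute_bin_mask(px, table, params)
  mask <- mask_local | !participate
  pxm <- drop_ignored_diags(px, table, params$ignore_diags)
  if (nrow(pxm)) {
    keep <- !mask[pxm$bin1_id + 1] & !mask[pxm$bin2_id + 1]
    pxm <- pxm[keep, , drop = FALSE]
  }
  unm <- which(!mask & participate)
  if (length(unm) == 0L)
    stop("no unmasked bins left to balance (filters removed everything)")
  w <- numeric(nb); w[unm] <- 1
  converged <- FALSE; iter <- 0L; variance <- NA_real_; mean_marg <- NA_real_
  b1 <- pxm$bin1_id + 1; b2 <- pxm$bin2_id + 1; cnt <- as.numeric(pxm$count)
  off <- b1 != b2
  repeat {
    iter <- iter + 1L
    bc <- cnt * w[b1] * w[b2]
    m <- rowsum_vec(pxm$bin1_id, bc, nb) + rowsum_vec(pxm$bin2_id[off], bc[off], nb)
    if (any(!is.finite(m[unm]))) stop("non-finite marginal during ICE")
    zero <- unm[m[unm] == 0]
    if (length(zero)) {               # bins emptied by the joint mask drop out
      mask[zero] <- TRUE; w[zero] <- 0
      keep <- !mask[b1] & !mask[b2]
      b1 <- b1[keep]; b2 <- b2[keep]; cnt <- cnt[keep]; off <- b1 != b2
      pxm <- pxm[keep, , drop = FALSE]
      unm <- which(!mask & participate)
      if (length(unm) == 0L) stop("no unmasked bins left to balance")
      next
    }
    mean_marg <- mean(m[unm])
    mh <- m[unm] / mean_marg
    variance <- stats::var(mh)
    if (is.na(variance)) variance <- 0
    w[unm] <- w[unm] / mh
    if (variance < params$tol) { converged <- TRUE; break }
    if (iter >= params$max_iter) break
  }
  # rescale so the mean balanced marginal equals one
  bc <- cnt * w[b1] * w[b2]
  m <- rowsum_vec(pxm$bin1_id, bc, nb) + rowsum_vec(pxm$bin2_id[off], bc[off], nb)
  scale <- mean(m[unm])
  if (is.finite(scale) && scale > 0) w[unm] <- w[unm] / sqrt(scale)
  w[mask | !participate] <- NaN
  list(w = w, scale = scale, converged = converged, iterations = iter,
       variance = variance, mask = mask)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' @param px Pixel data.frame (full upper-triangle matrix).
#' @param table A [bin_table()].
#' @param params An [ice_params()]; `params$mode` selects the pixel subset
#'   (`gw` all, `cis` intra solved per chromosome, `trans` inter only).
#' @return An `ice_result`: `weights` ([norm_weights()], multiplicative,
#'   masked bins NaN), `scale` (mean balanced marginal before the final
#'   rescale; per chromosome in cis mode), `converged`, `iterations`,
#'   `variance`, `mask`.
#' @export
ice_balance <- function(px, table, params = ice_params()) {
  stopifnot(inherits(params, "ice_params"))
  cp <- pixel_chrom_pair(px, table)
  name <- switch(params$mode, gw = "weight", cis = "cis_weight", trans = "trans_weight")
  if (params$mode == "gw") {
    r <- ice_core(px, table, params)
    res <- list(weights = norm_weights(r$w, "multiplicative", name),
                scale = r$scale, converged = r$converged,
                iterations = r$iterations, variance = r$variance, mask = r$mask)
  } else if (params$mode == "cis") {
    w <- rep(NaN, table$n_bins)
    scales <- stats::setNames(rep(NA_real_, nrow(table$reference)),
                              table$reference$name)
    conv <- TRUE; iters <- 0L; varmax <- 0
    mask <- rep(TRUE, table$n_bins)
    for (ci in seq_len(nrow(table$reference))) {
      sub <- px[cp$ci1 == ci & cp$ci2 == ci, , drop = FALSE]
      ids <- seq(table$offsets[ci], table$offsets[ci + 1] - 1)
      if (nrow(sub) == 0L) next
      r <- tryCatch(ice_core(sub, table, params, bin_ids = ids),
                    error = function(e) NULL)
      if (is.null(r)) next
      w[ids + 1] <- r$w[ids + 1]
      scales[ci] <- r$scale
      conv <- conv && r$converged
      iters <- max(iters, r$iterations)
      varmax <- max(varmax, r$variance)
      mask[ids + 1] <- r$mask[ids + 1]
    }
    res <- list(weights = norm_weights(w, "multiplicative", name), scale = scales,
                converged = conv, iterations = iters, variance = varmax, mask = mask)
  } else {
    sub <- px[cp$ci1 != cp$ci2, , drop = FALSE]
    r <- ice_core(sub, table, params)
    res <- list(weights = norm_weights(r$w, "multiplicative", name),
                scale = r$scale, converged = r$converged,
                iterations = r$iterations, variance = r$variance, mask = r$mask)
  }
  class(res) <- "ice_result"
  res
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf("<ICE result '%s': %s after %d iterations (variance %.3g), %d masked>\n",
              x$weights$name, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$variance, sum(!is.finite(x$weights$values))))
  invisible(x)
}

#' Balance a stored matrix and write the weight column back
#'
#' Opens the file, runs [ice_balance()], and stores the resulting vector
#' into the Cooler group (column `weight`, `cis_weight` or `trans_weight`
#' under `bins/`) together with convergence metadata. Only Cooler-family
#' files can store new weights; .hic vectors are read-only.
#'
#' @param uri Cooler URI (`.cool` or `.mcool::/resolutions/<bp>`).
#' @param params An [ice_params()].
#' @return The `ice_result`, invisibly.
#' @export
balance_cooler <- function(uri, params = ice_params()) {
  h <- open_cooler(uri)
  px <- cooler_pixel_slab(h)
  res <- ice_balance(px, h$table, params)
  meta <- list(converged = res$converged, iterations = res$iterations,
               variance = res$variance, tol = params$tol,
               min_nnz = params$min_nnz, mad_max = params$mad_max,
               ignore_diags = params$ignore_diags, mode = params$mode,
               scale = as.numeric(res$scale)[is.finite(as.numeric(res$scale))])
  cooler_write_weights(uri, res$weights, metadata = meta)
  invisible(res)
}

#' Expected counts by distance, with per-chromosome scale factors
#'
#' The pooled profile averages intra-chromosomal counts over all
#' chromosomes at each bin distance d: `values[d]` = (total count at
#' distance d) / (number of valid bin pairs at distance d). The
#' per-chromosome scale factor rescales the pooled profile so that
#' observed/expected averages to one within each chromosome:
#' `scale[c]` = (observed intra total of c) / (sum over d of
#' `values[d] * pairs_c(d)`).
#'
#' @param px Pixel data.frame.
#' @param table A [bin_table()].
#' @return An [expected_profile()].
#' @export
compute_expected_pixels <- function(px, table) {
  cp <- pixel_chrom_pair(px, table)
  intra <- cp$ci1 == cp$ci2
  if (!any(intra)) stop("no intra-chromosomal pixels; expected profile undefined")
  d <- (px$bin2_id - px$bin1_id)[intra]
  cnt <- as.numeric(px$count[intra])
  ci <- cp$ci1[intra]
  D <- max(table$chrom_bins)
  sums <- rowsum_vec(d, cnt, D)                     # index = distance + 1
  npairs <- numeric(D)
  for (nbc in table$chrom_bins)
    npairs[seq_len(nbc)] <- npairs[seq_len(nbc)] + (nbc - seq_len(nbc) + 1)
  values <- ifelse(npairs > 0, sums / pmax(npairs, 1), 0)
  scale <- stats::setNames(rep(NaN, nrow(table$reference)), table$reference$name)
  for (k in seq_len(nrow(table$reference))) {
    obs <- sum(cnt[ci == k])
    if (obs <= 0) next
    nbc <- table$chrom_bins[k]
    exp_tot <- sum(values[seq_len(nbc)] * (nbc - seq_len(nbc) + 1))
    scale[k] <- if (exp_tot > 0) obs / exp_tot else NaN
  }
  expected_profile(values, scale, table$bin_size)
}

#' Expected profile of a stored contact matrix
#'
#' @param x A contact file path/URI or an open handle/[open_contacts()]
#'   object.
#' @param resolution Resolution in bp (required for paths to
#'   multi-resolution files).
#' @return An [expected_profile()].
#' @export
compute_expected <- function(x, resolution = NULL) {
  f <- if (inherits(x, "contact_file")) x else open_contacts(x, resolution)
  compute_expected_pixels(contacts_dump(f), f$table)
}
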