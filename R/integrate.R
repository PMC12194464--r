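# Azimuthal integration: collapse a circularly symmetric 2D pattern into a
# 1D intensity-vs-q profile with Poisson error propagation.

#' Equally spaced q bin edges
#'
#' @param q_min,q_max window limits in inverse nm.
#' @param n_bins number of bins (>= 1).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
q_bin_edges <- function(q_min, q_max, n_bins) {
  stopifnot(q_min < q_max, n_bins >= 1)
  seq(q_min, q_max, length.out = n_bins + 1)
}

#' Azimuthally integrate a detector frame into a 1D profile
#'
#' Each unmasked pixel is assigned to the q bin containing its center
#' (half-open bins `[lo, hi)`, last bin closed); the bin intensity is the
#' *mean* counts per pixel (so bins with different pixel populations are
#' comparable), and the bin uncertainty is the Poisson error propagated
#' through that mean. For a frame whose counts were scaled by a factor s
#' (see [normalize_frame()]), raw counts are recovered as `counts / s` for
#' the error model, so sigma scales linearly with s, as the intensity does.
#' For a raw frame, `sigma[b] = sqrt(sum counts in b) / n_pixels(b)`.
#'
#' Empty bins get `NaN` intensity/sigma (removed later by [remove_nan()]);
#' the reported q of each bin is its midpoint.
#'
#' @param frame a [waxs_frame()].
#' @param geometry a [detector_geometry()].
#' @param mask optional [pixel_mask()]; masked pixels never contribute.
#' @param q_edges strictly increasing bin edges in inverse nm (>= 2 values),
#'   e.g. from [q_bin_edges()].
#' @param meta metadata list passed to the output [profile1d()].
#' @return a [profile1d()] with `n_pixels` per bin.
#' @export
azimuthal_integrate <- function(frame, geometry, mask = NULL, q_edges,
                                meta = list()) {
  stopifnot(inherits(frame, "waxs_frame"),
            inherits(geometry, "detector_geometry"))
  if (length(q_edges) < 2 || any(diff(q_edges) <= 0))
    stop("`q_edges` must be at least two strictly increasing values",
         call. = FALSE)
  shape <- dim(frame$counts)
  live <- matrix(TRUE, shape[1], shape[2])
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"))
    if (!all(dim(mask$excluded) == shape))
      stop("mask/frame shape mismatch", call. = FALSE)
    live <- !mask$excluded
  }
  if (!any(live)) stop("all pixels are masked", call. = FALSE)

  qpix <- pixel_q_map(shape, geometry)
  cts <- frame$counts[live] / frame$scale # raw counts for Poisson stats
  qv <- qpix[live]
  nb <- length(q_edges) - 1L
  bin <- findInterval(qv, q_edges, rightmost.closed = TRUE, left.open = FALSE)
  inb <- bin >= 1L & bin <= nb
  bin <- bin[inb]; cts <- cts[inb]
  if (!length(bin)) stop("no unmasked pixel falls inside the q window",
                         call. = FALSE)

  n_b <- tabulate(bin, nbins = nb)
  sum_b <- numeric(nb)
  agg <- rowsum(cts, bin)
  sum_b[as.integer(rownames(agg))] <- agg[, 1]
  intensity <- frame$scale * sum_b / n_b              # NaN where n_b == 0
  sigma <- frame$scale * sqrt(pmax(sum_b, 0)) / n_b
  mids <- (q_edges[-1] + q_edges[-length(q_edges)]) / 2
  profile1d(mids, intensity, sigma, n_pixels = n_b, meta = meta)
}
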