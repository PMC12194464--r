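# Independent oracles and small fixture builders used across the suite.

# Brute-force azimuthal integration: per-pixel double loop, accumulating
# (sum, count) per bin with an explicit bin-rule scan. Kept deliberately
# independent of the production vectorized binning.
brute_force_integrate <- function(frame, geometry, mask, q_edges) {
  nr <- nrow(frame$counts); nc <- ncol(frame$counts)
  nb <- length(q_edges) - 1L
  sums <- numeric(nb); counts <- integer(nb)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is.null(mask) && mask$excluded[i, j]) next
      r <- geometry$pixel_mm * sqrt((i - geometry$beam_center[1])^2 +
                                    (j - geometry$beam_center[2])^2)
      q <- pixel_to_q(r, geometry)
      b <- 0L
      for (k in seq_len(nb)) {
        hi_ok <- if (k == nb) q <= q_edges[k + 1] else q < q_edges[k + 1]
        if (q >= q_edges[k] && hi_ok) { b <- k; break }
      }
      if (b == 0L) next
      sums[b] <- sums[b] + frame$counts[i, j]
      counts[b] <- counts[b] + 1L
    }
  }
  list(intensity = sums / counts, n_pixels = counts,
       sigma = sqrt(sums) / counts)
}

# Single-Gaussian parameter set (no background) for ring tests.
single_peak_params <- function(amplitude = 1, center = 13.5, width = 0.6) {
  composite_params(data.frame(amplitude = amplitude, center = center,
                              width = width))
}

# A small, fast cohort for functional tests.
small_cohort_spec <- function(seed = 1, n_per_group = 3,
                              positions_per_lobe = 4, ...) {
  cohort_spec(n_per_group = n_per_group,
              positions_per_lobe = positions_per_lobe, seed = seed, ...)
}

# Build a composite_fit by hand (for tests that need a fit-shaped object
# without running the optimizer).
manual_fit <- function(params, unc = NULL, meta = list(), window = c(10, 20.5),
                       converged = TRUE, rss = 0, reduced_chi2 = 0) {
  v <- rep(NA_real_, 3 * nrow(params$peaks) + 2)
  names(v) <- c(paste0(rep(c("A", "mu", "s"), nrow(params$peaks)),
                       rep(seq_len(nrow(params$peaks)), each = 3)), "B", "C")
  if (!is.null(unc)) v[names(unc)] <- unc
  structure(list(params = params, uncertainties = v, rss = rss,
                 reduced_chi2 = reduced_chi2, converged = converged,
                 n_evaluations = 0L, window = window,
                 n_points = NA_integer_, meta = meta, variant = "2peak",
                 broad_dropped = FALSE),
            class = "composite_fit")
}
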