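# Profile-level preprocessing: background subtraction, NaN removal, window
# restriction, L1 normalization, automated cleaning, and group averaging.
#
# Canonical stage order (fixed; see the methods vignette):
#   remove_nan -> subtract_background (optional) -> restrict_q -> l1_normalize

#' Subtract a background profile
#'
#' Pointwise intensity difference on identical q grids; uncertainties
#' combine in quadrature.
#'
#' @param profile,background [profile1d()] objects on the same q grid.
#' @return a [profile1d()] (metadata from `profile`).
#' @export
subtract_background <- function(profile, background) {
  stopifnot(inherits(profile, "profile1d"), inherits(background, "profile1d"))
  if (length(profile$q) != length(background$q) ||
      any(abs(profile$q - background$q) > 1e-9))
    stop("profile and background q grids differ", call. = FALSE)
  profile1d(profile$q, profile$intensity - background$intensity,
            sqrt(profile$sigma^2 + background$sigma^2),
            n_pixels = profile$n_pixels, meta = profile$meta)
}

#' Drop non-finite rows from a profile
#'
#' Removes points whose intensity or sigma is not finite (e.g. empty
#' integration bins); q ordering is preserved. Idempotent.
#'
#' @param profile a [profile1d()].
#' @return a [profile1d()] with only finite rows.
#' @export
remove_nan <- function(profile) {
  stopifnot(inherits(profile, "profile1d"))
  keep <- is.finite(profile$intensity) & is.finite(profile$sigma)
  if (!any(keep)) stop("no finite rows remain", call. = FALSE)
  if (all(keep)) return(profile)
  profile1d(profile$q[keep], profile$intensity[keep], profile$sigma[keep],
            n_pixels = profile$n_pixels[keep], meta = profile$meta)
}

#' Restrict a profile to a closed q window
#'
#' Keeps rows with `q_min <= q <= q_max`.
#'
#' @param profile a [profile1d()].
#' @param q_min,q_max window limits in inverse nm (`q_min < q_max`).
#' @return a [profile1d()].
#' @export
restrict_q <- function(profile, q_min, q_max) {
  stopifnot(inherits(profile, "profile1d"))
  if (!(q_min < q_max)) stop("need q_min < q_max", call. = FALSE)
  keep <- profile$q >= q_min & profile$q <= q_max
  if (!any(keep))
    stop(sprintf("no points in q window [%g, %g] (profile spans [%g, %g])",
                 q_min, q_max, min(profile$q), max(profile$q)), call. = FALSE)
  if (all(keep)) return(profile)
  profile1d(profile$q[keep], profile$intensity[keep], profile$sigma[keep],
            n_pixels = profile$n_pixels[keep], meta = profile$meta)
}

#' L1-normalize a profile
#'
#' Divides intensity and sigma by the sum of absolute intensities over the
#' profile's current q window, so the output has unit L1 mass and profiles
#' taken at different doses become comparable. The normalizer is treated as
#' a constant for error propagation.
#'
#' @param profile a [profile1d()] with positive total absolute intensity.
#' @return a [profile1d()] with `sum(abs(intensity)) == 1`.
#' @export
l1_normalize <- function(profile) {
  stopifnot(inherits(profile, "profile1d"))
  mass <- sum(abs(profile$intensity))
  if (!is.finite(mass) || mass <= 0)
    stop("profile has non-positive or non-finite total mass", call. = FALSE)
  profile1d(profile$q, profile$intensity / mass, profile$sigma / mass,
            n_pixels = profile$n_pixels, meta = profile$meta)
}

#' Run the canonical preprocessing chain on one profile
#'
#' `remove_nan`, then optional background subtraction, then restriction to
#' the analysis window, then L1 normalization.
#'
#' @param profile a [profile1d()].
#' @param background optional background [profile1d()] on the same grid.
#' @param q_window analysis window, default `c(3.25, 21)` inverse nm.
#' @param normalize apply [l1_normalize()] (default `TRUE`).
#' @return a [profile1d()].
#' @export
preprocess_profile <- function(profile, background = NULL,
                               q_window = c(3.25, 21), normalize = TRUE) {
  p <- remove_nan(profile)
  if (!is.null(background)) p <- subtract_background(p, background)
  p <- restrict_q(p, q_window[1], q_window[2])
  if (normalize) p <- l1_normalize(p)
  p
}

#' Cleaning criteria for [clean_profiles()]
#'
#' @param min_finite_fraction minimum fraction of finite points (default
#'   0.95).
#' @param mad_k robust outlier threshold: a profile is rejected when its L1
#'   distance to the stratum median profile exceeds `mad_k` times the
#'   stratum's robust distance scale (default 5).
#' @param min_scale floor on the robust distance scale, in L1-distance units
#'   (default 0.1, i.e. 5% of the maximum possible distance of 2 between two
#'   unit-mass shapes). Repeat measurements of the same animal cluster, which
#'   can collapse the stratum MAD far below genuine between-animal variation;
#'   the floor keeps sub-threshold biological variation from being flagged,
#'   while gross artifacts sit at distances of order 1.
#' @return a list of thresholds.
#' @export
cleaning_criteria <- function(min_finite_fraction = 0.95, mad_k = 5,
                              min_scale = 0.1) {
  stopifnot(min_finite_fraction >= 0, min_finite_fraction <= 1, mad_k > 0,
            min_scale >= 0)
  list(min_finite_fraction = min_finite_fraction, mad_k = mad_k,
       min_scale = min_scale)
}

#' Automated profile cleaning with a per-profile report
#'
#' A reproducible surrogate for manual curation. A profile is rejected when
#' (a) its finite fraction falls below `min_finite_fraction`, (b) its total
#' absolute intensity is not positive, or (c) within its (group, lobe)
#' stratum, the L1 distance of its normalized shape to the stratum's
#' pointwise-median shape exceeds `mad_k` times the robust distance scale
#' `max(MAD, median, min_scale)` (see [cleaning_criteria()]). Strata with
#' fewer than 3 profiles skip the outlier rule.
#'
#' @param profiles list of [profile1d()] objects on a common q grid (per
#'   stratum).
#' @param criteria a [cleaning_criteria()] list.
#' @return list with `profiles` (the retained ones) and `report`, a
#'   data.frame accounting for every input exactly once: metadata, the
#'   measured statistics, thresholds, `retained`, and `reason` (`""` when
#'   kept).
#' @export
clean_profiles <- function(profiles, criteria = cleaning_criteria()) {
  stopifnot(length(profiles) > 0)
  n <- length(profiles)
  meta_df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = as.character(p$meta$subject_id %||% NA),
               group = as.character(p$meta$group %||% NA),
               lobe = as.character(p$meta$lobe %||% NA),
               pos_row = as.integer(p$meta$pos_row %||% NA),
               pos_col = as.integer(p$meta$pos_col %||% NA))))
  finite_frac <- vapply(profiles, function(p)
    mean(is.finite(p$intensity) & is.finite(p$sigma)), numeric(1))
  mass <- vapply(profiles, function(p)
    sum(abs(p$intensity[is.finite(p$intensity)])), numeric(1))

  reason <- character(n)
  reason[finite_frac < criteria$min_finite_fraction] <- "low finite fraction"
  bad_mass <- mass <= 0 & reason == ""
  reason[bad_mass] <- "non-positive mass"

  # robust shape-outlier rule within (group, lobe)
  distance <- rep(NA_real_, n)
  threshold <- rep(NA_real_, n)
  strata <- paste(meta_df$group, meta_df$lobe, sep = "\r")
  for (st in unique(strata)) {
    idx <- which(strata == st & reason == "")
    if (length(idx) < 3) next
    shapes <- vapply(profiles[idx], function(p) {
      y <- p$intensity
      y[!is.finite(y)] <- 0
      y / sum(abs(y))
    }, numeric(length(profiles[[idx[1]]]$q)))
    med <- apply(shapes, 1, stats::median)
    d <- colSums(abs(shapes - med))
    thr <- criteria$mad_k * max(stats::mad(d), stats::median(d),
                                criteria$min_scale)
    distance[idx] <- d
    threshold[idx] <- thr
    reason[idx[d > thr]] <- "shape outlier"
  }

  report <- cbind(meta_df,
                  data.frame(finite_fraction = finite_frac, mass = mass,
                             shape_distance = distance,
                             shape_threshold = threshold,
                             retained = reason == "", reason = reason,
                             min_finite_fraction =
                               criteria$min_finite_fraction,
                             mad_k = criteria$mad_k))
  list(profiles = profiles[reason == ""], report = report)
}

#' Average profiles within each (group, lobe) stratum
#'
#' Pointwise arithmetic mean (or median) on a common q grid; the reported
#' sigma is the standard error of the mean across profiles (0 when a stratum
#' holds one profile). Invariant under permutation of the input order.
#'
#' @param profiles list of [profile1d()] objects; within each (group, lobe)
#'   stratum all profiles must share one q grid.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return named list (`"<group>/<lobe>"`) of [profile1d()] objects with an
#'   `n_profiles` entry in their metadata.
#' @export
group_average_profiles <- function(profiles, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(length(profiles) > 0)
  key <- vapply(profiles, function(p)
    paste(p$meta$group %||% NA, p$meta$lobe %||% NA, sep = "/"),
    character(1))
  out <- list()
  for (st in unique(key)) {
    ps <- profiles[key == st]
    q0 <- ps[[1]]$q
    for (p in ps)
      if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-9))
        stop("q grids differ within stratum ", st, call. = FALSE)
    m <- vapply(ps, `[[`, numeric(length(q0)), "intensity")
    m <- matrix(m, nrow = length(q0))
    center <- if (statistic == "mean") rowMeans(m)
              else apply(m, 1, stats::median)
    sem <- if (ncol(m) > 1) apply(m, 1, stats::sd) / sqrt(ncol(m))
           else rep(0, length(q0))
    meta <- ps[[1]]$meta
    meta$subject_id <- NA
    meta$pos_row <- meta$pos_col <- NA
    meta$n_profiles <- length(ps)
    out[[st]] <- profile1d(q0, center, sem, meta = meta)
  }
  out[order(names(out))]
}
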