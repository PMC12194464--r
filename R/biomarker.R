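# Lipid/water structural biomarker and group-level disease trajectories.
#
# Biomarker direction is fixed as lipid/water, so disease progression
# (lipid peak falling, water peak rising) DECREASES the biomarker; every
# report header prints the direction to avoid silent inversion.

BIOMARKER_DIRECTION <- "lipid/water"
LIPID_WINDOW <- c(12.0, 15.5)
WATER_WINDOW <- c(16.5, 20.5)

#' Assign fitted peaks to the lipid and water windows
#'
#' The lipid peak is the fitted Gaussian with center in `[12.0, 15.5]`
#' inverse nm; the water peak the one in `[16.5, 20.5]`. With several
#' candidates in a window the larger amplitude wins; a broad remainder peak
#' (role `"broad"`) is never assigned. Peaks are considered in order of
#' increasing center.
#'
#' @param result a `composite_fit` from [fit_composite()] (or a
#'   [composite_params()]).
#' @param lipid_window,water_window assignment windows in inverse nm.
#' @return list with `lipid` and `water` (each a list: `index` into the peak
#'   table, `amplitude`, `center`, `width`, `amplitude_unc`), or `NULL`
#'   entries plus a `reason` when unassignable.
#' @export
assign_peaks <- function(result, lipid_window = LIPID_WINDOW,
                         water_window = WATER_WINDOW) {
  if (inherits(result, "composite_fit")) {
    params <- result$params
    unc <- result$uncertainties
  } else if (inherits(result, "composite_params")) {
    params <- result
    unc <- NULL
  } else stop("need a composite_fit or composite_params", call. = FALSE)
  pk <- params$peaks
  cand <- which(pk$role != "broad")
  cand <- cand[order(pk$center[cand])]
  pick <- function(win) {
    ok <- cand[pk$center[cand] >= win[1] & pk$center[cand] <= win[2]]
    if (!length(ok)) return(NULL)
    i <- ok[which.max(pk$amplitude[ok])]
    list(index = i, amplitude = pk$amplitude[i], center = pk$center[i],
         width = pk$width[i],
         amplitude_unc = if (is.null(unc)) NA_real_
                         else unname(unc[paste0("A", i)]))
  }
  lipid <- pick(lipid_window)
  water <- pick(water_window)
  reason <- c(if (is.null(lipid)) "no peak in lipid window",
              if (is.null(water)) "no peak in water window")
  list(lipid = lipid, water = water,
       reason = if (length(reason)) paste(reason, collapse = "; ") else "")
}

#' Compute the lipid/water biomarker for one fit
#'
#' Ratio of the fitted lipid and water Gaussian heights, with first-order
#' error propagation:
#' `(dr/r)^2 = (dA_l/A_l)^2 + (dA_w/A_w)^2`. Peak areas
#' (`A * sigma * sqrt(2*pi)`) are reported alongside the heights.
#'
#' @param result a `composite_fit` from [fit_composite()].
#' @return a one-row data.frame (`biomarker_record`): metadata, heights,
#'   areas, uncertainties, `ratio`, `ratio_unc`, `ok` (usable for
#'   trajectories) and `reason` for unusable records.
#' @export
compute_biomarker <- function(result) {
  stopifnot(inherits(result, "composite_fit"))
  m <- result$meta %||% list()
  asg <- assign_peaks(result)
  rec <- data.frame(subject_id = as.character(m$subject_id %||% NA),
                    group = as.character(m$group %||% NA),
                    lobe = as.character(m$lobe %||% NA),
                    pos_row = as.integer(m$pos_row %||% NA),
                    pos_col = as.integer(m$pos_col %||% NA),
                    sacrifice_day = as.numeric(m$sacrifice_day %||% NA),
                    lipid_height = NA_real_, lipid_unc = NA_real_,
                    lipid_area = NA_real_,
                    water_height = NA_real_, water_unc = NA_real_,
                    water_area = NA_real_,
                    ratio = NA_real_, ratio_unc = NA_real_,
                    converged = result$converged,
                    ok = FALSE, reason = "")
  if (nzchar(asg$reason)) {
    rec$reason <- asg$reason
    return(rec)
  }
  l <- asg$lipid; w <- asg$water
  rec$lipid_height <- l$amplitude
  rec$lipid_unc <- l$amplitude_unc
  rec$lipid_area <- l$amplitude * l$width * sqrt(2 * pi)
  rec$water_height <- w$amplitude
  rec$water_unc <- w$amplitude_unc
  rec$water_area <- w$amplitude * w$width * sqrt(2 * pi)
  if (!isTRUE(result$converged)) {
    rec$reason <- "fit did not converge"
    return(rec)
  }
  if (!(w$amplitude > 0)) {
    rec$reason <- "water height not positive"
    return(rec)
  }
  rec$ratio <- l$amplitude / w$amplitude
  if (is.finite(l$amplitude_unc) && is.finite(w$amplitude_unc) &&
      l$amplitude > 0)
    rec$ratio_unc <- rec$ratio *
      sqrt((l$amplitude_unc / l$amplitude)^2 +
           (w$amplitude_unc / w$amplitude)^2)
  rec$ok <- TRUE
  rec
}

#' Biomarker records for a list of fits
#'
#' @param fits list of `composite_fit` objects.
#' @return data.frame with one [compute_biomarker()] row per fit.
#' @export
biomarker_records <- function(fits) {
  as.data.frame(data.table::rbindlist(lapply(fits, compute_biomarker)))
}

# subject-level means of the ratio (positions collapsed first)
subject_means <- function(records) {
  ok <- records[records$ok & is.finite(records$ratio), , drop = FALSE]
  if (!nrow(ok)) return(ok[0, c("subject_id", "group", "lobe")])
  agg <- stats::aggregate(ratio ~ subject_id + group + lobe, data = ok,
                          FUN = mean)
  day <- stats::aggregate(sacrifice_day ~ subject_id + group + lobe,
                          data = ok, FUN = function(x) x[1], na.action = NULL)
  merge(agg, day, by = c("subject_id", "group", "lobe"))
}

#' Temporally matched control statistics
#'
#' For each experimental day, the control mean and standard deviation are
#' computed over control subjects sacrificed at that day (subject-level
#' ratios, positions averaged first). Days with no matching control fall
#' back to the pooled control statistics and are flagged.
#'
#' @param records a [biomarker_records()] data.frame; control rows must
#'   carry `sacrifice_day`.
#' @param days experimental days to match (default the days present in the
#'   non-control groups' `sacrifice_day`).
#' @return data.frame per (day, lobe): `control_mean`, `control_sd`,
#'   `n_controls`, `matched` (FALSE when pooled fallback was used).
#' @export
match_controls <- function(records, days = NULL) {
  sm <- subject_means(records)
  ctl <- sm[sm$group == "Control", , drop = FALSE]
  if (!nrow(ctl)) stop("no usable control records", call. = FALSE)
  if (is.null(days)) {
    days <- sort(unique(sm$sacrifice_day[sm$group != "Control"]))
    if (!length(days)) days <- sort(unique(ctl$sacrifice_day))
  }
  out <- list()
  for (lobe in unique(ctl$lobe)) {
    cl <- ctl[ctl$lobe == lobe, ]
    for (d in days) {
      sub <- cl[!is.na(cl$sacrifice_day) & cl$sacrifice_day == d, ]
      matched <- nrow(sub) > 0
      if (!matched) sub <- cl
      out[[length(out) + 1L]] <- data.frame(
        day = d, lobe = lobe,
        control_mean = mean(sub$ratio),
        control_sd = if (nrow(sub) > 1) stats::sd(sub$ratio) else 0,
        n_controls = nrow(sub), matched = matched)
    }
  }
  do.call(rbind, out)
}

#' Build group-level biomarker trajectories
#'
#' Aggregation hierarchy: grid positions are averaged within each subject's
#' lobe first, then the group mean and standard deviation are taken over
#' subjects (so n counts animals, not measurements). Groups are ordered
#' Control, Day2, Day4, Day7, Day16; experimental points carry temporally
#' matched control statistics from [match_controls()]. Unusable records
#' (unassignable peaks, failed fits) are excluded and counted.
#'
#' @param records a [biomarker_records()] data.frame.
#' @param group_order group ordering (default the standard five groups).
#' @return an object of class `waxs_trajectory`: a data.frame per
#'   (group, lobe) with `mean_ratio`, `sd_ratio`, `n_subjects`,
#'   `control_mean`, `control_sd`, `control_matched`; attributes
#'   `direction`, `n_excluded`.
#' @export
build_trajectory <- function(records, group_order = COHORT_GROUPS) {
  sm <- subject_means(records)
  if (!nrow(sm)) stop("no usable biomarker records", call. = FALSE)
  groups <- intersect(group_order, unique(sm$group))
  dropped <- setdiff(unique(records$group), groups)
  if (length(dropped))
    warning("strata without usable records omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  ctl_stats <- if ("Control" %in% sm$group)
    tryCatch(match_controls(records), error = function(e) NULL) else NULL
  out <- list()
  for (lobe in sort(unique(sm$lobe))) {
    for (g in groups) {
      sub <- sm[sm$group == g & sm$lobe == lobe, ]
      if (!nrow(sub)) next
      d <- COHORT_DAYS[g]
      cs <- if (!is.null(ctl_stats) && !is.na(d))
        ctl_stats[ctl_stats$day == d & ctl_stats$lobe == lobe, ] else NULL
      out[[length(out) + 1L]] <- data.frame(
        group = g, lobe = lobe, day = unname(d),
        mean_ratio = mean(sub$ratio),
        sd_ratio = if (nrow(sub) > 1) stats::sd(sub$ratio) else 0,
        n_subjects = nrow(sub),
        control_mean = if (!is.null(cs) && nrow(cs)) cs$control_mean
                       else NA_real_,
        control_sd = if (!is.null(cs) && nrow(cs)) cs$control_sd
                     else NA_real_,
        control_matched = if (!is.null(cs) && nrow(cs)) cs$matched else NA)
    }
  }
  traj <- do.call(rbind, out)
  traj$group <- factor(traj$group, levels = groups)
  traj <- traj[order(traj$lobe, traj$group), ]
  rownames(traj) <- NULL
  attr(traj, "direction") <- BIOMARKER_DIRECTION
  attr(traj, "n_excluded") <- sum(!records$ok)
  class(traj) <- c("waxs_trajectory", "data.frame")
  traj
}

#' @export
print.waxs_trajectory <- function(x, ...) {
  cat(sprintf("Biomarker trajectory (direction: %s; %d records excluded)\n",
              attr(x, "direction"), attr(x, "n_excluded")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plain-text summary of peak magnitudes per group and lobe
#'
#' Mirrors the standard reporting layout: per lobe and group, the mean and
#' standard deviation (over subjects) of the fitted lipid and water peak
#' heights, alongside the ratio.
#'
#' @param records a [biomarker_records()] data.frame.
#' @return data.frame per (group, lobe) with mean/sd of both peak heights
#'   and of the ratio, plus subject counts.
#' @export
summarize_peak_magnitudes <- function(records) {
  ok <- records[records$ok, , drop = FALSE]
  stopifnot(nrow(ok) > 0)
  agg <- stats::aggregate(
    cbind(lipid_height, water_height, ratio) ~ subject_id + group + lobe,
    data = ok, FUN = mean)
  res <- list()
  for (lobe in sort(unique(agg$lobe)))
    for (g in intersect(COHORT_GROUPS, unique(agg$group))) {
      sub <- agg[agg$group == g & agg$lobe == lobe, ]
      if (!nrow(sub)) next
      res[[length(res) + 1L]] <- data.frame(
        group = g, lobe = lobe, n_subjects = nrow(sub),
        lipid_mean = mean(sub$lipid_height),
        lipid_sd = if (nrow(sub) > 1) stats::sd(sub$lipid_height) else 0,
        water_mean = mean(sub$water_height),
        water_sd = if (nrow(sub) > 1) stats::sd(sub$water_height) else 0,
        ratio_mean = mean(sub$ratio),
        ratio_sd = if (nrow(sub) > 1) stats::sd(sub$ratio) else 0)
    }
  do.call(rbind, res)
}
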