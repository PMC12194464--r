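# Seeded synthetic data emulating a longitudinal mouse-prostate WAXS study:
# 1D profiles, 2D detector frames, and full cohorts with known ground truth.
#
# Study design emulated: five groups (Control and Days 2/4/7/16 after tumor
# inoculation into the left prostate lobe), five mice per group, both lobes
# measured on a 5 x 5 grid of positions; the left lobe's lipid peak falls and
# water peak rises with day, the right (uninoculated) lobe stays at baseline.

COHORT_GROUPS <- c("Control", "Day2", "Day4", "Day7", "Day16")
COHORT_DAYS <- c(Control = NA, Day2 = 2, Day4 = 4, Day7 = 7, Day16 = 16)

#' Default analysis q grid
#'
#' 414 equally spaced points spanning 3.25 to 21 inverse nm, the resolution
#' and window of the reduced tissue profiles.
#'
#' @return numeric vector of length 414.
#' @export
default_q_grid <- function() seq(3.25, 21, length.out = 414)

#' Default healthy-control generating parameters
#'
#' Two Gaussian peaks — lipid (amplitude 1.0 at 13.5 inverse nm, width 1.2)
#' and water (amplitude 0.6 at 18.0, width 1.4) — on an amorphous background
#' `150/q^4 + 0.05`. Healthy tissue has the lipid peak taller than the water
#' peak; the background contributes roughly a third of the total signal over
#' the default grid. Amplitudes are in arbitrary units: profiles are L1
#' normalized downstream, so only ratios matter.
#'
#' @return a [composite_params()] with peak roles `"lipid"` and `"water"`.
#' @export
default_control_params <- function() {
  composite_params(data.frame(amplitude = c(1.0, 0.6),
                              center = c(13.5, 18.0),
                              width = c(1.2, 1.4),
                              role = c("lipid", "water")),
                   porod = 150, offset = 0.05)
}

#' Default disease-progression effect model
#'
#' Per-group multiplicative factors on the left lobe's lipid and water peak
#' amplitudes (the right lobe is always 1.0). Chosen to reproduce the
#' progression narrative: Day 2 indistinguishable from control and Day 4
#' still close to it, comparable peak heights by Day 7, water dominating by
#' Day 16; the lipid factor declines and the water factor rises
#' monotonically.
#'
#' @return data.frame with columns `group`, `lipid`, `water`.
#' @export
default_effect_model <- function() {
  data.frame(group = COHORT_GROUPS,
             lipid = c(1.0, 1.0, 0.90, 0.75, 0.45),
             water = c(1.0, 1.0, 1.12, 1.30, 1.80))
}

#' Synthetic cohort specification
#'
#' @param groups ordered group labels; the first must be `"Control"`.
#' @param n_per_group mice per group (>= 1).
#' @param lobes lobe labels.
#' @param positions_per_lobe measurement positions per lobe (a 5 x 5 grid by
#'   default).
#' @param effect_model data.frame (`group`, `lipid`, `water`) of left-lobe
#'   amplitude multipliers; Control must be 1.0 / 1.0 and all factors > 0.
#' @param control_params [composite_params()] generating the healthy
#'   baseline; must contain peaks with roles `"lipid"` and `"water"`.
#' @param noise_scale expected total photon counts per profile (> 0).
#' @param inter_subject_cv coefficient of variation of lognormal per-subject
#'   amplitude multipliers (>= 0).
#' @param amplitude_cor correlation between the log lipid and log water
#'   multipliers of one subject's lobe, in `[0, 1)`. Inter-animal amplitude
#'   variability is dominated by an overall signal scale (sample thickness,
#'   density, positioning) that moves both peaks together; only the residual
#'   part perturbs their ratio. Default 0.64.
#' @param seed integer root seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = COHORT_GROUPS,
                        n_per_group = 5,
                        lobes = c("left", "right"),
                        positions_per_lobe = 25,
                        effect_model = default_effect_model(),
                        control_params = default_control_params(),
                        noise_scale = 1e6,
                        inter_subject_cv = 0.15,
                        amplitude_cor = 0.64,
                        seed = 1) {
  stopifnot(length(groups) >= 1, groups[1] == "Control",
            n_per_group >= 1, positions_per_lobe >= 1,
            length(lobes) >= 1, inter_subject_cv >= 0,
            amplitude_cor >= 0, amplitude_cor < 1)
  stop_if_not_scalar_pos(noise_scale, "noise_scale")
  stopifnot(inherits(control_params, "composite_params"),
            all(c("lipid", "water") %in% control_params$peaks$role))
  em <- as.data.frame(effect_model)
  stopifnot(all(c("group", "lipid", "water") %in% names(em)),
            all(groups %in% em$group))
  em <- em[match(groups, em$group), ]
  if (any(em$lipid <= 0) || any(em$water <= 0))
    stop("effect multipliers must be > 0", call. = FALSE)
  ctl <- em[em$group == "Control", ]
  if (ctl$lipid != 1 || ctl$water != 1)
    stop("Control multipliers must be 1.0", call. = FALSE)
  structure(list(groups = groups, n_per_group = n_per_group, lobes = lobes,
                 positions_per_lobe = positions_per_lobe, effect_model = em,
                 control_params = control_params, noise_scale = noise_scale,
                 inter_subject_cv = inter_subject_cv,
                 amplitude_cor = amplitude_cor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d groups x %d mice x %d lobes x %d positions (seed %d)\n",
              length(x$groups), x$n_per_group, length(x$lobes),
              x$positions_per_lobe, x$seed))
  invisible(x)
}

#' Simulate one 1D profile with Poisson counting noise
#'
#' The composite model is evaluated on the grid, rescaled so the expected
#' total equals `noise_scale` counts, and each point is Poisson-sampled; the
#' per-point uncertainty is `sqrt(max(counts, 1))`. With `noise = FALSE` the
#' expected counts are returned exactly (the infinite-dose limit).
#'
#' @param true_params a [composite_params()].
#' @param q_grid strictly increasing positive q values.
#' @param noise_scale expected total counts (> 0).
#' @param seed integer seed; identical seeds give bit-identical profiles.
#' @param noise set `FALSE` to disable Poisson sampling.
#' @param meta metadata list for the output profile.
#' @return list with `profile` ([profile1d()]) and `truth` (list: `params`,
#'   `seed`, `noise_scale`, `noise`).
#' @export
simulate_profile <- function(true_params, q_grid = default_q_grid(),
                             noise_scale = 1e6, seed = 1, noise = TRUE,
                             meta = list()) {
  stopifnot(inherits(true_params, "composite_params"))
  if (any(q_grid <= 0)) stop("q grid must be strictly positive", call. = FALSE)
  if (any(diff(q_grid) <= 0)) stop("q grid must be strictly increasing",
                                   call. = FALSE)
  stop_if_not_scalar_pos(noise_scale, "noise_scale")
  y <- composite_model(q_grid, true_params)
  lambda <- noise_scale * y / sum(y)
  counts <- if (noise) with_seed(seed, stats::rpois(length(lambda), lambda))
            else lambda
  sigma <- sqrt(pmax(counts, 1))
  list(profile = profile1d(q_grid, counts, sigma, meta = meta),
       truth = list(params = true_params, seed = seed,
                    noise_scale = noise_scale, noise = noise))
}

#' Simulate a 2D detector frame
#'
#' Builds the circularly symmetric expected image of the composite model
#' (each pixel's mean is the model at that pixel's q, rescaled so the
#' unmasked expected total is `total_counts`), Poisson-samples it, and masks
#' the beam-stop shadow plus a random set of dead pixels.
#'
#' @param true_params a [composite_params()].
#' @param geometry a [detector_geometry()]; the beam center should be
#'   fractional so no pixel sits exactly on the beam axis.
#' @param shape detector (rows, cols).
#' @param total_counts expected total counts over unmasked pixels (> 0).
#' @param beamstop_radius_mm beam-stop shadow radius in mm.
#' @param dead_pixel_fraction fraction of pixels marked dead, in `[0, 1)`.
#' @param seed integer seed (sub-streams: dead pixels, counts).
#' @param noise set `FALSE` for the expected (noiseless) image.
#' @return list with `frame` ([waxs_frame()]), `mask` ([pixel_mask()]) and
#'   `truth`.
#' @export
simulate_frame <- function(true_params, geometry, shape = c(128, 128),
                           total_counts = 1e7, beamstop_radius_mm = 0,
                           dead_pixel_fraction = 0, seed = 1, noise = TRUE) {
  stopifnot(inherits(true_params, "composite_params"),
            inherits(geometry, "detector_geometry"),
            dead_pixel_fraction >= 0, dead_pixel_fraction < 1)
  stop_if_not_scalar_pos(total_counts, "total_counts")
  mask <- build_mask(shape, geometry, beamstop_radius_mm)
  excl <- mask$excluded
  prov <- mask$provenance
  if (dead_pixel_fraction > 0) {
    n_dead <- round(dead_pixel_fraction * prod(shape))
    dead <- with_seed(derive_seed(seed, "dead-pixels"),
                      sample.int(prod(shape), n_dead))
    excl[dead] <- TRUE
    prov[dead] <- "dead"
    mask <- pixel_mask(excl, prov)
  }
  if (all(mask$excluded))
    stop("mask covers the whole detector", call. = FALSE)

  qpix <- pixel_q_map(shape, geometry)
  lam <- matrix(0, shape[1], shape[2])
  pos <- qpix > 0
  lam[pos] <- composite_model(qpix[pos], true_params)
  live <- !mask$excluded
  lam <- lam * (total_counts / sum(lam[live]))
  counts <- lam
  if (noise) {
    counts[live] <- with_seed(derive_seed(seed, "frame-counts"),
                              stats::rpois(sum(live), lam[live]))
    counts[!live] <- 0
  } else counts[!live] <- 0
  list(frame = waxs_frame(counts, exposure_s = 0.1, monitor = 1, scale = 1),
       mask = mask,
       truth = list(params = true_params, seed = seed,
                    total_counts = total_counts, noise = noise))
}

# Gaussian heights of the lipid/water peaks for a params object
peak_heights <- function(params) {
  pk <- params$peaks
  c(lipid = pk$amplitude[pk$role == "lipid"][1],
    water = pk$amplitude[pk$role == "water"][1])
}

#' Simulate a full longitudinal cohort
#'
#' One profile per (subject, lobe, position). Per-subject lipid and water
#' amplitudes are drawn as lognormal multipliers (unit mean, coefficient of
#' variation `inter_subject_cv`, log-scale correlation `amplitude_cor`
#' between the two peaks) around the group-by-lobe means given by the effect
#' model applied to the control parameters; all positions of a subject's
#' lobe share its true parameters and differ only in counting noise. Control
#' mice are assigned sacrifice days (2, 4, 7, 16, round robin) for temporal
#' control matching downstream. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `profiles` (list of [profile1d()]) and `truth`
#'   (data.frame, one row per profile: metadata, true amplitudes/centers/
#'   widths, background, true peak heights and lipid/water ratio).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$control_params
  h0 <- peak_heights(base)
  cv <- spec$inter_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  grid <- default_q_grid()
  side <- as.integer(ceiling(sqrt(spec$positions_per_lobe)))

  subjects <- data.frame(
    subject_id = sprintf("M%02d", seq_len(length(spec$groups) *
                                            spec$n_per_group)),
    group = rep(spec$groups, each = spec$n_per_group))
  ctl <- subjects$group == "Control"
  subjects$sacrifice_day <- COHORT_DAYS[subjects$group]
  exp_days <- stats::na.omit(unique(COHORT_DAYS[spec$groups]))
  if (!length(exp_days)) exp_days <- NA
  subjects$sacrifice_day[ctl] <-
    rep_len(exp_days, sum(ctl))

  # per subject x lobe lognormal multipliers for the two peaks, built from a
  # shared overall-scale component plus peak-specific residuals so that each
  # amplitude has CV = inter_subject_cv and the log-amplitudes correlate at
  # amplitude_cor; all draws come from one sub-stream
  n_sub <- nrow(subjects)
  n_lobe <- length(spec$lobes)
  sd_shared <- sqrt(spec$amplitude_cor) * sdlog
  sd_spec <- sqrt(1 - spec$amplitude_cor) * sdlog
  mult <- with_seed(derive_seed(spec$seed, "subjects"), {
    z <- matrix(stats::rnorm(n_sub * n_lobe * 3), ncol = 3)
    exp(cbind(z[, 1] * sd_shared + z[, 2] * sd_spec,
              z[, 1] * sd_shared + z[, 3] * sd_spec) - sdlog^2 / 2)
  })

  n_prof <- n_sub * n_lobe * spec$positions_per_lobe
  profiles <- vector("list", n_prof)
  tt <- list(subject_id = character(n_prof), group = character(n_prof),
             lobe = character(n_prof), pos_row = integer(n_prof),
             pos_col = integer(n_prof), sacrifice_day = numeric(n_prof),
             seed = integer(n_prof), a_lipid = numeric(n_prof),
             mu_lipid = numeric(n_prof), w_lipid = numeric(n_prof),
             a_water = numeric(n_prof), mu_water = numeric(n_prof),
             w_water = numeric(n_prof))
  k <- 0L
  for (s in seq_len(n_sub)) {
    grp <- subjects$group[s]
    em <- spec$effect_model[spec$effect_model$group == grp, ]
    for (l in seq_len(n_lobe)) {
      lobe <- spec$lobes[l]
      eff_lipid <- if (lobe == "left") em$lipid else 1.0
      eff_water <- if (lobe == "left") em$water else 1.0
      m <- mult[(s - 1) * n_lobe + l, ]
      pk <- base$peaks
      pk$amplitude[pk$role == "lipid"] <- h0["lipid"] * eff_lipid * m[1]
      pk$amplitude[pk$role == "water"] <- h0["water"] * eff_water * m[2]
      pars <- composite_params(pk, porod = base$porod, offset = base$offset)
      hh <- peak_heights(pars)
      for (p in seq_len(spec$positions_per_lobe)) {
        k <- k + 1L
        meta <- list(subject_id = subjects$subject_id[s], group = grp,
                     lobe = lobe,
                     pos_row = ((p - 1L) %/% side) + 1L,
                     pos_col = ((p - 1L) %% side) + 1L,
                     sacrifice_day = subjects$sacrifice_day[s])
        pseed <- derive_seed(spec$seed,
                             sprintf("noise/%s/%s/%d",
                                     subjects$subject_id[s], lobe, p))
        sim <- simulate_profile(pars, grid, spec$noise_scale, seed = pseed,
                                meta = meta)
        profiles[[k]] <- sim$profile
        tt$subject_id[k] <- subjects$subject_id[s]
        tt$group[k] <- grp; tt$lobe[k] <- lobe
        tt$pos_row[k] <- meta$pos_row; tt$pos_col[k] <- meta$pos_col
        tt$sacrifice_day[k] <- subjects$sacrifice_day[s]
        tt$seed[k] <- pseed
        tt$a_lipid[k] <- hh[["lipid"]]
        tt$mu_lipid[k] <- pk$center[pk$role == "lipid"]
        tt$w_lipid[k] <- pk$width[pk$role == "lipid"]
        tt$a_water[k] <- hh[["water"]]
        tt$mu_water[k] <- pk$center[pk$role == "water"]
        tt$w_water[k] <- pk$width[pk$role == "water"]
      }
    }
  }
  truth <- as.data.frame(tt)
  truth$porod <- base$porod
  truth$offset <- base$offset
  truth$true_ratio <- truth$a_lipid / truth$a_water
  list(profiles = profiles, truth = truth)
}
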