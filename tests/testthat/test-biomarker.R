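# Lipid/water biomarker computation, control matching, and trajectories.

two_peak_fit <- function(a_lipid, a_water, mu = c(13.5, 18), unc = NULL,
                         meta = list()) {
  manual_fit(composite_params(data.frame(amplitude = c(a_lipid, a_water),
                                         center = mu, width = c(1.2, 1.4))),
             unc = unc, meta = meta)
}

test_that("peak assignment follows the window and amplitude rules", {
  asg <- assign_peaks(two_peak_fit(1, 0.6))
  expect_equal(asg$lipid$center, 13.5)
  expect_equal(asg$water$center, 18.0)

  crowded <- manual_fit(composite_params(
    data.frame(amplitude = c(0.1, 0.4, 0.3), center = c(13.0, 14.2, 18.1),
               width = rep(1, 3))))
  asg2 <- assign_peaks(crowded)
  expect_equal(asg2$lipid$center, 14.2) # larger amplitude wins
  expect_equal(asg2$water$center, 18.1)

  nowater <- manual_fit(composite_params(
    data.frame(amplitude = c(1, 0.6), center = c(13.5, 16.0),
               width = c(1, 1))))
  asg3 <- assign_peaks(nowater)
  expect_null(asg3$water)
  expect_match(asg3$reason, "water window")

  # a broad remainder peak is never assigned, even inside a window
  broad <- manual_fit(composite_params(
    data.frame(amplitude = c(1, 0.6, 5), center = c(13.5, 18, 14),
               width = c(1.2, 1.4, 3), role = c("seeded", "seeded", "broad"))))
  expect_equal(assign_peaks(broad)$lipid$center, 13.5)
})

test_that("biomarker ratio and its propagated uncertainty are correct", {
  equal <- compute_biomarker(two_peak_fit(0.3, 0.3,
                                          unc = c(A1 = 0.01, A2 = 0.01)))
  expect_equal(equal$ratio, 1.0)
  expect_true(equal$ok)

  rec <- compute_biomarker(two_peak_fit(0.004, 0.002,
                                        unc = c(A1 = 2e-4, A2 = 1e-4)))
  expect_equal(rec$ratio, 2.0)
  expect_equal(rec$ratio_unc, 2 * sqrt((2e-4 / 4e-3)^2 + (1e-4 / 2e-3)^2))

  unassignable <- compute_biomarker(manual_fit(composite_params(
    data.frame(amplitude = c(1, 1), center = c(13.5, 16), width = c(1, 1)))))
  expect_false(unassignable$ok)
  expect_match(unassignable$reason, "water window")

  failed <- compute_biomarker(two_peak_fit(1, 0.6, unc = c(A1 = 0.1, A2 = 0.1),
                                           meta = list()) |>
                                (\(f) { f$converged <- FALSE; f })())
  expect_false(failed$ok)
  expect_match(failed$reason, "converge")
})

test_that("propagated ratio uncertainty matches a Monte-Carlo oracle", {
  a_l <- 0.006; a_w <- 0.004; u_l <- 3e-4; u_w <- 2.5e-4
  rec <- compute_biomarker(two_peak_fit(a_l, a_w, unc = c(A1 = u_l, A2 = u_w)))
  set.seed(99)
  mc <- stats::sd(stats::rnorm(2e5, a_l, u_l) / stats::rnorm(2e5, a_w, u_w))
  expect_lt(abs(rec$ratio_unc - mc) / mc, 0.1)
})

test_that("control matching is per sacrifice day with pooled fallback", {
  mk <- function(subj, group, day, ratio)
    data.frame(subject_id = subj, group = group, lobe = "left",
               pos_row = 1, pos_col = 1, sacrifice_day = day,
               lipid_height = ratio, water_height = 1, ratio = ratio,
               ratio_unc = 0.01, converged = TRUE, ok = TRUE, reason = "")
  recs <- rbind(mk("C1", "Control", 2, 1.5), mk("C2", "Control", 4, 1.6),
                mk("C3", "Control", 7, 1.7), mk("C4", "Control", 16, 1.8),
                mk("E1", "Day2", 2, 1.2), mk("E2", "Day16", 16, 0.5))
  ms <- match_controls(recs)
  expect_true(all(ms$matched))
  expect_equal(ms$control_mean[ms$day == 2], 1.5)
  expect_equal(ms$control_mean[ms$day == 16], 1.8)

  lonely <- rbind(mk("C1", "Control", 2, 1.5),
                  mk("E1", "Day2", 2, 1.2), mk("E2", "Day16", 16, 0.5))
  ms2 <- match_controls(lonely)
  expect_true(ms2$matched[ms2$day == 2])
  expect_false(ms2$matched[ms2$day == 16]) # pooled fallback, flagged
  expect_equal(ms2$control_mean[ms2$day == 16], 1.5)

  expect_error(match_controls(mk("E1", "Day2", 2, 1.2)), "no usable control")
})

test_that("trajectories aggregate positions -> subject -> group", {
  mk <- function(subj, group, lobe, ratio, pos = 1)
    data.frame(subject_id = subj, group = group, lobe = lobe,
               pos_row = pos, pos_col = 1,
               sacrifice_day = unname(c(Control = 2, Day2 = 2, Day16 = 16)[group]),
               lipid_height = ratio, water_height = 1, ratio = ratio,
               ratio_unc = 0.01, converged = TRUE, ok = TRUE, reason = "")
  # two positions for one subject collapse to their mean before group stats
  recs <- rbind(mk("A", "Day2", "left", 1.0, pos = 1),
                mk("A", "Day2", "left", 2.0, pos = 2),
                mk("B", "Day2", "left", 1.5),
                mk("C", "Control", "left", 1.5))
  tr <- build_trajectory(recs)
  d2 <- tr[tr$group == "Day2", ]
  expect_equal(d2$mean_ratio, 1.5)
  expect_equal(d2$n_subjects, 2L)
  expect_equal(d2$sd_ratio, 0)
  ctl <- tr[tr$group == "Control", ]
  expect_equal(ctl$sd_ratio, 0) # single subject
  # permutation invariance
  shuffled <- recs[c(3, 1, 4, 2), ]
  expect_equal(as.data.frame(build_trajectory(shuffled)),
               as.data.frame(tr))
})

test_that("a synthetic cohort recovers the disease trajectory", {
  sim <- simulate_cohort(small_cohort_spec(seed = 6, n_per_group = 5,
                                           positions_per_lobe = 4))
  pp <- lapply(clean_profiles(sim$profiles)$profiles, preprocess_profile)
  fits <- lapply(pp, fit_composite, variant = "2peak")
  recs <- biomarker_records(fits)
  expect_true(all(recs$ok))

  # healthy controls: lipid peak dominates; Day 16 left lobe: water dominates
  expect_gt(min(recs$ratio[recs$group == "Control"]), 1)
  expect_lt(max(recs$ratio[recs$group == "Day16" & recs$lobe == "left"]), 1)

  tr <- build_trajectory(recs)
  left <- tr[tr$lobe == "left" & tr$group != "Control", ]
  expect_true(all(diff(left$mean_ratio) < 0)) # strict decrease Day2 -> Day16
  right <- tr[tr$lobe == "right", ]
  ctl_r <- right[right$group == "Control", ]
  days_r <- right[right$group != "Control", ]
  pooled <- sqrt((days_r$sd_ratio^2 + ctl_r$sd_ratio^2) / 2)
  expect_true(all(abs(days_r$mean_ratio - ctl_r$mean_ratio) <= 2 * pooled))
  expect_identical(attr(tr, "direction"), "lipid/water")
})

test_that("peak-magnitude summary reports animal-level means and sds", {
  sim <- simulate_cohort(small_cohort_spec(seed = 13))
  pp <- lapply(sim$profiles, preprocess_profile)
  fits <- lapply(pp, fit_composite, variant = "2peak")
  recs <- biomarker_records(fits)
  sm <- summarize_peak_magnitudes(recs)
  expect_identical(nrow(sm), 10L) # 5 groups x 2 lobes
  expect_true(all(sm$n_subjects == 3))
  left <- sm[sm$lobe == "left", ]
  expect_lt(left$lipid_mean[left$group == "Day16"],
            left$lipid_mean[left$group == "Control"])
  expect_gt(left$water_mean[left$group == "Day16"],
            left$water_mean[left$group == "Control"])
})
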