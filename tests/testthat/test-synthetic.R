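# The synthetic-data generator: effect model, profile/frame simulators, and
# full cohorts with ground truth.

test_that("default effect model reproduces the progression narrative", {
  em <- default_effect_model()
  h0 <- c(lipid = default_control_params()$peaks$amplitude[1],
          water = default_control_params()$peaks$amplitude[2])
  ctl <- em[em$group == "Control", ]
  expect_equal(c(ctl$lipid, ctl$water), c(1, 1))
  days <- em[em$group != "Control", ]
  # lipid falls, water rises monotonically over Day2 -> Day16
  expect_true(all(diff(days$lipid) <= 0))
  expect_true(all(diff(days$water) >= 0))
  # Day 7: peak heights comparable
  d7 <- em[em$group == "Day7", ]
  h7 <- c(h0["lipid"] * d7$lipid, h0["water"] * d7$water)
  expect_lt(abs(h7[1] - h7[2]) / max(h7), 0.15)
  # Day 16: water dominates
  d16 <- em[em$group == "Day16", ]
  expect_gt(h0["water"] * d16$water, h0["lipid"] * d16$lipid)
  # Days 2 and 4 stay close to control
  expect_true(all(abs(c(days$lipid[1:2], days$water[1:2]) - 1) <= 0.15))
})

test_that("profile simulator is seeded, Poisson-scaled, and exact when noiseless", {
  p <- default_control_params()
  a <- simulate_profile(p, seed = 5)
  b <- simulate_profile(p, seed = 5)
  expect_identical(a$profile$intensity, b$profile$intensity)
  expect_identical(a$profile$sigma, b$profile$sigma)
  c2 <- simulate_profile(p, seed = 6)
  expect_false(identical(a$profile$intensity, c2$profile$intensity))

  expect_length(a$profile$q, 414)
  expect_true(all(a$profile$sigma >= 0))

  # noiseless limit: exactly proportional to the composite model
  nl <- simulate_profile(p, noise = FALSE, noise_scale = 1e6)
  y <- composite_model(default_q_grid(), p)
  ratio <- nl$profile$intensity / y
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  expect_equal(sum(nl$profile$intensity), 1e6)

  expect_error(simulate_profile(p, q_grid = c(-1, 1, 2)), "positive")
})

test_that("frame simulator masks, seeds, and centers its rings correctly", {
  geom <- detector_geometry(beam_center = c(256.5, 256.5))
  p <- single_peak_params(center = 13.5, width = 0.5)
  sim <- simulate_frame(p, geom, shape = c(512, 512), total_counts = 1e6,
                        seed = 2)
  expect_false(any(sim$mask$excluded)) # no beamstop, no dead pixels
  sim_b <- simulate_frame(p, geom, shape = c(512, 512), total_counts = 1e6,
                          seed = 2)
  expect_identical(sim$frame$counts, sim_b$frame$counts)

  geom64 <- detector_geometry(beam_center = c(32.5, 32.5))
  withmask <- simulate_frame(p, geom64, shape = c(64, 64),
                             total_counts = 1e5, beamstop_radius_mm = 1,
                             dead_pixel_fraction = 0.01, seed = 2)
  expect_true(any(withmask$mask$provenance == "beamstop"))
  expect_identical(sum(withmask$mask$provenance == "dead"),
                   as.integer(round(0.01 * 64 * 64)))
  expect_true(all(withmask$frame$counts[withmask$mask$excluded] == 0))

  # beam stop swallowing the whole detector is rejected
  expect_error(simulate_frame(p, geom, shape = c(8, 8), total_counts = 1e5,
                              beamstop_radius_mm = 500),
               "whole detector")

  # azimuthal maximum of the expected image sits at the generating center
  noiseless <- simulate_frame(p, geom, shape = c(512, 512),
                              total_counts = 1e6, noise = FALSE)
  prof <- azimuthal_integrate(noiseless$frame, geom, noiseless$mask,
                              q_bin_edges(8, 15.5, 60))
  expect_lt(abs(prof$q[which.max(prof$intensity)] - 13.5), 0.125)
})

test_that("azimuthal integration of a simulated frame recovers the 1D shape", {
  geom <- detector_geometry(beam_center = c(256.5, 256.5))
  p <- default_control_params()
  sim <- simulate_frame(p, geom, shape = c(512, 512), total_counts = 1e6,
                        beamstop_radius_mm = 2, seed = 9)
  edges <- q_bin_edges(3.25, 15.5, 100)
  prof <- remove_nan(azimuthal_integrate(sim$frame, geom, sim$mask, edges))
  model <- composite_model(prof$q, p)
  expect_gt(stats::cor(prof$intensity, model), 0.99)
})

test_that("cohort simulation honors the study design and its seed", {
  spec <- cohort_spec(seed = 1)
  sim <- simulate_cohort(spec)
  expect_length(sim$profiles, 25 * 2 * 25)
  expect_identical(nrow(sim$truth), 1250L)
  expect_identical(length(unique(sim$truth$subject_id)), 25L)
  expect_identical(length(unique(sim$truth$group)), 5L)
  expect_true(all(table(sim$truth$subject_id) == 50))

  tiny <- simulate_cohort(cohort_spec(n_per_group = 1,
                                      positions_per_lobe = 1, seed = 2))
  expect_length(tiny$profiles, 10) # 5 groups x 2 lobes

  again <- simulate_cohort(spec)
  expect_identical(sim$truth, again$truth)
  expect_identical(sim$profiles[[37]]$intensity,
                   again$profiles[[37]]$intensity)
})

test_that("ground truth follows the effect model: trends and lobe control", {
  sim <- simulate_cohort(cohort_spec(seed = 4))
  tr <- sim$truth
  # left-lobe true heights: lipid non-increasing, water non-decreasing
  em <- default_effect_model()
  day_groups <- c("Day2", "Day4", "Day7", "Day16")
  left <- tr[tr$lobe == "left", ]
  mean_h <- function(g, col) mean(left[[col]][left$group == g])
  # compare the generating group means (effect x base), not the noisy draws
  expect_true(all(diff(em$lipid[match(day_groups, em$group)]) <= 0))
  expect_true(all(diff(em$water[match(day_groups, em$group)]) >= 0))
  # right lobe: no effect applied, group-mean ratios vary less than the
  # inter-subject CV
  right <- tr[tr$lobe == "right", ]
  per_subj <- unique(right[, c("subject_id", "group", "true_ratio")])
  gm <- tapply(per_subj$true_ratio, per_subj$group, mean)
  expect_lt(stats::sd(gm) / mean(gm), 0.15)
})

test_that("cohort spec validation rejects broken designs", {
  expect_error(cohort_spec(n_per_group = 0))
  expect_error(cohort_spec(noise_scale = -1))
  em <- default_effect_model()
  em$lipid[2] <- -0.5
  expect_error(cohort_spec(effect_model = em), "> 0")
  em2 <- default_effect_model()
  em2$water[em2$group == "Control"] <- 1.1
  expect_error(cohort_spec(effect_model = em2), "Control")
})
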