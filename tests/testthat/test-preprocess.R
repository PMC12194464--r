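# Preprocessing: background subtraction, NaN removal, windowing, L1
# normalization, cleaning, group averaging.

mk_prof <- function(q, i, s = sqrt(pmax(i, 1)), meta = list())
  profile1d(q, i, s, meta = meta)

test_that("background subtraction differences intensities, quadrature sigmas", {
  q <- seq(4, 20, by = 0.5)
  a <- mk_prof(q, 10 + q, s = rep(2, length(q)))
  zero <- mk_prof(q, rep(0, length(q)), s = rep(0, length(q)))
  expect_equal(subtract_background(a, zero)$intensity, a$intensity)
  self <- subtract_background(a, a)
  expect_equal(self$intensity, rep(0, length(q)))
  expect_equal(self$sigma, a$sigma * sqrt(2))
  roundtrip <- subtract_background(a, zero)
  back <- profile1d(q, roundtrip$intensity + zero$intensity, a$sigma)
  expect_equal(back$intensity, a$intensity)
  expect_error(subtract_background(a, mk_prof(q + 0.1, a$intensity)),
               "grids differ")
})

test_that("NaN removal drops non-finite rows, preserves order, idempotent", {
  q <- 1:10
  i <- c(1, 2, NA, 4, 5, Inf, 7, 8, 9, 10)
  p <- profile1d(q, i, rep(1, 10))
  clean <- remove_nan(p)
  expect_length(clean$q, 8)
  expect_true(all(diff(clean$q) > 0))
  expect_identical(remove_nan(clean), clean)
  full <- mk_prof(q, rep(1, 10))
  expect_identical(remove_nan(full), full)
  expect_error(remove_nan(profile1d(1:3, rep(NA_real_, 3))), "no finite")
})

test_that("q-window restriction keeps the closed interval", {
  grid <- default_q_grid()
  p <- mk_prof(grid, rep(1, length(grid)))
  expect_identical(restrict_q(p, 3.25, 21), p) # full window: all 414 points
  expect_length(restrict_q(p, 3.25, 21)$q, 414)
  win <- restrict_q(p, 10, 20.5)
  expect_identical(length(win$q), sum(grid >= 10 & grid <= 20.5))
  expect_error(restrict_q(p, 30, 40), "no points")
  expect_error(restrict_q(p, 5, 5), "q_min < q_max")
})

test_that("L1 normalization has unit mass, idempotence and scale invariance", {
  p <- mk_prof(c(1, 2), c(1, 3))
  n1 <- l1_normalize(p)
  expect_equal(n1$intensity, c(0.25, 0.75))
  expect_equal(l1_normalize(n1)$intensity, n1$intensity)
  scaled <- l1_normalize(mk_prof(c(1, 2), 17.3 * c(1, 3)))
  expect_equal(scaled$intensity, n1$intensity)
  # mass invariant on arbitrary synthetic profiles
  for (seed in 1:5) {
    s <- simulate_profile(default_control_params(), seed = seed)
    norm <- l1_normalize(s$profile)
    expect_lt(abs(sum(abs(norm$intensity)) - 1), 1e-12)
  }
  expect_error(l1_normalize(mk_prof(1:3, rep(0, 3))), "mass")
})

test_that("the canonical preprocessing order is fixed and composable", {
  s <- simulate_profile(default_control_params(), seed = 3)
  manual <- l1_normalize(restrict_q(remove_nan(s$profile), 3.25, 21))
  auto <- preprocess_profile(s$profile)
  expect_identical(auto$intensity, manual$intensity)
  expect_identical(auto$sigma, manual$sigma)
})

test_that("cleaning keeps nominal cohorts and rejects the pathological", {
  sim <- simulate_cohort(cohort_spec(seed = 11))
  res <- clean_profiles(sim$profiles)
  expect_identical(nrow(res$report), 1250L)
  expect_gte(mean(res$report$retained), 0.99)

  # an all-zero profile fails on mass
  grid <- default_q_grid()
  dead <- profile1d(grid, rep(0, 414), rep(0, 414),
                    meta = list(group = "Control", lobe = "left"))
  res2 <- clean_profiles(c(sim$profiles[1:20], list(dead)))
  rep2 <- res2$report
  expect_false(rep2$retained[21])
  expect_identical(rep2$reason[21], "non-positive mass")

  # a gross intensity artifact fails the robust shape rule
  victim <- sim$profiles[[1]]
  spiked <- victim$intensity
  idx <- seq(1, length(spiked), by = 2)
  spiked[idx] <- spiked[idx] * 100
  outlier <- profile1d(victim$q, spiked, victim$sigma, meta = victim$meta)
  stratum <- sim$profiles[vapply(sim$profiles, function(p)
    identical(p$meta$group, victim$meta$group) &&
      identical(p$meta$lobe, victim$meta$lobe), logical(1))]
  res3 <- clean_profiles(c(stratum, list(outlier)))
  rep3 <- res3$report
  expect_identical(rep3$reason[nrow(rep3)], "shape outlier")
  expect_true(all(rep3$retained[-nrow(rep3)]))

  # a mostly-NaN profile fails on finite fraction
  holey <- victim$intensity
  holey[1:42] <- NaN # > 5% of 414
  res4 <- clean_profiles(c(sim$profiles[1:10],
                           list(profile1d(victim$q, holey, victim$sigma,
                                          meta = victim$meta))))
  expect_identical(res4$report$reason[11], "low finite fraction")
})

test_that("group averaging uses SEM over profiles and ignores input order", {
  grid <- seq(4, 20, by = 0.5)
  m <- function(g, l, y) mk_prof(grid, y, meta = list(group = g, lobe = l))
  single <- group_average_profiles(list(m("A", "left", grid)))
  expect_equal(single[["A/left"]]$intensity, grid)
  expect_equal(single[["A/left"]]$sigma, rep(0, length(grid)))

  twins <- group_average_profiles(list(m("A", "left", grid),
                                       m("A", "left", grid)))
  expect_equal(twins[["A/left"]]$sigma, rep(0, length(grid)))

  set.seed(1)
  ps <- c(lapply(1:3, function(i) m("A", "left", grid + rnorm(length(grid)))),
          lapply(1:2, function(i) m("B", "right", 2 * grid)))
  a <- group_average_profiles(ps)
  b <- group_average_profiles(rev(ps))
  expect_equal(a, b)
  expect_error(group_average_profiles(list(m("A", "left", grid),
                                           mk_prof(grid + 1, grid,
                                                   meta = list(group = "A",
                                                               lobe = "left")))),
               "grids differ")
})

test_that("group means show the disease contrast in the expected q regions", {
  sim <- simulate_cohort(small_cohort_spec(seed = 8, n_per_group = 5))
  pp <- lapply(sim$profiles, preprocess_profile)
  means <- group_average_profiles(pp)
  region_mean <- function(p, lo, hi)
    mean(restrict_q(p, lo, hi)$intensity)
  d16 <- means[["Day16/left"]]; ctl <- means[["Control/left"]]
  expect_gt(region_mean(d16, 17, 19), region_mean(ctl, 17, 19)) # water up
  expect_lt(region_mean(d16, 12.5, 14.5), region_mean(ctl, 12.5, 14.5))
})
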