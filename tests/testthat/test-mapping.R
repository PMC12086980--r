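test_that("LMS z-score has its defining properties", {
  ref <- constant_lms(L = 1, M = 20, S = 0.1)
  # the median maps to zero, and the L = 1 case is exactly linear
  expect_equal(zbmi_score(20, 10, 1, ref), 0)
  expect_equal(zbmi_score(22, 10, 1, ref), 1)
  # strictly increasing in BMI at fixed age and sex
  ref2 <- synthetic_lms()
  b <- seq(12, 35, by = 0.5)
  z <- zbmi_score(b, age = 10, sex = 0, ref = ref2)
  expect_true(all(diff(z) > 0))
  # the L -> 0 limit agrees with the log form
  refL <- constant_lms(L = 1e-8, M = 20, S = 0.1)
  ref0 <- constant_lms(L = 0, M = 20, S = 0.1)
  expect_equal(zbmi_score(24, 10, 1, refL), zbmi_score(24, 10, 1, ref0),
               tolerance = 1e-6)
  # round trip through the inverse
  expect_equal(bmi_from_z(zbmi_score(17.3, 8, 0, ref2), 8, 0, ref2), 17.3,
               tolerance = 1e-10)
  expect_error(zbmi_score(20, 150, 1, ref2), "outside the reference range")
})

test_that("BMI sampling mapper matches the closed form for a linear reference", {
  ref <- constant_lms(L = 1, M = 20, S = 0.1)
  # with L = 1 and constant parameters, z = (bmi/M - 1)/S is linear, so
  # E[z] = (E[bmi]/M - 1)/S regardless of the BMI distribution
  m <- map_bmi_sampling(mean_bmi = 21, sd_bmi = 2.5, age_mean = 10,
                        age_sd = 1.5, prop_male = 0.5, ref = ref,
                        n_samples = 10000, seed = 3)
  expect_equal(m$method, "sampling")
  closed <- (21 / 20 - 1) / 0.1
  expect_lt(abs(m$mean - closed), 3 * m$mcse)
  # the lognormal moment matching preserves the mean, so this holds tightly
  expect_lt(abs(m$mean - closed), 0.05)
})

test_that("BMI sampling mapper is Monte-Carlo consistent", {
  ref <- synthetic_lms()
  args <- list(mean_bmi = 19, sd_bmi = 3, age_mean = 11, age_sd = 2,
               prop_male = 0.4, ref = ref)
  m1 <- do.call(map_bmi_sampling,
                c(args, n_samples = 1e6, seed = 1))
  m2 <- do.call(map_bmi_sampling,
                c(args, n_samples = 1e6, seed = 2))
  expect_lt(abs(m1$mean - m2$mean), 4 * sqrt(m1$mcse^2 + m2$mcse^2))
  # MC standard error shrinks as 1/sqrt(n)
  s1 <- do.call(map_bmi_sampling, c(args, n_samples = 1000, seed = 5))
  s2 <- do.call(map_bmi_sampling, c(args, n_samples = 100000, seed = 5))
  expect_lt(s2$mcse, s1$mcse / 5)
  # deterministic given the seed
  r1 <- do.call(map_bmi_sampling, c(args, n_samples = 2000, seed = 11))
  r2 <- do.call(map_bmi_sampling, c(args, n_samples = 2000, seed = 11))
  expect_identical(r1$mean, r2$mean)
})

test_that("percentile inversion has exact special cases", {
  # mean percentile 50 forces mu = 0 by symmetry
  m <- map_percentile_analytic(50, 15)
  expect_equal(m$mean, 0, tolerance = 1e-10)
  # degenerate SD -> mu = qnorm(mean/100), sigma = 0
  m0 <- map_percentile_analytic(70, 0)
  expect_equal(m0$mean, qnorm(0.7))
  expect_equal(m0$sd, 0)
  # an unattainably large SD has no solution
  expect_error(map_percentile_analytic(50, 60), "no solution")
})

test_that("percentile inversion recovers parameters from forward simulation", {
  set.seed(20)
  z <- rnorm(1e6, 0.5, 1)
  p <- 100 * pnorm(z)
  m <- map_percentile_analytic(mean(p), sd(p))
  expect_equal(m$mean, 0.5, tolerance = 1e-2)
  expect_equal(m$sd, 1, tolerance = 1e-2)
})

test_that("percentile inversion is self-consistent (moment round trip)", {
  for (mu in c(-0.8, 0, 0.6)) for (sg in c(0.6, 1.2)) {
    mm <- zbmeta:::.percentile_moments(mu, sg)
    inv <- map_percentile_analytic(mm[["mean"]], mm[["sd"]])
    expect_equal(inv$mean, mu, tolerance = 1e-5)
    expect_equal(inv$sd, sg, tolerance = 1e-5)
  }
})

test_that("prevalence inversion solves the normal tail equations", {
  # standard-normal tails above z = 1 and z = 2
  m <- map_prevalence(c(1 - pnorm(1), 1 - pnorm(2)), thresholds = c(1, 2))
  expect_equal(m$mean, 0, tolerance = 1e-10)
  expect_equal(m$sd, 1, tolerance = 1e-10)
  expect_false(m$sigma_assumed)
  # one category: median at the threshold, sigma fixed and flagged
  m1 <- map_prevalence(0.5, thresholds = 1.3)
  expect_equal(m1$mean, 1.3)
  expect_true(m1$sigma_assumed)
  # analytic round trip at (0.3, 1.2)
  pr <- c(1 - pnorm((1.036 - 0.3) / 1.2), 1 - pnorm((1.645 - 0.3) / 1.2))
  m2 <- map_prevalence(pr)
  expect_equal(m2$mean, 0.3, tolerance = 1e-6)
  expect_equal(m2$sd, 1.2, tolerance = 1e-6)
  # boundary and ordering errors
  expect_error(map_prevalence(c(0, 0.1), thresholds = c(1, 2)), "0 or 1")
  expect_error(map_prevalence(c(0.1, 0.2), thresholds = c(1, 2)), "ordering")
})

test_that("forward-simulated arm summaries invert correctly on each scale", {
  s <- simulate_arm_summaries(n_arms = 4, scale = "percentile",
                              n_per_arm = 20000, seed = 8)
  for (i in seq_len(nrow(s))) {
    inv <- map_percentile_analytic(s$mean[i], s$sd[i])
    expect_lt(abs(inv$mean - s$true_mu[i]), 0.05)
  }
  pv <- simulate_arm_summaries(n_arms = 4, scale = "prevalence",
                               n_per_arm = 50000, seed = 9, mu_range = c(0, 0.4))
  for (i in seq_len(nrow(pv))) {
    inv <- map_prevalence(c(pv$prop_above_1[i], pv$prop_above_2[i]),
                          thresholds = c(pv$threshold_1[i], pv$threshold_2[i]))
    expect_lt(abs(inv$mean - pv$true_mu[i]), 0.05)
  }
  bm <- simulate_arm_summaries(n_arms = 3, scale = "bmi", n_per_arm = 50000,
                               seed = 10, sigma = 0.8)
  for (i in seq_len(nrow(bm))) {
    inv <- map_bmi_sampling(bm$mean[i], bm$sd[i], bm$age_mean[i], bm$age_sd[i],
                            bm$prop_male[i], synthetic_lms(),
                            n_samples = 50000, seed = i)
    expect_lt(abs(inv$mean - bm$true_mu[i]), 0.1)
  }
})
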