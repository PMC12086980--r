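mk_obs <- function(arm, ref, cat, se) {
  data.frame(arm_id = arm, reference_arm_id = ref, followup_category = cat,
             se = se)
}

test_that("within-trial covariance follows the stated rules", {
  # single observation
  o1 <- mk_obs("a", "c", "short", 0.2)
  expect_equal(within_trial_covariance(o1), matrix(0.04))

  # same comparison at two times: off-diagonal rho_time * se_i * se_j
  o2 <- mk_obs(c("a", "a"), "c", c("short", "medium"), c(0.1, 0.2))
  V <- within_trial_covariance(o2, rho_time = 0.8)
  expect_equal(V[1, 2], 0.016)
  expect_equal(diag(V), c(0.01, 0.04))
  # sensitivity values are honoured
  expect_equal(within_trial_covariance(o2, rho_time = 0.95)[1, 2],
               0.95 * 0.1 * 0.2)
  expect_equal(within_trial_covariance(o2, rho_time = 0.5)[1, 2],
               0.5 * 0.1 * 0.2)

  # different comparisons sharing the reference arm: rho_arm
  o3 <- mk_obs(c("a", "b"), "c", "short", c(0.1, 0.3))
  expect_equal(within_trial_covariance(o3, rho_arm = 0.5)[1, 2],
               0.5 * 0.1 * 0.3)
  # no shared reference: independent
  o4 <- mk_obs(c("a", "b"), c("c", "d"), "short", c(0.1, 0.3))
  expect_equal(within_trial_covariance(o4)[1, 2], 0)

  # blocks are symmetric positive definite
  set.seed(2)
  o5 <- mk_obs(c("a", "a", "b", "b"), "c",
               c("short", "long", "short", "long"), runif(4, 0.05, 0.3))
  V5 <- within_trial_covariance(o5)
  expect_equal(V5, t(V5))
  expect_true(all(eigen(V5, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("random-effect structure encodes the multi-arm assumption", {
  # control-referenced: unit diagonal, tau^2/2 across arms and times
  o <- mk_obs(c("a", "a", "b"), "c", c("short", "medium", "short"),
              rep(0.1, 3))
  R <- re_structure(o, ref_is_control = rep(TRUE, 3))
  expect_equal(diag(R), rep(1, 3))
  expect_equal(R[1, 2], 0.5)  # same arm, different time
  expect_equal(R[1, 3], 0.5)  # different arm, same time
  expect_equal(R[2, 3], 0.5)

  # active-referenced difference still has unit variance
  o2 <- mk_obs("b", "a", "short", 0.1)
  R2 <- re_structure(o2, ref_is_control = FALSE)
  expect_equal(R2, matrix(1))

  # same active comparison at two times: every cross term is tau^2/2, so
  # Cov(u_b,s - u_a,s, u_b,l - u_a,l) = 1/2 - 1/2 - 1/2 + 1/2 = 0
  o3 <- mk_obs(c("b", "b"), "a", c("short", "long"), c(0.1, 0.1))
  R3 <- re_structure(o3, ref_is_control = c(FALSE, FALSE))
  expect_equal(R3[1, 2], 0)
})

test_that("whitened likelihood equals the explicit marginalisation oracle", {
  d <- tiny_data()
  prep <- zb_prepare(d)
  theta0 <- setNames(rep(0, ncol(prep$Xt)), colnames(prep$Xt))
  for (tau in c(0, 0.08, 0.3)) {
    ll <- zb_loglik(prep, theta0, tau)
    # oracle: per-trial explicit RE covariance via incidence x G x incidence'
    ll_oracle <- 0
    for (tid in unique(d$observations$trial_id)) {
      idx <- d$observations$trial_id == tid
      obs <- d$observations[idx, ]
      ric <- prep$design$control_ref[idx]
      Vw <- within_trial_covariance(obs)
      V <- marginal_cov_oracle(obs, ric, Vw, tau)
      ll_oracle <- ll_oracle + dmvnorm_log(obs$md, rep(0, nrow(obs)), V)
    }
    expect_equal(ll, ll_oracle, tolerance = 1e-8)
  }
  # and with a nonzero coefficient vector
  set.seed(4)
  th <- setNames(rnorm(ncol(prep$Xt), 0, 0.1), colnames(prep$Xt))
  X <- prep$design$X
  mu <- drop(X %*% th)
  ll <- zb_loglik(prep, th, 0.1)
  ll_oracle <- 0
  for (tid in unique(d$observations$trial_id)) {
    idx <- d$observations$trial_id == tid
    obs <- d$observations[idx, ]
    V <- marginal_cov_oracle(obs, prep$design$control_ref[idx],
                             within_trial_covariance(obs), 0.1)
    ll_oracle <- ll_oracle + dmvnorm_log(obs$md, mu[idx], V)
  }
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
})

test_that("likelihood reduces to the univariate normal and its quadrature", {
  trials <- trial_row("T")
  arms <- rbind(arm_row("T", "c", control = TRUE), arm_row("T", "a"))
  obs <- obs_row("T", "a", "c", md = 0.07, se = 0.2)
  d <- zb_data(trials, arms, obs)
  prep <- zb_prepare(d)
  th <- setNames(rep(0, ncol(prep$Xt)), colnames(prep$Xt))

  # tau = 0, mean = y: -log(sqrt(2 pi se^2)) at the maximum
  th["intercept"] <- 0.07
  expect_equal(zb_loglik(prep, th, 0), dnorm(0.07, 0.07, 0.2, log = TRUE))
  expect_equal(zb_loglik(prep, th, 0), -0.5 * log(2 * pi * 0.2^2))

  # tau > 0: numeric quadrature over the single random effect
  tau <- 0.15
  q <- integrate(function(u) dnorm(0.07, 0.07 + u, 0.2) * dnorm(u, 0, tau),
                 -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(zb_loglik(prep, th, tau), log(q), tolerance = 1e-9)

  # doubling the SE at fixed residual shifts the density by the Jacobian
  obs2 <- obs; obs2$se <- 0.4
  prep2 <- zb_prepare(zb_data(trials, arms, obs2))
  expect_equal(zb_loglik(prep2, th, 0),
               zb_loglik(prep, th, 0) - log(2))
})
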