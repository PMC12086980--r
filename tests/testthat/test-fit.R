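# draws of the intercept converted to its uncentred (all-indicators-zero)
# value, using the stored centring record
uncentred_intercept_draws <- function(fit) {
  m <- fit$design$means
  th <- fit$draws[, names(m), drop = FALSE]
  th[, "intercept"] - drop(th[, -1, drop = FALSE] %*% m[-1])
}

test_that("posterior summaries compute tail probabilities and intervals", {
  s <- zb_summarize(cbind(b = c(-1, -2, 3, 4)))
  expect_equal(s$p_lt0, 0.5)
  expect_equal(s$p_gt0, 0.5)
  s2 <- zb_summarize(cbind(b = c(-1, -2, -3)))
  expect_equal(s2$p_lt0, 1)
  # exact zeros count to neither side
  s3 <- zb_summarize(cbind(b = c(-1, 0, 0, 1)))
  expect_equal(s3$p_lt0 + s3$p_gt0, 0.5)
  expect_equal(s3$n_zero, 2)
  # large-sample normal draws give the familiar interval
  set.seed(1)
  s4 <- zb_summarize(cbind(z = rnorm(2e5)))
  expect_equal(s4$lower, -1.96, tolerance = 0.02)
  expect_equal(s4$upper, 1.96, tolerance = 0.02)
})

test_that("fixed-effects posterior matches the conjugate closed form", {
  sim <- simulate_zb_data(zb_sim_config(n_trials = 30), seed = 11)
  d <- sim$dataset
  fit <- zbmeta(d, effects = "fixed", chains = 2, iter = 4000, warmup = 1000,
                seed = 2)
  # oracle: theta | y ~ N((X'V^-1 X + D)^-1 X'V^-1 y, .), V block diagonal
  des <- build_design(d)
  X <- des$X
  p <- ncol(X)
  A <- diag(1 / 100, p)  # prior precision at sd 10
  b <- rep(0, p)
  for (tid in unique(d$observations$trial_id)) {
    idx <- d$observations$trial_id == tid
    V <- within_trial_covariance(d$observations[idx, , drop = FALSE])
    Xi <- X[idx, , drop = FALSE]
    A <- A + t(Xi) %*% solve(V, Xi)
    b <- b + t(Xi) %*% solve(V, d$observations$md[idx])
  }
  post_mean <- drop(solve(A, b))
  post_sd <- sqrt(diag(solve(A)))
  got <- fit$summary$mean[match(colnames(X), fit$summary$parameter)]
  expect_lt(max(abs(got - post_mean) / post_sd), 0.12)
  got_sd <- with(fit$summary, (upper - lower) / (2 * 1.96))[
    match(colnames(X), fit$summary$parameter)]
  expect_equal(got_sd, unname(post_sd), tolerance = 0.08)
})

test_that("fixed effects equal random effects with heterogeneity pinned at zero", {
  sim <- simulate_zb_data(zb_sim_config(n_trials = 30, tau = 0), seed = 12)
  fe <- zbmeta(sim$dataset, effects = "fixed", chains = 2, iter = 3000,
               warmup = 1000, seed = 5)
  re0 <- zbmeta(sim$dataset, effects = "random", tau_max = 1e-8, chains = 2,
                iter = 3000, warmup = 1000, seed = 5)
  cmp <- merge(fe$summary, re0$summary, by = "parameter")
  sd_fe <- (cmp$upper.x - cmp$lower.x) / (2 * 1.96)
  expect_lt(max(abs(cmp$mean.x - cmp$mean.y) / sd_fe), 0.15)
})

test_that("intercept-only reduction matches an independent JAGS oracle", {
  library(rjags)
  set.seed(33)
  n <- 60
  alpha_true <- -0.05; tau_true <- 0.1
  se <- runif(n, 0.05, 0.2)
  y <- alpha_true + rnorm(n, 0, tau_true) + rnorm(n, 0, se)
  trials <- do.call(rbind, lapply(seq_len(n), function(i)
    trial_row(paste0("T", i), age = 0, income = 0, ses = 0)))
  arms <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(arm_row(paste0("T", i), paste0("c", i), control = TRUE),
          arm_row(paste0("T", i), paste0("a", i)))))
  obs <- do.call(rbind, lapply(seq_len(n), function(i)
    obs_row(paste0("T", i), paste0("a", i), paste0("c", i), weeks = 20,
            md = y[i], se = se[i])))
  d <- zb_data(trials, arms, obs)
  fit <- zbmeta(d, chains = 2, iter = 6000, warmup = 2000, seed = 3)

  jm <- jags.model(textConnection("
    model {
      for (i in 1:n) {
        y[i] ~ dnorm(alpha + u[i], 1 / se2[i])
        u[i] ~ dnorm(0, 1 / tau2)
      }
      alpha ~ dnorm(0, 0.01)
      tau ~ dunif(0, 2)
      tau2 <- tau * tau
    }"), data = list(y = y, se2 = se^2, n = n),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
  update(jm, 2000, progress.bar = "none")
  sm <- coda.samples(jm, c("alpha", "tau"), 8000, progress.bar = "none")
  jsum <- summary(sm)$statistics
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "intercept"] - jsum["alpha", "Mean"]),
            0.01)
  expect_lt(abs(s$mean[s$parameter == "tau"] - jsum["tau", "Mean"]), 0.01)
  expect_lt(abs((s$upper - s$lower)[s$parameter == "intercept"] -
                  2 * 1.96 * jsum["alpha", "SD"]), 0.01)
})

test_that("centring leaves slopes and predictions invariant", {
  sim <- simulate_zb_data(zb_sim_config(n_trials = 40), seed = 14)
  fc <- zbmeta(sim$dataset, chains = 2, iter = 3000, warmup = 1000, seed = 6,
               center = TRUE)
  fu <- zbmeta(sim$dataset, chains = 2, iter = 3000, warmup = 1000, seed = 6,
               center = FALSE)
  cmp <- merge(fc$summary, fu$summary, by = "parameter")
  cmp <- cmp[!cmp$parameter %in% c("intercept"), ]
  sdc <- (cmp$upper.x - cmp$lower.x) / (2 * 1.96)
  expect_lt(max(abs(cmp$mean.x - cmp$mean.y) / sdc), 0.2)
  # centred intercept = uncentred intercept + sum(coef * mean)
  m <- fc$design$means
  au <- fu$summary$mean[fu$summary$parameter == "intercept"]
  ac <- fc$summary$mean[fc$summary$parameter == "intercept"]
  shift <- sum(fu$summary$mean[match(names(m)[-1], fu$summary$parameter)] *
                 m[-1])
  sd_a <- with(fc$summary, (upper - lower) / (2 * 1.96))[
    fc$summary$parameter == "intercept"]
  expect_lt(abs(ac - (au + shift)) / sd_a, 0.3)
  # predictions on new indicator rows agree
  nd <- data.frame(school = c(1, 0), pa_only = c(1, 0), education = 1,
                   age_group = c(0, 1), medium = 1)
  expect_equal(predict(fc, nd), predict(fu, nd), tolerance = 0.02)
})

test_that("active-referenced trials do not inform intercept or trial/time terms", {
  d1 <- tiny_data()
  d2 <- tiny_data()
  # perturb the trial-level covariates of trial B (active-vs-active only)
  d2$trials$age_group[d2$trials$trial_id == "B"] <- 1
  d2$trials$high_income[d2$trials$trial_id == "B"] <- 1
  des1 <- build_design(d1); des2 <- build_design(d2)
  expect_identical(des1$X, des2$X)
  expect_identical(des1$means, des2$means)
  # tau is barely identified on four observations; convergence warnings are
  # irrelevant to the identity being checked
  f1 <- suppressWarnings(quick_fit(d1))
  f2 <- suppressWarnings(quick_fit(d2))
  expect_equal(f1$summary, f2$summary)
})

test_that("fit recovers planted parameters on default-scale synthetic data", {
  sim <- simulate_zb_data(zb_sim_config(), seed = 21)
  fit <- zbmeta(sim$dataset, chains = 2, iter = 2000, warmup = 1000, seed = 9)
  expect_true(fit$convergence$ok)
  s <- fit$summary
  psd <- (s$upper - s$lower) / (2 * 1.96)
  chk <- function(par, truth) {
    i <- match(par, s$parameter)
    expect_lt(abs(s$mean[i] - truth) / psd[i], 3)
  }
  cf <- sim$truth$coefficients
  chk("pa_only", cf[["pa_only"]])
  chk("home", cf[["home"]])
  chk("age_group", cf[["age_group"]])
  chk("medium", cf[["medium"]])
  chk("tau", sim$truth$tau)
  au <- uncentred_intercept_draws(fit)
  expect_lt(abs(mean(au) - sim$truth$intercept) / sd(au), 3)
})
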