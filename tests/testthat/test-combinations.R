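all24 <- c(zb_indicators()$intervention, zb_indicators()$trial,
           zb_indicators()$time)

# brute-force plausibility filter over the full 2^k cube
brute_grid <- function(indicators, fix = NULL) {
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), length(indicators))))
  colnames(g) <- indicators
  ok <- rep(TRUE, nrow(g))
  if (all(c("medium", "long") %in% indicators))
    ok <- ok & !(g[, "medium"] == 1 & g[, "long"] == 1)
  if (all(c("diet_and_pa", "pa_only") %in% indicators))
    ok <- ok & !(g[, "diet_and_pa"] == 1 & g[, "pa_only"] == 1)
  mech <- intersect(c("participation", "education", "social_env",
                      "physical_env"), indicators)
  if (length(mech))
    ok <- ok & rowSums(g[, mech, drop = FALSE]) >= 1
  for (nm in names(fix)) ok <- ok & g[, nm] == fix[[nm]]
  g[ok, , drop = FALSE]
}

test_that("plausible-combination counts match brute force and the closed form", {
  # full system: 2^16 * 3 * 3 * 15
  expect_equal(count_plausible(all24), 8847360)
  # toy 5-indicator system (2 time, 2 behaviour, 1 mechanism): 3 * 3 * 1
  toy <- c("medium", "long", "diet_and_pa", "pa_only", "participation")
  expect_equal(count_plausible(toy), 9)
  bf <- brute_grid(toy)
  en <- enumerate_plausible(toy)
  expect_equal(nrow(en), nrow(bf))
  expect_setequal(apply(en, 1, paste, collapse = ""),
                  apply(bf, 1, paste, collapse = ""))
  # an 8-indicator mixed system with fixed values
  ids <- c("school", "electronic", "medium", "long", "pa_only",
           "diet_and_pa", "education", "physical_env")
  fix <- c(school = 1)
  bf2 <- brute_grid(ids, fix)
  en2 <- enumerate_plausible(ids, fix = fix)
  expect_equal(nrow(en2), nrow(bf2))
  expect_equal(count_plausible(ids, fix = fix), nrow(bf2))
  expect_setequal(apply(en2, 1, paste, collapse = ""),
                  apply(bf2, 1, paste, collapse = ""))
  # fixed columns are constant in the output
  expect_true(all(en2[, "school"] == 1))
  # contradictory fixing errors
  expect_error(enumerate_plausible(toy, fix = c(medium = 1, long = 1)),
               "contradictory")
  # property: count equals brute force over random subsets
  set.seed(50)
  for (r in 1:5) {
    sub <- sample(all24, sample(5:9, 1))
    expect_equal(count_plausible(sub), nrow(brute_grid(sub)))
  }
})

test_that("predictions are linear with an exactly de-centred intercept", {
  sim <- simulate_zb_data(zb_sim_config(n_trials = 40), seed = 51)
  fit <- quick_fit(sim$dataset, interactions = "age_group:electronic")
  cf <- coef(fit)
  m <- fit$design$means
  # all-zero row equals the de-centred intercept
  zero <- as.data.frame(matrix(0, 1, length(all24),
                               dimnames = list(NULL, all24)))
  a0 <- cf[["intercept"]] - sum(cf[names(m)[-1]] * m[-1])
  expect_equal(predict(fit, zero), a0)
  # toggling an indicator with no interactions moves the prediction by its
  # coefficient exactly
  one <- zero; one$school <- 1
  expect_equal(predict(fit, one) - predict(fit, zero),
               unname(cf["school"]))
  # and the interacting pair adds its product term
  both <- zero; both$age_group <- 1; both$electronic <- 1
  expect_equal(predict(fit, both) - predict(fit, zero),
               unname(cf["age_group"] + cf["electronic"] +
                        cf["age_group:electronic"]))
  # prediction of the mean-valued pseudo-row equals the centred intercept
  mrow <- as.data.frame(t(m[setdiff(names(m), "intercept")]))
  mrow <- mrow[!grepl(":", names(mrow))]
  pm <- a0 + sum(cf[names(mrow)] * unlist(mrow)) +
    cf[["age_group:electronic"]] * m[["age_group:electronic"]]
  expect_equal(pm, cf[["intercept"]], tolerance = 1e-10)
})

test_that("extreme profiling agrees with a brute-force sort oracle", {
  ids <- c("school", "electronic", "medium", "long", "pa_only",
           "diet_and_pa", "participation", "education")
  toy <- list(intercept = -0.02,
              coefficients = c(school = -0.03, electronic = 0.02,
                               medium = -0.036, long = -0.019,
                               pa_only = -0.227, diet_and_pa = 0.01,
                               participation = -0.005, education = 0.012),
              interactions = c("pa_only:electronic" = 0.08,
                               "school:medium" = -0.04))
  pr <- find_extremes(toy, tail = 0.05)
  # oracle: materialise, predict by hand, sort
  g <- brute_grid(ids)
  pred <- toy$intercept + drop(g %*% toy$coefficients[ids]) +
    toy$interactions[[1]] * g[, "pa_only"] * g[, "electronic"] +
    toy$interactions[[2]] * g[, "school"] * g[, "medium"]
  expect_equal(pr$n, nrow(g))
  expect_equal(pr$best$md, min(pred))
  expect_equal(pr$worst$md, max(pred))
  expect_equal(pr$fraction_beneficial, mean(pred < 0))
  k <- ceiling(0.05 * nrow(g))
  thr <- sort(pred)[k]
  best_set <- g[pred <= thr, , drop = FALSE]
  expect_equal(pr$profile$best_tail,
               unname(colMeans(best_set)[pr$profile$indicator]))
  thr_w <- sort(pred, decreasing = TRUE)[k]
  worst_set <- g[pred >= thr_w, , drop = FALSE]
  expect_equal(pr$profile$worst_tail,
               unname(colMeans(worst_set)[pr$profile$indicator]))
  # single-coefficient toy: the best row takes the sign-appropriate value
  toy1 <- list(intercept = 0,
               coefficients = c(school = -0.1, participation = 0.02))
  p1 <- find_extremes(toy1, rules = plausible_rules())
  expect_equal(unname(p1$best$rows[1, "school"]), 1)
  expect_equal(unname(p1$worst$rows[1, "school"]), 0)
  # ties at the extremes are all reported
  toy2 <- list(intercept = 0, coefficients = c(a = -0.1, b = 0))
  p2 <- find_extremes(toy2, rules = list())
  expect_equal(nrow(p2$best$rows), 2L)  # b free at the optimum
})

test_that("subgroup searches partition the grid and agree with the full search", {
  toy <- list(intercept = -0.04,
              coefficients = setNames(
                c(-0.227, 0.01, 0.033, 0.05, -0.04, -0.028, -0.284, -0.049,
                  rep(0, 16)),
                c("pa_only", "diet_and_pa", "home", "physical_env",
                  "multi_strategy", "integration", "age_group", "high_income",
                  setdiff(all24, c("pa_only", "diet_and_pa", "home",
                                   "physical_env", "multi_strategy",
                                   "integration", "age_group",
                                   "high_income")))),
              interactions = c("age_group:high_income" = 0.1))
  full <- find_extremes(toy)
  subs <- list(c(age_group = 0, high_income = 0),
               c(age_group = 0, high_income = 1),
               c(age_group = 1, high_income = 0),
               c(age_group = 1, high_income = 1))
  profs <- lapply(subs, function(s) subgroup_search(toy, s))
  expect_equal(sum(vapply(profs, `[[`, 0, "n")), full$n)
  bests <- vapply(profs, function(p) p$best$md, 0)
  expect_equal(min(bests), full$best$md)
  # the winning subgroup reproduces the full-grid best row
  win <- profs[[which.min(bests)]]
  expect_equal(win$best$rows, full$best$rows)
})
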