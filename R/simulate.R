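# Synthetic trial generator with known truth. The defaults emulate the scale
# and structure of the 204-trial childhood-obesity-prevention evidence base:
# ~250 intervention-vs-reference comparisons, ~295 time-point observations,
# indicator marginals at the coding-table percentages, between-trial SD 0.08,
# follow-up correlation 0.8 and observation SEs with median 0.05 zBMI units.

#' Configuration for the synthetic trial generator
#'
#' Defaults reproduce the study conditions of the real evidence base: trial
#' count, indicator marginal frequencies, multi-arm and multi-follow-up
#' structure, heterogeneity, residual correlation and standard-error scale.
#' True coefficients default to the headline posterior means of the primary
#' analysis, so that recovery runs are realistic in magnitude; coefficients
#' not listed are zero.
#'
#' @param n_trials number of trials (default 204).
#' @param p_multi_arm probability a trial has two active arms (default 0.225,
#'   giving ~250 comparisons from 204 trials).
#' @param p_no_control probability a multi-arm trial lacks a control arm, so
#'   its single comparison is active-vs-active.
#' @param indicator_probs named marginal probabilities of the 18
#'   intervention-level indicators. `diet_and_pa` and `pa_only` are sampled
#'   as one trichotomy (diet-alone the remainder); the four mechanism
#'   indicators are redrawn until at least one is 1.
#' @param trial_probs,p_rob_high marginals of the trial-level indicators and
#'   of high risk of bias per observation.
#' @param followup_probs distribution over the follow-up-category subsets a
#'   comparison is observed at (names over "s", "m", "l"; default tuned to
#'   the observed category marginals with ~1.18 observations per comparison).
#' @param intercept_at_mean mean-difference of the average intervention (the
#'   centred intercept), default -0.037.
#' @param coefficients named true coefficients (raw indicator scale).
#' @param interactions named true interaction coefficients (`"a:b"`).
#' @param tau between-trial heterogeneity SD (default 0.080).
#' @param rho_time,rho_arm residual correlations (defaults 0.8, 0.5).
#' @param se_meanlog,se_sdlog lognormal parameters of the observation SEs
#'   (default median 0.05 zBMI units).
#' @return list of class `zb_sim_config`.
#' @export
zb_sim_config <- function(
    n_trials = 204, p_multi_arm = 0.225, p_no_control = 0.03,
    indicator_probs = c(
      school = 0.708, home = 0.424, community = 0.280, individual = 0.476,
      electronic = 0.212, diet_and_pa = 0.548, pa_only = 0.272,
      multi_strategy = 0.644, duration_long = 0.500, intensity_high = 0.608,
      integration = 0.472, flexibility_choice = 0.464, fun_factor = 0.612,
      resonance = 0.524, participation = 0.672, education = 0.740,
      social_env = 0.696, physical_env = 0.316),
    trial_probs = c(age_group = 0.265, high_income = 0.858, mixed_ses = 0.770),
    p_rob_high = 0.241,
    followup_probs = c(s = 0.20, m = 0.34, l = 0.30, sm = 0.06, ml = 0.05,
                       sl = 0.02, sml = 0.03),
    intercept_at_mean = -0.037,
    coefficients = c(pa_only = -0.227, multi_strategy = -0.040,
                     integration = -0.028, physical_env = 0.050,
                     home = 0.033, age_group = -0.284, high_income = -0.049,
                     medium = -0.036, long = -0.019),
    interactions = numeric(0),
    tau = 0.080, rho_time = 0.8, rho_arm = 0.5,
    se_meanlog = log(0.05), se_sdlog = 0.4) {
  stopifnot(n_trials >= 1, tau >= 0, rho_time >= 0, rho_time < 1,
            all(indicator_probs >= 0 & indicator_probs <= 1),
            all(trial_probs >= 0 & trial_probs <= 1),
            abs(sum(followup_probs) - 1) < 1e-8,
            indicator_probs[["diet_and_pa"]] + indicator_probs[["pa_only"]] <= 1)
  structure(as.list(environment()), class = "zb_sim_config")
}

# population mean of each covariate implied by the config (independence
# approximation for interaction products)
.sim_means <- function(config) {
  m <- c(config$indicator_probs, config$trial_probs)
  fp <- config$followup_probs
  tot <- sum(fp * nchar(names(fp)))
  m["medium"] <- sum(fp[grepl("m", names(fp))]) / tot
  m["long"] <- sum(fp[grepl("l", names(fp))]) / tot
  m["rob_high"] <- config$p_rob_high
  m
}

#' Generate a synthetic analysis dataset with known truth
#'
#' Simulates trials, arms, indicator codings and observations under the
#' three-level model: observation = linear predictor + random effect +
#' residual, with random effects per (active arm, time) having variance
#' `tau^2` and covariance `tau^2/2` within trial, and residuals multivariate
#' normal under the within-trial covariance. Deterministic given the seed.
#'
#' @param config a [zb_sim_config()].
#' @param seed integer seed.
#' @return list of class `zb_sim`: `dataset` (a validated `zb_data`) and
#'   `truth` (list: `intercept` on the raw/uncentred scale,
#'   `intercept_at_mean`, `coefficients`, `interactions`, `tau`, per-
#'   observation `linpred` and random-effect draws `re`, and the config).
#' @export
simulate_zb_data <- function(config = zb_sim_config(), seed = 1) {
  stopifnot(inherits(config, "zb_sim_config"))
  set.seed(seed)
  ip <- config$indicator_probs
  means <- .sim_means(config)
  cf <- config$coefficients
  eta <- config$interactions
  cval <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  # uncentred intercept implied by the mean-level effect
  pair_nm <- if (length(eta)) strsplit(names(eta), ":", fixed = TRUE) else list()
  alpha0 <- config$intercept_at_mean - sum(vapply(names(cf), function(nm)
    cf[[nm]] * means[[nm]], 0)) -
    sum(vapply(seq_along(eta), function(k)
      eta[[k]] * means[[pair_nm[[k]][1]]] * means[[pair_nm[[k]][2]]], 0))

  draw_indicators <- function() {
    x <- stats::setNames(numeric(length(.zb_intervention)), .zb_intervention)
    beh <- sample(c("dpa", "pa", "diet"), 1, prob = c(
      ip[["diet_and_pa"]], ip[["pa_only"]],
      1 - ip[["diet_and_pa"]] - ip[["pa_only"]]))
    x["diet_and_pa"] <- as.numeric(beh == "dpa")
    x["pa_only"] <- as.numeric(beh == "pa")
    oth <- setdiff(.zb_intervention, c("diet_and_pa", "pa_only"))
    x[oth] <- stats::rbinom(length(oth), 1, ip[oth])
    mech <- c("participation", "education", "social_env", "physical_env")
    while (sum(x[mech]) == 0) x[mech] <- stats::rbinom(4, 1, ip[mech])
    x
  }

  cats <- c(s = "short", m = "medium", l = "long")
  b <- zb_followup_boundaries()
  rng <- list(short = c(12, b$medium_min), medium = c(b$medium_min, b$long_min),
              long = c(b$long_min, 130))

  trials <- list(); arms <- list(); obs <- list()
  re_rec <- numeric(0); lp_rec <- numeric(0)
  for (t in seq_len(config$n_trials)) {
    tid <- sprintf("T%03d", t)
    w <- stats::rbinom(3, 1, config$trial_probs)
    names(w) <- .zb_trial
    trials[[t]] <- data.frame(trial_id = tid, t(w))
    multi <- stats::runif(1) < config$p_multi_arm
    no_ctrl <- multi && stats::runif(1) < config$p_no_control
    n_act <- if (multi) 2L else 1L
    act_ids <- paste0(tid, "_a", seq_len(n_act))
    X <- t(vapply(seq_len(n_act), function(i) draw_indicators(),
                  numeric(length(.zb_intervention))))
    rownames(X) <- act_ids
    arm_df <- data.frame(trial_id = tid, arm_id = act_ids, is_control = 0L, X)
    if (!no_ctrl) {
      ctl <- data.frame(trial_id = tid, arm_id = paste0(tid, "_ctrl"),
                        is_control = 1L,
                        matrix(NA_real_, 1, length(.zb_intervention),
                               dimnames = list(NULL, .zb_intervention)))
      arm_df <- rbind(arm_df, ctl)
    }
    arms[[t]] <- arm_df

    cmp <- if (no_ctrl)
      data.frame(arm = act_ids[2], ref = act_ids[1]) else
      data.frame(arm = act_ids, ref = paste0(tid, "_ctrl"))
    ob_t <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
      pat <- sample(names(config$followup_probs), 1,
                    prob = config$followup_probs)
      cc <- cats[strsplit(pat, "")[[1]]]
      do.call(rbind, lapply(cc, function(ct) data.frame(
        trial_id = tid, arm_id = cmp$arm[i], reference_arm_id = cmp$ref[i],
        followup_weeks = stats::runif(1, rng[[ct]][1], rng[[ct]][2]),
        followup_category = ct,
        rob_high = stats::rbinom(1, 1, config$p_rob_high),
        se = stats::rlnorm(1, config$se_meanlog, config$se_sdlog),
        scale = "zbmi")))
    }))

    # linear predictor per observation
    vvec <- function(i) {
      v <- c(medium = as.numeric(ob_t$followup_category[i] == "medium"),
             long = as.numeric(ob_t$followup_category[i] == "long"),
             rob_high = ob_t$rob_high[i])
      v
    }
    uvec <- function(aid, i) c(X[aid, ], w, vvec(i))
    lp <- vapply(seq_len(nrow(ob_t)), function(i) {
      ua <- uvec(ob_t$arm_id[i], i)
      main_int <- function(u) sum(vapply(names(cf), function(nm)
        cf[[nm]] * u[[nm]], 0)) +
        sum(vapply(seq_along(eta), function(k)
          eta[[k]] * u[[pair_nm[[k]][1]]] * u[[pair_nm[[k]][2]]], 0))
      if (ob_t$reference_arm_id[i] %in% act_ids) {
        ur <- uvec(ob_t$reference_arm_id[i], i)
        main_int(ua) - main_int(ur)
      } else alpha0 + main_int(ua)
    }, 0)

    # random effects: u_{arm,time} = sqrt(tau^2/2) * (z0 + z_{arm,time})
    keys <- unique(data.frame(
      arm = c(ob_t$arm_id, ob_t$reference_arm_id[
        ob_t$reference_arm_id %in% act_ids]),
      time = c(ob_t$followup_category, ob_t$followup_category[
        ob_t$reference_arm_id %in% act_ids])))
    s2 <- config$tau / sqrt(2)
    z0 <- stats::rnorm(1)
    uu <- stats::setNames(s2 * (z0 + stats::rnorm(nrow(keys))),
                          paste(keys$arm, keys$time))
    re <- vapply(seq_len(nrow(ob_t)), function(i) {
      v <- uu[[paste(ob_t$arm_id[i], ob_t$followup_category[i])]]
      if (ob_t$reference_arm_id[i] %in% act_ids)
        v <- v - uu[[paste(ob_t$reference_arm_id[i],
                           ob_t$followup_category[i])]]
      v
    }, 0)

    Vw <- within_trial_covariance(ob_t, config$rho_time, config$rho_arm)
    eps <- drop(t(chol(Vw)) %*% stats::rnorm(nrow(ob_t)))
    ob_t$md <- lp + re + eps
    ob_t$followup_category <- NULL
    obs[[t]] <- ob_t
    re_rec <- c(re_rec, re); lp_rec <- c(lp_rec, lp)
  }

  dataset <- zb_data(do.call(rbind, trials), do.call(rbind, arms),
                     do.call(rbind, obs), select_times = FALSE)
  truth <- list(intercept = alpha0,
                intercept_at_mean = config$intercept_at_mean,
                coefficients = cf, interactions = eta, tau = config$tau,
                linpred = lp_rec, re = re_rec, means = means,
                config = config, seed = seed)
  structure(list(dataset = dataset, truth = truth), class = "zb_sim")
}

#' @export
print.zb_sim <- function(x, ...) {
  cat("<zb_sim> synthetic dataset (seed ", x$truth$seed, ")\n", sep = "")
  print(x$dataset)
  cat("true tau = ", x$truth$tau, "; true intercept at mean indicators = ",
      x$truth$intercept_at_mean, "\n", sep = "")
  invisible(x)
}

#' Simulate arm-level outcome summaries on a reporting scale
#'
#' Forward model for testing the outcome-mapping inverters: draws arms with
#' known true mean zBMI, simulates individuals, and summarises them on the
#' requested reporting scale.
#'
#' @param n_arms number of arms.
#' @param scale reporting scale: `"bmi"`, `"percentile"` or `"prevalence"`.
#' @param ref LMS reference (used for the BMI scale).
#' @param mu_range range of true mean zBMI across arms.
#' @param sigma true within-arm SD of zBMI.
#' @param n_per_arm individuals per arm.
#' @param age_mean,age_sd,prop_male demographics of each arm.
#' @param thresholds zBMI thresholds for the prevalence scale.
#' @param seed integer seed.
#' @return data.frame of arm summaries; column `true_mu` holds the true mean
#'   zBMI for inversion tests.
#' @export
simulate_arm_summaries <- function(n_arms = 10,
                                   scale = c("bmi", "percentile", "prevalence"),
                                   ref = synthetic_lms(), mu_range = c(-0.5, 0.5),
                                   sigma = 1, n_per_arm = 500, age_mean = 10,
                                   age_sd = 1, prop_male = 0.5,
                                   thresholds = c(1.036, 1.645), seed = 1) {
  scale <- match.arg(scale)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_arms), function(a) {
    mu <- stats::runif(1, mu_range[1], mu_range[2])
    z <- stats::rnorm(n_per_arm, mu, sigma)
    base <- data.frame(arm = a, scale = scale, n = n_per_arm, true_mu = mu,
                       age_mean = age_mean, age_sd = age_sd,
                       prop_male = prop_male)
    if (scale == "bmi") {
      age <- pmin(pmax(stats::rnorm(n_per_arm, age_mean, age_sd),
                       ref$age_range[1]), ref$age_range[2])
      sex <- stats::rbinom(n_per_arm, 1, prop_male)
      bmi <- bmi_from_z(z, age, sex, ref)
      cbind(base, mean = mean(bmi), sd = stats::sd(bmi))
    } else if (scale == "percentile") {
      p <- 100 * stats::pnorm(z)
      cbind(base, mean = mean(p), sd = stats::sd(p))
    } else {
      props <- vapply(thresholds, function(th) mean(z > th), 0)
      cbind(base, t(stats::setNames(props,
                                    paste0("prop_above_", seq_along(props)))),
            t(stats::setNames(thresholds,
                              paste0("threshold_", seq_along(thresholds)))))
    }
  }))
}
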