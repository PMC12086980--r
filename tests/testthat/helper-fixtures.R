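# Hand-built fixtures and independent oracles shared across tests.

ind_names <- zbmeta::zb_indicators()$intervention
wk <- 365.25 / 84  # weeks per month

# An active arm row with all indicators 0 except those named in `on`
arm_row <- function(trial, arm, on = character(), control = FALSE) {
  x <- as.list(setNames(rep(0, length(ind_names)), ind_names))
  if (control) x <- as.list(setNames(rep(NA_real_, length(ind_names)),
                                     ind_names))
  for (nm in on) x[[nm]] <- 1
  data.frame(trial_id = trial, arm_id = arm,
             is_control = as.integer(control), x)
}

obs_row <- function(trial, arm, ref, weeks = 20, rob = 0, md = 0, se = 0.1,
                    scale = "zbmi") {
  data.frame(trial_id = trial, arm_id = arm, reference_arm_id = ref,
             followup_weeks = weeks, rob_high = rob, md = md, se = se,
             scale = scale)
}

trial_row <- function(trial, age = 0, income = 1, ses = 1) {
  data.frame(trial_id = trial, age_group = age, high_income = income,
             mixed_ses = ses)
}

# Two-trial dataset: trial A = control + 2 active arms, two follow-up
# categories on arm a1; trial B = active-vs-active (no control arm).
tiny_data <- function(md = NULL) {
  trials <- rbind(trial_row("A", age = 1, income = 1, ses = 0),
                  trial_row("B", age = 0, income = 0, ses = 1))
  arms <- rbind(arm_row("A", "A_c", control = TRUE),
                arm_row("A", "a1", on = c("school", "pa_only", "participation")),
                arm_row("A", "a2", on = c("home", "diet_and_pa", "education")),
                arm_row("B", "b1", on = c("school", "education")),
                arm_row("B", "b2", on = c("school", "electronic", "education")))
  obs <- rbind(obs_row("A", "a1", "A_c", weeks = 20, md = -0.1, se = 0.10),
               obs_row("A", "a1", "A_c", weeks = 45, md = -0.15, se = 0.12),
               obs_row("A", "a2", "A_c", weeks = 20, md = 0.05, se = 0.08),
               obs_row("B", "b2", "b1", weeks = 70, md = -0.02, se = 0.09,
                       rob = 1))
  if (!is.null(md)) obs$md <- md
  zbmeta::zb_data(trials, arms, obs)
}

# Multivariate normal log-density via base solve()/determinant(): the
# independent route used to check the whitened likelihood.
dmvnorm_log <- function(y, mu, V) {
  r <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
}

# Explicit random-effect marginalisation oracle for one trial: builds the
# per-(active arm, time) effect covariance G (Var tau^2, Cov tau^2/2), the
# incidence of effects onto observations, and the resulting marginal
# covariance Vw + B G B'.
marginal_cov_oracle <- function(obs, ref_is_control, Vw, tau) {
  act_ref <- !ref_is_control
  keys <- unique(rbind(
    data.frame(arm = as.character(obs$arm_id),
               time = as.character(obs$followup_category)),
    data.frame(arm = as.character(obs$reference_arm_id)[act_ref],
               time = as.character(obs$followup_category)[act_ref])))
  m <- nrow(keys)
  G <- matrix(tau^2 / 2, m, m) + diag(tau^2 / 2, m)
  B <- matrix(0, nrow(obs), m)
  kk <- paste(keys$arm, keys$time)
  for (i in seq_len(nrow(obs))) {
    B[i, match(paste(obs$arm_id[i], obs$followup_category[i]), kk)] <- 1
    if (act_ref[i])
      B[i, match(paste(obs$reference_arm_id[i], obs$followup_category[i]),
                 kk)] <- -1
  }
  Vw + B %*% G %*% t(B)
}

quick_fit <- function(dataset, ...) {
  args <- list(dataset = dataset, chains = 2, iter = 800, warmup = 400,
               seed = 42)
  args[names(list(...))] <- list(...)
  do.call(zbmeta::zbmeta, args)
}
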