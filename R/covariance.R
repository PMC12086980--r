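# Within-trial covariance of the observed mean differences, and the
# random-effect structure shared by multi-arm and multi-follow-up trials.

#' Within-trial residual covariance block
#'
#' For the observations of one trial the residual covariance is built from the
#' reported standard errors: `se_i^2` on the diagonal;
#' `rho_time * se_i * se_j` between observations of the same comparison (same
#' intervention and reference arm) at different times; `rho_arm * se_i * se_j`
#' between different comparisons that share a reference arm; zero otherwise.
#' The block is checked for positive definiteness; a ridge of `1e-10 * mean
#' diagonal` is added once (with a message) if the Cholesky fails, and failure
#' after the ridge is an error.
#'
#' @param observations data.frame of one trial's observations (columns
#'   `arm_id`, `reference_arm_id`, `followup_category`, `se`).
#' @param rho_time correlation between follow-up times of the same comparison
#'   (default 0.8; sensitivity values 0.5 and 0.95).
#' @param rho_arm correlation between comparisons sharing a reference arm
#'   (default 0.5, the equal-variance common-control value).
#' @return symmetric positive-definite covariance matrix.
#' @export
within_trial_covariance <- function(observations, rho_time = 0.8,
                                    rho_arm = 0.5) {
  stopifnot(all(observations$se > 0), rho_time >= 0, rho_time < 1)
  se <- observations$se
  a <- as.character(observations$arm_id)
  r <- as.character(observations$reference_arm_id)
  tt <- as.character(observations$followup_category)
  n <- length(se)
  V <- diag(se^2, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      same_cmp <- a[i] == a[j] && r[i] == r[j]
      rho <- if (same_cmp && tt[i] != tt[j]) rho_time
             else if (!same_cmp && r[i] == r[j]) rho_arm
             else 0
      V[i, j] <- V[j, i] <- rho * se[i] * se[j]
    }
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    message("within-trial covariance not positive definite; adding ridge 1e-10")
    V <- V + diag(1e-10 * mean(diag(V)), n)
    ch <- tryCatch(chol(V), error = function(e)
      stop("within-trial covariance block is not positive definite ",
           "even after ridge"))
  }
  V
}

#' Random-effect structure matrix of one trial's observations
#'
#' Relative intervention effects carry a random effect per (active arm,
#' time point) with variance `tau^2` and covariance `tau^2 / 2` between any
#' two distinct (arm, time) effects of the same trial -- the usual network
#' meta-analysis multi-arm assumption, extended to multiple follow-up times.
#' Control arms carry no random effect. For an observation comparing arm `a`
#' with reference `r`, the effect is `u[a,t]` when `r` is a control and
#' `u[a,t] - u[r,t]` when `r` is active. The returned matrix `R` gives the
#' marginal random-effect covariance in units of `tau^2`: the trial's
#' contribution to the observation covariance is `tau^2 * R`.
#'
#' @param observations one trial's observations (columns `arm_id`,
#'   `reference_arm_id`, `followup_category`).
#' @param ref_is_control logical per observation: is the reference a control?
#' @return symmetric positive semi-definite matrix (unit diagonal).
#' @export
re_structure <- function(observations, ref_is_control) {
  a <- as.character(observations$arm_id)
  r <- as.character(observations$reference_arm_id)
  tt <- as.character(observations$followup_category)
  act <- !ref_is_control
  n <- length(a)
  g <- function(a1, t1, a2, t2) if (a1 == a2 && t1 == t2) 1 else 0.5
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- g(a[i], tt[i], a[j], tt[j])
    if (act[j]) v <- v - g(a[i], tt[i], r[j], tt[j])
    if (act[i]) v <- v - g(r[i], tt[i], a[j], tt[j])
    if (act[i] && act[j]) v <- v + g(r[i], tt[i], r[j], tt[j])
    R[i, j] <- R[j, i] <- v
  }
  R
}

#' Prepare a dataset for likelihood evaluation and fitting
#'
#' Builds the design, the per-trial residual covariance and random-effect
#' structure, and a whitened representation in which the marginal covariance
#' `V(tau) = V_W + tau^2 R` is simultaneously diagonalised: with
#' `V_W = L L'` and `Q diag(lambda) Q' = L^-1 R L^-T`, the transformed data
#' `y~ = Q' L^-1 y`, `X~ = Q' L^-1 X` have independent residuals with variance
#' `1 + tau^2 lambda_i`. This makes every likelihood evaluation and Gibbs
#' update a weighted least-squares computation.
#'
#' @param dataset a `zb_data` object.
#' @inheritParams build_design
#' @inheritParams within_trial_covariance
#' @return object of class `zb_prep`: list with the design, stacked whitened
#'   `y`, `X`, eigenvalues `lambda`, the constant part of the log-density, and
#'   per-trial bookkeeping.
#' @export
zb_prepare <- function(dataset, interactions = NULL, rho_time = 0.8,
                       rho_arm = 0.5, center = TRUE) {
  design <- build_design(dataset, interactions, center = center)
  ob <- dataset$observations
  tid <- as.character(ob$trial_id)
  trials <- unique(tid)
  n <- nrow(ob)
  yt <- numeric(n); Xt <- matrix(0, n, ncol(design$X),
                                 dimnames = list(NULL, colnames(design$X)))
  lambda <- numeric(n)
  logdet_vw <- 0
  for (tr in trials) {
    idx <- which(tid == tr)
    obs <- ob[idx, , drop = FALSE]
    Vw <- within_trial_covariance(obs, rho_time, rho_arm)
    R <- re_structure(obs, design$control_ref[idx])
    L <- t(chol(Vw))
    logdet_vw <- logdet_vw + 2 * sum(log(diag(L)))
    A <- forwardsolve(L, t(forwardsolve(L, R)))
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    Qt <- t(e$vectors)
    yt[idx] <- drop(Qt %*% forwardsolve(L, ob$md[idx]))
    Xt[idx, ] <- Qt %*% forwardsolve(L, design$X[idx, , drop = FALSE])
    lambda[idx] <- lam
  }
  structure(list(design = design, y = ob$md, yt = yt, Xt = Xt,
                 lambda = lambda, logdet_vw = logdet_vw, n = n,
                 rho_time = rho_time, rho_arm = rho_arm,
                 trial_id = tid),
            class = "zb_prep")
}

#' Marginal log-likelihood of the three-level model
#'
#' Evaluates the log-density of the observed mean differences under the model
#' with the random effects integrated out: per trial,
#' `y ~ N(X theta, V_W + tau^2 R)`.
#'
#' @param prep a [zb_prepare()] object.
#' @param theta coefficient vector in design-column order (or named).
#' @param tau between-trial heterogeneity SD (>= 0); 0 gives the fixed-effects
#'   model.
#' @return scalar log-likelihood.
#' @export
zb_loglik <- function(prep, theta, tau) {
  stopifnot(inherits(prep, "zb_prep"), tau >= 0)
  cn <- colnames(prep$Xt)
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), cn))
      stop("theta names do not match design columns")
    theta <- theta[cn]
  }
  stopifnot(length(theta) == ncol(prep$Xt))
  d <- 1 + tau^2 * prep$lambda
  r <- prep$yt - drop(prep$Xt %*% theta)
  -0.5 * (prep$n * log(2 * pi) + prep$logdet_vw + sum(log(d)) + sum(r^2 / d))
}
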