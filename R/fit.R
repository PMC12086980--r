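#' Fit the three-level Bayesian meta-regression
#'
#' Fits the multi-level meta-regression of mean differences in change from
#' baseline in zBMI on intervention-, trial- and time-point-level indicators.
#' The model is `y ~ N(X theta, V_W + tau^2 R)` per trial, where `V_W` is the
#' within-trial residual covariance built from the reported standard errors
#' (see [within_trial_covariance()]) and `tau^2 R` is the between-trial
#' random-effect covariance with the network-meta-analysis multi-arm structure
#' (see [re_structure()]). Coefficient priors are independent
#' `Normal(0, prior_coef_sd^2)` (a weakly informative realisation of
#' "uninformative" on the zBMI scale, where effects are well below 1 in
#' magnitude) and the heterogeneity SD prior is `Uniform(0, tau_max)`.
#' Sampling uses an exact blocked Gibbs sampler: the conditional for the
#' coefficient vector is conjugate multivariate normal and `tau` is updated by
#' slice sampling; this exploits a per-trial simultaneous diagonalisation so
#' each sweep costs one weighted least-squares solve.
#'
#' @param dataset a `zb_data` object (see [zb_data()], [read_zb_data()],
#'   [simulate_zb_data()]).
#' @param interactions interaction terms `"a:b"` to include as covariates.
#' @param effects `"random"` (primary) or `"fixed"` (tau fixed at zero).
#' @param rho_time within-comparison correlation across follow-up times
#'   (default 0.8; the study's sensitivity values are 0.5 and 0.95).
#' @param rho_arm correlation between comparisons sharing a reference arm.
#' @param prior_coef_sd prior SD of the coefficients (default 10).
#' @param tau_max upper bound of the uniform heterogeneity prior (default 2).
#' @param chains number of MCMC chains (>= 2 recommended).
#' @param iter total iterations per chain, including warmup.
#' @param warmup warmup (discarded) iterations per chain.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param center centre covariates about their dataset means (recommended; the
#'   intercept then represents the effect at mean indicator values).
#' @param ssvs optional [ssvs_config()]; gives the listed interaction columns
#'   a spike-and-slab mixture prior with latent inclusion indicators.
#' @return An object of class `zbmeta` with components `summary` (posterior
#'   mean, 95% credible interval, P(<0), P(>0), R-hat and effective sample
#'   size per parameter), `draws` (pooled post-warmup draws, columns =
#'   parameters plus `tau`), `chains` (per-chain draws), `design`, `prep`,
#'   `inclusion` (SSVS only) and `convergence`.
#' @seealso [summary.zbmeta()], [coef.zbmeta()], [predict.zbmeta()],
#'   [find_extremes()], [zb_ssvs()]
#' @examples
#' sim <- simulate_zb_data(zb_sim_config(n_trials = 30), seed = 1)
#' fit <- zbmeta(sim$dataset, chains = 2, iter = 600, warmup = 300, seed = 1)
#' coef(fit)["pa_only"]
#' @export
zbmeta <- function(dataset, interactions = NULL,
                   effects = c("random", "fixed"),
                   rho_time = 0.8, rho_arm = 0.5,
                   prior_coef_sd = 10, tau_max = 2,
                   chains = 2, iter = 4000, warmup = floor(iter / 2),
                   seed = 1, center = TRUE, ssvs = NULL) {
  effects <- match.arg(effects)
  stopifnot(inherits(dataset, "zb_data"), chains >= 1, iter > warmup,
            rho_time >= 0, rho_time < 1, tau_max > 0)
  prep <- zb_prepare(dataset, interactions, rho_time, rho_arm, center)
  p <- ncol(prep$Xt)
  prior_sd <- rep_len(prior_coef_sd, p)

  ssvs_int <- NULL
  if (!is.null(ssvs)) {
    stopifnot(inherits(ssvs, "zb_ssvs_config"))
    cand <- canon_terms(ssvs$candidates)
    idx <- match(cand, colnames(prep$Xt))
    if (anyNA(idx))
      stop("SSVS candidate(s) not in the design: ",
           paste(cand[is.na(idx)], collapse = ", "))
    ssvs_int <- list(idx = idx, p_incl = ssvs$p_incl,
                     spike_sd = ssvs$spike_sd, slab_sd = ssvs$slab_sd)
  }

  tau_fixed <- if (effects == "fixed") 0 else NULL
  # per-chain seeds stay inside the 32-bit integer range for any input seed
  runs <- lapply(seq_len(chains), function(ch)
    .gibbs_chain(prep$yt, prep$Xt, prep$lambda, prior_sd, tau_max, tau_fixed,
                 ssvs_int, iter, warmup,
                 seed = (as.integer(seed) %% 1000000L) * 1000L + ch))

  par_draws <- lapply(runs, function(r) cbind(r$theta, tau = r$tau))
  pooled <- do.call(rbind, par_draws)
  keep_tau <- effects == "random"
  report <- colnames(pooled)
  if (!keep_tau) report <- setdiff(report, "tau")

  summ <- zb_summarize(pooled[, report, drop = FALSE])
  summ$rhat <- vapply(report, function(cl)
    .split_rhat(lapply(par_draws, function(m) m[, cl])), 0)
  summ$ess <- vapply(report, function(cl)
    .ess(lapply(par_draws, function(m) m[, cl])), 0)

  conv <- list(max_rhat = max(summ$rhat, na.rm = TRUE),
               min_ess = min(summ$ess, na.rm = TRUE),
               ok = all(summ$rhat < 1.05, na.rm = TRUE))
  if (!conv$ok)
    warning("possible non-convergence: max split R-hat = ",
            format(conv$max_rhat, digits = 4))

  inclusion <- NULL
  if (!is.null(ssvs_int)) {
    im <- do.call(rbind, lapply(runs, `[[`, "incl"))
    inclusion <- data.frame(candidate = canon_terms(ssvs$candidates),
                            frequency = colMeans(im))
    inclusion$selected <- inclusion$frequency > ssvs$threshold
  }

  structure(list(call = match.call(), effects = effects,
                 summary = summ, draws = pooled, chains = par_draws,
                 design = prep$design, prep = prep,
                 inclusion = inclusion, convergence = conv,
                 n_observations = prep$n, seed = seed,
                 mcmc = list(chains = chains, iter = iter, warmup = warmup)),
            class = "zbmeta")
}

#' Posterior summaries of a draws matrix
#'
#' Posterior mean, central 95% credible interval (2.5 and 97.5 percentiles)
#' and the tail probabilities P(<0) and P(>0) per column. Draws exactly equal
#' to zero (a measure-zero event for continuous parameters) are counted to
#' neither side and reported in `n_zero`.
#'
#' @param draws numeric matrix, one column per parameter.
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `p_lt0`, `p_gt0`, `n_zero`.
#' @examples
#' zb_summarize(cbind(b = c(-1, -2, 3, 4)))
#' @export
zb_summarize <- function(draws) {
  draws <- as.matrix(draws)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    lower = apply(draws, 2, stats::quantile, 0.025),
    upper = apply(draws, 2, stats::quantile, 0.975),
    p_lt0 = colMeans(draws < 0),
    p_gt0 = colMeans(draws > 0),
    n_zero = colSums(draws == 0))
  rownames(out) <- NULL
  out
}

#' @export
print.zbmeta <- function(x, ...) {
  cat("Three-level Bayesian meta-regression (", x$effects, " effects), ",
      x$n_observations, " observations\n", sep = "")
  cat(x$mcmc$chains, " chains x ", x$mcmc$iter - x$mcmc$warmup,
      " post-warmup draws; max split R-hat ",
      format(x$convergence$max_rhat, digits = 4), "\n", sep = "")
  key <- x$summary[x$summary$parameter %in%
                     c("intercept", "pa_only", "diet_and_pa", "tau"), ]
  if (nrow(key)) print(key[1:6], row.names = FALSE, digits = 3)
  if (!is.null(x$inclusion)) {
    cat("SSVS inclusion frequencies:\n")
    print(x$inclusion, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.zbmeta <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.zbmeta", "data.frame")
  attr(out, "effects") <- object$effects
  out
}

#' @export
print.summary.zbmeta <- function(x, ...) {
  cat("Posterior summary (", attr(x, "effects"), " effects)\n", sep = "")
  print(as.data.frame(x)[c("parameter", "mean", "lower", "upper",
                           "p_lt0", "p_gt0", "rhat", "ess")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.zbmeta <- function(object, ...) {
  s <- object$summary
  stats::setNames(s$mean, s$parameter)
}

#' Predict mean differences for indicator combinations
#'
#' Evaluates the de-centred posterior-mean linear predictor for rows of
#' indicator values: `alpha_unc + sum(beta * x) + sum(eta * x_a * x_b)`, where
#' `alpha_unc = alpha_centred - sum(coef * centring mean)` converts the
#' intercept to its value at all-zero indicators. Predictions are mean
#' differences versus control in zBMI units; smaller is more beneficial.
#'
#' @param object a fitted `zbmeta` model.
#' @param newdata data.frame or matrix with one column per model covariate
#'   (missing covariates default to 0).
#' @param ... unused.
#' @return numeric vector of predicted mean differences.
#' @export
predict.zbmeta <- function(object, newdata, ...) {
  cf <- coef(object)
  means <- object$design$means
  covn <- setdiff(names(means), "intercept")
  covn <- covn[!grepl(":", covn, fixed = TRUE)]
  theta <- cf[names(means)]
  alpha_unc <- cf[["intercept"]] - sum(theta[-1] * means[-1])
  nd <- as.matrix(as.data.frame(newdata))
  X <- matrix(0, nrow(nd), length(covn), dimnames = list(NULL, covn))
  use <- intersect(colnames(nd), covn)
  X[, use] <- nd[, use]
  pred <- alpha_unc + drop(X %*% theta[covn])
  for (k in seq_len(nrow(object$design$pairs))) {
    a <- object$design$pairs[k, 1]; b <- object$design$pairs[k, 2]
    pred <- pred + theta[[paste(a, b, sep = ":")]] * X[, a] * X[, b]
  }
  unname(pred)
}

#' Forest-style plot of posterior coefficient estimates
#'
#' @param x a fitted `zbmeta` model.
#' @param parameters subset of parameter names to display (default: all but
#'   `tau`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.zbmeta <- function(x, parameters = NULL, ...) {
  s <- x$summary
  if (is.null(parameters)) parameters <- setdiff(s$parameter, "tau")
  s <- s[match(parameters, s$parameter), ]
  n <- nrow(s)
  ylim <- c(0.5, n + 0.5)
  graphics::plot(NA, xlim = range(c(s$lower, s$upper, 0)), ylim = ylim,
                 yaxt = "n", xlab = "Difference in mean difference (zBMI)",
                 ylab = "", ...)
  graphics::abline(v = 0, col = "grey60", lty = 2)
  yy <- rev(seq_len(n))
  graphics::segments(s$lower, yy, s$upper, yy)
  graphics::points(s$mean, yy, pch = 16)
  graphics::axis(2, at = yy, labels = s$parameter, las = 1, cex.axis = 0.7)
  invisible(x)
}
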