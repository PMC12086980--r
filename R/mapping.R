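# Mapping of arm-level outcome summaries reported on other scales
# (unstandardised BMI, BMI percentile, prevalence of overweight/obesity)
# onto the zBMI scale. Mapping applies at the arm-summary level; mapped arm
# means are differenced downstream exactly as directly-reported zBMI arms are.

.zb_mapping <- function(mean, sd = NA_real_, mcse = NA_real_, method,
                        extra = list()) {
  structure(c(list(mean = mean, sd = sd, mcse = mcse, method = method), extra),
            class = "zb_mapping")
}

#' @export
print.zb_mapping <- function(x, ...) {
  cat("<zb_mapping:", x$method, "> mean zBMI = ", format(x$mean, digits = 4),
      if (!is.na(x$sd)) paste0(", sd = ", format(x$sd, digits = 4)),
      if (!is.na(x$mcse)) paste0(" (MC SE ", format(x$mcse, digits = 3), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Map a BMI summary to mean zBMI by Monte Carlo sampling
#'
#' Draws `n_samples` pseudo-individuals -- BMI lognormal (moment-matched to the
#' reported mean and SD: `sdlog^2 = log(1 + SD^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2/2`), age normal truncated to the reference's
#' age range, sex Bernoulli -- transforms each through [zbmi_score()] and
#' returns the sample mean zBMI with its Monte-Carlo standard error.
#'
#' @param mean_bmi,sd_bmi reported arm mean and SD of BMI (kg/m^2).
#' @param age_mean,age_sd reported mean and SD of age (years).
#' @param prop_male reported proportion male, in `[0, 1]`.
#' @param ref an [lms_reference()] object.
#' @param n_samples number of Monte-Carlo draws (default 10 000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return A `zb_mapping` object with elements `mean`, `sd`, `mcse`,
#'   `method = "sampling"` and `age_truncation` (the probability mass of the
#'   age distribution cut off by the reference range).
#' @export
map_bmi_sampling <- function(mean_bmi, sd_bmi, age_mean, age_sd, prop_male,
                             ref, n_samples = 10000, seed = 1) {
  stopifnot(mean_bmi > 0, sd_bmi > 0, age_sd >= 0,
            prop_male >= 0, prop_male <= 1, inherits(ref, "lms_ref"))
  sdlog2 <- log(1 + sd_bmi^2 / mean_bmi^2)
  meanlog <- log(mean_bmi) - sdlog2 / 2
  lo <- ref$age_range[1]; hi <- ref$age_range[2]
  plo <- stats::pnorm(lo, age_mean, age_sd)
  phi <- stats::pnorm(hi, age_mean, age_sd)
  if (phi - plo <= 0)
    stop("reference age range cannot cover the arm's age distribution")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bmi <- stats::rlnorm(n_samples, meanlog, sqrt(sdlog2))
  age <- if (age_sd == 0) rep(age_mean, n_samples) else
    stats::qnorm(stats::runif(n_samples, plo, phi), age_mean, age_sd)
  age <- pmin(pmax(age, lo), hi)  # guard fp edges of the truncation
  sex <- stats::rbinom(n_samples, 1, prop_male)
  z <- zbmi_score(bmi, age, sex, ref)
  .zb_mapping(mean(z), sd = stats::sd(z), mcse = stats::sd(z) / sqrt(n_samples),
              method = "sampling",
              extra = list(n_samples = n_samples,
                           age_truncation = 1 - (phi - plo)))
}

# Equicorrelated standard bivariate normal orthant P(X <= a, Y <= a),
# correlation rho >= 0, via the one-factor representation
# X = sqrt(rho) T + sqrt(1-rho) E1 (and likewise Y).
.binorm_orthant <- function(a, rho) {
  if (rho <= 0) return(stats::pnorm(a)^2)
  if (rho >= 1) return(stats::pnorm(a))
  f <- function(t) stats::dnorm(t) *
    stats::pnorm((a - sqrt(rho) * t) / sqrt(1 - rho))^2
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# Moments of the percentile 100*Phi(Z) for Z ~ N(mu, sigma^2)
.percentile_moments <- function(mu, sigma) {
  a <- mu / sqrt(1 + sigma^2)
  rho <- sigma^2 / (1 + sigma^2)
  m <- 100 * stats::pnorm(a)
  v <- 100^2 * (.binorm_orthant(a, rho) - stats::pnorm(a)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Map a BMI-percentile summary to zBMI analytically
#'
#' Assumes zBMI in the arm is normal, `Z ~ N(mu, sigma^2)`, so that the BMI
#' percentile of an individual is `100 * Phi(Z)` with `Phi` the standard normal
#' CDF relative to the growth reference. Then
#' `E[percentile] = 100 * Phi(mu / sqrt(1 + sigma^2))` and the variance follows
#' from the equicorrelated bivariate-normal orthant probability with
#' correlation `sigma^2 / (1 + sigma^2)`. The pair `(mu, sigma)` is recovered
#' by matching these moments to the reported mean and SD: the mean fixes
#' `mu / sqrt(1 + sigma^2)` and a monotone one-dimensional root-find in `sigma`
#' matches the SD (tolerance 1e-8).
#'
#' @param mean_pct,sd_pct reported mean and SD of BMI percentile, in (0, 100).
#' @param sigma_max upper bracket for sigma (default 10); no root in
#'   `(0, sigma_max]` is a convergence error.
#' @return A `zb_mapping` object with `mean = mu`, `sd = sigma`,
#'   `method = "analytic"`.
#' @export
map_percentile_analytic <- function(mean_pct, sd_pct, sigma_max = 10) {
  stopifnot(mean_pct > 0, mean_pct < 100, sd_pct >= 0)
  a <- stats::qnorm(mean_pct / 100)
  if (sd_pct < 1e-6)
    return(.zb_mapping(a, sd = 0, method = "analytic"))
  sd_at <- function(sigma) .percentile_moments(
    a * sqrt(1 + sigma^2), sigma)[["sd"]]
  hi <- sd_at(sigma_max)
  if (sd_pct >= hi)
    stop("no solution with sigma in (0, ", sigma_max, "]: reported SD ",
         sd_pct, " exceeds attainable SD ", format(hi, digits = 5))
  root <- stats::uniroot(function(s) sd_at(s) - sd_pct,
                         lower = 1e-8, upper = sigma_max, tol = 1e-8)
  sigma <- root$root
  .zb_mapping(a * sqrt(1 + sigma^2), sd = sigma, method = "analytic")
}

#' Map overweight/obesity prevalence to mean zBMI under normality
#'
#' Given proportions of the arm above one or two zBMI thresholds (for example
#' the 85th- and 95th-percentile cut-offs z = 1.036 and z = 1.645), assumes
#' `Z ~ N(mu, sigma^2)` and solves the tail equations
#' `P(Z > z_k) = p_k`. With two categories both `mu` and `sigma` are
#' identified in closed form; with one category `sigma` is fixed (default 1,
#' the reference-population value) and only `mu` is solved for, which the
#' result flags.
#'
#' @param props proportions above each threshold, strictly inside (0, 1),
#'   strictly decreasing with increasing threshold.
#' @param thresholds zBMI thresholds; defaults `c(1.036, 1.645)` truncated to
#'   `length(props)`.
#' @param sigma SD used when only one category is available.
#' @return A `zb_mapping` object (`method = "prevalence"`); element
#'   `sigma_assumed` is `TRUE` when sigma was fixed rather than estimated.
#' @export
map_prevalence <- function(props, thresholds = c(1.036, 1.645)[seq_along(props)],
                           sigma = 1) {
  stopifnot(length(props) >= 1, length(props) == length(thresholds))
  if (any(props <= 0 | props >= 1))
    stop("proportions of 0 or 1 cannot be inverted under normality")
  o <- order(thresholds)
  thresholds <- thresholds[o]; props <- props[o]
  if (length(props) > 2)
    stop("at most two prevalence categories are supported")
  q <- stats::qnorm(1 - props)  # (z_k - mu) / sigma
  if (length(props) == 2) {
    if (diff(props) >= 0)
      stop("inconsistent ordering: proportion above the higher threshold ",
           "must be smaller")
    s <- diff(thresholds) / diff(q)
    mu <- thresholds[1] - s * q[1]
    .zb_mapping(mu, sd = s, method = "prevalence",
                extra = list(sigma_assumed = FALSE))
  } else {
    .zb_mapping(thresholds[1] - sigma * q[1], sd = sigma,
                method = "prevalence", extra = list(sigma_assumed = TRUE))
  }
}
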