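# Blocked Gibbs sampler for the whitened linear-Gaussian model
#   yt_i ~ N(xt_i' theta, 1 + tau^2 lambda_i)
# with independent normal priors on theta (optionally spike-and-slab mixture
# priors with latent Bernoulli inclusion indicators on selected columns) and a
# Uniform(0, tau_max) prior on tau. theta | tau, I is conjugate (one weighted
# least-squares draw); I | theta is an independent Bernoulli update per
# candidate; tau | theta is updated by shrinkage slice sampling on its bounded
# support.

.slice_tau <- function(tau, logf, tau_max, max_steps = 200) {
  y0 <- logf(tau) + log(stats::runif(1))
  L <- 0; R <- tau_max
  for (s in seq_len(max_steps)) {
    prop <- stats::runif(1, L, R)
    if (logf(prop) > y0) return(prop)
    if (prop < tau) L <- prop else R <- prop
  }
  tau  # degenerate slice; keep current value
}

.gibbs_chain <- function(yt, Xt, lambda, prior_sd, tau_max, tau_fixed,
                         ssvs, iter, warmup, seed) {
  set.seed(seed)
  n <- length(yt); p <- ncol(Xt)
  k <- if (is.null(ssvs)) 0L else length(ssvs$idx)
  prec <- 1 / prior_sd^2
  incl <- rep(1L, k)
  if (k) prec[ssvs$idx] <- 1 / ssvs$slab_sd^2
  theta <- numeric(p)
  tau <- if (is.null(tau_fixed)) min(0.1, tau_max / 2) else tau_fixed
  keep <- iter - warmup
  out_theta <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(Xt)))
  out_tau <- numeric(keep)
  out_incl <- if (k) matrix(NA_integer_, keep, k) else NULL

  for (s in seq_len(iter)) {
    w <- 1 / (1 + tau^2 * lambda)
    P <- crossprod(Xt * sqrt(w)) + diag(prec, p)
    b <- crossprod(Xt, w * yt)
    U <- chol(P)
    mu <- backsolve(U, forwardsolve(t(U), b))
    theta <- drop(mu + backsolve(U, stats::rnorm(p)))

    if (k) {
      th <- theta[ssvs$idx]
      l1 <- log(ssvs$p_incl) + stats::dnorm(th, 0, ssvs$slab_sd, log = TRUE)
      l0 <- log1p(-ssvs$p_incl) + stats::dnorm(th, 0, ssvs$spike_sd, log = TRUE)
      pr <- 1 / (1 + exp(l0 - l1))
      incl <- stats::rbinom(k, 1, pr)
      prec[ssvs$idx] <- ifelse(incl == 1, 1 / ssvs$slab_sd^2,
                               1 / ssvs$spike_sd^2)
    }

    if (is.null(tau_fixed)) {
      r2 <- (yt - drop(Xt %*% theta))^2
      logf <- function(tv) {
        d <- 1 + tv^2 * lambda
        -0.5 * (sum(log(d)) + sum(r2 / d))
      }
      tau <- .slice_tau(tau, logf, tau_max)
    }

    if (s > warmup) {
      out_theta[s - warmup, ] <- theta
      out_tau[s - warmup] <- tau
      if (k) out_incl[s - warmup, ] <- incl
    }
  }
  list(theta = out_theta, tau = out_tau, incl = out_incl)
}

# split-chain potential scale reduction factor (R-hat)
.split_rhat <- function(draws) {
  # draws: list of numeric vectors (one per chain)
  halves <- unlist(lapply(draws, function(v) {
    m <- floor(length(v) / 2)
    list(v[seq_len(m)], v[(length(v) - m + 1):length(v)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer initial positive sequence, pooled chains
.ess <- function(draws) {
  n <- length(draws[[1]]); m <- length(draws)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (v in draws) {
    if (stats::var(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (l in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[l] + ac[l + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  m * n / (1 + 2 * rho_sum / m)
}
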