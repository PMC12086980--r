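# Stochastic search variable selection (SSVS) over candidate interaction
# terms: each candidate coefficient gets a two-component normal mixture prior
# (narrow spike / wide slab) with a latent Bernoulli inclusion indicator; the
# posterior mean of the indicator is the inclusion frequency, and candidates
# selected more than half the time enter the final model.

#' Configure a spike-and-slab selection prior
#'
#' @param candidates character vector of interaction terms `"a:b"` subject to
#'   selection.
#' @param p_incl prior inclusion probability (default 0.5).
#' @param spike_sd SD of the spike (null) component; must be much smaller
#'   than `slab_sd`.
#' @param slab_sd SD of the slab component.
#' @param threshold posterior inclusion frequency above which a candidate is
#'   selected (default 0.5, strict).
#' @return object of class `zb_ssvs_config`.
#' @export
ssvs_config <- function(candidates, p_incl = 0.5, spike_sd = 0.01,
                        slab_sd = 1.0, threshold = 0.5) {
  stopifnot(p_incl > 0, p_incl < 1, spike_sd > 0, slab_sd > 0,
            length(candidates) >= 1)
  structure(list(candidates = candidates, p_incl = p_incl,
                 spike_sd = spike_sd, slab_sd = slab_sd,
                 threshold = threshold),
            class = "zb_ssvs_config")
}

#' Candidate interactions between age group and all other indicators
#'
#' @param dataset a `zb_data` object (supplies the current indicator set).
#' @return character vector of `"a:b"` terms.
#' @export
age_interaction_candidates <- function(dataset) {
  ind <- attr(dataset, "indicators")
  others <- setdiff(c(ind, .zb_trial, .zb_time), "age_group")
  unname(vapply(others, function(o)
    paste(sort(c("age_group", o)), collapse = ":"), ""))
}

#' Candidate interactions between behaviour targeted and all other indicators
#'
#' Crosses both behaviour dummies (`diet_and_pa` and `pa_only`, coded against
#' a diet-alone reference) with every other indicator; the two behaviour
#' dummies are never paired with each other or themselves.
#'
#' @param dataset a `zb_data` object.
#' @return character vector of `"a:b"` terms.
#' @export
behaviour_interaction_candidates <- function(dataset) {
  ind <- attr(dataset, "indicators")
  beh <- intersect(c("diet_and_pa", "pa_only"), ind)
  if (length(beh) == 0) stop("behaviour indicators are not present")
  others <- setdiff(c(ind, .zb_trial, .zb_time), beh)
  unname(unlist(lapply(beh, function(b) vapply(others, function(o)
    paste(sort(c(b, o)), collapse = ":"), ""))))
}

# canonical form of interaction term labels: alphabetical within each pair
canon_terms <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                                  function(v) paste(sort(v), collapse = ":"),
                                  "")

#' Run SSVS over a candidate interaction set
#'
#' Fits the full meta-regression with all candidate interactions included,
#' placing the spike-and-slab mixture prior on the candidate coefficients and
#' the ordinary normal prior on everything else. Deterministic given the seed.
#'
#' @param dataset a `zb_data` object.
#' @param candidates character vector of `"a:b"` interaction terms, or a
#'   ready-made [ssvs_config()].
#' @param effects,chains,iter,warmup,seed,rho_time,rho_arm passed to
#'   [zbmeta()].
#' @param ... further [ssvs_config()] settings (`p_incl`, `spike_sd`,
#'   `slab_sd`, `threshold`) when `candidates` is a character vector.
#' @return object of class `zb_ssvs`: list with `inclusion` (data.frame:
#'   candidate, frequency, selected), `fit` (the underlying `zbmeta`) and
#'   `config`.
#' @export
zb_ssvs <- function(dataset, candidates, effects = "random",
                    chains = 2, iter = 2000, warmup = floor(iter / 2),
                    seed = 1, rho_time = 0.8, rho_arm = 0.5, ...) {
  config <- if (inherits(candidates, "zb_ssvs_config")) candidates else
    ssvs_config(candidates, ...)
  fit <- zbmeta(dataset, interactions = config$candidates, effects = effects,
                chains = chains, iter = iter, warmup = warmup, seed = seed,
                rho_time = rho_time, rho_arm = rho_arm, ssvs = config)
  structure(list(inclusion = fit$inclusion, fit = fit, config = config),
            class = "zb_ssvs")
}

#' @export
print.zb_ssvs <- function(x, ...) {
  cat("<zb_ssvs> ", nrow(x$inclusion), " candidates; ",
      sum(x$inclusion$selected), " selected (frequency > ",
      x$config$threshold, ")\n", sep = "")
  print(x$inclusion[order(-x$inclusion$frequency), ],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stepwise interaction selection
#'
#' The three-stage procedure: (i) fit the model with no interactions; (ii)
#' SSVS over interactions between age group and all other indicators; (iii)
#' SSVS over interactions between the behaviour-targeted dummies and all
#' other indicators. Stages (ii) and (iii) are run independently and the
#' final interaction set is the union of candidates selected more than 50%
#' of the time in either.
#'
#' @inheritParams zb_ssvs
#' @param ssvs_settings list of [ssvs_config()] settings applied at stages
#'   (ii) and (iii).
#' @return list with components `stage1` (`zbmeta` fit without interactions),
#'   `stage2`, `stage3` (`zb_ssvs` results) and `selected` (character vector
#'   of interaction terms for the final model).
#' @export
stepwise_selection <- function(dataset, effects = "random", chains = 2,
                               iter = 2000, warmup = floor(iter / 2),
                               seed = 1, rho_time = 0.8, rho_arm = 0.5,
                               ssvs_settings = list()) {
  cfg <- function(cand) do.call(ssvs_config, c(list(candidates = cand),
                                               ssvs_settings))
  stage1 <- zbmeta(dataset, interactions = NULL, effects = effects,
                   chains = chains, iter = iter, warmup = warmup, seed = seed,
                   rho_time = rho_time, rho_arm = rho_arm)
  stage2 <- zb_ssvs(dataset, cfg(age_interaction_candidates(dataset)),
                    effects = effects, chains = chains, iter = iter,
                    warmup = warmup, seed = seed + 1,
                    rho_time = rho_time, rho_arm = rho_arm)
  stage3 <- zb_ssvs(dataset, cfg(behaviour_interaction_candidates(dataset)),
                    effects = effects, chains = chains, iter = iter,
                    warmup = warmup, seed = seed + 2,
                    rho_time = rho_time, rho_arm = rho_arm)
  sel <- union(stage2$inclusion$candidate[stage2$inclusion$selected],
               stage3$inclusion$candidate[stage3$inclusion$selected])
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3, selected = sel)
}
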