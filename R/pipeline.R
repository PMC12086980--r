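# End-to-end pipeline: validate -> screen -> stepwise SSVS -> final RE and FE
# fits -> posterior summary tables -> combination profile, with a manifest
# tying every output to its configuration and seed.

#' Render a posterior summary as a forest-style table
#'
#' One row per parameter with a 3-decimal `estimate (lower, upper)` string
#' (ASCII hyphens for minus signs) alongside the numeric columns and the
#' posterior tail probabilities.
#'
#' @param x a `zbmeta` fit or a posterior summary data.frame (from
#'   [zb_summarize()] / `fit$summary`).
#' @return data.frame with columns `parameter`, `estimate`, `lower`, `upper`,
#'   `formatted`, `p_lt0`, `p_gt0`.
#' @examples
#' forest_table(data.frame(parameter = "intercept", mean = -0.037,
#'                         lower = -0.053, upper = -0.022,
#'                         p_lt0 = 1, p_gt0 = 0))
#' @export
forest_table <- function(x) {
  s <- if (inherits(x, "zbmeta")) x$summary else as.data.frame(x)
  if (nrow(s) == 0)
    return(data.frame(parameter = character(), estimate = numeric(),
                      lower = numeric(), upper = numeric(),
                      formatted = character(), p_lt0 = numeric(),
                      p_gt0 = numeric()))
  data.frame(parameter = s$parameter,
             estimate = round(s$mean, 3),
             lower = round(s$lower, 3), upper = round(s$upper, 3),
             formatted = sprintf("%.3f (%.3f, %.3f)", s$mean, s$lower,
                                 s$upper),
             p_lt0 = round(s$p_lt0, 3), p_gt0 = round(s$p_gt0, 3))
}

#' Parse a rendered forest table back to numbers
#'
#' Inverse of the `formatted` column of [forest_table()].
#'
#' @param formatted character vector like `"-0.037 (-0.053, -0.022)"`.
#' @return data.frame with columns `estimate`, `lower`, `upper`.
#' @export
parse_forest <- function(formatted) {
  m <- regmatches(formatted,
                  regexec("^(-?[0-9.]+) \\((-?[0-9.]+), (-?[0-9.]+)\\)$",
                          formatted))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparseable forest entries: ",
                     paste(formatted[bad], collapse = "; "))
  out <- do.call(rbind, lapply(m, function(v) as.numeric(v[-1])))
  data.frame(estimate = out[, 1], lower = out[, 2], upper = out[, 3])
}

#' Read a model configuration from YAML
#'
#' Recognised fields: `rho_time`, `rho_arm`, `effects`, `outcome_subset`,
#' `chains`, `iter`, `warmup`, `seed`, `prior_coef_sd`, `tau_max`, and an
#' `ssvs` block (`p_incl`, `spike_sd`, `slab_sd`, `threshold`). Unset fields
#' take the package defaults.
#'
#' @param path YAML file path.
#' @return named list of validated settings.
#' @export
read_zb_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(rho_time = 0.8, rho_arm = 0.5, effects = "random",
                   outcome_subset = "all", chains = 2, iter = 4000,
                   warmup = NULL, seed = 1, prior_coef_sd = 10, tau_max = 2,
                   ssvs = list())
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$rho_time >= 0, cfg$rho_time < 1,
            cfg$effects %in% c("random", "fixed"),
            cfg$outcome_subset %in% c("all", "zbmi_only", "bmi_only",
                                      "zbmi_and_percentile"))
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes validate -> screen -> stepwise SSVS -> final random- and
#' fixed-effects fits (each with its own selected interaction set) ->
#' posterior summary and forest tables -> combination profile, writing every
#' stage's output to `out_dir` together with a JSON manifest (seed,
#' configuration, input/output checksums). Given the same dataset, settings
#' and seed the outputs are byte-identical.
#'
#' @param dataset a `zb_data` object, or `NULL` to simulate one.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @param sim_config [zb_sim_config()] used when `dataset` is `NULL`.
#' @param chains,iter,warmup MCMC settings shared by all fits.
#' @param rho_time,rho_arm residual correlation settings.
#' @param ssvs_settings list of [ssvs_config()] settings for the selection
#'   stages.
#' @param profile_fix optional fixed assignment for the combination profile.
#' @return list with the fitted objects (`screening`, `selection`, `fit_re`,
#'   `fit_fe`, `profile_re`) and `manifest`, invisibly; all outputs are also
#'   on disk in `out_dir`.
#' @export
run_zb_pipeline <- function(dataset = NULL, out_dir, seed = 1,
                            sim_config = zb_sim_config(),
                            chains = 2, iter = 2000,
                            warmup = floor(iter / 2),
                            rho_time = 0.8, rho_arm = 0.5,
                            ssvs_settings = list(),
                            profile_fix = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  simulated <- is.null(dataset)
  if (simulated)
    dataset <- stage("simulate", simulate_zb_data(sim_config, seed)$dataset)
  stage("validate", validate_zb_data(dataset))
  data_csv <- file.path(out_dir, "dataset.csv")
  write_zb_data(dataset, data_csv)
  utils::write.csv(describe_zb_data(dataset),
                   file.path(out_dir, "describe.csv"), row.names = FALSE)

  screening <- stage("screen", screen_indicators(dataset))
  utils::write.csv(screening$pairs, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)

  fits <- list(); profiles <- list(); selections <- list()
  for (eff in c("random", "fixed")) {
    tag <- if (eff == "random") "re" else "fe"
    sel <- stage(paste0("ssvs_", tag), stepwise_selection(
      dataset, effects = eff, chains = chains, iter = iter, warmup = warmup,
      seed = seed + ifelse(eff == "random", 0L, 100L),
      rho_time = rho_time, rho_arm = rho_arm,
      ssvs_settings = ssvs_settings))
    selections[[tag]] <- sel
    utils::write.csv(rbind(
      cbind(stage = "age", sel$stage2$inclusion),
      cbind(stage = "behaviour", sel$stage3$inclusion)),
      file.path(out_dir, paste0("ssvs_", tag, ".csv")), row.names = FALSE)
    fit <- stage(paste0("fit_", tag), zbmeta(
      dataset, interactions = sel$selected, effects = eff, chains = chains,
      iter = iter, warmup = warmup,
      seed = seed + ifelse(eff == "random", 10L, 110L),
      rho_time = rho_time, rho_arm = rho_arm))
    fits[[tag]] <- fit
    utils::write.csv(forest_table(fit),
                     file.path(out_dir, paste0("summary_", tag, ".csv")),
                     row.names = FALSE)
  }

  prof <- stage("combinations",
                find_extremes(fits$re, fix = profile_fix))
  utils::write.csv(prof$profile, file.path(out_dir, "profile_re.csv"),
                   row.names = FALSE)

  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("zbmeta")),
    seed = seed, simulated = simulated,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    rho_time = rho_time, rho_arm = rho_arm),
    selected_interactions = lapply(selections, `[[`, "selected"),
    checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = dataset, screening = screening,
                 selection = selections, fit_re = fits$re, fit_fe = fits$fe,
                 profile_re = prof, manifest = manifest))
}
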