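#' Assemble and validate an analysis dataset
#'
#' Builds the three-table representation of a comparison-level dataset: one row
#' per trial, one per arm (with intervention-level indicators on active arms
#' only; control arms are defined as the absence of any intervention and carry
#' no indicators) and one per observation (a mean difference in change from
#' baseline between an intervention arm and a reference arm at one follow-up
#' time, with its standard error).
#'
#' @param trials data.frame with columns `trial_id` and the trial-level
#'   indicators `age_group`, `high_income`, `mixed_ses` (binary).
#' @param arms data.frame with columns `trial_id`, `arm_id`, `is_control` and,
#'   for active arms, binary intervention-level indicator columns (see
#'   [zb_indicators()]). Indicator values on control arms must be `NA`.
#' @param observations data.frame with columns `trial_id`, `arm_id`,
#'   `reference_arm_id`, `followup_weeks`, `rob_high`, `md`, `se`, `scale`
#'   (one of `"zbmi"`, `"bmi"`, `"percentile"`, `"prevalence"`: the scale the
#'   trial originally reported on; `md`/`se` are on the zBMI scale after
#'   mapping). A `followup_category` column is recomputed from `followup_weeks`.
#' @param select_times apply [select_timepoints()] so that at most one
#'   observation remains per (trial, arm, reference, follow-up category).
#' @param validate run validity checks (recommended).
#' @return An object of class `zb_data`: a list with elements `trials`, `arms`,
#'   `observations`, plus counts `n_trials`, `n_arms`, `n_observations`,
#'   `n_comparisons`. The attribute `"indicators"` names the intervention-level
#'   indicator columns in use (screening may drop or merge columns). The
#'   attribute `"validation"` records rows dropped during assembly and why.
#' @seealso [read_zb_data()], [simulate_zb_data()], [describe_zb_data()]
#' @export
zb_data <- function(trials, arms, observations, select_times = TRUE,
                    validate = TRUE) {
  trials <- as.data.frame(trials)
  arms <- as.data.frame(arms)
  observations <- as.data.frame(observations)

  ind <- intersect(.zb_intervention, names(arms))
  extra <- setdiff(names(arms), c("trial_id", "arm_id", "is_control",
                                  .zb_intervention))
  # screening can create merged columns such as "home_or_home_activity"
  ind <- c(ind, extra[vapply(extra, function(cl)
    all(arms[[cl]] %in% c(0, 1, NA)), logical(1))])
  if (length(ind) == 0L)
    stop("no intervention-level indicator columns found in `arms`")

  dropped <- data.frame(row = integer(), reason = character())
  observations$followup_category <-
    categorize_followup(observations$followup_weeks)

  if (select_times) {
    sel <- select_timepoints(observations)
    if (nrow(sel) < nrow(observations)) {
      gone <- setdiff(seq_len(nrow(observations)), attr(sel, "kept_rows"))
      dropped <- rbind(dropped, data.frame(
        row = gone, reason = "time-point selection"))
    }
    observations <- sel
    attr(observations, "kept_rows") <- NULL
  }
  rownames(observations) <- NULL

  x <- structure(
    list(trials = trials, arms = arms, observations = observations,
         n_trials = nrow(trials), n_arms = nrow(arms),
         n_observations = nrow(observations),
         n_comparisons = nrow(unique(observations[
           c("trial_id", "arm_id", "reference_arm_id")]))),
    class = "zb_data", indicators = ind, validation = dropped)
  if (validate) validate_zb_data(x)
  x
}

#' @export
print.zb_data <- function(x, ...) {
  cat("<zb_data> ", x$n_trials, " trials, ", x$n_arms, " arms, ",
      x$n_comparisons, " comparisons, ", x$n_observations,
      " time-point observations\n", sep = "")
  cat("intervention-level indicators: ",
      paste(attr(x, "indicators"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate an analysis dataset
#'
#' Checks the structural invariants of a `zb_data` object: positive standard
#' errors, binary fully-observed indicators on active arms, no indicators on
#' control arms, trial-level indicators constant within trial, references
#' resolving to arms of the same trial, and follow-up categories consistent
#' with follow-up times. Errors name the offending rows.
#'
#' @param x a `zb_data` object.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_zb_data <- function(x) {
  stopifnot(inherits(x, "zb_data"))
  tr <- x$trials; ar <- x$arms; ob <- x$observations
  ind <- attr(x, "indicators")

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("missing required column(s) in ", what, ": ",
           paste(miss, collapse = ", "))
  }
  req(tr, c("trial_id", .zb_trial), "trials")
  req(ar, c("trial_id", "arm_id", "is_control"), "arms")
  req(ob, c("trial_id", "arm_id", "reference_arm_id", "followup_weeks",
            "followup_category", "rob_high", "md", "se", "scale"), "observations")

  for (cl in .zb_trial)
    if (!all(tr[[cl]] %in% c(0, 1)))
      stop("non-binary trial-level indicator: ", cl)

  act <- !as.logical(ar$is_control)
  for (cl in ind) {
    v <- ar[[cl]]
    if (anyNA(v[act]))
      stop("missing indicator value(s) in '", cl, "' on active arm(s) ",
           paste(ar$arm_id[act & is.na(v)], collapse = ", "))
    if (!all(v[act] %in% c(0, 1)))
      stop("non-binary indicator value in '", cl, "'")
    if (any(!is.na(v[!act])))
      stop("control arm(s) carry intervention indicators: ",
           paste(ar$arm_id[!act & !is.na(v)], collapse = ", "))
  }
  if (any(ar$pa_only %in% 1 & ar$diet_and_pa %in% 1))
    stop("arms coded both 'pa_only' and 'diet_and_pa' (mutually exclusive)")

  bad <- which(!(ob$se > 0))
  if (length(bad))
    stop("non-positive standard error in observation row(s) ",
         paste(bad, collapse = ", "))
  if (!all(ob$rob_high %in% c(0, 1)))
    stop("non-binary rob_high value in observations")

  key <- paste(ar$trial_id, ar$arm_id)
  if (!all(paste(ob$trial_id, ob$arm_id) %in% key))
    stop("observation references unknown intervention arm")
  if (!all(paste(ob$trial_id, ob$reference_arm_id) %in% key))
    stop("observation reference arm not found in the same trial")
  if (any(as.character(ob$arm_id) == as.character(ob$reference_arm_id)))
    stop("observation compares an arm with itself")

  nctl <- tapply(as.logical(ar$is_control), ar$trial_id, sum)
  if (any(nctl > 1))
    stop("trial(s) with more than one control arm: ",
         paste(names(nctl)[nctl > 1], collapse = ", "))
  narm <- table(ar$trial_id)
  if (any(narm < 2))
    stop("trial(s) with fewer than two arms: ",
         paste(names(narm)[narm < 2], collapse = ", "))

  cc <- categorize_followup(ob$followup_weeks)
  if (!all(cc == ob$followup_category))
    stop("followup_category inconsistent with followup_weeks in row(s) ",
         paste(which(cc != ob$followup_category), collapse = ", "))

  dup <- duplicated(ob[c("trial_id", "arm_id", "reference_arm_id",
                         "followup_category")])
  if (any(dup))
    stop("multiple observations per (trial, arm, reference, category); ",
         "run select_timepoints()")
  invisible(x)
}

#' Categorise follow-up times into short, medium and long term
#'
#' Short term runs from 12 weeks to under 9 months, medium term from 9 to
#' under 15 months, and long term from 15 months onwards (boundary inclusive).
#' Months are converted at 365.25/84 weeks per month.
#'
#' @param followup_weeks numeric vector of follow-up times in weeks (>= 12).
#' @return factor with levels `short`, `medium`, `long`.
#' @examples
#' categorize_followup(c(12, 10 * 365.25 / 84, 15 * 365.25 / 84))
#' @export
categorize_followup <- function(followup_weeks) {
  if (any(followup_weeks < 12))
    stop("follow-up time(s) below 12 weeks are outside the analysis window: ",
         paste(which(followup_weeks < 12), collapse = ", "))
  b <- zb_followup_boundaries()
  cut(followup_weeks, breaks = c(12, b$medium_min, b$long_min, Inf),
      labels = c("short", "medium", "long"), right = FALSE,
      include.lowest = TRUE)
}

#' Select one observation per comparison and follow-up category
#'
#' Where a comparison (trial, intervention arm, reference arm) is observed at
#' more than one time within a follow-up category, the observation closest to
#' the category target is kept: the interval midpoint for short and medium
#' term, 24 months for long term. Ties are broken toward the earlier time.
#'
#' @param observations observation data.frame (see [zb_data()]); must contain
#'   `followup_weeks` and `followup_category`.
#' @return The reduced data.frame, with attribute `"kept_rows"` giving the row
#'   indices retained from the input.
#' @export
select_timepoints <- function(observations) {
  tg <- zb_followup_boundaries()$targets
  key <- paste(observations$trial_id, observations$arm_id,
               observations$reference_arm_id, observations$followup_category,
               sep = "\r")
  keep <- vapply(split(seq_len(nrow(observations)), key), function(idx) {
    t <- observations$followup_weeks[idx]
    target <- tg[[as.character(observations$followup_category[idx[1]])]]
    d <- abs(t - target)
    cand <- idx[d == min(d)]
    cand[which.min(observations$followup_weeks[cand])]
  }, integer(1))
  keep <- sort(unname(keep))
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept_rows") <- keep
  out
}

#' Dichotomise intervention duration at the median
#'
#' Codes duration as long (1) when it is at least the median duration across
#' interventions, short (0) otherwise. The boundary is inclusive: a duration
#' exactly equal to the median codes as long.
#'
#' @param duration_weeks numeric vector of intervention durations in weeks.
#' @param median_weeks the dividing median; computed from `duration_weeks`
#'   when omitted.
#' @return integer vector of 0/1 codes.
#' @examples
#' dichotomize_duration(c(52, 30.33, 12), median_weeks = 30.33)
#' @export
dichotomize_duration <- function(duration_weeks, median_weeks = NULL) {
  stopifnot(all(duration_weeks > 0))
  if (is.null(median_weeks)) median_weeks <- stats::median(duration_weeks)
  stopifnot(median_weeks > 0)
  as.integer(duration_weeks >= median_weeks)
}

# ---- CSV interchange ---------------------------------------------------------

#' Read an analysis dataset from its flat CSV interchange format
#'
#' The canonical interchange format is one row per observation. Columns:
#' `trial_id`, `arm_id`, `reference_arm_id`, `reference_is_control`,
#' `followup_weeks`, `rob_high`, `md`, `se`, `scale`, the trial-level
#' indicators, the intervention-level indicators of the intervention arm under
#' their framework names, and (for rows whose reference is itself an active
#' intervention) the same indicator names prefixed `ref_`.
#'
#' @param path CSV file path.
#' @param outcome_subset restrict to originally-reported outcome scales:
#'   `"all"`, `"zbmi_only"`, `"bmi_only"` or `"zbmi_and_percentile"`. Dropped
#'   rows are listed in the validation report attached to the result.
#' @return A validated [zb_data] object.
#' @export
read_zb_data <- function(path, outcome_subset = c("all", "zbmi_only",
                                                  "bmi_only",
                                                  "zbmi_and_percentile")) {
  outcome_subset <- match.arg(outcome_subset)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ind <- intersect(.zb_intervention, names(df))
  extra <- setdiff(names(df), c(
    "trial_id", "arm_id", "reference_arm_id", "reference_is_control",
    "followup_weeks", "followup_category", "rob_high", "md", "se", "scale",
    .zb_trial, .zb_intervention, paste0("ref_", .zb_intervention)))
  extra <- extra[!startsWith(extra, "ref_")]
  ind <- c(ind, extra)
  req <- c("trial_id", "arm_id", "reference_arm_id", "reference_is_control",
           "followup_weeks", "rob_high", "md", "se", "scale", .zb_trial)
  if (length(miss <- setdiff(req, names(df))))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  keep_scale <- switch(outcome_subset,
    all = rep(TRUE, nrow(df)),
    zbmi_only = df$scale == "zbmi",
    bmi_only = df$scale == "bmi",
    zbmi_and_percentile = df$scale %in% c("zbmi", "percentile"))
  dropped <- data.frame(row = which(!keep_scale),
                        reason = rep("outcome_subset filter", sum(!keep_scale)))
  df <- df[keep_scale, , drop = FALSE]
  if (nrow(df) == 0L) stop("no observations remain after outcome_subset filter")

  trials <- unique(df[c("trial_id", .zb_trial)])
  if (anyDuplicated(trials$trial_id))
    stop("trial-level indicators vary within trial(s): ", paste(
      unique(trials$trial_id[duplicated(trials$trial_id)]), collapse = ", "))
  rownames(trials) <- NULL

  # intervention arms carry plain indicator columns; active references the
  # ref_-prefixed copies; control references contribute indicator-free arms
  a1 <- df[c("trial_id", "arm_id", ind)]
  a1$is_control <- 0L
  a2 <- df[c("trial_id", "reference_arm_id")]
  names(a2)[2] <- "arm_id"
  a2$is_control <- as.integer(df$reference_is_control)
  for (cl in ind) {
    rc <- paste0("ref_", cl)
    a2[[cl]] <- if (rc %in% names(df)) df[[rc]] else NA_real_
    a2[[cl]][a2$is_control == 1L] <- NA_real_
  }
  arms <- rbind(a1[c("trial_id", "arm_id", "is_control", ind)],
                a2[c("trial_id", "arm_id", "is_control", ind)])
  key <- paste(arms$trial_id, arms$arm_id)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    chk <- arms[order(key), ]
    for (cl in c("is_control", ind)) {
      v <- tapply(chk[[cl]], paste(chk$trial_id, chk$arm_id), function(z)
        length(unique(z[!is.na(z)])))
      if (any(v > 1, na.rm = TRUE))
        stop("inconsistent coding of '", cl, "' across rows for arm(s) ",
             paste(names(v)[which(v > 1)], collapse = ", "))
    }
    arms <- arms[first, , drop = FALSE]
  }
  rownames(arms) <- NULL

  obs <- df[c("trial_id", "arm_id", "reference_arm_id", "followup_weeks",
              "rob_high", "md", "se", "scale")]
  out <- zb_data(trials, arms, obs)
  attr(out, "validation") <- rbind(dropped, attr(out, "validation"))
  out
}

#' Write an analysis dataset to the flat CSV interchange format
#'
#' Inverse of [read_zb_data()]: a valid dataset written and re-read is
#' reproduced exactly (up to column classes).
#'
#' @param x a `zb_data` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_zb_data <- function(x, path) {
  stopifnot(inherits(x, "zb_data"))
  ind <- attr(x, "indicators")
  ob <- x$observations
  ar <- x$arms
  tr <- x$trials
  akey <- paste(ar$trial_id, ar$arm_id)
  ia <- match(paste(ob$trial_id, ob$arm_id), akey)
  ir <- match(paste(ob$trial_id, ob$reference_arm_id), akey)
  it <- match(ob$trial_id, tr$trial_id)
  df <- data.frame(ob[c("trial_id", "arm_id", "reference_arm_id")],
                   reference_is_control = as.integer(ar$is_control[ir]),
                   ob[c("followup_weeks", "rob_high", "md", "se", "scale")],
                   tr[it, .zb_trial, drop = FALSE],
                   ar[ia, ind, drop = FALSE],
                   check.names = FALSE)
  refind <- ar[ir, ind, drop = FALSE]
  names(refind) <- paste0("ref_", ind)
  df <- cbind(df, refind)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Tabulate indicator frequencies in the style of a coding summary table
#'
#' Counts and percentages of each intervention-level indicator over active
#' arms, each trial-level indicator over trials, and each time-point-level
#' indicator over observations (follow-up category shown as the medium/long
#' dummies against a short-term reference).
#'
#' @param x a `zb_data` object.
#' @return data.frame with columns `indicator`, `level`, `n`, `total`, `pct`.
#' @export
describe_zb_data <- function(x) {
  stopifnot(inherits(x, "zb_data"))
  ind <- attr(x, "indicators")
  act <- x$arms[!as.logical(x$arms$is_control), , drop = FALSE]
  ob <- x$observations
  row1 <- function(name, level, v) data.frame(
    indicator = name, level = level, n = sum(v == 1),
    total = length(v), pct = 100 * mean(v == 1))
  out <- do.call(rbind, c(
    lapply(ind, function(cl) row1(cl, "intervention", act[[cl]])),
    lapply(.zb_trial, function(cl) row1(cl, "trial", x$trials[[cl]])),
    list(row1("medium", "time", as.integer(ob$followup_category == "medium")),
         row1("long", "time", as.integer(ob$followup_category == "long")),
         row1("rob_high", "time", ob$rob_high))))
  rownames(out) <- NULL
  out
}
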