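# Canonical indicator sets of the three-level coding framework.

.zb_intervention <- c(
  "school", "home", "community", "individual", "electronic",
  "diet_and_pa", "pa_only", "multi_strategy", "duration_long",
  "intensity_high", "integration", "flexibility_choice", "fun_factor",
  "resonance", "participation", "education", "social_env", "physical_env"
)
.zb_trial <- c("age_group", "high_income", "mixed_ses")
.zb_time  <- c("medium", "long", "rob_high")

# Declared convention: 1 month = 365.25/84 weeks (365.25 days/year, 12 months, 7-day weeks).
.zb_weeks_per_month <- 365.25 / 84

#' Indicator names used by the three-level coding framework
#'
#' The analysis codes each intervention arm with 18 binary intervention-level
#' indicators, each trial with 3 trial-level indicators (age group 12-18 vs
#' 5-11 years, high- vs non-high-income country, mixed vs low socio-economic
#' status) and each observation with 3 time-point-level indicators (medium- and
#' long-term follow-up relative to short-term, and high risk of bias).
#'
#' @return A named list with elements `intervention`, `trial` and `time`,
#'   character vectors of indicator (column) names.
#' @examples
#' zb_indicators()$trial
#' @export
zb_indicators <- function() {
  list(intervention = .zb_intervention, trial = .zb_trial, time = .zb_time)
}

#' Follow-up interval boundaries and time-point selection targets, in weeks
#'
#' Follow-up is categorised as short (12 weeks to <9 months), medium (9 to <15
#' months) or long term (15 months or more). Months are converted to weeks at
#' 365.25/84 weeks per month. Selection targets are the interval midpoints for
#' short and medium term and 24 months for long term.
#'
#' @return Named list: `short_min`, `medium_min`, `long_min` (category
#'   boundaries) and `targets` (named vector of selection targets), all in weeks.
#' @export
zb_followup_boundaries <- function() {
  m <- .zb_weeks_per_month
  list(
    short_min  = 12,
    medium_min = 9 * m,
    long_min   = 15 * m,
    targets = c(
      short  = (12 + 9 * m) / 2,
      medium = (9 * m + 15 * m) / 2,
      long   = 24 * m
    )
  )
}
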