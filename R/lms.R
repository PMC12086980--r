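# LMS growth references: a table of (sex, age) -> (L, M, S) defining the
# age- and sex-standardised BMI z-score z = ((BMI/M)^L - 1) / (L * S),
# with the log-form limit (ln(BMI/M)) / S as L -> 0.

#' Construct an LMS growth reference
#'
#' @param table data.frame with columns `sex` (0 = female, 1 = male),
#'   `age_years`, `L` (Box-Cox power), `M` (median BMI, kg/m^2), `S`
#'   (coefficient of variation). Ages must be strictly increasing within sex;
#'   parameters are linearly interpolated over age.
#' @return object of class `lms_ref`.
#' @seealso [read_lms()], [synthetic_lms()], [zbmi_score()]
#' @export
lms_reference <- function(table) {
  table <- as.data.frame(table)
  req <- c("sex", "age_years", "L", "M", "S")
  if (length(miss <- setdiff(req, names(table))))
    stop("missing LMS column(s): ", paste(miss, collapse = ", "))
  if (!all(table$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (!all(table$M > 0) || !all(table$S > 0)) stop("M and S must be positive")
  table <- table[order(table$sex, table$age_years), ]
  for (s in unique(table$sex)) {
    a <- table$age_years[table$sex == s]
    if (any(diff(a) <= 0)) stop("ages must be strictly increasing within sex")
    if (length(a) < 2) stop("need at least two ages per sex to interpolate")
  }
  rownames(table) <- NULL
  structure(list(table = table,
                 age_range = range(table$age_years)),
            class = "lms_ref")
}

#' @export
print.lms_ref <- function(x, ...) {
  cat("<lms_ref> ", nrow(x$table), " rows, ages ",
      x$age_range[1], "-", x$age_range[2], " years\n", sep = "")
  invisible(x)
}

#' Read an LMS growth reference from CSV
#'
#' Expects the documented layout `sex, age_years, L, M, S` (see
#' [lms_reference()]); CDC/WHO tables can be reshaped to this layout.
#'
#' @param path CSV file path.
#' @return `lms_ref` object.
#' @export
read_lms <- function(path) lms_reference(utils::read.csv(path))

#' Bundled synthetic LMS reference for examples and tests
#'
#' A smooth synthetic reference (not a national growth chart): median BMI
#' rising linearly with age, constant coefficient of variation, Box-Cox power
#' near but not equal to 0 or 1, and a small sex offset in the median. It has
#' the qualitative shape of paediatric BMI references and exercises every code
#' path of the transform without requiring an external download.
#'
#' @param age_min,age_max age range covered, years.
#' @return `lms_ref` object.
#' @export
synthetic_lms <- function(age_min = 2, age_max = 20) {
  age <- seq(age_min, age_max, by = 0.5)
  tab <- do.call(rbind, lapply(c(0, 1), function(s) data.frame(
    sex = s, age_years = age,
    L = -0.8 + 0.01 * (age - 10),
    M = 15.5 + 0.45 * age + 0.3 * s,
    S = 0.12)))
  lms_reference(tab)
}

#' Constant LMS reference (single L, M, S at all ages)
#'
#' Convenience constructor for the degenerate reference in which the transform
#' is the same at every age and sex; with `L = 1` the z-score is exactly
#' `((bmi/M) - 1)/S`, giving closed forms against which the sampling mapper
#' can be checked.
#'
#' @param L,M,S the constant parameters.
#' @param age_min,age_max covered age range, years.
#' @return `lms_ref` object.
#' @export
constant_lms <- function(L = 1, M = 20, S = 0.1, age_min = 0, age_max = 100) {
  lms_reference(do.call(rbind, lapply(c(0, 1), function(s) data.frame(
    sex = s, age_years = c(age_min, age_max), L = L, M = M, S = S))))
}

.lms_at <- function(ref, age, sex) {
  out <- matrix(NA_real_, length(age), 3, dimnames = list(NULL, c("L", "M", "S")))
  for (s in c(0, 1)) {
    i <- which(sex == s)
    if (!length(i)) next
    tab <- ref$table[ref$table$sex == s, ]
    if (!nrow(tab)) stop("reference has no rows for sex ", s)
    for (p in c("L", "M", "S"))
      out[i, p] <- stats::approx(tab$age_years, tab[[p]], xout = age[i],
                                 rule = 1)$y
  }
  out
}

#' BMI z-score of an individual under an LMS reference
#'
#' Computes `z = ((bmi/M)^L - 1) / (L * S)` at the individual's age and sex,
#' using the log-form limit `ln(bmi/M) / S` where `|L|` is vanishingly small.
#' Strictly increasing in `bmi` at fixed age and sex.
#'
#' @param bmi BMI, kg/m^2 (> 0). Vectorised.
#' @param age age in years; must lie inside the reference's age range.
#' @param sex 0 = female, 1 = male.
#' @param ref an `lms_ref` object.
#' @return numeric vector of z-scores.
#' @examples
#' zbmi_score(22, age = 10, sex = 1, ref = constant_lms(L = 1, M = 20, S = 0.1))
#' @export
zbmi_score <- function(bmi, age, sex, ref) {
  stopifnot(inherits(ref, "lms_ref"), all(bmi > 0), all(sex %in% c(0, 1)))
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(age < ref$age_range[1] | age > ref$age_range[2]))
    stop("age(s) outside the reference range [", ref$age_range[1], ", ",
         ref$age_range[2], "]")
  p <- .lms_at(ref, age, sex)
  r <- bmi / p[, "M"]
  z <- ifelse(abs(p[, "L"]) < 1e-7,
              log(r) / p[, "S"],
              (r ^ p[, "L"] - 1) / (p[, "L"] * p[, "S"]))
  unname(z)
}

#' Inverse transform: BMI corresponding to a z-score
#'
#' @inheritParams zbmi_score
#' @param z z-score(s).
#' @return BMI values, kg/m^2.
#' @export
bmi_from_z <- function(z, age, sex, ref) {
  stopifnot(inherits(ref, "lms_ref"))
  n <- max(length(z), length(age), length(sex))
  z <- rep_len(z, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  p <- .lms_at(ref, age, sex)
  unname(ifelse(abs(p[, "L"]) < 1e-7,
                p[, "M"] * exp(z * p[, "S"]),
                p[, "M"] * (1 + p[, "L"] * p[, "S"] * z) ^ (1 / p[, "L"])))
}
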