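# Design construction for the three-level meta-regression.
#
# Each observation is a mean difference between an intervention arm and a
# reference arm. Rows referenced against a control arm carry an intercept and
# the (centred) intervention-, trial- and time-level covariates of the
# intervention arm. Rows referenced against another active intervention carry
# the difference of the two arms' covariate vectors: the intercept and all
# trial- and time-level entries cancel, so such rows do not inform the
# intercept, trial-level or time-point-level coefficients. Centring is applied
# to the raw per-arm covariates (including raw interaction products) before
# differencing, so it cancels identically on active-referenced rows.

.parse_interactions <- function(interactions, covnames) {
  if (is.null(interactions) || length(interactions) == 0L)
    return(matrix(character(), 0, 2))
  if (is.list(interactions))
    interactions <- vapply(interactions, paste, "", collapse = ":")
  pr <- do.call(rbind, strsplit(interactions, ":", fixed = TRUE))
  if (ncol(pr) != 2) stop("interactions must be pairs 'a:b'")
  bad <- setdiff(c(pr), covnames)
  if (length(bad))
    stop("interaction references unknown or dropped indicator(s): ",
         paste(unique(bad), collapse = ", "))
  # canonical order: alphabetical within pair, no self-pairs, no duplicates
  pr <- t(apply(pr, 1, sort))
  if (any(pr[, 1] == pr[, 2])) stop("self-interactions are not allowed")
  pr[!duplicated(paste(pr[, 1], pr[, 2])), , drop = FALSE]
}

#' Build the centred design matrix for a dataset
#'
#' @param dataset a `zb_data` object.
#' @param interactions character vector of interaction terms `"a:b"` (or list
#'   of pairs), where `a`, `b` are covariate names at any of the three levels.
#' @param center centre all covariates (including interaction products) about
#'   their dataset mean. The mean is taken over the control-referenced
#'   observations, using each observation's intervention-arm covariates.
#' @return object of class `zb_design`: list with `X` (n x p matrix, first
#'   column `intercept`), `means` (named centring record, 0 for the
#'   intercept), `control_ref` (logical per row), `pairs` (interaction name
#'   matrix) and `covnames`.
#' @export
build_design <- function(dataset, interactions = NULL, center = TRUE) {
  stopifnot(inherits(dataset, "zb_data"))
  ind <- attr(dataset, "indicators")
  covnames <- c(ind, .zb_trial, .zb_time)
  ob <- dataset$observations; ar <- dataset$arms; tr <- dataset$trials
  akey <- paste(ar$trial_id, ar$arm_id)
  ia <- match(paste(ob$trial_id, ob$arm_id), akey)
  ir <- match(paste(ob$trial_id, ob$reference_arm_id), akey)
  it <- match(ob$trial_id, tr$trial_id)
  ctrl_ref <- as.logical(ar$is_control[ir])
  n <- nrow(ob)

  armcov <- function(idx) {
    U <- matrix(0, n, length(covnames), dimnames = list(NULL, covnames))
    U[, ind] <- as.matrix(ar[idx, ind, drop = FALSE])
    U[, .zb_trial] <- as.matrix(tr[it, .zb_trial, drop = FALSE])
    U[, "medium"] <- as.integer(ob$followup_category == "medium")
    U[, "long"] <- as.integer(ob$followup_category == "long")
    U[, "rob_high"] <- ob$rob_high
    U
  }
  Ua <- armcov(ia)
  Ur <- armcov(ir)
  Ur[ctrl_ref, ] <- 0  # unused; avoids NA from uncoded control arms

  pairs <- .parse_interactions(interactions, covnames)
  iname <- if (nrow(pairs)) paste(pairs[, 1], pairs[, 2], sep = ":") else
    character()
  Pa <- matrix(0, n, nrow(pairs), dimnames = list(NULL, iname))
  Pr <- Pa
  for (k in seq_len(nrow(pairs))) {
    Pa[, k] <- Ua[, pairs[k, 1]] * Ua[, pairs[k, 2]]
    Pr[, k] <- Ur[, pairs[k, 1]] * Ur[, pairs[k, 2]]
  }

  # centring means are taken over the control-referenced observations (the
  # rows on which intercept-bearing covariates actually appear); active-vs-
  # active rows are differences and cancel any centring, so this keeps the
  # whole design invariant to covariates of trials without a control arm
  mrows <- if (any(ctrl_ref)) ctrl_ref else rep(TRUE, n)
  means <- c(intercept = 0,
             if (center) c(colMeans(Ua[mrows, , drop = FALSE]),
                           colMeans(Pa[mrows, , drop = FALSE])) else
               stats::setNames(numeric(length(covnames) + nrow(pairs)),
                               c(covnames, iname)))
  Xa <- cbind(Ua, Pa); Xr <- cbind(Ur, Pr)
  X <- matrix(0, n, 1 + ncol(Xa),
              dimnames = list(NULL, c("intercept", colnames(Xa))))
  X[ctrl_ref, 1] <- 1
  X[ctrl_ref, -1] <- sweep(Xa[ctrl_ref, , drop = FALSE], 2, means[-1])
  X[!ctrl_ref, -1] <- Xa[!ctrl_ref, , drop = FALSE] -
    Xr[!ctrl_ref, , drop = FALSE]

  structure(list(X = X, means = means, control_ref = ctrl_ref, pairs = pairs,
                 covnames = covnames, centered = center),
            class = "zb_design")
}
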