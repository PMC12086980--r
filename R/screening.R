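# Pre-model reduction of the indicator set: pairwise collinearity (phi
# correlation >= 0.5, inclusive) and near-constant agreement (> 80%, strict).

#' Phi (Pearson) correlation matrix over binary indicator columns
#'
#' For 0/1 columns the Pearson correlation equals the phi coefficient
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` of the 2x2 table. Constant columns
#' cannot be correlated; their entries are `NA` and they are listed in the
#' `"constant"` attribute.
#'
#' @param indicators matrix or data.frame of binary columns (rows = arms).
#' @return symmetric correlation matrix with unit diagonal, attribute
#'   `"constant"` naming any constant columns.
#' @export
indicator_correlations <- function(indicators) {
  m <- as.matrix(indicators)
  if (nrow(m) < 2) stop("need at least two arms")
  if (!all(m %in% c(0, 1))) stop("indicator matrix must be binary")
  const <- colnames(m)[apply(m, 2, function(v) length(unique(v)) == 1)]
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  attr(r, "constant") <- const
  r
}

#' Screen indicator pairs for collinearity and concordance
#'
#' Flags every pair of intervention-level indicators with absolute phi
#' correlation of at least `r_threshold` (inclusive) or identical responses in
#' strictly more than `agreement_threshold` of arms. Flagged pairs receive an
#' action: by default `"report"` (leave the decision to the analyst); actions
#' `"merge"` (replace the pair by its logical OR under a combined label),
#' `"drop_first"`/`"drop_second"` may be supplied per pair. Protected
#' indicators are never dropped.
#'
#' @param x a `zb_data` object, or a binary indicator matrix over arms.
#' @param r_threshold collinearity threshold on `|phi|` (default 0.5, boundary
#'   inclusive).
#' @param agreement_threshold concordance threshold on the fraction of
#'   identical responses (default 0.8, boundary strict).
#' @param protected indicator names that must never be dropped.
#' @param actions named character vector: names like `"a:b"` (alphabetical
#'   order), values in `c("keep", "merge", "drop_first", "drop_second")`.
#' @return object of class `zb_screening`: list with `correlations`, `pairs`
#'   (data.frame: a, b, phi, agreement, flagged_r, flagged_agreement, action),
#'   `constant` and `protected`.
#' @export
screen_indicators <- function(x, r_threshold = 0.5, agreement_threshold = 0.8,
                              protected = character(), actions = NULL) {
  m <- if (inherits(x, "zb_data")) {
    act <- !as.logical(x$arms$is_control)
    as.matrix(x$arms[act, attr(x, "indicators"), drop = FALSE])
  } else as.matrix(x)
  r <- indicator_correlations(m)
  nm <- colnames(m)
  pairs <- do.call(rbind, lapply(seq_len(ncol(m) - 1), function(i)
    do.call(rbind, lapply((i + 1):ncol(m), function(j) data.frame(
      a = nm[i], b = nm[j], phi = r[i, j],
      agreement = mean(m[, i] == m[, j]))))))
  pairs$flagged_r <- !is.na(pairs$phi) & abs(pairs$phi) >= r_threshold
  pairs$flagged_agreement <- pairs$agreement > agreement_threshold
  flagged <- pairs$flagged_r | pairs$flagged_agreement
  pairs$action <- ifelse(flagged, "report", "keep")
  if (!is.null(actions)) {
    key <- paste(pairs$a, pairs$b, sep = ":")
    for (k in names(actions)) {
      i <- match(k, key)
      if (is.na(i)) stop("action refers to unknown pair: ", k)
      a <- match.arg(actions[[k]],
                     c("keep", "merge", "drop_first", "drop_second"))
      if (a == "drop_first" && pairs$a[i] %in% protected)
        stop("cannot drop protected indicator: ", pairs$a[i])
      if (a == "drop_second" && pairs$b[i] %in% protected)
        stop("cannot drop protected indicator: ", pairs$b[i])
      pairs$action[i] <- a
    }
  }
  structure(list(correlations = r, pairs = pairs,
                 constant = attr(r, "constant"), protected = protected,
                 r_threshold = r_threshold,
                 agreement_threshold = agreement_threshold),
            class = "zb_screening")
}

#' @export
print.zb_screening <- function(x, ...) {
  fl <- x$pairs[x$pairs$flagged_r | x$pairs$flagged_agreement, ]
  cat("<zb_screening> ", nrow(x$pairs), " pairs assessed; ", nrow(fl),
      " flagged (|phi| >= ", x$r_threshold, " or agreement > ",
      100 * x$agreement_threshold, "%)\n", sep = "")
  if (nrow(fl)) print(fl, row.names = FALSE, digits = 3)
  if (length(x$constant))
    cat("constant column(s): ", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Apply screening actions to a dataset
#'
#' Executes the per-pair actions recorded in a [screen_indicators()] report on
#' the arm table of a dataset: merges replace both columns by their logical OR
#' under the label `"<a>_or_<b>"`; drops remove a column. `"report"` and
#' `"keep"` leave the data unchanged.
#'
#' @param dataset a `zb_data` object.
#' @param screening a `zb_screening` report whose actions to apply.
#' @return a new `zb_data` object with the reduced indicator set.
#' @export
apply_screening <- function(dataset, screening) {
  stopifnot(inherits(dataset, "zb_data"), inherits(screening, "zb_screening"))
  arms <- dataset$arms
  drop <- character()
  for (i in seq_len(nrow(screening$pairs))) {
    p <- screening$pairs[i, ]
    if (p$action == "merge") {
      new <- paste0(p$a, "_or_", p$b)
      arms[[new]] <- pmax(arms[[p$a]], arms[[p$b]])
      drop <- c(drop, p$a, p$b)
    } else if (p$action == "drop_first") drop <- c(drop, p$a)
    else if (p$action == "drop_second") drop <- c(drop, p$b)
  }
  arms <- arms[setdiff(names(arms), drop)]
  zb_data(dataset$trials, arms, dataset$observations, select_times = FALSE)
}
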