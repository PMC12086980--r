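# Exhaustive evaluation of the model over every plausible combination of
# indicator values: enumeration under mutual-exclusivity and
# at-least-one-mechanism rules, posterior-mean predictions, location of the
# best/worst combinations, and profiling of the extreme 1%.

#' Default plausibility rules for indicator combinations
#'
#' A follow-up time cannot be both medium- and long-term; an intervention
#' cannot target both "physical activity alone" and "both diet and physical
#' activity"; and at least one mechanism-of-action indicator (participation,
#' education, social environment, physical environment) must be non-zero.
#'
#' @return list with elements `exclusive` (list of indicator groups of which
#'   at most one may be 1) and `at_least_one` (list of groups of which at
#'   least one must be 1).
#' @export
plausible_rules <- function() list(
  exclusive = list(c("medium", "long"), c("diet_and_pa", "pa_only")),
  at_least_one = list(c("participation", "education", "social_env",
                        "physical_env")))

# All 0/1 rows over `nm` (small), as a matrix with named columns.
.binary_states <- function(nm) {
  m <- length(nm)
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  colnames(g) <- nm
  g
}

# Partition indicators into rule groups (with admissible state tables,
# honouring fixed values) and free indicators.
.grid_groups <- function(indicators, rules, fix = NULL) {
  fix <- unlist(fix)
  if (length(fix)) {
    if (is.null(names(fix)) || !all(names(fix) %in% indicators))
      stop("fix must be a named 0/1 assignment over the grid indicators")
    if (!all(fix %in% c(0, 1))) stop("fixed values must be 0 or 1")
  }
  grouped <- character()
  groups <- list()
  add_group <- function(members, states) {
    if (length(fx <- intersect(members, names(fix)))) {
      keep <- rep(TRUE, nrow(states))
      for (f in fx) keep <- keep & states[, f] == fix[[f]]
      states <- states[keep, , drop = FALSE]
      if (nrow(states) == 0)
        stop("contradictory fixed assignment for group {",
             paste(members, collapse = ", "), "}")
    }
    groups[[length(groups) + 1]] <<- list(members = members, states = states)
    grouped <<- c(grouped, members)
  }
  for (g in rules$exclusive) {
    g <- intersect(g, indicators)
    if (length(g) < 2) next
    if (length(intersect(g, grouped)))
      stop("indicator appears in more than one rule group")
    st <- rbind(0, diag(length(g)))
    colnames(st) <- g
    add_group(g, st)
  }
  for (g in rules$at_least_one) {
    g <- intersect(g, indicators)
    if (length(g) < 1) next
    if (length(intersect(g, grouped)))
      stop("indicator appears in more than one rule group")
    st <- .binary_states(g)
    add_group(g, st[rowSums(st) >= 1, , drop = FALSE])
  }
  free <- setdiff(indicators, grouped)
  free_fixed <- intersect(free, names(fix))
  list(groups = groups,
       free = setdiff(free, free_fixed),
       fixed = if (length(free_fixed))
         stats::setNames(as.numeric(fix[free_fixed]), free_fixed) else
           stats::setNames(numeric(0), character(0)))
}

#' Count plausible indicator combinations in closed form
#'
#' The plausibility rules partition the indicators into independent blocks,
#' so the count is a product: `2^f` for the `f` unconstrained free
#' indicators, `m + 1` per exclusive group of size `m`, and `2^m - 1` per
#' at-least-one group, reduced accordingly by any fixed assignment. With the
#' 24 default indicators this gives 2^16 * 3 * 3 * 15 = 8,847,360.
#'
#' @param indicators character vector of indicator names in the grid.
#' @param rules plausibility rules (see [plausible_rules()]).
#' @param fix optional named 0/1 assignment fixing some indicators.
#' @return the number of plausible combinations (double).
#' @export
count_plausible <- function(indicators, rules = plausible_rules(),
                            fix = NULL) {
  gg <- .grid_groups(indicators, rules, fix)
  2^length(gg$free) * prod(vapply(gg$groups,
                                  function(g) nrow(g$states), 0))
}

#' Enumerate plausible indicator combinations
#'
#' Materialises the full grid of plausible combinations as a 0/1 matrix.
#' Intended for small systems (toy models, subgroup checks, brute-force
#' oracles); the full 24-indicator grid (8,847,360 rows) is profiled without
#' materialisation by [find_extremes()].
#'
#' @inheritParams count_plausible
#' @param limit refuse to materialise more than this many rows.
#' @return matrix with one column per indicator (in the given order).
#' @export
enumerate_plausible <- function(indicators, rules = plausible_rules(),
                                fix = NULL, limit = 2^20) {
  n <- count_plausible(indicators, rules, fix)
  if (n > limit)
    stop("grid has ", format(n, big.mark = ","), " rows; raise `limit` or ",
         "use find_extremes() which profiles the grid without materialising it")
  gg <- .grid_groups(indicators, rules, fix)
  blocks <- c(lapply(gg$free, function(nm) {
    m <- matrix(c(0, 1), 2, 1); colnames(m) <- nm; m
  }),
  lapply(names(gg$fixed), function(nm) {
    m <- matrix(gg$fixed[[nm]], 1, 1); colnames(m) <- nm; m
  }),
  lapply(gg$groups, `[[`, "states"))
  sizes <- vapply(blocks, nrow, 0L)
  N <- prod(sizes)
  out <- matrix(0, N, length(indicators),
                dimnames = list(NULL, indicators))
  after <- rev(cumprod(rev(c(sizes[-1], 1))))
  before <- N / (sizes * after)
  for (b in seq_along(blocks)) {
    idx <- rep(rep(seq_len(sizes[b]), each = after[b]), times = before[b])
    out[, colnames(blocks[[b]])] <- blocks[[b]][idx, , drop = FALSE]
  }
  out[, indicators, drop = FALSE]
}

# Extract (intercept_uncentred, main coefficients, interaction pairs/coefs)
# from a zbmeta fit or a plain list(intercept=, coefficients=, interactions=).
.profile_coefs <- function(object) {
  if (inherits(object, "zbmeta")) {
    cf <- coef(object)
    means <- object$design$means
    theta <- cf[names(means)]
    list(intercept = cf[["intercept"]] - sum(theta[-1] * means[-1]),
         beta = theta[setdiff(names(means)[-1],
                              grep(":", names(means), value = TRUE))],
         pairs = object$design$pairs,
         eta = if (nrow(object$design$pairs))
           cf[paste(object$design$pairs[, 1], object$design$pairs[, 2],
                    sep = ":")] else numeric(0),
         indicators = object$design$covnames)
  } else {
    stopifnot(is.list(object), !is.null(object$coefficients))
    ints <- object$interactions
    pairs <- if (length(ints))
      do.call(rbind, strsplit(names(ints), ":", fixed = TRUE)) else
        matrix(character(), 0, 2)
    list(intercept = if (is.null(object$intercept)) 0 else object$intercept,
         beta = object$coefficients, pairs = pairs,
         eta = if (length(ints)) unname(unlist(ints)) else numeric(0),
         indicators = names(object$coefficients))
  }
}

#' Profile the best and worst plausible indicator combinations
#'
#' Evaluates the de-centred posterior-mean linear predictor over every
#' plausible indicator combination (optionally under a fixed subgroup
#' assignment), locates the minimum ("best": most beneficial, since the
#' outcome is a mean difference in zBMI) and the maximum ("worst"), profiles
#' the typical indicator values in the extreme `tail` fraction of
#' combinations, and reports the fraction of combinations predicting a
#' beneficial effect (negative mean difference). The grid is evaluated in
#' blocks and never materialised in full.
#'
#' @param object a fitted `zbmeta` model, or a list with elements `intercept`
#'   (uncentred), `coefficients` (named vector of main-effect coefficients)
#'   and optionally `interactions` (named vector, names `"a:b"`).
#' @param fix named 0/1 assignment fixing some indicators (e.g.
#'   `c(age_group = 1, high_income = 0)` for a subgroup search, or
#'   `c(rob_high = 0)` to condition on low risk of bias).
#' @param tail the extreme fraction to profile (default 0.01). The tail holds
#'   `ceiling(tail * N)` rows; ties at the boundary value are all included.
#' @param rules plausibility rules (see [plausible_rules()]).
#' @param indicators grid columns; defaults to the model's covariates.
#' @return object of class `zb_profile`: list with `n` (grid size), `best`
#'   and `worst` (each: `md` and a matrix of the tied extreme rows),
#'   `profile` (data.frame: indicator, prevalence in best and worst tails),
#'   `fraction_beneficial`, `tail`, `fix`.
#' @export
find_extremes <- function(object, fix = NULL, tail = 0.01,
                          rules = plausible_rules(), indicators = NULL) {
  pc <- .profile_coefs(object)
  if (is.null(indicators)) indicators <- pc$indicators
  stopifnot(tail > 0, tail < 1)
  gg <- .grid_groups(indicators, rules, fix)
  f <- length(gg$free)
  if (f > 24) stop("free block too large to enumerate")
  Fm <- .binary_states(gg$free)          # 2^f x f
  Cs <- if (length(gg$groups)) {
    tabs <- lapply(gg$groups, `[[`, "states")
    sizes <- vapply(tabs, nrow, 0L)
    S <- prod(sizes)
    after <- rev(cumprod(rev(c(sizes[-1], 1))))
    before <- S / (sizes * after)
    m <- matrix(0, S, sum(vapply(tabs, ncol, 0L)))
    colnames(m) <- unlist(lapply(tabs, colnames))
    for (b in seq_along(tabs)) {
      idx <- rep(rep(seq_len(sizes[b]), each = after[b]), times = before[b])
      m[, colnames(tabs[[b]])] <- tabs[[b]][idx, , drop = FALSE]
    }
    m
  } else matrix(numeric(0), 1, 0)
  nf <- nrow(Fm); S <- nrow(Cs)
  N <- nf * S

  beta <- pc$beta
  bval <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  const <- pc$intercept +
    sum(vapply(names(gg$fixed), function(nm) bval(nm) * gg$fixed[[nm]], 0))
  pred_free <- if (f) drop(Fm %*% vapply(gg$free, bval, 0)) else
    numeric(nf)
  pred_con <- if (ncol(Cs)) drop(Cs %*% vapply(colnames(Cs), bval, 0)) else
    numeric(S)

  cross <- list()   # interactions spanning the free and constrained blocks
  for (k in seq_len(nrow(pc$pairs))) {
    a <- pc$pairs[k, 1]; b <- pc$pairs[k, 2]; e <- pc$eta[[k]]
    loc <- function(nm) if (nm %in% gg$free) "free" else
      if (nm %in% colnames(Cs)) "con" else
        if (nm %in% names(gg$fixed)) "fixed" else
          stop("interaction references indicator outside the grid: ", nm)
    la <- loc(a); lb <- loc(b)
    val <- function(nm, where) switch(where, free = Fm[, nm],
                                      con = Cs[, nm], fixed = gg$fixed[[nm]])
    if (la == "free" && lb == "free")
      pred_free <- pred_free + e * Fm[, a] * Fm[, b]
    else if (la == "con" && lb == "con")
      pred_con <- pred_con + e * Cs[, a] * Cs[, b]
    else if (la == "fixed" && lb == "fixed")
      const <- const + e * gg$fixed[[a]] * gg$fixed[[b]]
    else if (la == "free")
      if (lb == "fixed") pred_free <- pred_free + e * gg$fixed[[b]] * Fm[, a]
      else cross[[length(cross) + 1]] <- list(fr = a, cn = b, eta = e)
    else if (lb == "free")
      if (la == "fixed") pred_free <- pred_free + e * gg$fixed[[a]] * Fm[, b]
      else cross[[length(cross) + 1]] <- list(fr = b, cn = a, eta = e)
    else if (la == "con")  # con x fixed
      pred_con <- pred_con + e * gg$fixed[[b]] * Cs[, a]
    else
      pred_con <- pred_con + e * gg$fixed[[a]] * Cs[, b]
  }

  P <- matrix(0, nf, S)
  for (s in seq_len(S)) {
    v <- pred_free + pred_con[s] + const
    for (cr in cross) v <- v + (cr$eta * Cs[s, cr$cn]) * Fm[, cr$fr]
    P[, s] <- v
  }

  k <- ceiling(tail * N)
  ps <- sort(as.vector(P), partial = c(k, N - k + 1))
  thr_best <- ps[k]; thr_worst <- ps[N - k + 1]
  decode <- function(idx) {
    i <- (idx - 1) %% nf + 1
    s <- (idx - 1) %/% nf + 1
    out <- matrix(0, length(idx), length(indicators),
                  dimnames = list(NULL, indicators))
    if (f) out[, gg$free] <- Fm[i, , drop = FALSE]
    if (ncol(Cs)) out[, colnames(Cs)] <- Cs[s, , drop = FALSE]
    for (nm in names(gg$fixed)) out[, nm] <- gg$fixed[[nm]]
    out
  }
  best_idx <- which(P == min(P)); worst_idx <- which(P == max(P))
  tb <- decode(which(P <= thr_best))
  tw <- decode(which(P >= thr_worst))
  profile <- data.frame(indicator = indicators,
                        best_tail = colMeans(tb)[indicators],
                        worst_tail = colMeans(tw)[indicators])
  rownames(profile) <- NULL
  structure(list(n = N, tail = tail, k_tail = k, fix = fix,
                 best = list(md = min(P), rows = decode(best_idx)),
                 worst = list(md = max(P), rows = decode(worst_idx)),
                 profile = profile,
                 fraction_beneficial = mean(P < 0)),
            class = "zb_profile")
}

#' @export
print.zb_profile <- function(x, ...) {
  cat("<zb_profile> ", format(x$n, big.mark = ","), " plausible combinations",
      if (length(x$fix)) paste0(" (fixed: ",
        paste(names(x$fix), unlist(x$fix), sep = "=", collapse = ", "), ")"),
      "\n", sep = "")
  cat("best MD  = ", format(x$best$md, digits = 4), " (",
      nrow(x$best$rows), " row(s))\n", sep = "")
  cat("worst MD = ", format(x$worst$md, digits = 4), " (",
      nrow(x$worst$rows), " row(s))\n", sep = "")
  cat("fraction predicting benefit (MD < 0): ",
      format(100 * x$fraction_beneficial, digits = 4), "%\n", sep = "")
  cat("prevalence of each indicator in the best/worst ",
      100 * x$tail, "%:\n", sep = "")
  print(x$profile, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Best/worst combinations within a subgroup
#'
#' Re-runs the combination profile with the subgroup's trial- and
#' time-point-level indicators fixed, e.g. each age group in high and
#' non-high-income countries.
#'
#' @inheritParams find_extremes
#' @param subgroup named 0/1 assignment (e.g.
#'   `c(age_group = 0, high_income = 1)`).
#' @return a `zb_profile` object.
#' @export
subgroup_search <- function(object, subgroup, tail = 0.01,
                            rules = plausible_rules(), indicators = NULL) {
  find_extremes(object, fix = subgroup, tail = tail, rules = rules,
                indicators = indicators)
}
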