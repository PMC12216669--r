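# Fuzzy-set Qualitative Comparative Analysis engine: quartile-anchored
# direct calibration, necessity analysis, truth-table construction,
# Quine-McCluskey minimization (complex / parsimonious / intermediate
# solutions with core/peripheral labelling), coverage bookkeeping and
# robustness scans.
#
# Implicants are integer vectors over the ordered condition set with
# values 1 (condition present), 0 (absent) and NA (don't care). Corners
# of the condition space are 0/1 vectors of the same length.

#' Quartile calibration anchors
#'
#' Returns the three direct-calibration anchors from the empirical
#' distribution of a variable: full membership at the 75th percentile,
#' crossover at the 50th, full non-membership at the 25th. Percentiles
#' use linear interpolation between order statistics (the p-th percentile
#' sits at rank `1 + (n-1)p/100`), so the anchors are equivariant under
#' increasing affine transforms.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @param name variable name used in error messages.
#' @return A list of class `calibration_anchors` with elements `full`,
#'   `crossover`, `non`.
#' @export
#' @examples
#' quartile_anchors(1:5)
quartile_anchors <- function(values, name = "variable") {
  if (length(unique(values)) < 4)
    stop_esh("calibration of '", name, "' needs at least 4 distinct values")
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75),
                       names = FALSE, type = 7)
  if (!(q[1] < q[2] && q[2] < q[3]))
    stop_esh("calibration anchors for '", name,
             "' are not strictly ordered (heavy ties): non=", q[1],
             ", crossover=", q[2], ", full=", q[3])
  structure(list(full = q[3], crossover = q[2], non = q[1]),
            class = "calibration_anchors")
}

#' Direct-method fuzzy calibration
#'
#' Maps raw values to set memberships through a piecewise-linear log-odds
#' transform anchored at the full/crossover/non anchors and squashed by
#' the logistic function: `L(x) = s*(x - crossover)/(full - crossover)`
#' above the crossover and `L(x) = s*(x - crossover)/(crossover - non)`
#' below it, membership `= 1/(1 + exp(-L))`. With the default scaling
#' `s = 3` the anchors map to memberships `plogis(3) = 0.9526` and
#' `plogis(-3) = 0.0474`; `scaling = "log19"` uses `s = log(19)` so the
#' anchors map to exactly 0.95/0.05.
#'
#' Values landing exactly on the crossover would have membership 0.5 and
#' belong to neither set; they are nudged to `0.5 + tie_adjust`
#' (reported via the `"tie_adjusted"` attribute).
#'
#' @param values numeric vector of raw values.
#' @param anchors a `calibration_anchors` object, or anything coercible
#'   via `list(full=, crossover=, non=)`.
#' @param scaling `"three"` (default) or `"log19"`.
#' @param tie_adjust nudge applied at the crossover (default `1e-3`).
#' @return Numeric memberships in `(0, 1)`; strictly increasing in the
#'   raw value except for the tie nudge.
#' @export
calibrate <- function(values, anchors, scaling = c("three", "log19"),
                      tie_adjust = 1e-3) {
  scaling <- match.arg(scaling)
  s <- if (scaling == "three") 3 else log(19)
  full <- anchors$full; cross <- anchors$crossover; non <- anchors$non
  if (!(non < cross && cross < full))
    stop_esh("calibration anchors must satisfy non < crossover < full")
  L <- ifelse(values >= cross,
              s * (values - cross) / (full - cross),
              s * (values - cross) / (cross - non))
  m <- stats::plogis(L)
  ties <- which(m == 0.5)
  m[ties] <- 0.5 + tie_adjust
  m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
  attr(m, "tie_adjusted") <- ties
  m
}

#' Fuzzy negation
#'
#' Elementwise complement `1 - m`. An involution: negating twice returns
#' the original memberships.
#'
#' @param m memberships in `[0, 1]`.
#' @return `1 - m` (attributes dropped).
#' @export
fuzzy_negate <- function(m) as.numeric(1 - m)

# nudge exact 0.5 memberships upward so every case falls on one side of
# every set boundary (applied at matrix construction and to negated
# outcomes before truth-table use)
apply_tie_rule <- function(m, tie_adjust = 1e-3) {
  m[m == 0.5] <- 0.5 + tie_adjust
  m
}

#' Assemble a fuzzy case matrix
#'
#' Bundles calibrated memberships of the causal conditions and the
#' outcome over the analysis cases. When `calibrated = FALSE` each
#' variable is calibrated with its own quartile anchors
#' ([quartile_anchors()] + [calibrate()]); per-variable anchors can be
#' overridden through `anchors`.
#'
#' @param data data frame with a `case` column, one column per condition
#'   and the outcome column.
#' @param conditions character vector of condition column names (default
#'   `Z1, Z5, Z6, Z7, Z8`, the subsystem condition values retained for
#'   the configurational analysis).
#' @param outcome outcome column name (default `"D"`).
#' @param calibrated set `TRUE` if the columns are already memberships.
#' @param anchors optional named list of `calibration_anchors` overriding
#'   the quartile defaults per variable.
#' @param scaling,tie_adjust passed to [calibrate()].
#' @return An object of class `fuzzy_case_matrix`: list with `cases`,
#'   `conditions`, `outcome` and the membership matrix `mb`
#'   (cases x variables).
#' @export
fuzzy_case_matrix <- function(data,
                              conditions = c("Z1", "Z5", "Z6", "Z7", "Z8"),
                              outcome = "D", calibrated = FALSE,
                              anchors = NULL,
                              scaling = c("three", "log19"),
                              tie_adjust = 1e-3) {
  scaling <- match.arg(scaling)
  vars <- c(conditions, outcome)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0)
    stop_esh("case data is missing columns: ", paste(missing, collapse = ", "))
  cases <- if ("case" %in% names(data)) as.character(data$case)
           else rownames(data) %||% as.character(seq_len(nrow(data)))
  mb <- matrix(NA_real_, nrow = nrow(data), ncol = length(vars),
               dimnames = list(cases, vars))
  for (v in vars) {
    x <- as.numeric(data[[v]])
    if (any(!is.finite(x))) stop_esh("non-finite values in '", v, "'")
    if (calibrated) {
      if (any(x < 0 | x > 1))
        stop_esh("'", v, "' declared calibrated but outside [0, 1]")
      mb[, v] <- apply_tie_rule(x, tie_adjust)
    } else {
      a <- anchors[[v]] %||% quartile_anchors(x, name = v)
      mb[, v] <- as.numeric(calibrate(x, a, scaling = scaling,
                                      tie_adjust = tie_adjust))
    }
  }
  structure(list(cases = cases, conditions = conditions,
                 outcome = outcome, mb = mb),
            class = "fuzzy_case_matrix")
}

#' @export
print.fuzzy_case_matrix <- function(x, ...) {
  cat("<fuzzy_case_matrix> ", length(x$cases), " cases, conditions: ",
      paste(x$conditions, collapse = ", "), ", outcome: ", x$outcome,
      "\n", sep = "")
  invisible(x)
}

# sufficiency-oriented inclusion and coverage of set x in outcome y
suff_incl_cov <- function(x, y) {
  s <- sum(pmin(x, y))
  list(consistency = if (sum(x) > 0) s / sum(x) else NA_real_,
       coverage = if (sum(y) > 0) s / sum(y) else NA_real_)
}

#' Necessity decision rule
#'
#' A condition is flagged necessary for an outcome when its necessity
#' consistency is at least `cons_threshold` (default 0.9) and its
#' necessity coverage at least `cov_threshold` (default 0.5).
#'
#' @param consistency,coverage necessity statistics.
#' @param cons_threshold,cov_threshold decision thresholds.
#' @return Logical vector (`NA` where a statistic is undefined).
#' @export
necessity_flag <- function(consistency, coverage,
                           cons_threshold = 0.9, cov_threshold = 0.5) {
  consistency >= cons_threshold & coverage >= cov_threshold
}

#' Necessity analysis of conditions and their negations
#'
#' For each condition X (and its negation) versus outcome Y computes the
#' standard fuzzy necessity statistics
#' `consistency = sum(min(x, y)) / sum(y)` and
#' `coverage = sum(min(x, y)) / sum(x)`, and applies the decision rule of
#' [necessity_flag()]. Necessity and sufficiency metrics are duals: the
#' necessity consistency of X for Y equals the sufficiency consistency of
#' Y for X.
#'
#' @param fcm a `fuzzy_case_matrix`.
#' @param negate_outcome analyze the absence of the outcome instead.
#' @inheritParams necessity_flag
#' @return A tibble `condition, consistency, coverage, necessary`, with
#'   negated conditions written `~X`.
#' @export
necessity_analysis <- function(fcm, negate_outcome = FALSE,
                               cons_threshold = 0.9, cov_threshold = 0.5) {
  stopifnot(inherits(fcm, "fuzzy_case_matrix"))
  y <- fcm$mb[, fcm$outcome]
  if (negate_outcome) y <- fuzzy_negate(y)
  if (sum(y) == 0) stop_esh("outcome has zero total membership")
  rows <- lapply(fcm$conditions, function(cn) {
    res <- lapply(list(fcm$mb[, cn], fuzzy_negate(fcm$mb[, cn])), function(x) {
      s <- sum(pmin(x, y))
      tibble::tibble(
        consistency = if (sum(y) > 0) s / sum(y) else NA_real_,
        coverage = if (sum(x) > 0) s / sum(x) else NA_real_
      )
    })
    dplyr::bind_rows(res) |>
      dplyr::mutate(condition = c(cn, paste0("~", cn)), .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$necessary <- necessity_flag(out$consistency, out$coverage,
                                  cons_threshold, cov_threshold)
  out
}

# all 2^k corners as a matrix (row i = bits of i-1, first condition most
# significant); fixed order keeps outputs deterministic
corner_matrix <- function(conditions) {
  k <- length(conditions)
  idx <- 0:(2^k - 1)
  m <- sapply(rev(seq_len(k)) - 1, function(b) bitwAnd(idx %/% 2^b, 1L))
  m <- matrix(as.integer(m), ncol = k,
              dimnames = list(NULL, conditions))
  m
}

# membership of every case in the corner's conjunction: min over literals
corner_membership <- function(mb_cond, corner) {
  lit <- mb_cond
  for (j in seq_along(corner))
    if (corner[j] == 0) lit[, j] <- 1 - lit[, j]
  apply(lit, 1, min)
}

#' Natural-break PRI cutoff
#'
#' Operationalizes the "natural break" choice of a PRI threshold as the
#' midpoint of the largest gap between consecutive sorted observed PRI
#' values whose midpoint lies in `[window_low, cons_threshold]`; when no
#' such gap exists (e.g. all PRI values equal) a documented fallback of
#' 0.70 is used.
#'
#' @param pri numeric vector of observed-row PRI values.
#' @param cons_threshold upper end of the admissible window.
#' @param window_low lower end of the admissible window (default 0.5).
#' @param fallback cutoff used when no admissible gap exists.
#' @return A single PRI cutoff.
#' @export
natural_break_pri <- function(pri, cons_threshold = 0.80,
                              window_low = 0.5, fallback = 0.70) {
  pri <- pri[is.finite(pri)]
  if (length(pri) == 0) stop_esh("no observed truth-table rows")
  v <- sort(pri)
  if (length(v) >= 2) {
    gaps <- diff(v)
    mids <- (v[-length(v)] + v[-1]) / 2
    ok <- gaps > 0 & mids >= window_low & mids <= cons_threshold
    if (any(ok)) {
      best <- which(ok)[which.max(gaps[ok])]
      return(mids[best])
    }
  }
  fallback
}

#' Build a fuzzy truth table
#'
#' Assigns every case to the corner of the condition space where its
#' conjunction membership exceeds 0.5 (exactly one corner per case, since
#' ties at 0.5 are nudged at calibration), and scores every corner:
#' `n_cases`, raw consistency `sum(min(r, y)) / sum(r)` and PRI
#' `(sum(min(r,y)) - sum(min(r,y,1-y))) / (sum(r) - sum(min(r,y,1-y)))`,
#' where `r` is the corner membership over all cases. Corners with fewer
#' than `freq_threshold` assigned cases are logical remainders; the rest
#' are coded 1 when both the consistency and PRI cutoffs are met and 0
#' otherwise (contradictory rows fail the PRI screen and code 0).
#'
#' @param fcm a `fuzzy_case_matrix`.
#' @param negate_outcome analyze the absence of the outcome.
#' @param freq_threshold minimum case frequency for an observed row.
#' @param cons_threshold raw-consistency cutoff (default 0.80).
#' @param pri_threshold numeric cutoff, or `"auto"` for
#'   [natural_break_pri()].
#' @return A tibble of class `qca_truth_table`: one row per corner with
#'   the condition columns, `n_cases`, `consistency`, `pri`,
#'   `outcome_code` in `{"1", "0", "remainder"}`; thresholds and the case
#'   matrix ride along as attributes.
#' @export
build_truth_table <- function(fcm, negate_outcome = FALSE,
                              freq_threshold = 1, cons_threshold = 0.80,
                              pri_threshold = "auto") {
  stopifnot(inherits(fcm, "fuzzy_case_matrix"))
  k <- length(fcm$conditions)
  if (k > 12) stop_esh("truth table limited to 12 conditions (2^k rows)")
  mb_cond <- fcm$mb[, fcm$conditions, drop = FALSE]
  y <- fcm$mb[, fcm$outcome]
  if (negate_outcome) y <- apply_tie_rule(fuzzy_negate(y))

  corners <- corner_matrix(fcm$conditions)
  n_rows <- nrow(corners)
  n_cases <- integer(n_rows); incl <- numeric(n_rows); pri <- numeric(n_rows)
  for (i in seq_len(n_rows)) {
    r <- corner_membership(mb_cond, corners[i, ])
    n_cases[i] <- sum(r > 0.5)
    sr <- sum(r); sry <- sum(pmin(r, y)); sryn <- sum(pmin(r, y, 1 - y))
    incl[i] <- if (sr > 0) sry / sr else NA_real_
    pri[i] <- if (sr - sryn > 0) (sry - sryn) / (sr - sryn) else NA_real_
  }
  observed <- n_cases >= freq_threshold
  if (any(observed & !is.finite(incl)))
    stop_esh("observed truth-table row with zero membership mass")
  pri_cut <- if (identical(pri_threshold, "auto"))
    natural_break_pri(pri[observed], cons_threshold = cons_threshold)
  else as.numeric(pri_threshold)

  code <- ifelse(!observed, "remainder",
                 ifelse(incl >= cons_threshold & pri >= pri_cut, "1", "0"))
  out <- tibble::as_tibble(as.data.frame(corners))
  out$n_cases <- n_cases
  out$consistency <- incl
  out$pri <- pri
  out$outcome_code <- code
  attr(out, "conditions") <- fcm$conditions
  attr(out, "outcome") <- fcm$outcome
  attr(out, "negate_outcome") <- negate_outcome
  attr(out, "thresholds") <- list(freq = freq_threshold,
                                  consistency = cons_threshold,
                                  pri = pri_cut)
  attr(out, "fcm") <- fcm
  class(out) <- c("qca_truth_table", class(out))
  out
}

## ---- Quine-McCluskey -------------------------------------------------

impl_key <- function(impl) paste(ifelse(is.na(impl), "-", impl), collapse = "")

# TRUE where corner (0/1 matrix rows) is covered by the implicant
implicant_covers <- function(impl, corners) {
  keep <- !is.na(impl)
  if (!any(keep)) return(rep(TRUE, nrow(corners)))
  rowSums(corners[, keep, drop = FALSE] ==
            matrix(impl[keep], nrow(corners), sum(keep), byrow = TRUE)) ==
    sum(keep)
}

#' Quine-McCluskey minimization
#'
#' Classic two-level minimization: iterative pairwise merging of
#' implicants (two implicants merge when they share the same don't-care
#' pattern and differ in exactly one literal) down to the complete set of
#' prime implicants, followed by exact minimal covering of the onset via
#' Petrick's method. Ties between equally sized covers are broken by
#' fewer total literals, then lexicographically in condition order, so
#' the result is deterministic.
#'
#' @param onset 0/1 matrix of corners that must evaluate TRUE (one corner
#'   per row, columns = conditions in order).
#' @param dontcare optional 0/1 matrix of corners free to evaluate either
#'   way (logical remainders admitted to the minimization).
#' @param conditions character vector of condition names.
#' @return A list of class `qm_result`: `primes` (list of implicants;
#'   integer vectors with 1/0/NA), `solution` (the chosen minimal cover),
#'   `covers` (all minimal covers found). An empty onset yields an empty
#'   solution ("no sufficient configuration"); a full onset yields the
#'   tautology (single all-don't-care implicant).
#' @export
quine_mccluskey <- function(onset, dontcare = NULL, conditions) {
  k <- length(conditions)
  if (is.null(dim(onset))) onset <- matrix(onset, ncol = k)
  if (!is.null(dontcare) && is.null(dim(dontcare)))
    dontcare <- matrix(dontcare, ncol = k)
  if (nrow(onset) == 0)
    return(structure(list(primes = list(), solution = list(),
                          covers = list(), conditions = conditions),
                     class = "qm_result"))
  both <- rbind(onset, dontcare)
  if (!is.null(dontcare) && nrow(dontcare) > 0) {
    on_keys <- apply(onset, 1, paste, collapse = "")
    dc_keys <- apply(dontcare, 1, paste, collapse = "")
    if (length(intersect(on_keys, dc_keys)) > 0)
      stop_esh("onset and don't-care sets overlap")
  }

  current <- unique(lapply(seq_len(nrow(both)),
                           function(i) as.integer(both[i, ])))
  primes <- list()
  while (length(current) > 0) {
    keys <- vapply(current, impl_key, "")
    merged_flag <- logical(length(current))
    nxt <- list(); nxt_keys <- character(0)
    if (length(current) > 1) {
      for (i in seq_len(length(current) - 1)) {
        for (j in (i + 1):length(current)) {
          a <- current[[i]]; b <- current[[j]]
          if (!identical(is.na(a), is.na(b))) next
          diffpos <- which(!is.na(a) & a != b)
          if (length(diffpos) != 1) next
          m <- a; m[diffpos] <- NA_integer_
          merged_flag[i] <- merged_flag[j] <- TRUE
          mk <- impl_key(m)
          if (!mk %in% nxt_keys) {
            nxt[[length(nxt) + 1]] <- m
            nxt_keys <- c(nxt_keys, mk)
          }
        }
      }
    }
    primes <- c(primes, current[!merged_flag])
    current <- nxt
  }
  # deduplicate primes
  primes <- primes[!duplicated(vapply(primes, impl_key, ""))]

  # Petrick cover of the onset
  cover_sets <- lapply(seq_len(nrow(onset)), function(i) {
    which(vapply(primes, function(p)
      implicant_covers(p, onset[i, , drop = FALSE]), logical(1)))
  })
  sums <- list(integer(0))
  for (cs in cover_sets) {
    sums <- unique(unlist(lapply(sums, function(s)
      lapply(cs, function(p) sort(unique(c(s, p))))), recursive = FALSE))
    # absorption: drop supersets of any other term
    keep <- rep(TRUE, length(sums))
    for (a in seq_along(sums)) {
      if (!keep[a]) next
      for (b in seq_along(sums)) {
        if (a == b || !keep[b]) next
        if (all(sums[[b]] %in% sums[[a]]) &&
            length(sums[[b]]) < length(sums[[a]])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sums <- sums[keep]
  }
  sizes <- lengths(sums)
  cand <- sums[sizes == min(sizes)]
  lits <- vapply(cand, function(s)
    sum(vapply(primes[s], function(p) sum(!is.na(p)), 0L)), 0)
  cand <- cand[lits == min(lits)]
  labels <- vapply(cand, function(s)
    paste(sort(vapply(primes[s], impl_key, "")), collapse = "+"), "")
  chosen <- cand[[order(labels)[1]]]
  covers <- lapply(cand, function(s) primes[s])
  structure(list(primes = primes, solution = primes[chosen],
                 covers = covers, conditions = conditions),
            class = "qm_result")
}

# human-readable product term, e.g. "Z6*~Z7"
recipe_label <- function(impl, conditions) {
  keep <- which(!is.na(impl))
  if (length(keep) == 0) return("(always)")
  paste(ifelse(impl[keep] == 1, conditions[keep],
               paste0("~", conditions[keep])), collapse = "*")
}

## ---- solutions -------------------------------------------------------

tt_corners <- function(tt) {
  as.matrix(tt[, attr(tt, "conditions"), drop = FALSE])
}

#' Derive complex, parsimonious and intermediate solutions
#'
#' Minimizes a truth table three ways: the complex solution admits no
#' logical remainders, the parsimonious solution admits all of them, and
#' the intermediate solution admits only "easy counterfactuals" --
#' remainder rows whose literals agree with the stated directional
#' expectation wherever one is stated (`present`/`absent`; `none` leaves
#' a condition unconstrained). When no expectation is stated at all the
#' intermediate solution equals the complex one.
#'
#' Core conditions are the literals of an intermediate recipe that also
#' appear in some parsimonious recipe subsuming it; the remaining
#' literals are peripheral.
#'
#' @param tt a `qca_truth_table` from [build_truth_table()].
#' @param expectations named character vector/list mapping conditions to
#'   `"present"`, `"absent"` or `"none"`; missing conditions default to
#'   `"none"`.
#' @return A list of class `qca_solutions` with elements `complex`,
#'   `parsimonious`, `intermediate` (each a `qca_solution` carrying
#'   recipes, core/peripheral marks and consistency/coverage statistics)
#'   plus the truth table and expectations.
#' @export
derive_solutions <- function(tt, expectations = NULL) {
  stopifnot(inherits(tt, "qca_truth_table"))
  conditions <- attr(tt, "conditions")
  if (!is.null(expectations)) {
    unknown <- setdiff(names(expectations), conditions)
    if (length(unknown) > 0)
      stop_esh("expectations reference unknown condition(s): ",
               paste(unknown, collapse = ", "))
    bad <- setdiff(unlist(expectations), c("present", "absent", "none"))
    if (length(bad) > 0)
      stop_esh("expectations must be present/absent/none, got: ",
               paste(bad, collapse = ", "))
  }
  exp_vec <- stats::setNames(rep("none", length(conditions)), conditions)
  exp_vec[names(expectations)] <- unlist(expectations)

  corners <- tt_corners(tt)
  onset <- corners[tt$outcome_code == "1", , drop = FALSE]
  remainders <- corners[tt$outcome_code == "remainder", , drop = FALSE]

  easy <- if (all(exp_vec == "none")) {
    remainders[integer(0), , drop = FALSE]
  } else {
    ok <- rep(TRUE, nrow(remainders))
    for (cn in conditions) {
      if (exp_vec[cn] == "present") ok <- ok & remainders[, cn] == 1
      if (exp_vec[cn] == "absent") ok <- ok & remainders[, cn] == 0
    }
    remainders[ok, , drop = FALSE]
  }

  qm_complex <- quine_mccluskey(onset, NULL, conditions)
  qm_pars <- quine_mccluskey(onset, remainders, conditions)
  qm_int <- quine_mccluskey(onset, easy, conditions)

  fcm <- attr(tt, "fcm")
  y <- fcm$mb[, fcm$outcome]
  if (attr(tt, "negate_outcome")) y <- apply_tie_rule(fuzzy_negate(y))

  mk_solution <- function(qm, type, pars_recipes = NULL) {
    recipes <- qm$solution
    marks <- lapply(recipes, function(r) {
      core <- rep(FALSE, length(conditions))
      if (!is.null(pars_recipes)) {
        for (p in pars_recipes) {
          sub <- all(is.na(p) | (!is.na(r) & p == r))
          if (sub) core <- core | (!is.na(p))
        }
      } else {
        core <- !is.na(r)   # parsimonious literals are core by definition
      }
      stats::setNames(ifelse(is.na(r), NA_character_,
                             paste0(ifelse(core & !is.na(r), "core", "peripheral"),
                                    "_", ifelse(r == 1, "present", "absent"))),
                      conditions)
    })
    sol <- structure(list(type = type, recipes = recipes, marks = marks,
                          conditions = conditions,
                          labels = vapply(recipes, recipe_label, "",
                                          conditions = conditions)),
                     class = "qca_solution")
    solution_statistics(sol, fcm, y = y)
  }

  pars <- mk_solution(qm_pars, "parsimonious")
  structure(list(
    complex = mk_solution(qm_complex, "complex", pars_recipes = qm_pars$solution),
    parsimonious = pars,
    intermediate = mk_solution(qm_int, "intermediate",
                               pars_recipes = qm_pars$solution),
    truth_table = tt, expectations = exp_vec
  ), class = "qca_solutions")
}

# membership of every case in one recipe: min over its literals
recipe_membership <- function(impl, fcm) {
  keep <- which(!is.na(impl))
  if (length(keep) == 0) return(rep(1, length(fcm$cases)))
  lit <- fcm$mb[, fcm$conditions[keep], drop = FALSE]
  for (j in seq_along(keep))
    if (impl[keep[j]] == 0) lit[, j] <- 1 - lit[, j]
  apply(lit, 1, min)
}

#' Consistency and coverage statistics of a solution
#'
#' Fills per-recipe consistency (`sum(min(s, y)) / sum(s)`), raw coverage
#' (`sum(min(s, y)) / sum(y)`) and unique coverage (the solution coverage
#' minus the coverage of the solution with that recipe removed), plus
#' solution-level consistency and coverage of the max-over-recipes
#' membership.
#'
#' @param sol a `qca_solution`.
#' @param fcm the `fuzzy_case_matrix` the solution was derived from.
#' @param y outcome memberships (defaults to the matrix's outcome column).
#' @return `sol` with a `stats` tibble (`recipe, consistency,
#'   raw_coverage, unique_coverage`) and `solution_consistency` /
#'   `solution_coverage` fields filled.
#' @export
solution_statistics <- function(sol, fcm, y = NULL) {
  stopifnot(inherits(sol, "qca_solution"))
  if (is.null(y)) y <- fcm$mb[, fcm$outcome]
  recipes <- sol$recipes
  if (length(recipes) == 0) {
    sol$stats <- tibble::tibble(recipe = character(0),
                                consistency = numeric(0),
                                raw_coverage = numeric(0),
                                unique_coverage = numeric(0))
    sol$solution_consistency <- NA_real_
    sol$solution_coverage <- NA_real_
    return(sol)
  }
  mem <- vapply(recipes, recipe_membership, numeric(length(fcm$cases)),
                fcm = fcm)
  mem <- matrix(mem, nrow = length(fcm$cases))
  sol_mem <- apply(mem, 1, max)
  sol_cov <- suff_incl_cov(sol_mem, y)
  cov_without <- vapply(seq_along(recipes), function(i) {
    if (length(recipes) == 1) return(0)
    others <- apply(mem[, -i, drop = FALSE], 1, max)
    suff_incl_cov(others, y)$coverage
  }, numeric(1))
  per <- lapply(seq_along(recipes), function(i) {
    ic <- suff_incl_cov(mem[, i], y)
    tibble::tibble(recipe = sol$labels[i],
                   consistency = ic$consistency,
                   raw_coverage = ic$coverage,
                   unique_coverage = sol_cov$coverage - cov_without[i])
  })
  sol$stats <- dplyr::bind_rows(per)
  sol$solution_consistency <- sol_cov$consistency
  sol$solution_coverage <- sol_cov$coverage
  sol
}

#' @export
print.qca_solution <- function(x, digits = 3, ...) {
  cat("<qca_solution> ", x$type, " (", length(x$recipes), " recipe",
      if (length(x$recipes) != 1) "s", ")\n", sep = "")
  if (length(x$recipes) == 0) {
    cat("  no sufficient configuration\n")
    return(invisible(x))
  }
  print(format_solution_chart(x), right = FALSE)
  cat(sprintf("solution consistency %.3f, coverage %.3f\n",
              x$solution_consistency, x$solution_coverage))
  invisible(x)
}

#' Configuration chart of a solution
#'
#' Text rendering of the configuration table: one column per recipe with
#' the marks `●` core condition present, `•` peripheral
#' present, `⊗` core condition absent, `⊘` peripheral absent,
#' blank for don't-care, followed by the consistency/coverage rows.
#'
#' @param sol a `qca_solution` with statistics filled.
#' @return A character data frame (conditions + statistics as rows).
#' @export
format_solution_chart <- function(sol) {
  sym <- c(core_present = "●", peripheral_present = "•",
           core_absent = "⊗", peripheral_absent = "⊘")
  cols <- lapply(seq_along(sol$recipes), function(i) {
    m <- sol$marks[[i]]
    c(ifelse(is.na(m), "", sym[m]),
      sprintf("%.3f", sol$stats$consistency[i]),
      sprintf("%.3f", sol$stats$raw_coverage[i]),
      sprintf("%.3f", sol$stats$unique_coverage[i]))
  })
  df <- as.data.frame(cols,
                      col.names = paste0("path", seq_along(sol$recipes)),
                      check.names = FALSE)
  rownames(df) <- c(sol$conditions,
                    "consistency", "raw coverage", "unique coverage")
  df
}

# canonical string of a solution's recipe set (for robustness comparisons)
solution_signature <- function(sol) {
  paste(sort(vapply(sol$recipes, impl_key, "")), collapse = "+")
}

#' Robustness scan over consistency thresholds
#'
#' Re-runs truth-table construction and minimization at each consistency
#' threshold in `thresholds` and flags whether the parsimonious and
#' intermediate recipe sets equal those at the baseline threshold
#' (which is always included in the scan).
#'
#' @param fcm a `fuzzy_case_matrix`.
#' @param negate_outcome analyze the absence of the outcome.
#' @param thresholds consistency thresholds to scan (default
#'   `c(0.75, 0.80, 0.85)`), each in `(0.5, 1]`.
#' @param baseline baseline threshold (default 0.80).
#' @param freq_threshold,pri_threshold,expectations passed through to
#'   [build_truth_table()] / [derive_solutions()].
#' @return A tibble `threshold, n_recipes, solution, same_as_baseline`
#'   (class `qca_robustness`) with the full solution objects as the
#'   `solutions` attribute.
#' @export
robustness_scan <- function(fcm, negate_outcome = FALSE,
                            thresholds = c(0.75, 0.80, 0.85),
                            baseline = 0.80, freq_threshold = 1,
                            pri_threshold = "auto", expectations = NULL) {
  thresholds <- sort(unique(c(thresholds, baseline)))
  if (any(thresholds <= 0.5 | thresholds > 1))
    stop_esh("consistency thresholds must lie in (0.5, 1]")
  runs <- lapply(thresholds, function(th) {
    tt <- build_truth_table(fcm, negate_outcome = negate_outcome,
                            freq_threshold = freq_threshold,
                            cons_threshold = th,
                            pri_threshold = pri_threshold)
    derive_solutions(tt, expectations = expectations)
  })
  names(runs) <- as.character(thresholds)
  sig <- function(s) paste(solution_signature(s$parsimonious),
                           solution_signature(s$intermediate), sep = " | ")
  base_sig <- sig(runs[[as.character(baseline)]])
  out <- tibble::tibble(
    threshold = thresholds,
    n_recipes = unname(vapply(runs, function(s)
      length(s$intermediate$recipes), 0L)),
    solution = unname(vapply(runs, function(s)
      if (length(s$intermediate$recipes) == 0) "no sufficient configuration"
      else paste(s$intermediate$labels, collapse = " + "), "")),
    same_as_baseline = unname(vapply(runs, function(s)
      identical(sig(s), base_sig), logical(1)))
  )
  attr(out, "solutions") <- runs
  attr(out, "baseline") <- baseline
  class(out) <- c("qca_robustness", class(out))
  out
}

#' One-call fsQCA of a case matrix
#'
#' Runs necessity analysis, truth-table construction, minimization and a
#' robustness scan for one outcome orientation.
#'
#' @inheritParams robustness_scan
#' @param cons_threshold baseline consistency threshold.
#' @param scan_thresholds thresholds for the robustness scan, or `NULL`
#'   to skip it.
#' @return A list with `necessity`, `truth_table`, `solutions` and
#'   (optionally) `robustness`.
#' @export
fsqca <- function(fcm, negate_outcome = FALSE, freq_threshold = 1,
                  cons_threshold = 0.80, pri_threshold = "auto",
                  expectations = NULL,
                  scan_thresholds = c(0.75, 0.80, 0.85)) {
  nec <- necessity_analysis(fcm, negate_outcome = negate_outcome)
  tt <- build_truth_table(fcm, negate_outcome = negate_outcome,
                          freq_threshold = freq_threshold,
                          cons_threshold = cons_threshold,
                          pri_threshold = pri_threshold)
  sols <- derive_solutions(tt, expectations = expectations)
  rob <- if (!is.null(scan_thresholds))
    robustness_scan(fcm, negate_outcome = negate_outcome,
                    thresholds = scan_thresholds, baseline = cons_threshold,
                    freq_threshold = freq_threshold,
                    pri_threshold = pri_threshold,
                    expectations = expectations)
  list(necessity = nec, truth_table = tt, solutions = sols,
       robustness = rob)
}
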