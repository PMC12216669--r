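# Synthetic-data generators: indicator panels with a two-stratum county
# structure and fuzzy case matrices with planted sufficient
# configurations, both fully reproducible under a seed.

#' Specify a synthetic indicator panel
#'
#' The default specification emulates the structure of the study region:
#' 86 counties over 2020--2022, 25 of them in a mountain/island stratum
#' with systematically lower economy and healthcare levels, 20 positive
#' log-normal indicators with mild year-on-year growth. Magnitudes are
#' generic, not calibrated to any real yearbook.
#'
#' @param n_counties number of counties.
#' @param n_mountain_island number of counties in the disadvantaged
#'   stratum (must be in `1 .. n_counties - 1`).
#' @param years integer vector of panel years.
#' @param group_gap log-scale deficit of the mountain/island stratum on
#'   economy and healthcare indicators (society gets half the gap).
#' @param drift log-scale year-on-year growth.
#' @param noise_sd log-scale county-level noise standard deviation; 0
#'   gives a deterministic two-level panel.
#' @param seed integer RNG seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_counties = 86, n_mountain_island = 25,
                       years = 2020:2022, group_gap = 0.8, drift = 0.05,
                       noise_sd = 0.35, seed = 1) {
  if (n_mountain_island < 1 || n_mountain_island >= n_counties)
    stop_esh("n_mountain_island must be between 1 and n_counties - 1")
  if (noise_sd < 0 || group_gap < 0) stop_esh("scales must be nonnegative")
  structure(list(n_counties = n_counties,
                 n_mountain_island = n_mountain_island,
                 years = as.integer(years), group_gap = group_gap,
                 drift = drift, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic indicator panel
#'
#' Draws log-normal positive indicator values
#' `x = exp(mu_j + group effect + drift * (t - t0) + county noise)`,
#' where the mountain/island stratum receives a negative location shift
#' on the economy and healthcare blocks (and half of it on the society
#' block). County noise is drawn independently per county-indicator-year,
#' so yearly cross-sections differ while the stratum gap and growth drift
#' persist. Identical spec and seed give identical panels (fixed
#' Mersenne-Twister / inversion RNG).
#'
#' @param spec a `panel_spec`.
#' @return An `indicator_panel`; the region assignment ships in the
#'   `region_groups` attribute (tibble `county, group`).
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  old <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit(do.call(RNGkind, as.list(old)), add = TRUE)
  set.seed(spec$seed)

  scheme <- esh_scheme()
  counties <- sprintf("county%02d", seq_len(spec$n_counties))
  group <- rep("other", spec$n_counties)
  group[seq_len(spec$n_mountain_island)] <- "mountain_island"

  # generic indicator base levels (log scale), roughly spanning the unit
  # range of real systems after min-max normalization
  mu <- stats::runif(nrow(scheme), min = 1, max = 6)
  gap <- ifelse(scheme$system == "society", spec$group_gap / 2,
                spec$group_gap)

  t0 <- min(spec$years)
  rows <- lapply(seq_along(spec$years), function(ti) {
    yr <- spec$years[ti]
    noise <- matrix(stats::rnorm(spec$n_counties * nrow(scheme),
                                 sd = spec$noise_sd),
                    nrow = spec$n_counties)
    logval <- matrix(mu, spec$n_counties, nrow(scheme), byrow = TRUE) -
      outer(group == "mountain_island", gap) +
      spec$drift * (yr - t0) + noise
    tibble::tibble(
      county = rep(counties, times = nrow(scheme)),
      year = as.integer(yr),
      indicator = rep(scheme$id, each = spec$n_counties),
      value = exp(as.numeric(logval))
    )
  })
  panel <- as_indicator_panel(dplyr::bind_rows(rows), scheme = scheme)
  attr(panel, "region_groups") <- tibble::tibble(
    county = counties,
    group = factor(group, levels = c("mountain_island", "other"))
  )
  panel
}

#' Specify a planted configurational data set
#'
#' @param recipes list of planted sufficient recipes, each a character
#'   vector of literals over the five default conditions, `~` marking
#'   negation (e.g. `c("Z6", "Z7")` for the conjunction `Z6*Z7`).
#' @param n_cases number of cases.
#' @param noise standard deviation of truncated-normal noise added to
#'   the outcome memberships (0 = exact set-theoretic outcome).
#' @param seed integer RNG seed.
#' @param conditions condition names.
#' @return A list of class `qca_plant`.
#' @export
qca_plant <- function(recipes = list(c("Z6", "Z7")), n_cases = 25,
                      noise = 0, seed = 1,
                      conditions = c("Z1", "Z5", "Z6", "Z7", "Z8")) {
  if (noise < 0) stop_esh("noise must be nonnegative")
  parsed <- lapply(recipes, function(r) {
    neg <- startsWith(r, "~")
    cond <- sub("^~", "", r)
    unknown <- setdiff(cond, conditions)
    if (length(unknown) > 0)
      stop_esh("recipe references unknown condition(s): ",
               paste(unknown, collapse = ", "))
    list(condition = cond, value = ifelse(neg, 0L, 1L))
  })
  structure(list(recipes = recipes, parsed = parsed, n_cases = n_cases,
                 noise = noise, seed = as.integer(seed),
                 conditions = conditions),
            class = "qca_plant")
}

# fuzzy evaluation of planted recipes: max over recipes of min over literals
plant_outcome <- function(plant, mb) {
  per <- vapply(plant$parsed, function(p) {
    lit <- mb[, p$condition, drop = FALSE]
    for (j in seq_along(p$condition))
      if (p$value[j] == 0) lit[, j] <- 1 - lit[, j]
    apply(lit, 1, min)
  }, numeric(nrow(mb)))
  apply(matrix(per, nrow = nrow(mb)), 1, max)
}

#' Generate a fuzzy case matrix with planted recipes
#'
#' Condition memberships are uniform on `[0.05, 0.95]`; the outcome is
#' the max-min evaluation of the planted recipes plus truncated-normal
#' noise, clipped to `[0.001, 0.999]` to respect fuzzy-set bounds. With
#' `noise = 0` every case's outcome equals the planted evaluation
#' exactly, so minimization must recover a solution logically equivalent
#' to the plant on the observed rows.
#'
#' @param plant a `qca_plant`.
#' @return A `fuzzy_case_matrix` (memberships taken as already
#'   calibrated).
#' @export
generate_qca_cases <- function(plant = qca_plant()) {
  stopifnot(inherits(plant, "qca_plant"))
  old <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit(do.call(RNGkind, as.list(old)), add = TRUE)
  set.seed(plant$seed)
  k <- length(plant$conditions)
  mb <- matrix(stats::runif(plant$n_cases * k, 0.05, 0.95),
               nrow = plant$n_cases,
               dimnames = list(sprintf("case%02d", seq_len(plant$n_cases)),
                               plant$conditions))
  y <- plant_outcome(plant, mb)
  if (plant$noise > 0) {
    y <- y + stats::rnorm(plant$n_cases, sd = plant$noise)
    y <- pmin(pmax(y, 0.001), 0.999)
  }
  df <- tibble::as_tibble(as.data.frame(mb))
  df$case <- rownames(mb)
  df$D <- y
  fuzzy_case_matrix(df, conditions = plant$conditions, outcome = "D",
                    calibrated = TRUE)
}

#' End-to-end recovery harness
#'
#' Runs the full pipeline on synthetic data with known ground truth and
#' reports whether it is recovered: (i) scoring + CCD on a generated
#' panel must rank the mountain/island stratum below the other stratum in
#' mean CCD every year; (ii) fsQCA on a planted case matrix must produce
#' an intermediate solution logically equivalent to the planted recipes
#' on the observed truth-table rows, and (iii) the robustness scan must
#' be stable across its thresholds for noise-free plants.
#'
#' @param spec a `panel_spec`.
#' @param plant a `qca_plant`.
#' @param cons_threshold baseline consistency threshold.
#' @return A list with `group_ordering` (tibble per year),
#'   `ordering_recovered`, `solutions`, `recipes_recovered`,
#'   `n_contradictions` (corners whose assigned cases disagree on which
#'   side of 0.5 the outcome falls), and `robustness`.
#' @export
recovery_harness <- function(spec = panel_spec(), plant = qca_plant(),
                             cons_threshold = 0.80) {
  panel <- generate_panel(spec)
  groups <- attr(panel, "region_groups")
  scored <- score_panel(panel)
  ccd <- ccd_table(scored$scores)
  summ <- regional_summary(ccd, groups, digits = NULL)
  bygrp <- summ[summ$group != "all", c("year", "group", "mean")]
  wide <- tidyr::pivot_wider(bygrp, names_from = "group",
                             values_from = "mean")
  ordering <- dplyr::mutate(
    wide, recovered = .data$mountain_island < .data$other)

  fcm <- generate_qca_cases(plant)
  tt <- build_truth_table(fcm, cons_threshold = cons_threshold)
  sols <- derive_solutions(tt)
  rob <- robustness_scan(fcm, baseline = cons_threshold)

  corners <- tt_corners(tt)
  observed <- tt$outcome_code != "remainder"
  plant_truth <- plant_truth_on_corners(plant, corners)
  sol_truth <- solution_truth_on_corners(sols$intermediate, corners)
  recovered <- all(sol_truth[observed] == plant_truth[observed])

  list(
    group_ordering = ordering,
    ordering_recovered = all(ordering$recovered),
    solutions = sols,
    recipes_recovered = recovered,
    n_contradictions = count_contradictory_corners(fcm),
    robustness = rob
  )
}

#' Count crisply contradictory truth-table corners
#'
#' A corner is contradictory when the cases assigned to it (membership in
#' the corner's conjunction above 0.5) fall on both sides of the outcome's
#' 0.5 crossover. Noise-free planted data have none; planting an outcome
#' and its negation on the same corner guarantees some.
#'
#' @param fcm a `fuzzy_case_matrix`.
#' @return Integer count of contradictory corners.
#' @export
count_contradictory_corners <- function(fcm) {
  crisp <- fcm$mb[, fcm$conditions, drop = FALSE] > 0.5
  y_high <- fcm$mb[, fcm$outcome] > 0.5
  keys <- apply(crisp, 1, paste, collapse = "")
  sides <- tapply(y_high, keys, function(s) length(unique(s)))
  sum(sides > 1)
}

# Boolean evaluation of planted recipes on 0/1 corners
plant_truth_on_corners <- function(plant, corners) {
  hit <- rep(FALSE, nrow(corners))
  for (p in plant$parsed) {
    ok <- rep(TRUE, nrow(corners))
    for (j in seq_along(p$condition))
      ok <- ok & corners[, p$condition[j]] == p$value[j]
    hit <- hit | ok
  }
  hit
}

# Boolean evaluation of a derived solution on 0/1 corners
solution_truth_on_corners <- function(sol, corners) {
  if (length(sol$recipes) == 0) return(rep(FALSE, nrow(corners)))
  hit <- rep(FALSE, nrow(corners))
  for (r in sol$recipes) hit <- hit | implicant_covers(r, corners)
  hit
}
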