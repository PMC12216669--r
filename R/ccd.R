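# Coupling coordination degree model: coupling degree C, composite index
# T, coordination degree D, the ten-grade classification, and the
# regional/temporal summary statistics.

#' Coupling degree of the three system scores
#'
#' `C = 3 * ((U_EC * U_SO * U_HE) / (U_EC + U_SO + U_HE)^3)^(1/3)`,
#' a `[0, 1]` index of how evenly the three systems develop: `C = 1`
#' exactly when all three scores are equal and positive, and `C = 0`
#' whenever any score is 0 (including the all-zero case, where the ratio
#' is taken as 0).
#'
#' @param u_ec,u_so,u_he system scores in `[0, 1]`; vectors are recycled
#'   to a common length.
#' @return Numeric vector of coupling degrees in `[0, 1]`.
#' @export
#' @examples
#' coupling_degree(0.2, 0.4, 0.6)
coupling_degree <- function(u_ec, u_so, u_he) {
  n <- max(length(u_ec), length(u_so), length(u_he))
  u_ec <- rep_len(u_ec, n); u_so <- rep_len(u_so, n); u_he <- rep_len(u_he, n)
  u <- cbind(u_ec, u_so, u_he)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop_esh("system scores must lie in [0, 1]")
  s <- u_ec + u_so + u_he
  ratio <- ifelse(s > 0, (u_ec * u_so * u_he) / s^3, 0)
  pmin(3 * ratio^(1 / 3), 1)
}

#' Composite index and coordination degree
#'
#' `T = alpha*U_EC + beta*U_SO + gamma*U_HE` is the weighted overall
#' development level and `D = sqrt(C * T)` the coupling coordination
#' degree. The three weights default to 1/3 each and must be nonnegative
#' and sum to 1 (tolerance 1e-9).
#'
#' @inheritParams coupling_degree
#' @param C coupling degrees from [coupling_degree()].
#' @param alpha,beta,gamma subsystem weights.
#' @return A tibble with columns `T` and `D`.
#' @export
coordination_degree <- function(C, u_ec, u_so, u_he,
                                alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  w <- c(alpha, beta, gamma)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_esh("subsystem weights must be nonnegative and sum to 1")
  if (any(C < 0 | C > 1)) stop_esh("C must lie in [0, 1]")
  T <- alpha * u_ec + beta * u_so + gamma * u_he
  tibble::tibble(T = T, D = sqrt(C * T))
}

# the ten grades, in increasing order of coordination
ccd_grade_labels <- c(
  "Extreme disorder", "Severe disorder", "Moderate disorder",
  "Mild disorder", "Near disorder", "Reluctant coordination",
  "Primary coordination", "Intermediate coordination",
  "Good coordination", "Excellent coordination"
)

#' The ten-grade CCD classification scale
#'
#' @return A tibble with columns `grade`, `lower`, `upper`. Intervals are
#'   half-open `[lower, upper)` with the top interval closed at 1, so the
#'   grades partition `[0, 1]` and every D maps to exactly one grade.
#' @export
ccd_grades <- function() {
  tibble::tibble(
    grade = factor(ccd_grade_labels, levels = ccd_grade_labels),
    lower = (0:9) / 10,
    upper = (1:10) / 10
  )
}

#' Classify coordination degrees into the ten grades
#'
#' @param D numeric vector of coordination degrees in `[0, 1]`.
#' @return Factor of grade labels with levels in increasing order.
#' @export
#' @examples
#' classify_ccd(c(0, 0.7, 0.85))
classify_ccd <- function(D) {
  if (any(!is.finite(D)) || any(D < 0 | D > 1))
    stop_esh("D must lie in [0, 1]")
  idx <- pmin(floor(D * 10), 9) + 1
  factor(ccd_grade_labels[idx], levels = ccd_grade_labels)
}

#' CCD table from system scores
#'
#' Computes, per county-year, the coupling degree `C`, composite index
#' `T`, coordination degree `D` and its grade.
#'
#' @param scores tibble with columns `county, year, U_EC, U_SO, U_HE`
#'   (see [system_scores()]).
#' @inheritParams coordination_degree
#' @return A tibble `county, year, C, T, D, grade`.
#' @export
ccd_table <- function(scores, alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  C <- coupling_degree(scores$U_EC, scores$U_SO, scores$U_HE)
  td <- coordination_degree(C, scores$U_EC, scores$U_SO, scores$U_HE,
                            alpha, beta, gamma)
  tibble::tibble(
    county = scores$county, year = as.integer(scores$year),
    C = C, T = td$T, D = td$D, grade = classify_ccd(td$D)
  )
}

#' Regional summary statistics of CCD values
#'
#' Per year and region group (plus an `all` group), computes the count,
#' mean, median (mean of the two middle order statistics for even n),
#' standard deviation and coefficient of variation `CV = std/mean` of the
#' D values. Values are reported rounded to `digits` decimals, half away
#' from zero, matching conventional summary-table precision; pass
#' `digits = NULL` for full precision.
#'
#' @param ccd tibble with columns `county`, `year`, `D` (e.g. from
#'   [ccd_table()] or [load_ccd_fixture()]).
#' @param groups optional tibble from [read_region_groups()]; when
#'   omitted only the `all` group is summarized.
#' @param estimator `"sample"` (n-1 denominator, default) or
#'   `"population"` for the standard deviation.
#' @param digits decimals for reporting, or `NULL`.
#' @return A tibble `year, group, n, mean, median, std, cv`.
#' @export
regional_summary <- function(ccd, groups = NULL,
                             estimator = c("sample", "population"),
                             digits = 3) {
  estimator <- match.arg(estimator)
  stopifnot(all(c("county", "year", "D") %in% names(ccd)))
  ccd <- tibble::as_tibble(ccd[c("county", "year", "D")])
  pieces <- list(dplyr::mutate(ccd, group = "all"))
  if (!is.null(groups)) {
    g <- as.character(match_region_groups(ccd$county, groups))
    pieces <- c(pieces, list(dplyr::mutate(ccd, group = g)))
  }
  dat <- dplyr::bind_rows(pieces)
  sdev <- function(x) {
    if (estimator == "sample") stats::sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  out <- dat |>
    dplyr::group_by(.data$year, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$D),
      median = stats::median(.data$D),
      std = sdev(.data$D),
      cv = .data$std / .data$mean,
      .groups = "drop"
    )
  if (any(out$n == 0)) stop_esh("empty region group")
  if (!is.null(digits)) {
    num <- c("mean", "median", "std", "cv")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' Temporal trend summary of CCD values
#'
#' Counts counties per grade and year, counts counties at or above
#' `high_cut` and strictly below `low_cut`, and reports the fold increase
#' of the high band and the percent decrease of the low band between two
#' years: `fold = (N_high(b) - N_high(a)) / N_high(a)` and
#' `pct_decrease = (N_low(a) - N_low(b)) / N_low(a) * 100`.
#'
#' @inheritParams regional_summary
#' @param low_cut lower band cutoff (default 0.4, i.e. "Mild disorder or
#'   below" is `D < 0.4`).
#' @param high_cut upper band cutoff (default 0.7, i.e. "Intermediate
#'   coordination or above" is `D >= 0.7`).
#' @param year_a,year_b comparison years (a = baseline).
#' @return A list with `grade_counts` (tibble year x grade), `bands`
#'   (tibble `year, n_high, n_low`), `fold_increase_high` and
#'   `pct_decrease_low` (the latter two `NA` with a note when the
#'   baseline count is 0).
#' @export
trend_summary <- function(ccd, low_cut = 0.4, high_cut = 0.7,
                          year_a, year_b) {
  stopifnot(all(c("year", "D") %in% names(ccd)))
  if (!all(c(year_a, year_b) %in% ccd$year))
    stop_esh("comparison year(s) absent from data")
  grade_counts <- ccd |>
    dplyr::mutate(grade = classify_ccd(.data$D)) |>
    dplyr::count(.data$year, .data$grade, .drop = FALSE, name = "n")
  bands <- ccd |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_high = sum(.data$D >= high_cut),
                     n_low = sum(.data$D < low_cut), .groups = "drop")
  nh <- function(y) bands$n_high[bands$year == y]
  nl <- function(y) bands$n_low[bands$year == y]
  fold <- if (nh(year_a) == 0) NA_real_ else
    (nh(year_b) - nh(year_a)) / nh(year_a)
  pct <- if (nl(year_a) == 0) NA_real_ else
    (nl(year_a) - nl(year_b)) / nl(year_a) * 100
  list(
    grade_counts = grade_counts,
    bands = bands,
    year_a = year_a, year_b = year_b,
    fold_increase_high = fold,
    pct_decrease_low = pct,
    note = if (is.na(fold)) "fold change undefined: baseline high-band count is 0"
           else NULL
  )
}
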