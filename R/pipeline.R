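# End-to-end orchestration: panel -> scores -> CCD -> summaries ->
# per-year fsQCA, with reproducible artifacts and a run manifest.

#' Build a pipeline run configuration
#'
#' Collects every tunable of the analysis with the defaults used
#' throughout the package: per-year min-max normalization, per-system
#' entropy weights, equal CCD weights (1/3 each), frequency threshold 1,
#' consistency threshold 0.80 with automatic (natural-break) PRI cutoff,
#' robustness scan over `{0.75, 0.80, 0.85}`, and directional
#' expectations of `present` for every condition for the high outcome
#' (`none` for the negated outcome).
#'
#' @param panel_path,region_path optional input CSVs; when `NULL` a
#'   synthetic panel is generated from `spec`.
#' @param spec a [panel_spec()] used when no panel path is given.
#' @param pooling,scope,shift scoring options, see [score_panel()].
#' @param alpha,beta,gamma CCD weights.
#' @param conditions,outcome fsQCA variable names.
#' @param qca_group which region group forms the fsQCA case set
#'   (`"mountain_island"`, `"other"` or `"all"`).
#' @param freq_threshold,cons_threshold,pri_threshold truth-table
#'   cutoffs.
#' @param expectations directional expectations for the high outcome.
#' @param scan_thresholds robustness scan set.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and used for
#'   synthetic generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel_path = NULL, region_path = NULL,
                       spec = panel_spec(),
                       pooling = "per_year", scope = "per_system",
                       shift = 0,
                       alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3,
                       conditions = c("Z1", "Z5", "Z6", "Z7", "Z8"),
                       outcome = "D", qca_group = "mountain_island",
                       freq_threshold = 1, cons_threshold = 0.80,
                       pri_threshold = "auto",
                       expectations = stats::setNames(
                         rep("present", length(conditions)), conditions),
                       scan_thresholds = c(0.75, 0.80, 0.85),
                       out_dir = tempfile("eshcoord_run"), seed = 1) {
  structure(list(panel_path = panel_path, region_path = region_path,
                 spec = spec, pooling = pooling, scope = scope,
                 shift = shift, alpha = alpha, beta = beta, gamma = gamma,
                 conditions = conditions, outcome = outcome,
                 qca_group = qca_group, freq_threshold = freq_threshold,
                 cons_threshold = cons_threshold,
                 pri_threshold = pri_threshold,
                 expectations = expectations,
                 scan_thresholds = scan_thresholds,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Scores the panel (entropy weights), computes the CCD table, regional
#' and temporal summaries, and per-year fsQCA of both the high and
#' negated outcome over the configured case group, writing every artifact
#' as CSV/JSON to `config$out_dir` together with a manifest (config,
#' package version, seed, input checksums). Any stage error aborts the
#' run and removes partial outputs.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results (`scores`, `ccd`,
#'   `regional`, `trend`, `qca` per year, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  tryCatch({
    stage <- "input"
    if (is.null(config$panel_path)) {
      spec <- config$spec
      spec$seed <- config$seed
      panel <- generate_panel(spec)
      groups <- attr(panel, "region_groups")
    } else {
      panel <- read_panel(config$panel_path)
      groups <- if (!is.null(config$region_path))
        read_region_groups(config$region_path, counties = panel$counties)
    }

    stage <- "scoring"
    scored <- score_panel(panel, pooling = config$pooling,
                          scope = config$scope, shift = config$shift)
    emit(scored$weights, "weights.csv")
    emit(scored$scores, "scores.csv")

    stage <- "ccd"
    ccd <- ccd_table(scored$scores, config$alpha, config$beta, config$gamma)
    emit(ccd, "ccd.csv")

    stage <- "summaries"
    regional <- regional_summary(ccd, groups)
    emit(regional, "regional_summary.csv")
    yrs <- range(panel$years)
    trend <- trend_summary(ccd, year_a = yrs[1], year_b = yrs[2])
    trend_path <- file.path(out_dir, "trend_summary.json")
    jsonlite::write_json(
      list(bands = trend$bands,
           grade_counts = trend$grade_counts,
           fold_increase_high = trend$fold_increase_high,
           pct_decrease_low = trend$pct_decrease_low),
      trend_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, trend_path)

    stage <- "fsqca"
    qca_counties <- if (is.null(groups) || config$qca_group == "all")
      panel$counties
    else groups$county[groups$group == config$qca_group]
    qca <- lapply(panel$years, function(yr) {
      dat <- scored$scores[scored$scores$year == yr &
                             scored$scores$county %in% qca_counties, ]
      dat <- dplyr::left_join(dat, ccd[ccd$year == yr, c("county", "D")],
                              by = "county")
      dat$case <- dat$county
      fcm <- fuzzy_case_matrix(dat, conditions = config$conditions,
                               outcome = config$outcome)
      high <- fsqca(fcm, freq_threshold = config$freq_threshold,
                    cons_threshold = config$cons_threshold,
                    pri_threshold = config$pri_threshold,
                    expectations = config$expectations,
                    scan_thresholds = config$scan_thresholds)
      low <- fsqca(fcm, negate_outcome = TRUE,
                   freq_threshold = config$freq_threshold,
                   cons_threshold = config$cons_threshold,
                   pri_threshold = config$pri_threshold,
                   expectations = NULL,
                   scan_thresholds = config$scan_thresholds)
      emit(high$necessity, sprintf("necessity_high_%d.csv", yr))
      emit(low$necessity, sprintf("necessity_low_%d.csv", yr))
      emit(as.data.frame(high$truth_table),
           sprintf("truth_table_high_%d.csv", yr))
      emit(tibble::as_tibble(high$robustness),
           sprintf("robustness_high_%d.csv", yr))
      sol_path <- file.path(out_dir, sprintf("solutions_%d.json", yr))
      jsonlite::write_json(
        list(high = solution_report(high$solutions),
             low = solution_report(low$solutions)),
        sol_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <<- c(written, sol_path)
      list(year = yr, high = high, low = low)
    })

    stage <- "manifest"
    inputs <- c(config$panel_path, config$region_path)
    manifest <- list(
      package = "eshcoord",
      version = as.character(utils::packageVersion("eshcoord")),
      seed = config$seed,
      config = config[setdiff(names(config), "spec")],
      spec = unclass(config$spec),
      input_checksums = if (length(inputs) > 0)
        as.list(tools::md5sum(inputs)) else list()
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    invisible(list(scores = scored, ccd = ccd, regional = regional,
                   trend = trend, qca = qca, manifest = manifest,
                   out_dir = out_dir))
  }, error = function(e) {
    unlink(written)
    stop_esh("pipeline failed at stage '", stage, "': ",
             conditionMessage(e))
  })
}

# JSON-friendly rendering of a qca_solutions object
solution_report <- function(sols) {
  one <- function(sol) list(
    type = sol$type,
    recipes = if (length(sol$recipes) == 0) list() else
      lapply(seq_along(sol$recipes), function(i) list(
        recipe = sol$labels[i],
        marks = as.list(sol$marks[[i]][!is.na(sol$marks[[i]])]),
        consistency = sol$stats$consistency[i],
        raw_coverage = sol$stats$raw_coverage[i],
        unique_coverage = sol$stats$unique_coverage[i])),
    solution_consistency = sol$solution_consistency,
    solution_coverage = sol$solution_coverage
  )
  list(complex = one(sols$complex),
       parsimonious = one(sols$parsimonious),
       intermediate = one(sols$intermediate))
}

#' Headline statistics recomputed from the packaged CCD fixture
#'
#' Recomputes, from the packaged county-by-year CCD matrix, the published
#' headline quantities: the provincial mean CCD in 2020 and 2022, the
#' share of 2022 counties between reluctant and primary coordination
#' (`0.5 <= D < 0.7`), the fold increase of counties at intermediate
#' coordination or above (`D >= 0.7`) from 2020 to 2022, the percent
#' decrease of counties at mild disorder or below (`D < 0.4`), and the
#' coefficient of variation implied by the published 2022 mountain/island
#' summary row (std/mean of the printed dispersion fixture). Each
#' quantity is compared against its published value.
#'
#' @return A tibble `quantity, value, published, pass`, where `value` is
#'   rounded to the published precision (half away from zero) before
#'   comparison.
#' @export
fixture_headline_stats <- function() {
  ccd <- load_ccd_fixture()
  d20 <- ccd$D[ccd$year == 2020]
  d22 <- ccd$D[ccd$year == 2022]
  tr <- trend_summary(ccd, year_a = 2020, year_b = 2022)
  t3 <- load_regional_summary_fixture()
  mi22 <- t3[t3$year == 2022 & t3$group == "mountain_island", ]

  tib <- tibble::tibble(
    quantity = c("mean_ccd_2022", "mean_ccd_2020",
                 "share_2022_reluctant_to_primary_pct",
                 "fold_increase_intermediate_or_above",
                 "pct_decrease_mild_disorder_or_below",
                 "cv_mountain_island_2022"),
    value = c(
      round_half_up(mean(d22), 3),
      round_half_up(mean(d20), 3),
      round_half_up(100 * mean(d22 >= 0.5 & d22 < 0.7), 0),
      round_half_up(tr$fold_increase_high, 1),
      round_half_up(tr$pct_decrease_low, 0),
      round_half_up(mi22$printed_cv_col / mi22$mean, 3)
    ),
    published = c(0.536, 0.468, 48, 2.3, 27, 0.270)
  )
  tib$pass <- tib$value == tib$published
  tib
}
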