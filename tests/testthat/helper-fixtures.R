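# in-code fixtures shared across test files

# minimal complete long panel: every county/year/indicator cell filled
# with deterministic values (positive, distinct per county)
tiny_panel_df <- function(counties = c("A", "B"), years = 2020L,
                          scheme = esh_scheme()) {
  grid <- expand.grid(county = counties, year = years,
                      indicator = scheme$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- 10 * match(grid$county, counties) +
    match(grid$indicator, scheme$id) + 0.5 * (grid$year - min(years))
  grid
}

tiny_panel <- function(...) as_indicator_panel(tiny_panel_df(...))

write_tmp_csv <- function(df, name = "data.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# random panel under a fixed seed, for property-style loops
random_panel <- function(n_counties = 6, years = 2020:2021, seed = 1) {
  set.seed(seed)
  scheme <- esh_scheme()
  grid <- expand.grid(county = sprintf("c%02d", seq_len(n_counties)),
                      year = years, indicator = scheme$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- stats::rlnorm(nrow(grid), meanlog = 2, sdlog = 0.7)
  as_indicator_panel(grid)
}

# small calibrated case matrix built directly from memberships
mb_case_matrix <- function(mb, outcome = "Y") {
  df <- as.data.frame(mb)
  df$case <- sprintf("k%02d", seq_len(nrow(df)))
  fuzzy_case_matrix(df, conditions = setdiff(colnames(mb), outcome),
                    outcome = outcome, calibrated = TRUE)
}

# random calibrated case matrix over k conditions
random_case_matrix <- function(n = 20, k = 3, seed = 1) {
  set.seed(seed)
  conds <- paste0("C", seq_len(k))
  mb <- matrix(runif(n * (k + 1), 0.02, 0.98), nrow = n,
               dimnames = list(NULL, c(conds, "Y")))
  mb_case_matrix(mb)
}

# exhaustive Boolean evaluation of a recipe list on all corners of k conds
eval_recipes_on_corners <- function(recipes, corners) {
  if (length(recipes) == 0) return(rep(FALSE, nrow(corners)))
  hit <- rep(FALSE, nrow(corners))
  for (r in recipes) {
    keep <- !is.na(r)
    ok <- if (!any(keep)) rep(TRUE, nrow(corners)) else
      rowSums(corners[, keep, drop = FALSE] ==
                matrix(r[keep], nrow(corners), sum(keep), byrow = TRUE)) ==
        sum(keep)
    hit <- hit | ok
  }
  hit
}

all_corners <- function(conditions) {
  k <- length(conditions)
  m <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  colnames(m) <- conditions
  m
}

# label a 1/0/NA implicant over named conditions, e.g. "A*~B"
recipe_label_for_test <- function(impl, conds) {
  keep <- which(!is.na(impl))
  if (length(keep) == 0) return("(always)")
  paste(ifelse(impl[keep] == 1, conds[keep], paste0("~", conds[keep])),
        collapse = "*")
}

# hand-built solution object with statistics filled
make_solution_for_test <- function(recipes, fcm) {
  sol <- structure(
    list(type = "manual", recipes = recipes, marks = NULL,
         conditions = fcm$conditions,
         labels = vapply(recipes, recipe_label_for_test, "",
                         conds = fcm$conditions)),
    class = "qca_solution")
  solution_statistics(sol, fcm)
}
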