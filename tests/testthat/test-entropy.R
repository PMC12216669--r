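make_panel_one_indicator <- function(values, direction = "positive") {
  # full 20-indicator panel where x1 carries the values of interest and
  # the rest are distinct filler
  df <- tiny_panel_df(counties = sprintf("c%d", seq_along(values)))
  df$value[df$indicator == "x1"] <- values
  scheme <- esh_scheme()
  scheme$direction[scheme$id == "x1"] <- direction
  as_indicator_panel(df, scheme = scheme)
}

test_that("min-max normalization follows the direction-specific formulas", {
  p <- make_panel_one_indicator(c(2, 4, 10))
  n <- normalize_panel(p)
  x1 <- n$data$value[n$data$indicator == "x1"]
  expect_equal(sort(x1), c(0, 0.25, 1))  # (4-2)/(10-2) = 0.25

  p_neg <- make_panel_one_indicator(c(2, 4, 10), direction = "negative")
  n_neg <- normalize_panel(p_neg)
  x1n <- n_neg$data$value[n_neg$data$indicator == "x1"]
  expect_equal(sort(x1n), c(0, 0.75, 1))  # reversed formula

  # per scope every non-degenerate column attains 0 and 1
  rp <- random_panel(seed = 11)
  nn <- normalize_panel(rp)
  rng <- nn$data |>
    dplyr::group_by(year, indicator) |>
    dplyr::summarise(lo = min(value), hi = max(value), .groups = "drop")
  expect_true(all(rng$lo == 0))
  expect_true(all(rng$hi == 1))
  expect_true(all(nn$data$value >= 0 & nn$data$value <= 1))
})

test_that("degenerate constant columns are flagged, zeroed and weightless", {
  df <- tiny_panel_df(counties = c("A", "B", "C"))
  df$value[df$indicator == "x3"] <- 7  # constant column
  p <- as_indicator_panel(df)
  expect_warning(n <- normalize_panel(p), "constant indicator.*x3")
  expect_true(all(n$data$value[n$data$indicator == "x3"] == 0))
  w <- entropy_weights(n)
  expect_equal(w$entropy[w$indicator == "x3"], 1)
  expect_equal(w$weight[w$indicator == "x3"], 0)
})

test_that("characteristic proportions divide by column sums", {
  p <- make_panel_one_indicator(c(0, 0.5, 1.5))
  n <- normalize_panel(p)
  pr <- indicator_proportions(n, 2020)
  # normalized x1 = {0, 1/3, 1}; proportions = value / colsum
  expect_equal(unname(sort(pr[, "x1"])), c(0, 0.25, 0.75))
  expect_equal(unname(colSums(pr)), rep(1, 20), tolerance = 1e-12)
})

test_that("entropy matches its closed forms and a direct summation oracle", {
  # uniform proportions attain the maximum
  p_unif <- matrix(1 / 4, nrow = 4, ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(entropy_values(p_unif)), c(1, 1))
  # two-point mass on four alternatives: ln2 / ln4 = 0.5
  p_half <- matrix(c(0.5, 0.5, 0, 0), ncol = 1,
                   dimnames = list(NULL, "a"))
  expect_equal(unname(entropy_values(p_half)), 0.5)
  # single point mass has zero entropy
  p_point <- matrix(c(1, 0, 0), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(unname(entropy_values(p_point)), 0)
  expect_error(entropy_values(matrix(1, nrow = 1)), "at least 2")

  # random columns agree with an independent high-precision summation
  set.seed(42)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    x <- runif(m)
    p <- matrix(x / sum(x), ncol = 1, dimnames = list(NULL, "a"))
    acc <- 0
    for (j in seq_len(m)) if (p[j] > 0) acc <- acc + p[j] * log(p[j])
    expect_equal(unname(entropy_values(p)), -acc / log(m),
                 tolerance = 1e-12)
  }
})

test_that("entropy weights normalize within scope blocks", {
  rp <- random_panel(n_counties = 8, seed = 5)
  n <- normalize_panel(rp)
  scheme <- esh_scheme()

  w_sys <- entropy_weights(n, scope = "per_system")
  w_sys$system <- scheme$system[match(w_sys$indicator, scheme$id)]
  sums <- tapply(w_sys$weight, list(w_sys$year, w_sys$system), sum)
  expect_equal(unname(as.vector(sums)), rep(1, length(sums)),
               tolerance = 1e-12)

  w_glob <- entropy_weights(n, scope = "global")
  gsums <- tapply(w_glob$weight, w_glob$year, sum)
  expect_equal(unname(as.vector(gsums)), rep(1, length(gsums)),
               tolerance = 1e-12)
  expect_true(all(w_sys$weight >= 0))
  expect_true(all(w_glob$weight >= 0))

  # hand-checked weight arithmetic: (1 - E) renormalized
  e <- c(0.2, 0.6)
  expect_equal((1 - e) / sum(1 - e), c(2 / 3, 1 / 3))
})

test_that("system scores are blockwise weighted sums with Z condition means", {
  rp <- random_panel(n_counties = 5, years = 2020L, seed = 9)
  n <- normalize_panel(rp)
  w <- entropy_weights(n)
  s <- system_scores(n, w)
  expect_true(all(s$U_EC >= 0 & s$U_EC <= 1))
  expect_true(all(s$U_SO >= 0 & s$U_SO <= 1))
  expect_true(all(s$U_HE >= 0 & s$U_HE <= 1))

  # manual recomputation for one county
  cty <- s$county[1]
  sub <- n$data[n$data$county == cty, ]
  wv <- w$weight[match(sub$indicator, w$indicator)]
  sch <- esh_scheme()
  eco <- sch$id[sch$system == "economy"]
  manual <- sum((sub$value * wv)[sub$indicator %in% eco])
  expect_equal(s$U_EC[s$county == cty], manual, tolerance = 1e-12)

  # single-member subsystem: Z6 equals normalized x12 exactly
  x12 <- vapply(s$county, function(ct)
    n$data$value[n$data$county == ct & n$data$indicator == "x12"], 0)
  expect_equal(unname(s$Z6), unname(x12))

  # all normalized values 1 would give U = 1: weights sum to 1 per system
  wsum <- tapply(w$weight, sch$system[match(w$indicator, sch$id)], sum)
  expect_equal(unname(as.vector(wsum)), c(1, 1, 1), tolerance = 1e-12)

  expect_error(system_scores(n, w[w$year == 2099, ]), "years")
})

test_that("scoring is monotone and scale invariant", {
  base_df <- tiny_panel_df(counties = c("A", "B", "C"))
  p0 <- as_indicator_panel(base_df)
  n0 <- normalize_panel(p0)
  w0 <- entropy_weights(n0)
  s0 <- system_scores(n0, w0)

  # raising one raw value of a positive indicator never lowers that
  # county's normalized value or its U score at fixed weights
  up <- base_df
  i <- which(up$county == "B" & up$indicator == "x5")
  up$value[i] <- up$value[i] * 3
  n1 <- normalize_panel(as_indicator_panel(up))
  v0 <- n0$data$value[n0$data$county == "B" & n0$data$indicator == "x5"]
  v1 <- n1$data$value[n1$data$county == "B" & n1$data$indicator == "x5"]
  expect_gte(v1, v0)
  s1 <- system_scores(n1, w0)
  expect_gte(s1$U_EC[s1$county == "B"], s0$U_EC[s0$county == "B"])

  # multiplying a raw column by a positive constant leaves the
  # normalized column unchanged
  sc <- base_df
  j <- sc$indicator == "x7"
  sc$value[j] <- sc$value[j] * 1000
  n2 <- normalize_panel(as_indicator_panel(sc))
  expect_equal(n2$data$value[n2$data$indicator == "x7"],
               n0$data$value[n0$data$indicator == "x7"],
               tolerance = 1e-12)
})

test_that("pooled normalization uses a common scale across years", {
  df <- tiny_panel_df(counties = c("A", "B"), years = 2020:2021)
  p <- as_indicator_panel(df)
  n <- normalize_panel(p, pooling = "pooled")
  # pooled: per indicator the global max over both years maps to 1,
  # so the earlier year cannot also reach 1 (values grow with year)
  by_ind <- n$data |>
    dplyr::group_by(indicator) |>
    dplyr::summarise(hi = max(value), lo = min(value), .groups = "drop")
  expect_true(all(by_ind$hi == 1) && all(by_ind$lo == 0))
  y2020 <- n$data$value[n$data$year == 2020]
  expect_true(max(y2020) < 1)
})
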