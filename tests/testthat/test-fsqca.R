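test_that("quartile anchors follow the interpolated-rank convention", {
  a <- quartile_anchors(c(1, 2, 3, 4, 5))
  expect_equal(a$full, 4)
  expect_equal(a$crossover, 3)
  expect_equal(a$non, 2)
  expect_error(quartile_anchors(rep(7, 10), name = "Z6"), "Z6")

  # anchors are equivariant under increasing affine transforms
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(15)
    aa <- quartile_anchors(v)
    bb <- quartile_anchors(2.5 * v + 3)
    expect_equal(bb$full, 2.5 * aa$full + 3, tolerance = 1e-12)
    expect_equal(bb$crossover, 2.5 * aa$crossover + 3, tolerance = 1e-12)
    expect_equal(bb$non, 2.5 * aa$non + 3, tolerance = 1e-12)
  }
})

test_that("direct calibration maps anchors and stays strictly monotone", {
  a <- quartile_anchors(c(10, 20, 30, 40, 50))  # (40, 30, 20)
  m <- as.numeric(calibrate(c(40, 20, 35), a))
  expect_equal(m[1], stats::plogis(3), tolerance = 1e-12)   # ~0.9526
  expect_equal(m[2], stats::plogis(-3), tolerance = 1e-12)  # ~0.0474
  expect_equal(m[3], stats::plogis(1.5), tolerance = 1e-12) # ~0.8176

  # log19 scaling puts the anchors at exactly 0.95 / 0.05
  m19 <- as.numeric(calibrate(c(40, 20), a, scaling = "log19"))
  expect_equal(m19, c(0.95, 0.05), tolerance = 1e-12)

  # crossover ties are nudged above 0.5 and logged
  tie <- calibrate(30, a)
  expect_equal(as.numeric(tie), 0.501)
  expect_equal(attr(tie, "tie_adjusted"), 1L)

  # strict monotonicity in the raw value (away from the tie nudge)
  x <- sort(c(seq(5, 55, by = 2.5), 29.9, 30.1))
  mm <- as.numeric(calibrate(x, a))
  expect_true(all(diff(mm[x != 30]) > 0))
})

test_that("negation is an involution that composes with the tie rule", {
  m <- c(0.047, 0.5 + 1e-3, 0.953)
  expect_equal(fuzzy_negate(fuzzy_negate(m)), m)
  expect_equal(fuzzy_negate(0.953), 0.047)
  # a tie-adjusted membership negates to just below 0.5 ...
  expect_equal(fuzzy_negate(0.5 + 1e-3), 0.5 - 1e-3)
  # ... and truth-table construction re-applies the nudge to exact ties
  mb <- matrix(c(0.9, 0.2, 0.5, 0.5), ncol = 2,
               dimnames = list(NULL, c("A", "Y")))
  fcm <- mb_case_matrix(mb)
  expect_true(all(fcm$mb[, "Y"] != 0.5))
})

test_that("necessity statistics and decision rule behave as published", {
  # perfect identity: consistency = coverage = 1
  mb <- cbind(A = c(0.3, 0.7), Y = c(0.3, 0.7))
  fcm <- mb_case_matrix(mb)
  nec <- necessity_analysis(fcm)
  expect_equal(nec$consistency[nec$condition == "A"], 1)
  expect_equal(nec$coverage[nec$condition == "A"], 1)

  # worked two-case example: sum(min) = 0.8, both totals 1.0
  mb2 <- cbind(A = c(0.2, 0.8), Y = c(0.4, 0.6))
  nec2 <- necessity_analysis(mb_case_matrix(mb2))
  expect_equal(nec2$consistency[nec2$condition == "A"], 0.8)
  expect_equal(nec2$coverage[nec2$condition == "A"], 0.8)
  # negations are evaluated too
  expect_true("~A" %in% nec2$condition)

  # decision thresholds: consistency >= 0.9 AND coverage >= 0.5
  expect_true(necessity_flag(0.989, 0.910))
  expect_false(necessity_flag(0.939, 0.321))  # coverage too low
  expect_false(necessity_flag(0.85, 0.95))    # consistency too low

  # duality: necessity consistency of X for Y equals sufficiency
  # consistency of Y for X (sum(min)/sum(x) with roles swapped)
  set.seed(13)
  for (i in 1:10) {
    x <- runif(12); y <- runif(12)
    expect_equal(sum(pmin(x, y)) / sum(y),   # necessity consistency
                 sum(pmin(y, x)) / sum(y),   # sufficiency of y in x
                 tolerance = 1e-12)
  }
})

test_that("truth table assigns each case to one corner and scores rows", {
  mb <- rbind(c(0.9, 0.8, 0.9),
              c(0.9, 0.2, 0.8),
              c(0.1, 0.9, 0.3),
              c(0.2, 0.1, 0.1))
  colnames(mb) <- c("A", "B", "Y")
  fcm <- mb_case_matrix(mb)
  tt <- build_truth_table(fcm, pri_threshold = 0.75)
  expect_equal(sum(tt$n_cases), 4)          # every case lands somewhere
  expect_true(all(tt$n_cases == 1))         # one case per corner here
  ab <- tt[tt$A == 1 & tt$B == 1, ]
  # row A*B: sum rowmem = 1.2, sum min(rowmem, y) = 1.2
  expect_equal(ab$consistency, 1)
  expect_equal(ab$pri, 1)

  # outcome equal to row membership gives consistency 1 and PRI 1
  # (perfect subset) on the case's own row
  mbp <- cbind(A = c(0.9, 0.8, 0.7), B = c(0.9, 0.85, 0.75))
  y <- pmin(mbp[, "A"], mbp[, "B"])
  fcm2 <- mb_case_matrix(cbind(mbp, Y = y))
  tt2 <- build_truth_table(fcm2, pri_threshold = 0.75)
  r11 <- tt2[tt2$A == 1 & tt2$B == 1, ]
  expect_equal(r11$consistency, 1)
  expect_equal(r11$pri, 1)
  expect_equal(r11$outcome_code, "1")

  # raising the frequency threshold turns sparse rows into remainders
  tt_f2 <- build_truth_table(fcm, freq_threshold = 2, pri_threshold = 0.75)
  expect_true(all(tt_f2$outcome_code == "remainder"))

  # PRI <= raw consistency on random case matrices
  for (seed in 1:15) {
    fcmr <- random_case_matrix(n = 18, k = 3, seed = seed)
    ttr <- build_truth_table(fcmr, pri_threshold = 0.7)
    obs <- ttr$outcome_code != "remainder"
    expect_true(all(ttr$pri[obs] <= ttr$consistency[obs] + 1e-12))
  }
})

test_that("natural-break PRI cutoff finds the windowed largest gap", {
  expect_equal(natural_break_pri(c(0.95, 0.92, 0.55, 0.50)), 0.735)
  expect_equal(natural_break_pri(rep(0.8, 4)), 0.70)   # no gap: fallback
  expect_equal(natural_break_pri(c(1, 0)), 0.5)        # boundary midpoint
  # gaps outside the [0.5, consistency] window are ignored
  expect_equal(natural_break_pri(c(0.1, 0.4, 0.95), cons_threshold = 0.8),
               0.675)
  expect_error(natural_break_pri(numeric(0)), "no observed")
})

test_that("Quine-McCluskey reduces to prime implicants and minimal covers", {
  conds <- c("A", "B")
  # adjacent merge: A*B + A*~B -> A
  qm <- quine_mccluskey(rbind(c(1, 1), c(1, 0)), conditions = conds)
  expect_equal(length(qm$solution), 1)
  expect_equal(recipe_label_for_test(qm$solution[[1]], conds), "A")

  # three-corner onset over three conditions minimizes to A*B + A*C
  conds3 <- c("A", "B", "C")
  onset <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1))
  qm3 <- quine_mccluskey(onset, conditions = conds3)
  labels <- sort(vapply(qm3$solution, recipe_label_for_test, "",
                        conds = conds3))
  expect_equal(labels, c("A*B", "A*C"))
  # exhaustive oracle: solution TRUE exactly on the onset corners
  corners <- all_corners(conds3)
  truth <- eval_recipes_on_corners(qm3$solution, corners)
  onset_keys <- apply(onset, 1, paste, collapse = "")
  corner_keys <- apply(corners, 1, paste, collapse = "")
  expect_equal(truth, corner_keys %in% onset_keys)

  # complete onset collapses to the tautology
  qm_all <- quine_mccluskey(all_corners(conds), conditions = conds)
  expect_equal(length(qm_all$solution), 1)
  expect_true(all(is.na(qm_all$solution[[1]])))

  # empty onset means no sufficient configuration
  qm_none <- quine_mccluskey(matrix(0L, 0, 2), conditions = conds)
  expect_equal(length(qm_none$solution), 0)

  # don't-cares may be absorbed: onset A*B with remainder A*~B gives A
  qm_dc <- quine_mccluskey(rbind(c(1, 1)), dontcare = rbind(c(1, 0)),
                           conditions = conds)
  expect_equal(recipe_label_for_test(qm_dc$solution[[1]], conds), "A")
  expect_error(quine_mccluskey(rbind(c(1, 1)), dontcare = rbind(c(1, 1)),
                               conditions = conds), "overlap")
})

test_that("solution triple obeys the counterfactual sandwich", {
  # onset A*B observed, remainder A*~B, expectation A present:
  # complex A*B, parsimonious A, intermediate A with A core
  mb <- rbind(c(0.9, 0.9, 0.9),   # A*B, outcome high
              c(0.1, 0.9, 0.2),   # ~A*B, outcome low
              c(0.1, 0.1, 0.1))   # ~A*~B, outcome low
  colnames(mb) <- c("A", "B", "Y")
  fcm <- mb_case_matrix(mb)
  tt <- build_truth_table(fcm, pri_threshold = 0.75)
  expect_equal(tt$outcome_code[tt$A == 1 & tt$B == 0], "remainder")

  sols <- derive_solutions(tt, expectations = c(A = "present"))
  expect_equal(sols$complex$labels, "A*B")
  expect_equal(sols$parsimonious$labels, "A")
  expect_equal(sols$intermediate$labels, "A")
  expect_equal(unname(sols$intermediate$marks[[1]][["A"]]), "core_present")

  # with no stated expectations the intermediate equals the complex
  sols_none <- derive_solutions(tt)
  expect_equal(sort(sols_none$intermediate$labels),
               sort(sols_none$complex$labels))
  # with no remainders all three solutions coincide
  mb_full <- rbind(c(0.9, 0.9, 0.9), c(0.9, 0.1, 0.8),
                   c(0.1, 0.9, 0.2), c(0.1, 0.1, 0.1))
  colnames(mb_full) <- c("A", "B", "Y")
  tt_full <- build_truth_table(mb_case_matrix(mb_full), pri_threshold = 0.75)
  s_full <- derive_solutions(tt_full, expectations = c(A = "present"))
  expect_equal(sort(s_full$complex$labels), sort(s_full$parsimonious$labels))
  expect_equal(sort(s_full$complex$labels), sort(s_full$intermediate$labels))

  expect_error(derive_solutions(tt, expectations = c(Q = "present")),
               "unknown condition")
})

test_that("solution semantics verified exhaustively on random truth tables", {
  # complex solutions must be TRUE exactly on coded-1 corners;
  # parsimonious solutions must cover every 1 and no 0 (remainders free);
  # every intermediate recipe sits between a parsimonious recipe (superset
  # of cases) and the onset it explains
  set.seed(99)
  n_checked <- 0
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    conds <- paste0("C", seq_len(k))
    corners <- all_corners(conds)
    code <- sample(c("1", "0", "remainder"), 2^k, replace = TRUE,
                   prob = c(0.35, 0.35, 0.3))
    onset <- corners[code == "1", , drop = FALSE]
    remainders <- corners[code == "remainder", , drop = FALSE]
    if (nrow(onset) == 0) next
    qm_c <- quine_mccluskey(onset, NULL, conds)
    qm_p <- quine_mccluskey(onset, remainders, conds)
    truth_c <- eval_recipes_on_corners(qm_c$solution, corners)
    truth_p <- eval_recipes_on_corners(qm_p$solution, corners)
    expect_equal(truth_c, code == "1")
    expect_true(all(truth_p[code == "1"]))
    expect_false(any(truth_p[code == "0"]))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("solution statistics do standard coverage bookkeeping", {
  mb <- cbind(A = c(0.2, 0.8), B = c(0.3, 0.6), Y = c(0.4, 0.6))
  fcm <- mb_case_matrix(mb)

  # single-recipe solution: unique coverage equals raw coverage
  sol1 <- make_solution_for_test(list(c(1L, NA)), fcm)
  expect_equal(sol1$stats$unique_coverage, sol1$stats$raw_coverage)
  # recipe membership {0.2, 0.8} against y {0.4, 0.6}: 0.8/1.0
  expect_equal(sol1$stats$consistency, 0.8)
  expect_equal(sol1$stats$raw_coverage, 0.8)

  # duplicate recipes contribute nothing uniquely
  sol2 <- make_solution_for_test(list(c(1L, NA), c(1L, NA)), fcm)
  expect_equal(sol2$stats$unique_coverage, c(0, 0))
  expect_equal(sol2$solution_coverage, 0.8)

  # unique <= raw, and solution coverage >= any raw coverage, on random runs
  for (seed in 1:10) {
    fcmr <- random_case_matrix(n = 16, k = 3, seed = seed + 100)
    ttr <- build_truth_table(fcmr, cons_threshold = 0.6, pri_threshold = 0.5)
    if (!any(ttr$outcome_code == "1")) next
    sols <- derive_solutions(ttr)
    for (s in list(sols$complex, sols$parsimonious, sols$intermediate)) {
      if (nrow(s$stats) == 0) next
      expect_true(all(s$stats$unique_coverage <=
                        s$stats$raw_coverage + 1e-12))
      expect_true(all(s$stats$raw_coverage <=
                        s$solution_coverage + 1e-12))
      expect_lte(sum(s$stats$unique_coverage),
                 s$solution_coverage + 1e-12)
    }
    # every intermediate recipe is subsumed by some parsimonious recipe
    for (r in sols$intermediate$recipes) {
      subsumed <- any(vapply(sols$parsimonious$recipes, function(p)
        all(is.na(p) | (!is.na(r) & p == r)), logical(1)))
      expect_true(subsumed)
    }
  }
})

test_that("robustness scan flags stability against the baseline", {
  fcm <- generate_qca_cases(qca_plant(recipes = list(c("Z6", "Z7")),
                                      n_cases = 25, noise = 0, seed = 3))
  rob <- robustness_scan(fcm)
  expect_equal(rob$threshold, c(0.75, 0.80, 0.85))
  expect_true(all(rob$same_as_baseline))

  # baseline-only scan contains exactly the baseline, flagged same
  rob1 <- robustness_scan(fcm, thresholds = 0.80)
  expect_equal(nrow(rob1), 1)
  expect_true(rob1$same_as_baseline)

  # an extreme threshold may empty the onset; flagged as changed
  noisy <- random_case_matrix(n = 24, k = 5, seed = 7)
  rob_x <- robustness_scan(noisy, thresholds = c(0.80, 1.0))
  row_x <- rob_x[rob_x$threshold == 1, ]
  if (row_x$n_recipes == 0) {
    expect_equal(row_x$solution, "no sufficient configuration")
    expect_false(row_x$same_as_baseline)
  }
  expect_error(robustness_scan(fcm, thresholds = c(0.4)), "\\(0.5, 1\\]")
})
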