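test_that("indicator selection reproduces the published choice and a brute-force rank", {
  screening <- reference_group_tests()
  structure <- reference_structure_matrix()
  sel <- select_indicators(screening, structure, n = 4)
  expect_setequal(sel, c("P8", "P12", "P14", "P17"))

  # brute-force oracle for the composite rank
  f_rank <- rank(-screening$F)
  s_rank <- rank(-apply(abs(structure[screening$variable, ]), 1, max))
  composite <- f_rank + s_rank
  oracle <- screening$variable[order(composite, f_rank)][1:4]
  expect_identical(sel, oracle)

  # n = 1 with a dominant variable
  expect_identical(select_indicators(screening, structure, n = 1), "P17")
  expect_error(select_indicators(screening, structure, n = 99), "exceeds")
})

test_that("extremum ranges equal direct min/max and quantile ranges the quantiles", {
  set.seed(41)
  tbl <- peak_table(data.frame(
    sample_id = sprintf("s%02d", 1:30),
    origin = rep(c("Korean", "Chinese", "Vietnamese"), each = 10),
    P8 = c(runif(10, 1, 3), runif(10, 2.5, 6), runif(10, 4, 7))))
  rules <- derive_ranges(tbl, "P8", origins = c("Korean", "Vietnamese"))
  k <- rules$origins$Korean[[1]]
  v <- rules$origins$Vietnamese[[1]]
  # Korean sits low: one-sided upper bound at its own maximum
  expect_true(is.na(k$lower))
  expect_equal(k$upper, max(tbl$P8[tbl$origin == "Korean"]))
  # Vietnamese sits high: one-sided lower bound at its own minimum
  expect_true(is.na(v$upper))
  expect_equal(v$lower, min(tbl$P8[tbl$origin == "Vietnamese"]))
  # intermediate origin gets a two-sided range
  rc <- derive_ranges(tbl, "P8", origins = "Chinese")$origins$Chinese[[1]]
  expect_equal(c(rc$lower, rc$upper),
               range(tbl$P8[tbl$origin == "Chinese"]))

  rq <- derive_ranges(tbl, "P8", origins = "Chinese",
                      strategy = "quantile", q = 0.1)$origins$Chinese[[1]]
  expect_equal(rq$lower,
               unname(quantile(tbl$P8[tbl$origin == "Chinese"], 0.1)))
  expect_equal(rq$upper,
               unname(quantile(tbl$P8[tbl$origin == "Chinese"], 0.9)))

  expect_error(derive_ranges(tbl, "P9", origins = "Korean"), "lacks")
  expect_error(derive_ranges(tbl, "P8", origins = "Japanese"), "absent")

  one <- tbl[c(1, 11:30), ]
  expect_warning(derive_ranges(one, "P8", origins = "Korean"), "degenerate")
})

test_that("sequential range application matches the published blind rows", {
  rules <- reference_rules()
  expect_identical(
    apply_rules(rules, c(P8 = 2.703, P12 = 0.804, P14 = 1.097, P17 = 0.624)),
    "Korean")
  expect_identical(
    apply_rules(rules, c(P8 = 7.074, P12 = 2.778, P14 = 2.220, P17 = 1.117)),
    "neither")
  expect_identical(
    apply_rules(rules, c(P8 = 6.971, P12 = 2.468, P14 = 1.955, P17 = 0.559)),
    "Vietnamese")
  expect_error(apply_rules(rules, c(P8 = 1, P12 = 1, P14 = 1)), "P17")
})

test_that("bound semantics: printed </> are strict, a-b inclusive", {
  rules <- reference_rules()
  # Korean P17 range 0.620-0.945 is inclusive at both ends
  expect_identical(apply_rules(rules, c(P8 = 2, P12 = 0.5, P14 = 1,
                                        P17 = 0.620)), "Korean")
  # Korean P8 < 4.945 is strict at the boundary
  expect_identical(apply_rules(rules, c(P8 = 4.945, P12 = 0.5, P14 = 1,
                                        P17 = 0.7)), "neither")
  # Vietnamese P17 < 0.699 strict
  expect_identical(apply_rules(rules, c(P8 = 5, P12 = 2, P14 = 1.5,
                                        P17 = 0.699)), "neither")
})

test_that("rule evaluation reproduces the blind confusion and is order invariant", {
  rules <- reference_rules()
  blind <- reference_blind_peaks()
  ev <- evaluate_rules(rules, blind)
  expect_equal(unname(ev$counts[c("Korean", "Vietnamese", "neither",
                                  "ambiguous")]),
               c(9L, 5L, 5L, 0L), ignore_attr = TRUE)
  expected <- ifelse(blind$origin == "Chinese", "neither", blind$origin)
  expect_identical(ev$predictions$predicted, expected)
  expect_true(ev$order_invariant)

  empty <- evaluate_rules(rules, blind[0, ])
  expect_equal(nrow(empty$predictions), 0)
})

test_that("overlapping rule sets surface as the ambiguous sentinel", {
  r <- indicator_rules(list(
    A = list(list(variable = "P1", lower = 0, upper = 2,
                  lower_inclusive = TRUE, upper_inclusive = TRUE)),
    B = list(list(variable = "P1", lower = 1, upper = 3,
                  lower_inclusive = TRUE, upper_inclusive = TRUE))))
  expect_identical(apply_rules(r, c(P1 = 1.5)), "ambiguous")
  expect_identical(apply_rules(r, c(P1 = 0.5)), "A")
  expect_identical(apply_rules(r, c(P1 = 9)), "neither")
})

test_that("rule-set construction validates its invariants", {
  expect_error(indicator_rules(list(
    A = list(list(variable = "P1", lower = NA, upper = NA,
                  lower_inclusive = TRUE, upper_inclusive = TRUE)))),
    "no bounds")
  expect_error(indicator_rules(list(
    A = list(list(variable = "P1", lower = 2, upper = 1,
                  lower_inclusive = TRUE, upper_inclusive = TRUE)))),
    "lower >= upper")
  expect_error(indicator_rules(list(
    A = list(list(variable = "P1", lower = 0, upper = 1,
                  lower_inclusive = TRUE, upper_inclusive = TRUE)),
    B = list(list(variable = "P2", lower = 0, upper = 1,
                  lower_inclusive = TRUE, upper_inclusive = TRUE)))),
    "same indicator variables")
})

test_that("training-table evaluation of derived extremum ranges never mislabels", {
  # with ranges derived for every origin, each training row matches its own
  # extremum ranges, so a single wrong-origin label is impossible (overlap
  # surfaces as "ambiguous" instead)
  for (seed in c(51, 52, 53)) {
    tbl <- simulate_peak_table(seed = seed)
    rules <- derive_ranges(tbl, c("P8", "P12", "P14", "P17"))
    ev <- evaluate_rules(rules, tbl)
    wrong <- with(ev$predictions,
                  predicted != origin & !predicted %in% c("neither",
                                                          "ambiguous"))
    expect_equal(sum(wrong), 0)
  }
})

test_that("rule sets round-trip through JSON", {
  rules <- reference_rules()
  f <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, f)
  again <- read_rules(f)
  expect_equal(again$origins, rules$origins, tolerance = 1e-15)
  expect_identical(again$application_order, rules$application_order)
  blind <- reference_blind_peaks()
  expect_identical(predict(again, blind), predict(rules, blind))
})
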