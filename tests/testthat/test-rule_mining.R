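test_that("transaction encoding emits namespaced items per report", {
  db <- simulate_srs(synthetic_config(n_reports = 500, seed = 9))
  f <- report_features(db)
  # hand-built single report: age 75, 4 CNS-active drugs, fall event
  f1 <- f[1, ]
  f1$age_band <- "70-79"; f1$n_cns <- 4L; f1$n_ccb <- 0L
  f1$fall_related <- TRUE
  tx1 <- encode_transactions(f1, items = c("age", "n_cns", "n_ccb"))
  expect_setequal(tx1$items[[1]],
                  c("age:70-79", "n_cns:4", "ev:fall_related"))
  # a report with nothing mapped is kept as an empty transaction
  f1$age_band <- "EXCLUDED"; f1$n_cns <- 0L; f1$fall_related <- FALSE
  tx0 <- encode_transactions(f1, items = c("age", "n_cns", "n_ccb"))
  expect_identical(tx0$items[[1]], character(0))
  expect_identical(tx0$D, 1L)
  # consequent count equals the fall-related report count
  tx <- encode_transactions(f)
  expect_identical(
    sum(vapply(tx$items, function(t) "ev:fall_related" %in% t, TRUE)),
    sum(f$fall_related))
  expect_identical(tx$D, nrow(f))
  expect_error(encode_transactions(f, items = "bogus"), "namespace")
})

test_that("class and history namespaces encode exposures and terms", {
  db <- simulate_srs(synthetic_config(n_reports = 2000, seed = 13))
  f <- report_features(db)
  tx <- encode_transactions(f, items = c("class", "hist"))
  i <- which(f$cls_benzodiazepines)[1]
  expect_true("class:benzodiazepines" %in% tx$items[[i]])
  j <- which(lengths(f$histories) > 0)[1]
  expect_true(paste0("hist:", f$histories[[j]][1]) %in% tx$items[[j]])
})

test_that("apriori equals exhaustive enumeration on toy data", {
  tx <- list(c("a", "b", "d"), c("a", "c"), c("a", "b", "c"),
             c("b", "c"), c("a", "b", "c", "d"))
  got <- apriori(tx, min_support = 0.2, maxlen = 3)
  want <- enumerate_itemsets(tx, 0.2, 3)
  expect_setequal(itemset_key(got$items), itemset_key(lapply(want, `[[`,
                                                             "items")))
  wc <- setNames(vapply(want, `[[`, 1L, "count"),
                 itemset_key(lapply(want, `[[`, "items")))
  expect_identical(unname(wc[itemset_key(got$items)]), got$count)
})

test_that("support threshold and maxlen boundaries behave", {
  tx <- list(c("a", "b"), c("a", "b"), c("a", "c"))
  top <- apriori(tx, min_support = 1, maxlen = 3)
  expect_identical(itemset_key(top$items), "a")  # only universal item
  singles <- apriori(tx, min_support = 0.5, maxlen = 1)
  expect_setequal(itemset_key(singles$items), c("a", "b"))
  expect_true(all(singles$size == 1))
  expect_error(apriori(list(), 0.1, 2), "empty")
  # every transaction counted in D even when empty
  expect_equal(apriori(list(character(0), "a"), 0.1, 1)$support, 0.5)
})

test_that("support is anti-monotone on every mined level", {
  set.seed(31)
  for (rep in 1:10) {
    tx <- random_transactions(100, 10)
    got <- apriori(tx, min_support = 0.02, maxlen = 4)
    key <- itemset_key(got$items)
    cnt <- setNames(got$count, key)
    for (i in which(got$size > 1)) {
      s <- got$items[[i]]
      for (drop in seq_along(s)) {
        sub <- paste(sort(s[-drop]), collapse = "|")
        expect_true(cnt[[sub]] >= got$count[i])
      }
    }
  }
})

test_that("rule metrics reproduce printed small-count examples", {
  # antecedent totals recovered from printed case n / confidence
  sc <- score_rule(n_xy = c(4, 4, 7), n_x = c(110, 120, 308),
                   n_y = 3715, D = 430587)
  expect_equal(round(sc$confidence, 4), c(0.0364, 0.0333, 0.0227))
  expect_equal(round(sc$lift, 2), c(4.21, 3.86, 2.63))
  expect_equal(sc$chi_squared, c(9.90, 8.57, 7.16), tolerance = 0.005)
  # single-item antecedent support at printed precision
  expect_equal(round(622 / 430587, 5), 0.00144, tolerance = 1e-12)
  expect_equal(round(score_rule(622, 43357, 3715, 430587)$support, 5),
               0.00144)
})

test_that("independence gives lift 1 and chi-squared exactly 0", {
  sc <- score_rule(n_xy = 10, n_x = 100, n_y = 100, D = 1000)
  expect_equal(sc$lift, 1)
  expect_identical(sc$chi_squared, 0)
})

test_that("lift-based chi-squared equals the Pearson 2x2 statistic", {
  set.seed(77)
  for (i in 1:200) {
    D <- sample(50:5000, 1)
    n_x <- sample(seq_len(D - 1), 1)
    n_y <- sample(seq_len(D - 1), 1)
    n_xy <- sample(seq_len(min(n_x, n_y)), 1)
    if (D - n_x - n_y + n_xy < 0) next
    sc <- score_rule(n_xy, n_x, n_y, D)
    if (is.na(sc$chi_squared)) next
    expect_equal(sc$chi_squared, pearson_chi2(n_xy, n_x, n_y, D),
                 tolerance = 1e-6)
  }
})

test_that("degenerate denominators are flagged, not silently scored", {
  sc <- score_rule(n_xy = 5, n_x = 10, n_y = 10, D = 10)
  expect_true(is.na(sc$chi_squared))
  expect_match(sc$chi_flag, "covers all")
  sc0 <- score_rule(n_xy = 0, n_x = 10, n_y = 10, D = 100)
  expect_true(is.na(sc0$chi_squared))
  expect_error(score_rule(5, 0, 10, 100))
})

test_that("rule generation restricts the consequent and filters", {
  tx <- list(c("x", "y"), c("x", "y"), c("x", "z"), c("w", "y"),
             c("x", "w", "y"))
  sets <- apriori(tx, min_support = 0.1, maxlen = 3)
  rules <- generate_rules(sets, rhs_item = "y", min_confidence = 0.5)
  expect_true(all(rules$rhs == "y"))
  expect_false(any(grepl("y", rules$lhs)))
  # a perfectly confident antecedent is emitted with confidence 1
  w <- rules[rules$lhs == "w", ]
  expect_equal(w$confidence, 1)
  # thresholds above every confidence yield an empty set
  expect_identical(nrow(generate_rules(sets, rhs_item = "y",
                                       min_confidence = 0.99)),
                   sum(rules$confidence > 0.99 - 1e-12))
  expect_warning(none <- generate_rules(sets, rhs_item = "absent"),
                 "not frequent")
  expect_identical(nrow(none), 0L)
})

test_that("rules sort by lift with deterministic tie-breaks", {
  db <- simulate_srs(synthetic_config(n_reports = 5000, seed = 17,
                                      baseline_fall_prob = 0.05))
  f <- report_features(db)
  r <- mine_rules(f, min_support = 1e-6, min_confidence = 0.001,
                  maxlen = 3)
  expect_true(all(diff(r$lift) <= 1e-12))
  ties <- which(abs(diff(r$lift)) < 1e-12)
  expect_true(all(diff(r$support)[ties] <= 1e-12))
  r2 <- mine_rules(f, min_support = 1e-6, min_confidence = 0.001,
                   maxlen = 3)
  expect_identical(r, r2)
  # support <= confidence <= 1 and case counts match support * D
  expect_true(all(r$support <= r$confidence + 1e-12))
  expect_true(all(r$confidence <= 1 + 1e-12))
  expect_equal(r$support * nrow(f), r$case_n)
})

test_that("subgroup mining can keep the full-database denominator", {
  db <- simulate_srs(synthetic_config(n_reports = 4000, seed = 23,
                                      baseline_fall_prob = 0.05))
  f <- report_features(db)
  sub <- f[f$age_band %in% c("60-69", "70-79", "80-89", ">=90"), ]
  r_sub <- mine_rules(sub, items = "class", min_confidence = 0.001,
                      maxlen = 2)
  r_full <- mine_rules(sub, items = "class", min_confidence = 0.001,
                       maxlen = 2, support_denominator = "full",
                       full_D = nrow(f))
  both <- intersect(r_sub$lhs, r_full$lhs)
  i <- match(both, r_sub$lhs); j <- match(both, r_full$lhs)
  # counts and confidence are subgroup quantities either way
  expect_identical(r_sub$case_n[i], r_full$case_n[j])
  expect_equal(r_sub$confidence[i], r_full$confidence[j])
  # support scales by the denominator ratio
  expect_equal(r_full$support[j] * nrow(f),
               r_sub$support[i] * nrow(sub))
  expect_error(mine_rules(sub, support_denominator = "full"), "full_D")
})
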