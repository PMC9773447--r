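test_that("pseudo-first-order rates are the product of constant and concentration", {
  expect_equal(pseudo_first_order(1e5, 5e-6), 0.5)
  expect_equal(pseudo_first_order(0, 1e-3), 0)
  # bilinear in both arguments
  expect_equal(pseudo_first_order(3e5, 5e-6), 3 * pseudo_first_order(1e5, 5e-6))
  expect_equal(pseudo_first_order(1e5, 1.5e-5), 3 * pseudo_first_order(1e5, 5e-6))
  expect_error(pseudo_first_order(-1, 1), ">= 0")
})

test_that("rate table rows multiply constants with the partner enzyme pools", {
  enz <- test_enzymes()
  cond <- folding_condition(c(cat1 = 1e4, cat2 = 3e3, cat3 = 1e3), enz, 0.5)
  p <- test_params(v_syn = substrate_influx_rates(cond$demand, 0.5, "minute"))
  row <- rate_table_row(p, cond)
  expect_equal(row$R2, p$k2)
  expect_equal(row$R3, p$k3 * enz[["DsbB"]])
  expect_equal(row$R4_cat1, p$k45[["cat1"]] * enz[["DsbA"]])
  expect_equal(row$R678_cat3, p$k678[["cat3"]] * (enz[["DsbC"]] + enz[["DsbG"]]))
})

test_that("rate-table summaries match a brute-force order-statistic oracle", {
  set.seed(13)
  tab <- data.frame(condition_label = paste0("c", 1:9), growth_rate = NA,
                    R2 = runif(9, 0.01, 0.3), R3 = runif(9, 2, 8),
                    R4_cat1 = runif(9, 0.5, 3), R45_cat2 = runif(9, 0.3, 1),
                    R5_cat3 = runif(9, 0.9, 3), R678_cat2 = runif(9, 0.1, 0.7),
                    R678_cat3 = runif(9, 0.2, 2))
  s <- summarize_rate_table(tab)
  for (cl in c("R2", "R3", "R678_cat3")) {
    x <- sort(tab[[cl]])
    expect_equal(s[[cl]][s$statistic == "median"], x[5])
    expect_equal(s[[cl]][s$statistic == "fold_range"], x[9] / x[1])
    q <- quantile(tab[[cl]], c(0.25, 0.75), names = FALSE)
    expect_equal(s[[cl]][s$statistic == "iqr_fold"], q[2] / q[1])
  }
  # a constant column has median = value and unit folds
  tab$R2 <- 0.5
  s2 <- summarize_rate_table(tab)
  expect_equal(s2$R2, c(0.5, 1, 1))
  tab$R3[1] <- 0
  expect_error(summarize_rate_table(tab), "non-positive")
  expect_error(summarize_rate_table(tab[1, ]), "at least two")
})

test_that("growth-rate correlation behaves like Pearson's r", {
  tab <- data.frame(growth_rate = c(0.1, 0.2, 0.3, 0.4),
                    R3 = 2 + 5 * c(0.1, 0.2, 0.3, 0.4))
  expect_equal(correlate_with_growth_rate(tab, "R3"), 1.0)
  tab$R3 <- -tab$R3
  expect_equal(correlate_with_growth_rate(tab, "R3"), -1.0)
  expect_error(correlate_with_growth_rate(tab[1:2, ], "R3"), "at least three")
  tab$R3 <- 1
  expect_error(correlate_with_growth_rate(tab, "R3"), "zero variance")
  expect_error(correlate_with_growth_rate(tab, "nope"), "no column")
})

test_that("the bundled reference table has the published layout", {
  ref <- reference_rate_table()
  expect_equal(nrow(ref), 20)
  expect_true(all(c("R2", "R3", "R4_cat1", "R45_cat2", "R5_cat3",
                    "R678_cat2", "R678_cat3") %in% names(ref)))
  expect_equal(sum(!is.na(ref$growth_rate)), 4)  # chemostat rows only
  expect_true(all(ref[, 4:10] > 0))
})

test_that("feasibility checking reports the binding constraint", {
  cond <- folding_condition(c(cat1 = 1e5, cat2 = 3e4, cat3 = 1e4),
                            test_enzymes(), 1.0, total_protein = 1e7)
  ok <- check_feasibility(rate_ceilings(cond), cond)
  expect_true(ok$feasible)
  expect_equal(ok$binding, "none")
  expect_lte(ok$doubling_time, 1.05 * ok$reported_doubling)
  # strangling the oxidation constant must surface as substrate accumulation
  weak <- rate_ceilings(cond)
  weak[["k45.cat1"]] <- 1e-7
  bad <- check_feasibility(weak, cond)
  expect_false(bad$feasible)
  expect_match(bad$binding, "accumulation")
})

test_that("inference recovers generously feasible ground truth from below", {
  gt <- ground_truth_condition(synthetic_spec(seed = 31, growth_rate = 0.7))
  inf <- infer_minimal_rates(gt$condition)
  k <- attr(inf, "k")
  expect_true(all(k[names(gt$truth)] <= gt$truth + 1e-12))
  fe <- attr(inf, "feasibility")
  expect_true(fe$feasible)
  expect_true(all(fe$accumulation <= 0.005 + 1e-9))
  expect_lte(fe$doubling_time, 1.05 * fe$reported_doubling)
  # deterministic: a rerun reproduces the same constants exactly
  inf2 <- infer_minimal_rates(gt$condition)
  expect_identical(attr(inf2, "k"), k)
})

test_that("more enzyme means smaller inferred association constants", {
  demand <- c(cat1 = 1.2e5, cat2 = 4e4, cat3 = 1.5e4)
  cond1 <- folding_condition(demand, test_enzymes(1), 0.8)
  cond2 <- folding_condition(demand, test_enzymes(2), 0.8)
  k1 <- attr(infer_minimal_rates(cond1), "k")
  k2 <- attr(infer_minimal_rates(cond2), "k")
  assoc <- c("k3", "k45.cat1", "k45.cat2", "k45.cat3", "k678.cat2",
             "k678.cat3", "k9")
  expect_true(all(k2[assoc] <= k1[assoc] + 1e-12))
  # when the enzyme pool is limiting the constant roughly halves
  expect_equal(unname(k2["k45.cat1"] / k1["k45.cat1"]), 0.5, tolerance = 0.1)
})

test_that("inference is monotone in growth rate and fails without DsbA", {
  demand <- c(cat1 = 1.2e5, cat2 = 4e4, cat3 = 1.5e4)
  k_slow <- attr(infer_minimal_rates(folding_condition(demand, test_enzymes(), 0.4)), "k")
  k_fast <- attr(infer_minimal_rates(folding_condition(demand, test_enzymes(), 1.2)), "k")
  grows <- c("k2", "k3", "k45.cat1", "k45.cat2", "k45.cat3")
  expect_true(all(k_fast[grows] >= k_slow[grows] - 1e-12))
  no_dsba <- c(DsbA = 0, DsbB = 1400, DsbC = 1440, DsbD = 290, DsbG = 270)
  expect_error(infer_minimal_rates(folding_condition(demand, no_dsba, 0.8)),
               "infeasible even at ceiling")
})
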