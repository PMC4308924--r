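test_that("subtractive prior odds reproduce the published worked values", {
  # KCNH2 non-radical: prints as 25 after rounding
  expect_equal(round(prior_odds_subtractive(0.1256, 0.0048)), 25)
  # zero control burden replaced by 0.0002: KCNH2 radical
  expect_equal(prior_odds_subtractive(0.0392, 0), 195)
  # SCN5A radical
  expect_equal(prior_odds_subtractive(0.0028, 0.0002), 13)
  # missing control treated like zero
  expect_equal(prior_odds_subtractive(0.0020, NA), 9)
  # SCN5A non-radical rounds to 4
  expect_equal(round(prior_odds_subtractive(0.0584, 0.0112)), 4)
  expect_error(prior_odds_subtractive(-0.1, 0.01), "non-negative")
})

test_that("subtractive odds are monotone in case and control burdens", {
  set.seed(3)
  for (i in 1:25) {
    b <- runif(1, 0.001, 0.05)
    c1 <- runif(1, 0.001, 0.3)
    c2 <- c1 + runif(1, 0.001, 0.1)
    expect_gt(prior_odds_subtractive(c2, b), prior_odds_subtractive(c1, b))
    b2 <- b + runif(1, 0.001, 0.05)
    expect_lt(prior_odds_subtractive(c1, b2), prior_odds_subtractive(c1, b))
  }
})

test_that("LQTS policy halves literature odds then floors at 0.2", {
  expect_equal(prior_odds_lqts_adjust(0.8, "literature"), 0.4)
  expect_equal(prior_odds_lqts_adjust(0.05, "case_series"), 0.2)
  # halving takes 0.3 to 0.15, below the floor
  expect_equal(prior_odds_lqts_adjust(0.3, "literature"), 0.2)
  expect_error(prior_odds_lqts_adjust(1, "guesswork"), "unknown")
})

test_that("fixed-control policy reproduces the HCM/BrS ratios", {
  expect_equal(prior_odds_fixed_control(0.375), 37.5)  # MYBPC3
  expect_equal(prior_odds_fixed_control(0.30), 30)     # SCN5A in BrS
  expect_equal(prior_odds_fixed_control(0.01), 1)
  # linear in the case burden
  x <- runif(10)
  expect_equal(prior_odds_fixed_control(2 * x), 2 * prior_odds_fixed_control(x))
})

test_that("build_prior_table applies per-syndrome policies", {
  one <- tibble::tibble(gene = "KCNE1", syndrome = "LQTS",
                        class_group = c("non_radical", "radical"),
                        case_burden = c(0.0124, 0.002),
                        control_burden = c(0.0014, 0),
                        source = "case_series")
  out <- build_prior_table(one)
  expect_equal(round(out$prior_odds[out$class_group == "radical"]), 9)

  myh7 <- tibble::tibble(gene = "MYH7", syndrome = "HCM",
                         class_group = "non_radical", case_burden = 0.25,
                         control_burden = NA_real_, source = "literature")
  out <- build_prior_table(myh7)
  expect_equal(nrow(out), 2)  # expanded to both class groups
  expect_equal(out$prior_odds, c(25, 25))

  empty <- build_prior_table(one[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("case-series rows are preferred over literature rows", {
  both <- tibble::tibble(
    gene = "KCNH2", syndrome = "LQTS",
    class_group = rep(c("non_radical", "radical"), 2),
    case_burden = c(0.1256, 0.0392, 0.3, 0.08),
    control_burden = c(0.0048, 0, 0.0048, 0),
    source = rep(c("case_series", "literature"), each = 2))
  out <- build_prior_table(both)
  expect_equal(round(out$prior_odds[out$class_group == "radical"]), 195)
  expect_match(out$policy, "case_series", all = TRUE)
})

test_that("prior table is invariant to row order and rejects duplicates", {
  b <- cardiac_burden()
  set.seed(1)
  shuffled <- b[sample(nrow(b)), ]
  expect_equal(build_prior_table(b), build_prior_table(shuffled))
  expect_error(build_prior_table(dplyr::bind_rows(b, b[1, ])), "duplicate")
})

test_that("packaged burden table reproduces the published prior odds", {
  pri <- build_prior_table(cardiac_burden())
  odds <- function(g, s, grp) {
    pri$prior_odds[pri$gene == g & pri$syndrome == s &
                     pri$class_group == grp]
  }
  # LQTS, prospective case series + subtractive formula (rounded as printed)
  expect_equal(round(odds("KCNQ1", "LQTS", "non_radical")), 45)
  expect_equal(round(odds("KCNH2", "LQTS", "non_radical")), 25)
  expect_equal(round(odds("SCN5A", "LQTS", "non_radical")), 4)
  expect_equal(round(odds("KCNQ1", "LQTS", "radical")), 191)
  expect_equal(round(odds("KCNH2", "LQTS", "radical")), 195)
  expect_equal(round(odds("SCN5A", "LQTS", "radical")), 13)
  expect_equal(round(odds("KCNE1", "LQTS", "radical")), 9)
  expect_equal(round(odds("KCNE2", "LQTS", "radical")), 1)
  # HCM / BrS fixed-control ratios are exact
  expect_equal(odds("MYBPC3", "HCM", "non_radical"), 37.5)
  expect_equal(odds("MYH7", "HCM", "non_radical"), 25)
  expect_equal(odds("TNNT2", "HCM", "non_radical"), 6)
  expect_equal(odds("SCN5A", "BrS", "non_radical"), 30)
  expect_equal(odds("KCND3", "BrS", "non_radical"), 1)
  # every LQTS prior respects the truncation floor
  expect_true(all(pri$prior_odds[pri$syndrome == "LQTS"] >= 0.2))
  expect_true(all(nzchar(pri$policy)))
})
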