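test_that("stratified splits follow the floor rule and the seed", {
  labels <- rep(c("pathogenic", "benign"), c(164, 156))
  sp <- make_splits(labels, n_splits = 20, test_fraction = 0.1, seed = 5)
  for (idx in sp$test) {
    expect_equal(sum(labels[idx] == "pathogenic"), 16)
    expect_equal(sum(labels[idx] == "benign"), 15)
    expect_equal(anyDuplicated(idx), 0)
  }
  sp2 <- make_splits(labels, n_splits = 20, test_fraction = 0.1, seed = 5)
  expect_identical(sp$test, sp2$test)

  tiny <- make_splits(rep(c("pathogenic", "benign"), each = 10),
                      n_splits = 3, seed = 1)
  expect_true(all(vapply(tiny$test, length, 0L) == 2))

  expect_error(make_splits(c(rep("pathogenic", 3), rep("benign", 50)),
                           test_fraction = 0.1), "at least")
})

test_that("ROC sweep matches the concordant-pair oracle", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("pathogenic", "pathogenic", "benign", "benign")), 1)
  # all tied: single diagonal segment, area one half
  roc <- roc_points(rep(0.5, 6), rep(c("pathogenic", "benign"), 3))
  expect_equal(attr(roc, "auc"), 0.5)
  expect_equal(nrow(roc), 2)

  five <- list(prob = c(0.9, 0.6, 0.6, 0.3, 0.2),
               lab = c("pathogenic", "benign", "pathogenic", "benign",
                       "pathogenic"))
  expect_equal(roc_auc(five$prob, five$lab),
               auc_pair_oracle(five$prob, five$lab))

  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    prob <- round(runif(n), 2)  # rounding forces ties
    lab <- sample(c("pathogenic", "benign"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(prob, lab), auc_pair_oracle(prob, lab))
  }

  expect_error(roc_points(runif(5), rep("benign", 5)), "both labels")
})

test_that("ROC points are monotone in both coordinates", {
  set.seed(7)
  roc <- roc_points(runif(80), sample(c("pathogenic", "benign"), 80, TRUE))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
})

test_that("prior-adjusted PPV evaluates the stated formula", {
  expect_equal(ppv_adjusted(25, 0.76, 0.006), 19 / 19.006)
  expect_gte(ppv_adjusted(25, 0.76, 0.006), 0.999)
  expect_equal(ppv_adjusted(7, 0.4, 0), 1)
  for (x in c(0.1, 0.5, 0.9)) {
    expect_equal(ppv_adjusted(1, x, x), 0.5)
  }
  # monotonicity
  expect_gt(ppv_adjusted(30, 0.7, 0.01), ppv_adjusted(25, 0.7, 0.01))
  expect_gt(ppv_adjusted(25, 0.8, 0.01), ppv_adjusted(25, 0.7, 0.01))
  expect_lt(ppv_adjusted(25, 0.7, 0.02), ppv_adjusted(25, 0.7, 0.01))
  expect_error(ppv_adjusted(0, 0.5, 0.1), "positive")
  expect_error(ppv_adjusted(25, 0, 0), "positive")
})

test_that("threshold metrics equal brute-force confusion counts", {
  set.seed(17)
  prob <- runif(200)
  lab <- sample(c("pathogenic", "benign"), 200, TRUE)
  tm <- threshold_metrics(prob, lab, thresholds = c(0.25, 0.5, 0.9),
                          prior_odds = 25)
  for (i in seq_len(nrow(tm))) {
    t <- tm$threshold[i]
    tp <- sum(prob >= t & lab == "pathogenic")
    fn <- sum(prob < t & lab == "pathogenic")
    fp <- sum(prob >= t & lab == "benign")
    tn <- sum(prob < t & lab == "benign")
    expect_equal(tm$sensitivity[i], tp / (tp + fn))
    expect_equal(tm$specificity[i], tn / (tn + fp))
    expect_equal(tm$fpr[i], 1 - tm$specificity[i])
    expect_equal(tm$ppv[i], 25 * tm$sensitivity[i] /
                   (25 * tm$sensitivity[i] + tm$fpr[i]))
  }
})

test_that("cross-validation pools test predictions over all splits", {
  spec <- generator_spec()
  v <- simulate_from_model(80, spec, seed = 19)
  # ensure both labels in every training set by construction
  sp <- make_splits(v$label, n_splits = 4, test_fraction = 0.1, seed = 2)
  cv <- evaluate_cv(v, generator_priors(spec), model_config(model = "gene"),
                    sp, chains = 2, iter = 600, seed = 3,
                    thresholds = 0.9, ppv_prior_odds = 25)
  per_split <- vapply(sp$test, length, 0L)
  expect_equal(nrow(cv$predictions), sum(per_split))
  expect_s3_class(cv$roc, "pp_roc")
  expect_equal(cv$metrics$fpr, 1 - cv$metrics$specificity)

  # metrics recomputed from the pooled predictions agree
  oracle <- threshold_metrics(cv$predictions$probability,
                              cv$predictions$label, 0.9, 25)
  expect_equal(cv$metrics, oracle)

  cv2 <- evaluate_cv(v, generator_priors(spec), model_config(model = "gene"),
                     sp, chains = 2, iter = 600, seed = 3,
                     thresholds = 0.9, ppv_prior_odds = 25)
  expect_equal(cv$predictions$probability, cv2$predictions$probability)
  expect_equal(cv$auc, cv2$auc)
})
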