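#' Stratified random splits for cross-validation
#'
#' Generates independent random train/test splits in which each test set
#' contains `floor(test_fraction * n)` variants of each label, sampled
#' without replacement per split (the splits are re-draws, not a partition).
#'
#' @param labels Character vector of `"pathogenic"`/`"benign"` labels.
#' @param n_splits Number of splits (default 100).
#' @param test_fraction Fraction of each label class held out per split.
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return A `pp_splits` tibble with columns `split` and `test`
#'   (list-column of test row indices).
#' @export
make_splits <- function(labels, n_splits = 100, test_fraction = 0.1,
                        seed = 1) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), pp_labels)
  if (length(bad) > 0) pp_stop("unknown label(s): ", paste(bad, collapse = ", "))
  idx_p <- which(labels == "pathogenic")
  idx_b <- which(labels == "benign")
  n_p <- floor(test_fraction * length(idx_p))
  n_b <- floor(test_fraction * length(idx_b))
  if (length(idx_p) == 0 || length(idx_b) == 0 || n_p < 1 || n_b < 1) {
    pp_stop("each label class needs at least 1/test_fraction members")
  }
  set.seed(as.integer(seed))
  out <- tibble(
    split = seq_len(n_splits),
    test = purrr::map(seq_len(n_splits), function(i) {
      sort(c(sample(idx_p, n_p), sample(idx_b, n_b)))
    })
  )
  structure(out, class = c("pp_splits", class(out)),
            seed = seed, test_fraction = test_fraction)
}

#' Receiver operating characteristic points and area
#'
#' Standard threshold sweep over the distinct scores (tied scores grouped at
#' one threshold), anchored at (0, 0) and (1, 1); the area is computed by
#' the trapezoid rule, which gives ties the conventional half credit.
#'
#' @param probability Numeric scores (higher = more pathogenic).
#' @param label `"pathogenic"`/`"benign"` labels.
#' @return A `pp_roc` tibble of `threshold`, `fpr`, `tpr` ordered by
#'   descending threshold, with the area under the curve in `attr(, "auc")`.
#' @export
roc_points <- function(probability, label) {
  label <- as.character(label)
  y <- label == "pathogenic"
  if (!any(y) || all(y)) pp_stop("ROC needs both labels present")
  ord <- order(probability, decreasing = TRUE)
  p <- probability[ord]
  y <- y[ord]
  keep <- !duplicated(p, fromLast = TRUE)  # group ties at one threshold
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  out <- tibble(
    threshold = c(Inf, p[keep]),
    fpr = c(0, fp / sum(!y)),
    tpr = c(0, tp / sum(y))
  )
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  structure(out, class = c("pp_roc", class(out)), auc = auc)
}

#' @rdname roc_points
#' @export
roc_auc <- function(probability, label) {
  attr(roc_points(probability, label), "auc")
}

#' Prior-adjusted positive predictive value
#'
#' The PPV among variants exceeding a probability threshold, adjusted to the
#' prevalence implied by the gene-level prior odds of the intended test
#' population rather than the label balance of a cross-validation test set:
#' \deqn{\mathrm{PPV} = \frac{\mathrm{prior\ odds} \times \mathrm{TPR}}
#'   {\mathrm{prior\ odds} \times \mathrm{TPR} + \mathrm{FPR}}}
#' with the false positive rate equal to one minus specificity.
#'
#' @param prior_odds Positive prior odds of pathogenicity.
#' @param tpr True positive rate (sensitivity) in \[0, 1\].
#' @param fpr False positive rate in \[0, 1\].
#' @return PPV in \[0, 1\].
#' @export
#' @examples
#' ppv_adjusted(25, 0.76, 0.006)  # ~0.9997
ppv_adjusted <- function(prior_odds, tpr, fpr) {
  if (any(prior_odds <= 0)) pp_stop("prior_odds must be positive")
  if (any(tpr < 0 | tpr > 1) || any(fpr < 0 | fpr > 1)) {
    pp_stop("tpr and fpr must lie in [0, 1]")
  }
  denom <- prior_odds * tpr + fpr
  if (any(denom == 0)) pp_stop("prior_odds * tpr + fpr must be positive")
  prior_odds * tpr / denom
}

#' Confusion-matrix metrics at thresholds
#'
#' @param probability Scores in \[0, 1\].
#' @param label `"pathogenic"`/`"benign"` labels.
#' @param thresholds Probability thresholds; a variant counts as called
#'   pathogenic when `probability >= threshold`.
#' @param prior_odds Optional prior odds for [ppv_adjusted()].
#' @return Tibble of `threshold`, `sensitivity`, `specificity`, `fpr` and,
#'   when `prior_odds` is given, `ppv`.
#' @export
threshold_metrics <- function(probability, label, thresholds = 0.9,
                              prior_odds = NULL) {
  y <- as.character(label) == "pathogenic"
  out <- purrr::map_dfr(thresholds, function(t) {
    call_p <- probability >= t
    tibble(threshold = t,
           sensitivity = sum(call_p & y) / sum(y),
           specificity = sum(!call_p & !y) / sum(!y),
           fpr = sum(call_p & !y) / sum(!y))
  })
  if (!is.null(prior_odds)) {
    out$ppv <- ppv_adjusted(prior_odds, out$sensitivity, out$fpr)
  }
  out
}

#' Cross-validated performance of a model configuration
#'
#' For each split, fits the model to the training rows and scores the held
#' out rows; test-set predictions are pooled over all splits before any
#' thresholding, and the ROC, the area under it, and threshold metrics are
#' computed overall, per gene and per variant class. The PPV uses the
#' gene-level prior odds supplied in `ppv_prior_odds`, not the test-set
#' class balance.
#'
#' @param variants Labelled variant table.
#' @param priors Prior odds table.
#' @param config A [model_config()].
#' @param splits A [make_splits()] plan for `variants`.
#' @param chains,iter,burn_fraction,seed Sampler settings per split fit.
#' @param thresholds Probability thresholds for [threshold_metrics()].
#' @param ppv_prior_odds Prior odds used for the prior-adjusted PPV.
#' @return A `pp_cv` list: pooled `predictions`, `roc`, `auc`, `metrics`,
#'   `by_gene`, `by_class`.
#' @export
evaluate_cv <- function(variants, priors, config = model_config(),
                        splits, chains = 2, iter = 2000,
                        burn_fraction = 0.2, seed = 1, thresholds = 0.9,
                        ppv_prior_odds = NULL) {
  variants <- as_tibble(variants)
  stopifnot(inherits(splits, "pp_splits"))
  if (any(unlist(splits$test) > nrow(variants))) {
    pp_stop("split plan does not match the variant table")
  }

  preds <- purrr::map_dfr(seq_len(nrow(splits)), function(i) {
    test_idx <- splits$test[[i]]
    train <- variants[-test_idx, , drop = FALSE]
    test <- variants[test_idx, , drop = FALSE]
    fit <- tryCatch({
      m <- build_model(train, priors, config)
      fit_model(m, chains = chains, iter = iter,
                burn_fraction = burn_fraction, seed = seed + i)
    }, error = function(e) {
      pp_stop("fit failed in split ", i, ": ", conditionMessage(e))
    })
    p <- suppressWarnings(predict_pathogenicity(fit, test, apply_lod = FALSE))
    p$split <- i
    p$label <- as.character(test$label)
    p
  })

  roc <- roc_points(preds$probability, preds$label)
  metrics <- threshold_metrics(preds$probability, preds$label, thresholds,
                               ppv_prior_odds)
  by_gene <- preds %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(function(d, key) {
      threshold_metrics(d$probability, d$label, thresholds)
    }) %>%
    ungroup()
  by_class <- preds %>%
    group_by(.data$variant_class) %>%
    dplyr::group_modify(function(d, key) {
      threshold_metrics(d$probability, d$label, thresholds)
    }) %>%
    ungroup()

  structure(
    list(predictions = preds, roc = roc, auc = attr(roc, "auc"),
         metrics = metrics, by_gene = by_gene, by_class = by_class,
         config = config, seed = seed),
    class = "pp_cv")
}

#' @export
print.pp_cv <- function(x, ...) {
  cat("<pp_cv> ", length(unique(x$predictions$split)), " splits, ",
      nrow(x$predictions), " pooled test predictions\n", sep = "")
  cat("  AUC: ", format(x$auc, digits = 4), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Write a cross-validation performance report
#'
#' @param x A `pp_cv`.
#' @param path File path for the threshold-metric table; the ROC points are
#'   written next to it with suffix `_roc.tsv`.
#' @param meta Extra comment-header lines.
#' @export
write_performance <- function(x, path, meta = character()) {
  stopifnot(inherits(x, "pp_cv"))
  overall <- mutate(x$metrics, stratum = "overall", .before = 1)
  gene <- rename(x$by_gene, stratum = "gene")
  cls <- rename(x$by_class, stratum = "variant_class")
  pp_write_tsv(bind_rows(overall, gene, cls), path,
               c(meta, paste0("auc=", format(x$auc, digits = 6))))
  roc_path <- sub("\\.tsv$", "_roc.tsv", path)
  if (roc_path == path) roc_path <- paste0(path, "_roc.tsv")
  pp_write_tsv(as_tibble(x$roc), roc_path, meta)
  invisible(path)
}
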