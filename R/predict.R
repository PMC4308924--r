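#' Score variants with a fitted model
#'
#' Computes the posterior probability of pathogenicity for each variant as
#' the inverse logit of the linear predictor evaluated at the posterior
#' parameter medians (plug-in prediction). Optionally, `average_draws`
#' averages the per-draw probabilities over the posterior instead. If the
#' variant table carries a `lod` column (a familial segregation log10
#' likelihood ratio), it is multiplied onto the posterior odds.
#'
#' @param fit A `pp_fit`.
#' @param variants Variant table to score; defaults to the training table.
#' @param thresholds Band cut points passed to [band_probability()].
#' @param average_draws Average probabilities over posterior draws instead
#'   of plugging in the medians.
#' @param apply_lod Apply the `lod` column (if present) to the odds.
#' @return Tibble: `variant_id`, `gene`, `syndrome`, `variant_class`,
#'   `logit`, `probability`, `band`, `lod_applied`.
#' @export
predict_pathogenicity <- function(fit, variants = NULL,
                                  thresholds = c(0.1, 0.9),
                                  average_draws = FALSE, apply_lod = TRUE) {
  stopifnot(inherits(fit, "pp_fit"))
  model <- fit$model
  design <- if (is.null(variants)) {
    model$design
  } else {
    d <- encode_design(variants, model$priors)
    pp_apply_domain_merge(d, model$config)
  }
  X <- if (is.null(variants)) {
    model$X
  } else {
    pp_design_matrix(design, model$columns, warn_novel = TRUE,
                     no_domain_genes = model$config$no_domain_genes)
  }

  if (average_draws) {
    nm <- model$columns$name
    flat <- apply(fit$draws[, , nm, drop = FALSE], 3, as.vector)
    prob <- rowMeans(plogis(X %*% t(flat)))
    logit <- qlogis(prob)
  } else {
    med <- posterior_medians(fit)
    logit <- drop(X %*% med[model$columns$name])
    prob <- plogis(logit)
  }

  out <- tibble(
    variant_id = design$variant_id, gene = design$gene,
    syndrome = design$syndrome, variant_class = design$variant_class,
    logit = logit, probability = prob,
    band = band_probability(prob, thresholds),
    lod_applied = 0
  )
  if (apply_lod && "lod" %in% names(design)) {
    lod <- ifelse(is.na(design$lod), 0, design$lod)
    out <- combine_segregation(out, lod)
  }
  out$band <- band_probability(out$probability, thresholds)
  out
}

#' @export
predict.pp_fit <- function(object, newdata = NULL, ...) {
  predict_pathogenicity(object, variants = newdata, ...)
}

#' Combine predictions with segregation evidence
#'
#' Familial co-segregation is summarised by a LOD score, the log10 of a
#' likelihood ratio independent of the model's predictors, so the posterior
#' odds multiply: `odds' = odds * 10^lod`. The probability and logit are
#' recomputed from the updated odds.
#'
#' @param predictions Prediction tibble from [predict_pathogenicity()] (any
#'   data frame with a `probability` column works).
#' @param lod Numeric LOD score(s), recycled across rows.
#' @return The predictions with updated `logit`, `probability`, `band` and
#'   accumulated `lod_applied`.
#' @export
#' @examples
#' p <- tibble::tibble(probability = 0.5, logit = 0, lod_applied = 0)
#' combine_segregation(p, 1)$probability  # odds 10 -> 10/11
combine_segregation <- function(predictions, lod) {
  if (any(!is.finite(lod))) pp_stop("lod must be finite")
  predictions <- as_tibble(predictions)
  logit <- qlogis(predictions$probability) + lod * log(10)
  predictions$logit <- logit
  predictions$probability <- plogis(logit)
  predictions$lod_applied <-
    (if ("lod_applied" %in% names(predictions)) predictions$lod_applied else 0) + lod
  if ("band" %in% names(predictions)) {
    predictions$band <- band_probability(predictions$probability)
  }
  predictions
}

#' Band probabilities into reporting categories
#'
#' Partitions the probability scale at the given cut points. Bands are
#' half-open `[lo, hi)`: a probability exactly at a threshold falls in the
#' upper band. The default partition reports probabilities below 0.1 as
#' likely benign, above (or at) 0.9 as pathogenic, and uncertain between.
#'
#' @param probability Probabilities in \[0, 1\].
#' @param thresholds Strictly increasing cut points in (0, 1).
#' @param labels Band labels, one more than there are thresholds.
#' @return Factor of band labels.
#' @export
band_probability <- function(probability, thresholds = c(0.1, 0.9),
                             labels = NULL) {
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    pp_stop("thresholds must be strictly increasing and inside (0, 1)")
  }
  if (is.null(labels)) {
    labels <- if (length(thresholds) == 2) {
      c("likely_benign", "uncertain", "pathogenic")
    } else {
      paste0("band", seq_len(length(thresholds) + 1))
    }
  }
  if (length(labels) != length(thresholds) + 1) {
    pp_stop("need one more label than thresholds")
  }
  idx <- findInterval(probability, thresholds, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}
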