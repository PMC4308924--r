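#' Model configuration
#'
#' Describes which of the nested model variants to build and how parameters
#' are shared across syndromes when two syndromes are fitted jointly.
#'
#' Model variants:
#' \describe{
#'   \item{`full`}{class intercepts, gene terms (scale times log prior
#'     odds), domain effects, frequency indicator and all score covariates.}
#'   \item{`low_res_domain`}{as `full` with domain labels coarsened through
#'     `domain_merge` before fitting.}
#'   \item{`gene`}{`full` without domain effects.}
#'   \item{`genome_wide`}{neither gene nor domain effects.}
#'   \item{`prior_sift`}{class intercepts, gene terms and SIFT only.}
#'   \item{`prior_only`}{class intercepts and gene terms.}
#'   \item{`sift_only`}{class intercepts and SIFT.}
#' }
#'
#' Joint plans: `lqts_brs` ties all fixed parameters (domain variance, gene
#' scale parameters, the three class intercepts and every covariate
#' coefficient) across the two syndromes, estimating gene and domain effects
#' separately; `lqts_hcm` ties only the domain variance and the SIFT,
#' PolyPhen, Grantham and conservation coefficients, keeping intercepts,
#' gene scales and the frequency coefficient syndrome-specific.
#'
#' @param model Model variant, see Details.
#' @param join Cross-syndrome sharing plan: `"none"`, `"lqts_brs"` or
#'   `"lqts_hcm"`.
#' @param no_domain_genes Genes that never receive a domain term.
#' @param domain_merge Named character vector mapping training domain labels
#'   to merged labels (required for `low_res_domain`).
#' @param coeff_var Prior variance of the zero-mean normal prior on every
#'   fixed coefficient and intercept (default 10).
#' @param domain_shape,domain_rate Shape and rate of the inverse-gamma prior
#'   on the domain-effect variance.
#' @return A `pp_model_config` list.
#' @export
model_config <- function(model = c("full", "low_res_domain", "gene",
                                   "genome_wide", "prior_sift", "prior_only",
                                   "sift_only"),
                         join = c("none", "lqts_brs", "lqts_hcm"),
                         no_domain_genes = pp_no_domain_genes,
                         domain_merge = NULL,
                         coeff_var = 10,
                         domain_shape = 2,
                         domain_rate = 0.5) {
  model <- match.arg(model)
  join <- match.arg(join)
  if (model == "low_res_domain" && is.null(domain_merge)) {
    pp_stop("low_res_domain requires a domain_merge map")
  }
  stopifnot(coeff_var > 0, domain_shape > 0, domain_rate > 0)
  structure(
    list(model = model, join = join, no_domain_genes = no_domain_genes,
         domain_merge = domain_merge, coeff_var = coeff_var,
         domain_shape = domain_shape, domain_rate = domain_rate),
    class = "pp_model_config"
  )
}

# Which parameter kinds exist under each model variant.
pp_param_plan <- function(model) {
  score_full <- c("beta_sift", "beta_polyphen", "beta_polyphen_sq",
                  "beta_grantham", "beta_grantham_sq", "beta_cons_primates",
                  "beta_cons_all")
  alphas <- c("alpha_radical", "alpha_nonradical", "alpha_inframe")
  lambdas <- c("lambda_nonradical", "lambda_radical")
  switch(model,
    full = ,
    low_res_domain = list(fixed = c(alphas, lambdas, "beta_freq", score_full),
                          domains = TRUE),
    gene = list(fixed = c(alphas, lambdas, "beta_freq", score_full),
                domains = FALSE),
    genome_wide = list(fixed = c(alphas, "beta_freq", score_full),
                       domains = FALSE),
    prior_sift = list(fixed = c(alphas, lambdas, "beta_sift"),
                      domains = FALSE),
    prior_only = list(fixed = c(alphas, lambdas), domains = FALSE),
    sift_only = list(fixed = c(alphas, "beta_sift"), domains = FALSE)
  )
}

# Parameters tied across syndromes under each joint plan.
pp_shared_params <- function(join) {
  score_full <- c("beta_sift", "beta_polyphen", "beta_polyphen_sq",
                  "beta_grantham", "beta_grantham_sq", "beta_cons_primates",
                  "beta_cons_all")
  switch(join,
    none = character(),
    lqts_brs = c("alpha_radical", "alpha_nonradical", "alpha_inframe",
                 "lambda_nonradical", "lambda_radical", "beta_freq",
                 score_full),
    lqts_hcm = score_full
  )
}

pp_base_covariate <- function(design, param) {
  cls <- design$variant_class
  switch(param,
    alpha_radical = as.numeric(cls == "radical"),
    alpha_nonradical = as.numeric(cls != "radical"),
    alpha_inframe = as.numeric(cls == "inframe"),
    lambda_radical = ifelse(cls == "radical", design$log_prior_odds, 0),
    lambda_nonradical = ifelse(cls != "radical", design$log_prior_odds, 0),
    beta_freq = design$freq_indicator,
    beta_sift = design$sift_t,
    beta_polyphen = design$polyphen,
    beta_polyphen_sq = design$polyphen_sq,
    beta_grantham = design$grantham_t,
    beta_grantham_sq = design$grantham_t_sq,
    beta_cons_primates = design$cons_primates,
    beta_cons_all = design$cons_all,
    pp_stop("unknown parameter kind: ", param)
  )
}

pp_apply_domain_merge <- function(design, config) {
  if (is.null(config$domain_merge) || config$model != "low_res_domain") {
    return(design)
  }
  eligible <- design$variant_class != "radical" & !is.na(design$domain) &
    !design$gene %in% config$no_domain_genes
  unmapped <- setdiff(unique(design$domain[eligible]),
                      names(config$domain_merge))
  if (length(unmapped) > 0) {
    pp_stop("domain merge map lacks training domain(s): ",
            paste(unmapped, collapse = ", "))
  }
  design$domain[eligible] <- unname(config$domain_merge[design$domain[eligible]])
  design
}

#' Build the parameter graph and design matrix for a training set
#'
#' Lays out the free parameters of the network of class-specific logistic
#' regressions over the syndromes present in `variants`: three class
#' intercepts, gene-effect scale parameters multiplying the log prior odds
#' of the variant's gene, covariate coefficients, and one zero-mean domain
#' effect per (syndrome, gene, domain) observed in the training data for
#' domain-bearing genes. Every fixed parameter has a normal prior with mean
#' zero and variance `coeff_var`; domain effects share a variance with an
#' inverse-gamma prior. The sharing plan in `config` determines which fixed
#' parameters are tied across syndromes; tied parameters are represented by
#' a single column used by rows of every syndrome that shares them.
#'
#' @param variants Labelled (for training) or unlabelled variant table.
#' @param priors Prior odds table covering every gene in `variants`.
#' @param config A [model_config()].
#' @return A `pp_model` object: design matrix `X`, outcome `y` (if labels
#'   present), parameter metadata `columns`, hyperparameters and the inputs
#'   needed to encode new data.
#' @export
build_model <- function(variants, priors, config = model_config()) {
  stopifnot(inherits(config, "pp_model_config"))
  design <- encode_design(variants, priors)
  design <- pp_apply_domain_merge(design, config)

  syndromes <- sort(unique(design$syndrome))
  if (config$join == "lqts_brs" && !all(syndromes %in% c("LQTS", "BrS"))) {
    pp_stop("join='lqts_brs' admits only LQTS and BrS data")
  }
  if (config$join == "lqts_hcm" && !all(syndromes %in% c("LQTS", "HCM"))) {
    pp_stop("join='lqts_hcm' admits only LQTS and HCM data")
  }

  plan <- pp_param_plan(config$model)
  shared <- pp_shared_params(config$join)

  cols <- list()
  for (param in plan$fixed) {
    if (param %in% shared || length(syndromes) == 1) {
      blk <- paste(syndromes, collapse = "+")
      cols[[length(cols) + 1L]] <- tibble(
        name = param, kind = "fixed", param = param, block = blk,
        gene = NA_character_, domain = NA_character_)
    } else {
      for (s in syndromes) {
        cols[[length(cols) + 1L]] <- tibble(
          name = paste0(param, ":", s), kind = "fixed", param = param,
          block = s, gene = NA_character_, domain = NA_character_)
      }
    }
  }

  if (isTRUE(plan$domains)) {
    dom <- design %>%
      filter(.data$variant_class != "radical", !is.na(.data$domain),
             !.data$gene %in% config$no_domain_genes) %>%
      distinct(.data$syndrome, .data$gene, .data$domain) %>%
      arrange(.data$syndrome, .data$gene, .data$domain)
    if (nrow(dom) > 0) {
      cols[[length(cols) + 1L]] <- tibble(
        name = paste0("delta[", dom$syndrome, "|", dom$gene, ":",
                      dom$domain, "]"),
        kind = "domain", param = "delta", block = dom$syndrome,
        gene = dom$gene, domain = dom$domain)
    }
  }

  columns <- bind_rows(cols)
  X <- pp_design_matrix(design, columns)
  y <- NULL
  if ("label" %in% names(design) && !anyNA(design$label)) {
    y <- as.integer(design$label == "pathogenic")
  }

  structure(
    list(X = X, y = y, columns = columns, design = design, config = config,
         priors = as_tibble(priors), syndromes = syndromes,
         hyper = list(coeff_var = config$coeff_var,
                      domain_shape = config$domain_shape,
                      domain_rate = config$domain_rate)),
    class = "pp_model"
  )
}

# Encode a design tibble into the model's column space. Unknown domains for
# domain-bearing genes contribute no domain effect (a zero column entry);
# warn_novel surfaces them at prediction time.
pp_design_matrix <- function(design, columns, warn_novel = FALSE,
                             no_domain_genes = pp_no_domain_genes) {
  n <- nrow(design)
  X <- matrix(0, nrow = n, ncol = nrow(columns),
              dimnames = list(NULL, columns$name))
  for (j in seq_len(nrow(columns))) {
    cl <- columns[j, ]
    if (cl$kind == "fixed") {
      block_syn <- strsplit(cl$block, "+", fixed = TRUE)[[1]]
      X[, j] <- pp_base_covariate(design, cl$param) *
        (design$syndrome %in% block_syn)
    } else {
      X[, j] <- as.numeric(design$variant_class != "radical" &
                             design$syndrome == cl$block &
                             !is.na(design$domain) &
                             design$domain == cl$domain &
                             design$gene == cl$gene)
    }
  }
  if (warn_novel && any(columns$kind == "domain")) {
    dom_cols <- columns[columns$kind == "domain", ]
    known <- paste(dom_cols$block, dom_cols$gene, dom_cols$domain)
    eligible <- design$variant_class != "radical" & !is.na(design$domain) &
      !design$gene %in% no_domain_genes
    seen <- paste(design$syndrome, design$gene, design$domain)[eligible]
    novel <- setdiff(unique(seen), known)
    if (length(novel) > 0) {
      warn(paste0("novel domain(s) at prediction time, effect set to 0: ",
                  paste(novel, collapse = ", ")))
    }
  }
  X
}

#' Evaluate the linear predictors of a model
#'
#' Computes the class-specific linear predictor on the logit scale for every
#' variant, at a given parameter vector. The model is additive on the
#' logistic scale: a radical variant receives its class intercept, the
#' radical gene term and the frequency term; an inframe indel receives the
#' non-radical intercept plus the inframe offset, the non-radical gene term,
#' its domain effect and the frequency term; a missense substitution
#' additionally receives the SIFT, PolyPhen (quadratic), Grantham
#' (quadratic) and conservation terms.
#'
#' @param model A `pp_model`.
#' @param params Named numeric vector covering every model column (extra
#'   entries such as `sigma2_domain` are ignored).
#' @param newdata Optional variant table to encode instead of the training
#'   data; unknown domains contribute no domain effect (with a warning).
#' @return Numeric vector of logits.
#' @export
linear_predictor <- function(model, params, newdata = NULL) {
  stopifnot(inherits(model, "pp_model"))
  need <- model$columns$name
  if (!all(need %in% names(params))) {
    pp_stop("params lacks value(s) for: ",
            paste(setdiff(need, names(params)), collapse = ", "))
  }
  X <- if (is.null(newdata)) {
    model$X
  } else {
    d <- encode_design(newdata, model$priors)
    d <- pp_apply_domain_merge(d, model$config)
    pp_design_matrix(d, model$columns, warn_novel = TRUE,
                     no_domain_genes = model$config$no_domain_genes)
  }
  drop(X %*% params[need])
}

#' @export
print.pp_model <- function(x, ...) {
  cat("<pp_model> ", x$config$model, " model, join=", x$config$join, "\n",
      sep = "")
  cat("  ", nrow(x$X), " variants across ",
      paste(x$syndromes, collapse = ", "), "\n", sep = "")
  cat("  ", sum(x$columns$kind == "fixed"), " fixed parameters, ",
      sum(x$columns$kind == "domain"), " domain effects",
      if (any(x$columns$kind == "domain")) " (+ shared variance)", "\n",
      sep = "")
  invisible(x)
}

#' List the free parameters of a model
#'
#' @param model A `pp_model`.
#' @return Tibble of parameter metadata, including the `sigma2_domain`
#'   hyperparameter row when domain effects are present.
#' @export
model_parameters <- function(model) {
  stopifnot(inherits(model, "pp_model"))
  out <- model$columns
  if (any(out$kind == "domain")) {
    out <- bind_rows(out, tibble(name = "sigma2_domain", kind = "variance",
                                 param = "sigma2_domain", block = "shared",
                                 gene = NA_character_, domain = NA_character_))
  }
  out
}
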