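#' Fit the model network by Markov chain Monte Carlo
#'
#' Samples the posterior of all model parameters jointly over the three
#' variant classes (and, under a joint plan, over two syndromes) under the
#' Bernoulli-logistic likelihood of the training labels, zero-mean normal
#' priors with variance `coeff_var` on all fixed parameters, zero-mean
#' normal domain effects and an inverse-gamma prior on their shared
#' variance. The sampler is an adaptive random-walk Metropolis-within-Gibbs
#' scheme with an exact conjugate update for the domain variance. The first
#' `burn_fraction` of each chain is discarded as burn-in; proposal scales
#' adapt only during burn-in.
#'
#' Defaults match routine production use of the model (10 chains of 40,000
#' iterations, 20% burn-in); far smaller runs are adequate for the
#' moderately sized problems in the examples and tests.
#'
#' @param model A `pp_model` with training labels (see [build_model()]).
#' @param chains Number of independent chains.
#' @param iter Iterations per chain.
#' @param burn_fraction Fraction of each chain discarded as burn-in.
#' @param seed Integer seed; all chains derive from it, and the fit is
#'   reproducible bit-for-bit for a given (data, settings, seed).
#' @param extend_until_converged If `TRUE`, the chain length is doubled (up
#'   to `max_doublings` times) until every parameter satisfies
#'   `max(R) < rhat_target`, mirroring the termination rule of requiring
#'   the potential scale reduction below 1.1.
#' @param rhat_target,max_doublings Control the optional extension.
#' @return A `pp_fit` object holding the kept draws (`n_kept` per chain for
#'   every parameter, plus the domain variance where applicable), the model
#'   and the run metadata.
#' @export
fit_model <- function(model, chains = 10, iter = 40000, burn_fraction = 0.2,
                      seed = 1, extend_until_converged = FALSE,
                      rhat_target = 1.1, max_doublings = 3) {
  stopifnot(inherits(model, "pp_model"))
  if (is.null(model$y)) {
    pp_stop("model has no training labels; build it from a labelled table")
  }
  if (length(unique(model$y)) < 2) {
    pp_stop("training data must contain both pathogenic and benign variants")
  }
  stopifnot(chains >= 1, iter >= 2, burn_fraction >= 0, burn_fraction < 1)

  run <- function(n_iter) {
    set.seed(as.integer(seed))
    res <- pp_mcmc_cpp(model$X, model$y,
                       model$columns$kind == "domain",
                       model$hyper$coeff_var, model$hyper$domain_shape,
                       model$hyper$domain_rate,
                       as.integer(chains), as.integer(n_iter), burn_fraction)
    pnames <- c(model$columns$name, "sigma2_domain")
    has_dom <- any(model$columns$kind == "domain")
    keep <- if (has_dom) seq_along(pnames) else seq_len(length(pnames) - 1L)
    # pp_mcmc_cpp stacks chains in blocks of `kept` rows
    draws <- array(res$draws[, keep, drop = FALSE],
                   dim = c(res$kept, chains, length(keep)))
    dimnames(draws) <- list(NULL, paste0("chain", seq_len(chains)),
                            pnames[keep])
    structure(
      list(draws = draws, parameters = pnames[keep], model = model,
           n_chains = chains, n_iter = n_iter,
           burn_fraction = burn_fraction, n_kept = res$kept, seed = seed,
           accept = res$accept),
      class = "pp_fit")
  }

  fit <- run(iter)
  if (extend_until_converged) {
    d <- 0
    while (max(rhat(fit)$rhat) >= rhat_target && d < max_doublings) {
      iter <- iter * 2L
      d <- d + 1L
      fit <- run(iter)
    }
  }
  fit
}

#' Potential scale reduction diagnostic
#'
#' For each parameter, with `n` kept draws per chain, the between-chain
#' variance `B` (the variance of sampled parameter values between chains,
#' computed from the chain means), the mean within-chain variance `W`, the
#' pooled estimate `Var = W (n-1)/n + B/n` and
#' `R = sqrt(Var / W)` are reported. Chains that agree exactly (`W = 0`)
#' are assigned `R = 1` by convention. Values of `R` below 1.1 for every
#' parameter are taken to indicate convergence.
#'
#' @param fit A `pp_fit`.
#' @return Tibble with `parameter`, `W`, `B`, `var_plus` and `rhat`.
#' @export
rhat <- function(fit) {
  stopifnot(inherits(fit, "pp_fit"))
  if (fit$n_chains < 2) {
    pp_stop("potential scale reduction needs at least two chains")
  }
  if (fit$n_kept < 2) {
    pp_stop("potential scale reduction needs at least two kept draws")
  }
  purrr::map_dfr(fit$parameters, function(p) {
    ch <- fit$draws[, , p, drop = TRUE]  # kept x chains
    stats <- pp_rhat(ch)
    tibble(parameter = p, W = stats["W"], B = stats["B"],
           var_plus = stats["var_plus"], rhat = stats["rhat"])
  })
}

# chains: matrix of kept draws (rows) by chain (columns)
pp_rhat <- function(chains) {
  n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  B <- var(colMeans(chains))
  if (W == 0) {
    return(c(W = W, B = B, var_plus = 0, rhat = 1))
  }
  var_plus <- W * (n - 1) / n + B / n
  c(W = W, B = B, var_plus = var_plus, rhat = sqrt(var_plus / W))
}

#' Posterior summary of a fitted model
#'
#' Pools the kept draws of all chains and reports, per parameter, the
#' posterior median (used downstream as the plug-in fitted value), the 5%
#' and 95% quantiles, and the potential scale reduction.
#'
#' @param x A `pp_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate` (median), `q05`, `q95`,
#'   `rhat`.
#' @method tidy pp_fit
#' @export
tidy.pp_fit <- function(x, ...) {
  rh <- rhat(x)
  purrr::map_dfr(x$parameters, function(p) {
    draws <- as.vector(x$draws[, , p])
    tibble(parameter = p,
           estimate = median(draws),
           q05 = quantile(draws, 0.05, names = FALSE),
           q95 = quantile(draws, 0.95, names = FALSE))
  }) %>%
    left_join(rh[, c("parameter", "rhat")], by = "parameter")
}

#' One-row summary of a fitted model
#'
#' @param x A `pp_fit`.
#' @param ... Unused.
#' @return Tibble with chain geometry, the largest potential scale
#'   reduction and whether it falls below the 1.1 convergence rule.
#' @method glance pp_fit
#' @export
glance.pp_fit <- function(x, ...) {
  mr <- max(rhat(x)$rhat)
  tibble(n_params = length(x$parameters), n_chains = x$n_chains,
         n_iter = x$n_iter, n_kept = x$n_kept, max_rhat = mr,
         converged = mr < 1.1)
}

#' @export
print.pp_fit <- function(x, ...) {
  cat("<pp_fit> ", length(x$parameters), " parameters, ", x$n_chains,
      " chains x ", x$n_kept, " kept draws (", x$n_iter,
      " iterations, ", round(100 * x$burn_fraction), "% burn-in)\n",
      sep = "")
  cat("  max potential scale reduction: ",
      format(max(rhat(x)$rhat), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Posterior medians as a named vector
#'
#' @param fit A `pp_fit`.
#' @return Named numeric vector of posterior medians, the plug-in values
#'   used for prediction.
#' @export
posterior_medians <- function(fit) {
  td <- tidy(fit)
  setNames(td$estimate, td$parameter)
}
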