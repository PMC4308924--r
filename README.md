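# pathprob

Bayesian probabilities of pathogenicity for rare coding variants in genes
for inherited cardiac conditions — long QT syndrome (LQTS), Brugada
syndrome (BrS) and hypertrophic cardiomyopathy (HCM).

Clinical genetic testing routinely finds rare protein-altering variants in
disease genes, but healthy people carry rare variants in the same genes.
`pathprob` is for clinical scientists and method developers who want a
*probability* that a given variant causes a given patient's syndrome — not
a hard pathogenic/benign call — computed from a transparent model whose
every assumption is inspectable.

## The model

The posterior odds of pathogenicity combine a gene-level prior with
variant-level evidence:

    posterior odds = prior odds × likelihood ratio

**Prior odds** per gene, syndrome and variant-class group come from rare
variant burdens: (b_case − b_ctrl) / b_ctrl, with a zero control burden
replaced by 0.0002, literature-derived LQTS odds halved then floored at
0.2, and HCM/BrS odds taken as b_case / 0.01 against a fixed 1% benign
burden. A burden table spanning 26 genes ships with the package.

**The likelihood ratio** is supplied by a network of nine interrelated
logistic regressions (3 variant classes × 3 syndromes), additive on the
logit scale:

| class    | linear predictor                                             |
|----------|--------------------------------------------------------------|
| radical  | α_rad + λ_rad·log(prior odds) + β_f·f                        |
| inframe  | α_nr + α_if + λ_nr·log(prior odds) + δ_domain + β_f·f        |
| missense | as inframe (without α_if) + β_s·(1−SIFT) + β_p1·p + β_p2·p² + β_g1·g + β_g2·g² + β_c1·c₁ + β_c2·c₂ |

with f = control-database presence, p = PolyPhen (HumVar), g =
Grantham/205, (c₁, c₂) = conservation indicators (primates / all species).
Domain effects δ are zero-mean random effects with an inverse-gamma
variance; coefficients have N(0, 10) priors; parameters can be shared
across syndromes when two models are fitted jointly. Fitting is by MCMC
(adaptive Metropolis-within-Gibbs in C++), convergence is monitored with
the potential scale reduction R (required < 1.1), and posterior medians
are the plug-in values for prediction. Segregation evidence multiplies the
odds by 10^LOD. Cross-validation reports ROC curves and a prior-adjusted
PPV = prior·TPR / (prior·TPR + FPR).

## Worked example

```r
library(pathprob)

priors <- build_prior_table(cardiac_burden())
dplyr::filter(priors, gene %in% c("KCNQ1", "KCNH2", "SCN5A"),
              syndrome == "LQTS")
#>   gene  syndrome class_group prior_odds policy
#> 1 KCNH2 LQTS     non_radical      25.2  subtractive/case_series
#> 2 KCNH2 LQTS     radical         195    subtractive/case_series
#> 3 KCNQ1 LQTS     non_radical      44.7  subtractive/case_series
#> 4 KCNQ1 LQTS     radical         191    subtractive/case_series
#> 5 SCN5A LQTS     non_radical       4.21 subtractive/case_series
#> 6 SCN5A LQTS     radical          13    subtractive/case_series
```

A variant in KCNQ1 has prior odds 45:1 of being causal in an LQTS referral;
the same class of variant in SCN5A only 4:1. Train the network (here on a
synthetic LQTS-like training set; real use would read a curated table with
`read_variant_table()`):

```r
train <- simulate_variants(320, seed = 20)
fit <- fit_model(build_model(train, generator_priors(generator_spec())),
                 chains = 4, iter = 4000, seed = 1)
glance(fit)
#>   n_params n_chains n_iter n_kept max_rhat converged
#> 1       20        4   4000   3200     1.00 TRUE
```

All 20 parameters converged (max R = 1.00 < 1.1). Score two novel variants:

```r
novel <- tibble::tibble(
  variant_id = c("KCNQ1:p.G314S", "SCN5A:p.T220I"),
  gene = c("KCNQ1", "SCN5A"), syndrome = "LQTS",
  variant_class = "missense", domain = c("TM_pore", NA),
  grantham = c(56, 89), sift = c(0, 0.12), polyphen = c(0.99, 0.35),
  conservation = c("conserved_all", "conserved_primates"),
  in_control_db = c(0, 0))
(preds <- predict_pathogenicity(fit, novel))
#>   variant_id    gene  ... logit probability band
#> 1 KCNQ1:p.G314S KCNQ1     6.55        0.999 pathogenic
#> 2 SCN5A:p.T220I SCN5A     0.991       0.729 uncertain
```

The KCNQ1 pore variant — absent from controls, damaging by every score,
conserved in all species, in a high-risk gene — is all but certainly
pathogenic (P = 0.999). The SCN5A variant is uncertain (P = 0.73): its
annotations are mixed and its gene prior is low. Co-segregation in a small
family (LOD 1.2) settles it:

```r
combine_segregation(preds[2, ], lod = 1.2)
#>   variant_id    ... logit probability band       lod_applied
#> 1 SCN5A:p.T220I      3.75       0.977 pathogenic         1.2
```

`autoplot(fit)` shows posterior effect sizes; `evaluate_cv()` produces
pooled cross-validated ROC curves and prior-adjusted PPVs, and
`autoplot()` of its result draws the ROC. A command-line front end with
`priors`, `simulate`, `fit`, `predict` and `evaluate` subcommands is
installed at `inst/cli/pathprob`.

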