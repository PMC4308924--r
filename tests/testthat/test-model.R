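spec <- generator_spec()
gpri <- generator_priors(spec)

test_that("linear predictor follows the class-specific formulas", {
  v <- toy_variants()
  pri <- build_prior_table(cardiac_burden())
  m <- build_model(v, pri, model_config())
  zero <- setNames(rep(0, nrow(m$columns)), m$columns$name)
  expect_equal(linear_predictor(m, zero), rep(0, 4))

  # radical: alpha + lambda * log(prior) with unit parameters
  p1 <- zero
  p1["alpha_radical"] <- 1
  p1["lambda_radical"] <- 1
  eta <- linear_predictor(m, p1)
  rad_prior <- pri$prior_odds[pri$gene == "SCN5A" & pri$syndrome == "LQTS" &
                                pri$class_group == "radical"]
  expect_equal(eta[4], 1 + log(rad_prior))
  expect_equal(eta[1:3], rep(0, 3))

  # missense with unit coefficients on the worked all-ones design sums to 6
  p2 <- zero
  p2[c("beta_sift", "beta_polyphen", "beta_polyphen_sq", "beta_grantham",
       "beta_grantham_sq", "beta_cons_primates", "beta_cons_all")] <- 1
  expect_equal(linear_predictor(m, p2)[1], 6)  # cons_primates stays 0
})

test_that("linear predictor is exactly additive in each covariate", {
  v <- simulate_variants(50, spec, seed = 9)
  m <- build_model(v, gpri)
  set.seed(2)
  params <- setNames(rnorm(nrow(m$columns)), m$columns$name)
  base <- linear_predictor(m, params)
  for (nm in c("beta_sift", "beta_freq", "lambda_nonradical")) {
    shifted <- params
    shifted[nm] <- shifted[nm] + 0.7
    expect_equal(linear_predictor(m, shifted) - base,
                 0.7 * m$X[, nm])
  }
})

test_that("full model lays out one domain effect per observed training domain", {
  v <- simulate_variants(300, spec, seed = 21)
  m <- build_model(v, gpri)
  dom <- m$columns[m$columns$kind == "domain", ]
  seen <- dplyr::distinct(
    dplyr::filter(m$design, variant_class != "radical", !is.na(domain)),
    gene, domain)
  expect_equal(nrow(dom), nrow(seen))
  expect_equal(sum(m$columns$kind == "fixed"), 13)
  expect_true("sigma2_domain" %in% model_parameters(m)$name)
})

test_that("genes on the no-domain list never receive domain effects", {
  v <- toy_variants()
  v$gene <- c("KCNJ2", "KCNJ2", "CAV3", "SCN5A")  # all on the no-domain list
  pri <- build_prior_table(cardiac_burden())
  m <- build_model(v, pri, model_config())
  expect_equal(sum(m$columns$kind == "domain"), 0)
  expect_false("sigma2_domain" %in% model_parameters(m)$name)
})

test_that("ablations drop the advertised parameter sets", {
  v <- simulate_variants(120, spec, seed = 4)
  params_of <- function(model) {
    build_model(v, gpri, model_config(model = model))$columns$param
  }
  gw <- params_of("genome_wide")
  expect_false(any(grepl("lambda", gw)))
  expect_false(any(gw == "delta"))
  expect_true(all(c("alpha_radical", "beta_sift") %in% gw))

  so <- params_of("sift_only")
  expect_setequal(unique(so), c("alpha_radical", "alpha_nonradical",
                                "alpha_inframe", "beta_sift"))

  po <- params_of("prior_only")
  expect_setequal(unique(po),
                  c("alpha_radical", "alpha_nonradical", "alpha_inframe",
                    "lambda_nonradical", "lambda_radical"))

  ps <- params_of("prior_sift")
  expect_true("beta_sift" %in% ps)
  expect_false("beta_freq" %in% ps)

  gene_only <- params_of("gene")
  expect_false(any(gene_only == "delta"))
  expect_true(any(grepl("lambda", gene_only)))
})

test_that("low-resolution domain merging relabels and validates the map", {
  v <- simulate_variants(200, spec, seed = 6)
  merge_map <- c(TM_pore = "TM", PAS = "N_term", C_term = "C_term",
                 DIII_DIV = "TM")
  m <- build_model(v, gpri, model_config(model = "low_res_domain",
                                         domain_merge = merge_map,
                                         no_domain_genes = character()))
  doms <- unique(m$columns$domain[m$columns$kind == "domain"])
  expect_true(all(doms %in% c("TM", "N_term", "C_term")))

  expect_error(
    build_model(v, gpri, model_config(model = "low_res_domain",
                                      domain_merge = merge_map["PAS"],
                                      no_domain_genes = character())),
    "merge map lacks")
})

test_that("joint syndrome plans tie exactly the advertised parameters", {
  v_lqts <- simulate_variants(60, spec, seed = 7)
  brs_spec <- generator_spec(
    genes = tibble::tibble(
      gene = c("SCN5A_B", "GPD1L_B"), syndrome = "BrS",
      weight = c(0.7, 0.3), prior_nonradical = c(30, 1),
      prior_radical = c(30, 1),
      domains = list(c("TM1"), c("TM2"))))
  v_brs <- simulate_variants(40, brs_spec, seed = 8)
  v <- dplyr::bind_rows(v_lqts, v_brs)
  v$variant_id <- paste0("v", seq_len(nrow(v)))
  pri <- dplyr::bind_rows(gpri, generator_priors(brs_spec))

  m <- build_model(v, pri, model_config(join = "lqts_brs"))
  fixed <- m$columns[m$columns$kind == "fixed", ]
  # everything fixed is shared: no syndrome-suffixed parameter names
  expect_false(any(grepl(":", fixed$name)))
  expect_equal(nrow(fixed), 13)
  # domain effects stay syndrome-specific
  expect_true(all(m$columns$block[m$columns$kind == "domain"] %in%
                    c("LQTS", "BrS")))

  # a shared coefficient moves predictions in both syndromes
  params <- setNames(rep(0, nrow(m$columns)), m$columns$name)
  params["beta_freq"] <- 1
  eta <- linear_predictor(m, params)
  touched <- tapply(abs(eta) > 0, m$design$syndrome, any)
  has_freq <- tapply(m$design$freq_indicator == 1, m$design$syndrome, any)
  expect_equal(as.vector(touched[has_freq]), rep(TRUE, sum(has_freq)))

  # LQTS+HCM ties only the score coefficients
  v_hcm <- v_brs
  v_hcm$syndrome <- "HCM"
  v_hcm$gene <- sub("_B", "_H", v_hcm$gene)
  pri_hcm <- generator_priors(brs_spec)
  pri_hcm$syndrome <- "HCM"
  pri_hcm$gene <- sub("_B", "_H", pri_hcm$gene)
  m2 <- build_model(dplyr::bind_rows(v_lqts, v_hcm),
                    dplyr::bind_rows(gpri, pri_hcm),
                    model_config(join = "lqts_hcm"))
  f2 <- m2$columns[m2$columns$kind == "fixed", ]
  shared <- f2$param[!grepl(":", f2$name)]
  expect_setequal(unique(shared),
                  c("beta_sift", "beta_polyphen", "beta_polyphen_sq",
                    "beta_grantham", "beta_grantham_sq",
                    "beta_cons_primates", "beta_cons_all"))
  split_params <- f2$param[grepl(":", f2$name)]
  expect_true(all(c("alpha_radical", "lambda_nonradical", "beta_freq") %in%
                    split_params))
})

test_that("novel domains at prediction time contribute zero with a warning", {
  v <- simulate_variants(150, spec, seed = 10)
  m <- build_model(v, gpri)
  params <- setNames(rnorm(nrow(m$columns)), m$columns$name)
  new <- v[v$variant_class == "missense", ][1, ]
  new$domain <- "never_seen_domain"
  expect_warning(eta <- linear_predictor(m, params, newdata = new),
                 "novel domain")
  ref <- new
  ref$domain <- NA  # no-domain encoding is the declared fallback
  expect_equal(eta, suppressWarnings(linear_predictor(m, params,
                                                      newdata = ref)))
})
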