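# Shared builders for small in-code fixtures.

# One fully annotated variant per class, all in genes covered by the
# packaged burden table.
toy_variants <- function() {
  tibble::tribble(
    ~variant_id, ~gene, ~syndrome, ~variant_class, ~domain, ~grantham,
    ~sift, ~polyphen, ~conservation, ~in_control_db, ~label,
    "m1", "KCNQ1", "LQTS", "missense", "TM", 205, 0, 1,
    "conserved_all", 0, "pathogenic",
    "m2", "KCNQ1", "LQTS", "missense", "Cterm", 0, 1, 0,
    "not_conserved", 1, "benign",
    "i1", "KCNH2", "LQTS", "inframe", "PAS", NA, NA, NA, NA, 0, "pathogenic",
    "r1", "SCN5A", "LQTS", "radical", NA, NA, NA, NA, NA, 1, "benign"
  )
}

# Per-species conservation evidence builder.
cons_evidence <- function(primates = character(), mammals = character(),
                          vertebrates = character(), all_70 = character()) {
  status <- c(primates, mammals, vertebrates, all_70)
  clade <- rep(c("primates", "mammals", "vertebrates", "all_70"),
               c(length(primates), length(mammals), length(vertebrates),
                 length(all_70)))
  tibble::tibble(species = paste0("sp", seq_along(status)),
                 clade = clade, status = status)
}

# A pp_fit built directly from given per-chain draws of one parameter, for
# testing summaries against hand-computed values.
manual_fit <- function(chain_draws, parameter = "theta") {
  kept <- length(chain_draws[[1]])
  draws <- array(unlist(chain_draws), dim = c(kept, length(chain_draws), 1))
  dimnames(draws) <- list(NULL, paste0("chain", seq_along(chain_draws)),
                          parameter)
  structure(
    list(draws = draws, parameters = parameter, model = NULL,
         n_chains = length(chain_draws), n_iter = kept,
         burn_fraction = 0, n_kept = kept, seed = NA),
    class = "pp_fit")
}

# Brute-force AUC oracle: concordant pairs with ties counted one half.
auc_pair_oracle <- function(probability, label) {
  pos <- probability[label == "pathogenic"]
  neg <- probability[label == "benign"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
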