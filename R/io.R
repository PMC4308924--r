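# Tab-separated IO with '#'-prefixed comment headers. Writers emit a fixed
# column order and a header recording the package version and a content hash;
# readers are indifferent to column order.

pp_write_tsv <- function(x, path, meta = character()) {
  header <- c(
    paste0("# pathprob ", as.character(packageVersion("pathprob"))),
    paste0("# hash=", rlang::hash(x)),
    if (length(meta) > 0) paste0("# ", meta)
  )
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

pp_read_tsv <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  na = c("", "NA"), progress = FALSE)
}

#' Read and write variant annotation tables
#'
#' The native variant format is a TSV with header-named columns matching the
#' variant record fields (`variant_id`, `gene`, `syndrome`, `variant_class`,
#' `domain`, `grantham`, `sift`, `polyphen`, `conservation`,
#' `in_control_db`, optionally `label` and `lod`); missing values are empty
#' cells and `#`-prefixed lines are comments. Rows are validated on read and
#' all problems reported together with their row numbers.
#'
#' @param path File path.
#' @param require_scores Passed to [validate_variants()].
#' @return `read_variant_table()` returns a validated variant tibble.
#' @export
read_variant_table <- function(path, require_scores = TRUE) {
  x <- pp_read_tsv(path, readr::cols(
    variant_id = readr::col_character(),
    gene = readr::col_character(),
    syndrome = readr::col_character(),
    variant_class = readr::col_character(),
    domain = readr::col_character(),
    grantham = readr::col_double(),
    sift = readr::col_double(),
    polyphen = readr::col_double(),
    conservation = readr::col_character(),
    in_control_db = readr::col_double(),
    label = readr::col_character(),
    lod = readr::col_double(),
    .default = readr::col_guess()
  ))
  validate_variants(x, require_scores = require_scores)
}

#' @rdname read_variant_table
#' @param x Variant tibble.
#' @param meta Extra comment-header lines (e.g. a seed).
#' @export
write_variant_table <- function(x, path, meta = character()) {
  cols <- c("variant_id", "gene", "syndrome", "variant_class", "domain",
            "grantham", "sift", "polyphen", "conservation", "in_control_db",
            "label", "lod")
  x <- as_tibble(x)
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  pp_write_tsv(x[cols], path, meta)
}

#' Read a burden table
#'
#' @param path TSV with columns `gene`, `syndrome`, `class_group`,
#'   `case_burden`, `control_burden`, `source`.
#' @return Burden tibble.
#' @export
read_burden_table <- function(path) {
  pp_read_tsv(path, readr::cols(
    gene = readr::col_character(),
    syndrome = readr::col_character(),
    class_group = readr::col_character(),
    case_burden = readr::col_double(),
    control_burden = readr::col_double(),
    source = readr::col_character()
  ))
}

#' Write a prior odds table
#'
#' @param x Prior odds tibble from [build_prior_table()].
#' @param path File path.
#' @param meta Extra comment-header lines.
#' @export
write_prior_table <- function(x, path, meta = character()) {
  pp_write_tsv(as_tibble(x)[c("gene", "syndrome", "class_group",
                              "prior_odds", "policy")], path, meta)
}

#' Write per-variant predictions
#'
#' @param x Prediction tibble from [predict_pathogenicity()].
#' @param path File path.
#' @param meta Extra comment-header lines.
#' @export
write_predictions <- function(x, path, meta = character()) {
  cols <- c("variant_id", "gene", "syndrome", "variant_class", "logit",
            "probability", "band", "lod_applied")
  x <- as_tibble(x)
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  pp_write_tsv(x[cols], path, meta)
}

#' Write a posterior parameter summary
#'
#' One row per parameter with the posterior median (the plug-in fitted
#' value), 5% and 95% quantiles and the potential scale reduction.
#'
#' @param x Tidy fit summary from [tidy.pp_fit()].
#' @param path File path.
#' @param meta Extra comment-header lines.
#' @export
write_posterior_summary <- function(x, path, meta = character()) {
  pp_write_tsv(as_tibble(x), path, meta)
}
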