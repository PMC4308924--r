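#' Validate a table of annotated variants
#'
#' Checks the vocabulary and ranges of a variant annotation table: syndromes
#' (`LQTS`, `BrS`, `HCM`), variant classes (`radical`, `inframe`,
#' `missense`), score ranges (SIFT and PolyPhen in \[0, 1\], Grantham a
#' non-negative number), conservation categories, and the class-specific
#' field requirements (missense records must carry SIFT, PolyPhen, Grantham
#' and conservation; radical and inframe records must not). All row-level
#' problems are aggregated into a single error naming fields and rows.
#'
#' @param variants Data frame with columns `variant_id`, `gene`, `syndrome`,
#'   `variant_class` and the per-class annotation columns (`domain`,
#'   `grantham`, `sift`, `polyphen`, `conservation`, `in_control_db`,
#'   optionally `label` and `lod`).
#' @param require_scores Should missense rows be required to carry all
#'   missense annotations? Set `FALSE` when validating partially annotated
#'   tables.
#' @return The input, as a tibble, invisibly; errors on any violation.
#' @export
validate_variants <- function(variants, require_scores = TRUE) {
  variants <- as_tibble(variants)
  required <- c("variant_id", "gene", "syndrome", "variant_class")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    pp_stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("domain", "grantham", "sift", "polyphen", "conservation",
                "in_control_db", "label", "lod")) {
    if (!col %in% names(variants)) variants[[col]] <- NA
  }

  problems <- character()
  note <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems, paste0(
        msg, " (rows ", paste(head(which(rows), 5), collapse = ", "),
        if (sum(rows) > 5) ", ..." else "", ")"))
    }
  }

  note(!variants$syndrome %in% pp_syndromes,
       paste0("syndrome must be one of ", paste(pp_syndromes, collapse = "/")))
  note(!variants$variant_class %in% pp_classes,
       paste0("variant_class must be one of ", paste(pp_classes, collapse = "/")))
  note(!is.na(variants$sift) & (variants$sift < 0 | variants$sift > 1),
       "sift outside [0, 1]")
  note(!is.na(variants$polyphen) & (variants$polyphen < 0 | variants$polyphen > 1),
       "polyphen outside [0, 1]")
  note(!is.na(variants$grantham) & variants$grantham < 0,
       "grantham negative")
  note(!is.na(variants$conservation) &
         !as.character(variants$conservation) %in% pp_cons3,
       paste0("conservation must be one of ", paste(pp_cons3, collapse = "/")))
  note(!is.na(variants$in_control_db) & !variants$in_control_db %in% c(0, 1),
       "in_control_db must be 0/1")
  note(!is.na(variants$label) & !as.character(variants$label) %in% pp_labels,
       paste0("label must be one of ", paste(pp_labels, collapse = "/")))

  is_missense <- variants$variant_class == "missense"
  if (require_scores) {
    for (col in c("sift", "polyphen", "grantham", "conservation")) {
      note(is_missense & is.na(variants[[col]]),
           paste0("missense variant missing required field '", col, "'"))
    }
  }
  for (col in c("sift", "polyphen", "grantham", "conservation")) {
    note(!is_missense & !is.na(variants[[col]]),
         paste0("field '", col, "' is missense-only"))
  }

  if (length(problems) > 0) {
    pp_stop("invalid variant table:\n  - ",
            paste(problems, collapse = "\n  - "),
            class = "pathprob_validation_error")
  }
  invisible(variants)
}

#' Encode variants as model design covariates
#'
#' Applies the predictor transformations feeding the class-specific linear
#' predictors: SIFT is flipped to `1 - SIFT`, Grantham is rescaled by 1/205
#' and entered together with its square, PolyPhen is entered with its square,
#' conservation becomes two binary indicators, the control-database presence
#' becomes the frequency indicator (missing treated as absent), and each
#' variant picks up the logarithm of its gene's prior odds for the matching
#' class group. Radical variants carry only the frequency indicator and the
#' radical-class gene term; inframe indels add the domain label; missense
#' substitutions carry everything.
#'
#' @param variants Validated variant table (see [validate_variants()]).
#' @param priors Prior odds table from [build_prior_table()].
#' @param grantham_max Rescaling constant for Grantham scores; values above
#'   it are clamped to 1 after rescaling, with a warning.
#' @return Tibble with one row per variant: identifiers, `freq_indicator`,
#'   `sift_t`, `grantham_t`, `grantham_t_sq`, `polyphen`, `polyphen_sq`,
#'   `cons_primates`, `cons_all`, `log_prior_odds`, `domain`,
#'   `variant_class` (and `label` if present).
#' @export
encode_design <- function(variants, priors, grantham_max = 205) {
  variants <- validate_variants(variants)
  priors <- as_tibble(priors)

  class_group <- ifelse(variants$variant_class == "radical",
                        "radical", "non_radical")
  key <- paste(variants$gene, variants$syndrome, class_group)
  pkey <- paste(priors$gene, priors$syndrome, priors$class_group)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    miss <- unique(paste0(variants$gene, "/", variants$syndrome)[is.na(idx)])
    pp_stop("no prior odds for: ", paste(miss, collapse = ", "),
            ". Extend the burden table to cover these genes and rebuild the ",
            "prior odds table.")
  }

  is_missense <- variants$variant_class == "missense"
  grantham_t <- ifelse(is_missense, variants$grantham / grantham_max, 0)
  if (any(grantham_t > 1, na.rm = TRUE)) {
    warn(paste0("Grantham score(s) above ", grantham_max,
                " clamped to the top of the fitted range"))
    grantham_t <- pmin(grantham_t, 1)
  }
  cons <- encode_conservation(ifelse(is_missense,
                                     as.character(variants$conservation), NA))

  out <- tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    syndrome = variants$syndrome,
    variant_class = variants$variant_class,
    domain = ifelse(variants$variant_class == "radical", NA_character_,
                    as.character(variants$domain)),
    freq_indicator = as.integer(!is.na(variants$in_control_db) &
                                  variants$in_control_db == 1),
    sift_t = ifelse(is_missense, 1 - variants$sift, 0),
    grantham_t = grantham_t,
    grantham_t_sq = grantham_t^2,
    polyphen = ifelse(is_missense, variants$polyphen, 0),
    polyphen_sq = ifelse(is_missense, variants$polyphen, 0)^2,
    cons_primates = cons$cons_primates,
    cons_all = cons$cons_all,
    log_prior_odds = log(priors$prior_odds[idx])
  )
  if (!all(is.na(variants$label))) out$label <- as.character(variants$label)
  if ("lod" %in% names(variants) && !all(is.na(variants$lod))) {
    out$lod <- variants$lod
  }
  out
}
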