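#' Categorise residue conservation from per-species alignment evidence
#'
#' For each variant site, per-species orthologue alignment evidence is reduced
#' to the deepest nested clade within which every informative species carries
#' the same residue. Species are grouped into nested clades
#' (primates &sube; mammals &sube; vertebrates &sube; all 70 species); a species
#' aligning with a gap or an `X` carries no evidence and is disregarded.
#'
#' A conservation level is claimed only when the cumulative clade set contains
#' at least one informative (non-disregarded) species and all of them match
#' the reference residue; levels deeper than the deepest clade represented in
#' the evidence are never claimed (absence of data is not evidence of
#' conservation). If any informative primate differs, or no level can be
#' claimed, the site is `not_conserved`.
#'
#' @param evidence A data frame with columns `species`, `clade` (one of
#'   `"primates"`, `"mammals"`, `"vertebrates"`, `"all_70"`, the innermost
#'   clade the species belongs to) and `status` (one of `"same_residue"`,
#'   `"different_residue"`, `"disregard"`). An optional `variant_id` column
#'   groups rows into sites; without it all rows are treated as one site.
#' @return A tibble with one row per site: `variant_id` and `conservation`,
#'   an ordered factor with levels `not_conserved < primates < mammals <
#'   vertebrates < all_species`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   species = paste0("sp", 1:4),
#'   clade = c("primates", "primates", "mammals", "vertebrates"),
#'   status = c("same_residue", "same_residue", "same_residue",
#'              "different_residue")
#' )
#' categorize_conservation(ev)
categorize_conservation <- function(evidence) {
  evidence <- as_tibble(evidence)
  required <- c("species", "clade", "status")
  missing <- setdiff(required, names(evidence))
  if (length(missing) > 0) {
    pp_stop("conservation evidence lacks column(s): ",
            paste(missing, collapse = ", "))
  }
  if (!"variant_id" %in% names(evidence)) evidence$variant_id <- "site"
  bad_clade <- setdiff(unique(evidence$clade), pp_clades)
  if (length(bad_clade) > 0) {
    pp_stop("unknown clade value(s): ", paste(bad_clade, collapse = ", "))
  }
  bad_status <- setdiff(unique(evidence$status),
                        c("same_residue", "different_residue", "disregard"))
  if (length(bad_status) > 0) {
    pp_stop("unknown match status value(s): ",
            paste(bad_status, collapse = ", "))
  }

  evidence %>%
    group_by(.data$variant_id) %>%
    summarise(conservation = categorize_one(.data$clade, .data$status),
              .groups = "drop") %>%
    mutate(conservation = factor(.data$conservation, levels = pp_cons5,
                                 ordered = TRUE))
}

categorize_one <- function(clade, status) {
  informative <- status != "disregard"
  if (!any(informative)) {
    pp_stop("all species disregarded at this site: no conservation evidence",
            class = "pathprob_missing_evidence")
  }
  depth <- match(clade, pp_clades)
  level <- "not_conserved"
  # levels deeper than the deepest clade represented in the evidence are
  # never claimed: absence of data is not evidence of conservation
  for (k in seq_len(max(depth))) {
    inside <- depth <= k
    inf_inside <- inside & informative
    if (!any(inf_inside)) next          # vacuous claim: skip this level
    if (any(inf_inside & status == "different_residue")) break
    level <- pp_cons5[k + 1L]           # primates .. all_species
  }
  level
}

#' Collapse five conservation levels to the three modelled categories
#'
#' The five-level categorisation (`not_conserved`, `primates`, `mammals`,
#' `vertebrates`, `all_species`) is simplified to three categories encoded
#' downstream as two binary indicators (conserved in primates, conserved in
#' all species), with `not_conserved` the reference state. By default the
#' intermediate mammal and vertebrate levels map to the conserved-in-primates
#' indicator; the mapping is configurable.
#'
#' @param category Character or factor vector of five-level categories.
#' @param mapping Named character vector mapping each five-level category to
#'   a three-level one; see [conservation_mapping()].
#' @return Factor with levels `not_conserved`, `conserved_primates`,
#'   `conserved_all`.
#' @export
simplify_conservation <- function(category, mapping = conservation_mapping()) {
  category <- as.character(category)
  bad <- setdiff(unique(category[!is.na(category)]), names(mapping))
  if (length(bad) > 0) {
    pp_stop("unknown conservation category: ", paste(bad, collapse = ", "))
  }
  out <- unname(mapping[category])
  if (any(!is.na(out) & !out %in% pp_cons3)) {
    pp_stop("mapping targets must be one of: ", paste(pp_cons3, collapse = ", "))
  }
  factor(out, levels = pp_cons3)
}

#' Default five-to-three conservation level mapping
#'
#' @return Named character vector used by [simplify_conservation()].
#' @export
conservation_mapping <- function() {
  c(not_conserved = "not_conserved",
    primates = "conserved_primates",
    mammals = "conserved_primates",
    vertebrates = "conserved_primates",
    all_species = "conserved_all")
}

# Two-indicator encoding; not_conserved is the reference (0, 0).
encode_conservation <- function(cons3) {
  cons3 <- as.character(cons3)
  tibble(
    cons_primates = as.integer(!is.na(cons3) & cons3 == "conserved_primates"),
    cons_all = as.integer(!is.na(cons3) & cons3 == "conserved_all")
  )
}
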