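#' Gene-level prior odds from case/control rare-variant burdens
#'
#' The prior odds that a rare variant found in an affected individual is
#' pathogenic are estimated from the excess rare-variant burden in cases over
#' controls,
#' \deqn{\mathrm{odds} = \frac{b_{case} - b_{ctrl}}{b_{ctrl}},}
#' where burdens are proportions of individuals carrying a rare variant of
#' the stated class in the gene. A control burden of zero (or missing) is
#' replaced by the minimum observable non-zero frequency before evaluation,
#' on the assumption that the smallest observed frequency corresponds to a
#' single carrier.
#'
#' @param case_burden,control_burden Proportions in \[0, 1\]; `control_burden`
#'   may be `NA`.
#' @param zero_replacement Replacement for a zero or missing control burden.
#' @return Numeric vector of raw prior odds (no truncation applied).
#' @export
#' @examples
#' prior_odds_subtractive(0.1256, 0.0048)  # ~25, KCNH2 non-radical
#' prior_odds_subtractive(0.0392, 0)       # 195, KCNH2 radical
prior_odds_subtractive <- function(case_burden, control_burden,
                                   zero_replacement = 2e-4) {
  if (any(case_burden < 0, na.rm = TRUE) ||
      any(control_burden < 0, na.rm = TRUE)) {
    pp_stop("burdens must be non-negative proportions")
  }
  ctrl <- ifelse(is.na(control_burden) | control_burden == 0,
                 zero_replacement, control_burden)
  (case_burden - ctrl) / ctrl
}

#' Adjustment policy for long QT syndrome prior odds
#'
#' Literature-derived burden estimates for LQTS genes run about twice the
#' yield seen in prospective diagnostic referrals, so literature-sourced
#' prior odds are halved. Any resulting value below the truncation floor is
#' replaced by the floor, because burden estimation is unstable in the low
#' range.
#'
#' @param odds Raw prior odds (from [prior_odds_subtractive()]).
#' @param source `"case_series"` or `"literature"` per element.
#' @param floor Truncation floor (default 0.2).
#' @return Adjusted prior odds.
#' @export
prior_odds_lqts_adjust <- function(odds, source, floor = 0.2) {
  bad <- setdiff(unique(source), c("case_series", "literature"))
  if (length(bad) > 0) {
    pp_stop("unknown burden source: ", paste(bad, collapse = ", "))
  }
  out <- ifelse(source == "literature", odds / 2, odds)
  pmax(out, floor)
}

#' Prior odds under a fixed average control burden
#'
#' For syndromes where per-gene control burdens are too noisy to use
#' directly (HCM and BrS), the benign rare-variant burden is fixed at an
#' average value and the prior odds are the ratio of the literature case
#' burden to that fixed control burden.
#'
#' @param case_burden Proportion of cases carrying a rare variant.
#' @param control_burden Assumed benign burden (default 0.01).
#' @return `case_burden / control_burden`.
#' @export
#' @examples
#' prior_odds_fixed_control(0.375)  # 37.5, MYBPC3 in HCM
prior_odds_fixed_control <- function(case_burden, control_burden = 0.01) {
  if (any(case_burden < 0, na.rm = TRUE)) {
    pp_stop("burdens must be non-negative proportions")
  }
  case_burden / control_burden
}

#' Build the prior odds table from a burden table
#'
#' Applies the per-syndrome policies: for LQTS, prior odds come from the
#' subtractive formula, preferring prospective case-series burden rows where
#' available, halving literature-derived odds and flooring the result; for
#' HCM and BrS, odds are the literature case burden over a fixed 1% control
#' burden. When an HCM/BrS gene has a single (combined) burden row, the same
#' odds are used for both class groups. Each output row records the policy
#' that produced it.
#'
#' @param burdens Burden table: columns `gene`, `syndrome`, `class_group`
#'   (`non_radical`/`radical`), `case_burden`, `control_burden` (may be
#'   `NA`), `source` (`case_series`/`literature`).
#' @param zero_replacement Control-burden zero replacement for LQTS.
#' @param lqts_floor Truncation floor for LQTS prior odds.
#' @param fixed_control Fixed control burden for HCM/BrS.
#' @return Tibble `gene`, `syndrome`, `class_group`, `prior_odds`, `policy`.
#' @export
build_prior_table <- function(burdens, zero_replacement = 2e-4,
                              lqts_floor = 0.2, fixed_control = 0.01) {
  burdens <- as_tibble(burdens)
  required <- c("gene", "syndrome", "class_group", "case_burden",
                "control_burden", "source")
  missing <- setdiff(required, names(burdens))
  if (length(missing) > 0) {
    pp_stop("burden table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(burdens) == 0) {
    return(tibble(gene = character(), syndrome = character(),
                  class_group = character(), prior_odds = numeric(),
                  policy = character()))
  }
  bad_syn <- setdiff(unique(burdens$syndrome), pp_syndromes)
  if (length(bad_syn) > 0) {
    pp_stop("unknown syndrome: ", paste(bad_syn, collapse = ", "))
  }
  bad_grp <- setdiff(unique(burdens$class_group), pp_class_groups)
  if (length(bad_grp) > 0) {
    pp_stop("unknown class_group: ", paste(bad_grp, collapse = ", "))
  }
  dup <- burdens %>%
    count(.data$gene, .data$syndrome, .data$class_group, .data$source) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    pp_stop("duplicate burden rows for: ",
            paste(paste(dup$gene, dup$syndrome, dup$class_group, dup$source,
                        sep = "/"), collapse = ", "))
  }

  per_gene <- function(rows) {
    syndrome <- rows$syndrome[1]
    if (syndrome == "LQTS") {
      out <- purrr::map_dfr(pp_class_groups, function(grp) {
        grows <- rows[rows$class_group == grp, ]
        if (nrow(grows) == 0) {
          pp_stop("LQTS gene ", rows$gene[1], " lacks a burden row for ",
                  "class group ", grp)
        }
        use <- if (any(grows$source == "case_series")) {
          grows[grows$source == "case_series", ][1, ]
        } else {
          grows[grows$source == "literature", ][1, ]
        }
        raw <- prior_odds_subtractive(use$case_burden, use$control_burden,
                                      zero_replacement)
        odds <- prior_odds_lqts_adjust(raw, use$source, floor = lqts_floor)
        policy <- paste0("subtractive/", use$source,
                         if (use$source == "literature") "+halved" else "",
                         if (odds > raw / ifelse(use$source == "literature", 2, 1))
                           "+floored" else "")
        tibble(class_group = grp, prior_odds = odds, policy = policy)
      })
    } else {
      out <- purrr::map_dfr(pp_class_groups, function(grp) {
        grows <- rows[rows$class_group == grp, ]
        use <- if (nrow(grows) > 0) grows[1, ] else rows[1, ]
        tibble(class_group = grp,
               prior_odds = prior_odds_fixed_control(use$case_burden,
                                                     fixed_control),
               policy = paste0("fixed_control/", use$source))
      })
    }
    out$gene <- rows$gene[1]
    out$syndrome <- syndrome
    out
  }

  burdens %>%
    group_by(.data$gene, .data$syndrome) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(per_gene) %>%
    select("gene", "syndrome", "class_group", "prior_odds", "policy") %>%
    arrange(.data$syndrome, .data$gene, .data$class_group)
}

#' Packaged rare-variant burden table for cardiac condition genes
#'
#' Burdens of rare (allele frequency < 0.0005) variants in cases and
#' controls for the 13 LQTS genes, 4 HCM genes and 9 BrS genes, split into
#' radical and non-radical (missense + inframe) class groups. Five LQTS
#' genes carry prospective case-series burdens in addition to literature
#' estimates. Per-class case burdens for the eight literature-only LQTS
#' genes are reconstructed to be consistent with the published control
#' burdens and prior odds (see the fixture file header).
#'
#' @return Burden tibble suitable for [build_prior_table()].
#' @export
cardiac_burden <- function() {
  read_burden_table(system.file("extdata", "cardiac_burden.tsv",
                                package = "pathprob", mustWork = TRUE))
}
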