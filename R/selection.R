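# Single-trait genetic gains and multi-trait selection-index gains.

#' Define a multi-trait selection scenario
#'
#' A named weight vector over traits (weights in `[0, 1]` summing to 1) and a
#' selection proportion.
#'
#' @param name Scenario name.
#' @param weights Named numeric weights per trait.
#' @param proportion Selected fraction of candidates.
#' @return List of class `selection_scenario`.
#' @export
selection_scenario <- function(name, weights, proportion = 0.05) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop_input("weights must be named by trait")
  }
  if (any(weights < 0 | weights > 1)) {
    stop_input("weights must lie in [0, 1]")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_input(sprintf("weights must sum to 1 (got %.6f)", sum(weights)))
  }
  if (proportion <= 0 || proportion >= 1) {
    stop_input("proportion must lie in (0, 1)")
  }
  structure(list(name = name, weights = weights, proportion = proportion),
            class = "selection_scenario")
}

#' Standard height-priority selection scenarios S1-S5
#'
#' S1: height alone; S2/S3 add resistance/resilience at weight 0.2 alongside
#' height 0.8; S4/S5 add wood density 0.2 alongside height 0.6 and
#' resistance/resilience 0.2.
#'
#' @param proportion Selected fraction.
#' @return Named list of [selection_scenario()] objects.
#' @export
default_scenarios <- function(proportion = 0.05) {
  list(
    S1 = selection_scenario("S1", c(height = 1), proportion),
    S2 = selection_scenario("S2", c(height = 0.8, resistance = 0.2),
                            proportion),
    S3 = selection_scenario("S3", c(height = 0.8, resilience = 0.2),
                            proportion),
    S4 = selection_scenario("S4", c(height = 0.6, wood_density = 0.2,
                                    resistance = 0.2), proportion),
    S5 = selection_scenario("S5", c(height = 0.6, wood_density = 0.2,
                                    resilience = 0.2), proportion)
  )
}

# Deterministic top fraction: descending score, ties broken by ascending id.
select_top <- function(ids, score, proportion) {
  n_sel <- ceiling(proportion * length(ids))
  ord <- order(-score, ids)
  ids[ord][seq_len(n_sel)]
}

#' Genetic gain from single-trait truncation selection
#'
#' Gain (%) = 100 x mean EBV of the top `proportion` of candidates (ranked by
#' EBV) divided by the trait's phenotypic mean.
#'
#' @param ebv Tibble with columns `id`, `ebv` (or a named numeric vector).
#' @param phenotypic_mean Trait phenotypic mean on the measurement scale.
#' @param proportion Selected fraction (default 0.05, the top 5%).
#' @return One-row tibble with `gain_pct`, `n_selected` and the selected ids
#'   in attribute `"selected"`.
#' @export
single_trait_gain <- function(ebv, phenotypic_mean, proportion = 0.05) {
  if (is.numeric(ebv) && !is.null(names(ebv))) {
    ebv <- tibble(id = names(ebv), ebv = unname(ebv))
  }
  check_columns(ebv, c("id", "ebv"), "EBV table")
  if (!is_number(phenotypic_mean) || phenotypic_mean == 0) {
    stop_input("phenotypic mean is zero; report absolute gains instead of %")
  }
  if (ceiling(proportion * nrow(ebv)) < 1L) {
    stop_input("selection proportion selects no individuals")
  }
  sel <- select_top(ebv$id, ebv$ebv, proportion)
  gain <- 100 * mean(ebv$ebv[ebv$id %in% sel]) / phenotypic_mean
  out <- tibble(gain_pct = gain, n_selected = length(sel))
  attr(out, "selected") <- sel
  out
}

#' Per-trait genetic gains under a multi-trait selection index
#'
#' Ranks candidates by the weighted sum of per-trait breeding values
#' (standardized to unit variance by default, so weights are
#' scale-independent; `standardize = FALSE` combines raw-scale EBVs) and
#' reports, for every trait in the table, the mean EBV of the selected top
#' fraction as a percentage of that trait's phenotypic mean.
#'
#' @param ebv_table Tibble with an `id` column and one EBV column per trait.
#' @param scenario A [selection_scenario()].
#' @param trait_means Named phenotypic means for every trait in `ebv_table`.
#' @param standardize Standardize EBVs to unit variance before weighting.
#' @return Object of class `gs_gain`: tibble (`scenario`, `trait`,
#'   `gain_pct`) with the selected ids in attribute `"selected"`.
#' @export
index_gains <- function(ebv_table, scenario, trait_means,
                        standardize = TRUE) {
  check_columns(ebv_table, "id", "EBV table")
  traits <- setdiff(names(ebv_table), "id")
  w_traits <- names(scenario$weights)
  missing_tr <- setdiff(w_traits, traits)
  if (length(missing_tr) > 0L) {
    stop_input(sprintf("EBV table lacks weighted trait(s): %s",
                       paste(missing_tr, collapse = ", ")))
  }
  na_rows <- !complete.cases(ebv_table[, w_traits, drop = FALSE])
  if (any(na_rows)) {
    stop_input(sprintf("missing EBVs for tree(s): %s",
                       paste(head(ebv_table$id[na_rows], 5L), collapse = ", ")))
  }
  missing_means <- setdiff(traits, names(trait_means))
  if (length(missing_means) > 0L) {
    stop_input(sprintf("trait_means lacks: %s",
                       paste(missing_means, collapse = ", ")))
  }
  si <- rep(0, nrow(ebv_table))
  for (tr in w_traits) {
    v <- ebv_table[[tr]]
    if (standardize) {
      s <- sd(v)
      if (s > 0) v <- v / s
    }
    si <- si + scenario$weights[[tr]] * v
  }
  sel <- select_top(ebv_table$id, si, scenario$proportion)
  in_sel <- ebv_table$id %in% sel
  gains <- vapply(traits, function(tr) {
    m <- trait_means[[tr]]
    if (!is.finite(m) || m == 0) return(NA_real_)
    100 * mean(ebv_table[[tr]][in_sel]) / m
  }, numeric(1))
  out <- tibble(scenario = scenario$name, trait = traits,
                gain_pct = unname(gains))
  attr(out, "selected") <- sel
  class(out) <- c("gs_gain", class(out))
  out
}

#' Compare selection scenarios, including single-trait references
#'
#' Runs [index_gains()] for every scenario plus one single-trait truncation
#' reference per trait, and reports the overlap of selected sets.
#'
#' @inheritParams index_gains
#' @param scenarios List of [selection_scenario()] objects (unique names).
#' @param proportion Selection fraction for the single-trait references.
#' @return Tibble (`scenario`, `trait`, `gain_pct`) with the selected-set
#'   overlap matrix in attribute `"overlap"`.
#' @export
compare_scenarios <- function(ebv_table, scenarios, trait_means,
                              proportion = 0.05, standardize = TRUE) {
  nm <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop_input("duplicate scenario names")
  traits <- setdiff(names(ebv_table), "id")
  single <- lapply(traits, function(tr) {
    keep <- is.finite(ebv_table[[tr]])
    g <- single_trait_gain(
      tibble(id = ebv_table$id[keep], ebv = ebv_table[[tr]][keep]),
      trait_means[[tr]], proportion
    )
    out <- tibble(scenario = "single_trait", trait = tr,
                  gain_pct = g$gain_pct)
    attr(out, "selected") <- attr(g, "selected")
    out
  })
  multi <- lapply(scenarios, index_gains, ebv_table = ebv_table,
                  trait_means = trait_means, standardize = standardize)
  sel_sets <- c(setNames(lapply(single, attr, "selected"),
                         paste0("single_", traits)),
                setNames(lapply(multi, attr, "selected"), nm))
  overlap <- outer(seq_along(sel_sets), seq_along(sel_sets),
                   Vectorize(function(i, j) {
                     length(intersect(sel_sets[[i]], sel_sets[[j]]))
                   }))
  dimnames(overlap) <- list(names(sel_sets), names(sel_sets))
  out <- dplyr::bind_rows(c(single, multi))
  attr(out, "overlap") <- overlap
  out
}
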